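#!/usr/bin/env Rscript
# Reaction-time task: error-trial confidence rises with coherence when choice
# and confidence are reported together, but falls (sometimes below 0.5) when
# confidence is reported after the choice and post-decision observations from
# the 250 ms non-decision time revise it.

library(pomdpconf)
dir.create("results", showWarnings = FALSE)

e <- run_rt_confidence(n_per_coherence = 5000L, seed = 20260501L)
write_experiment_report(e, "results")
print(e)

for (mode in c("simultaneous", "sequential")) {
  d <- e$results[e$results$mode == mode & e$results$coherence > 0 &
                   e$results$n_error > 0, ]
  sl <- coef(lm(conf_error ~ coherence, data = d, weights = d$n_error))[2]
  cat(sprintf("%s report: error-confidence slope vs coherence = %+.2f\n",
              mode, sl))
}
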