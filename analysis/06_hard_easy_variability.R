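#!/usr/bin/env Rscript
# Two dissociations that follow from the decision maker's incomplete
# knowledge of the stimulus statistics:
#  - hard-easy effect: marginalising over unknown stimulus strength makes
#    confidence exceed accuracy on hard trials and lag it on easy ones;
#  - stimulus-variability effect: raising the true observation noise while
#    the learned noise stays fixed lowers accuracy but raises confidence and
#    sure-bet rejections.

library(pomdpconf)
dir.create("results", showWarnings = FALSE)

he <- run_hard_easy(config = task_config(n_trials = 40000L), seed = 20260601L)
write_experiment_report(he, "results")
print(he)

va <- run_variability(config = task_config(n_trials = 40000L), seed = 20260602L)
write_experiment_report(va, "results")
print(va)

nz <- he$results[he$results$coherence > 0, ]
cat(sprintf(
  "\nHard-easy: at %.1f%% coherence confidence %.2f vs accuracy %.2f (over); at %.1f%% confidence %.2f vs accuracy %.2f (under).\n",
  100 * nz$coherence[1], nz$mean_confidence[1], nz$accuracy[1],
  100 * nz$coherence[nrow(nz)], nz$mean_confidence[nrow(nz)],
  nz$accuracy[nrow(nz)]))
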