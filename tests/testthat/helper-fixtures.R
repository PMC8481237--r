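# shared fixtures: parameter sets and small simulated tables built in code

m1 <- function(...) monkey_params("M1", ...)

# balanced two-sided single-coherence stimulus set
two_sided_trials <- function(n, coherence, steps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(coherence = sample(c(-coherence, coherence), n, replace = TRUE),
             duration_steps = as.integer(steps), sure_shown = FALSE)
}

# closed-form confidence as a function of the observation sum (independent of
# the package's belief plumbing): Phi(|S| / sqrt(t sigma_z^2 + sigma_z^4/sigma_0^2))
conf_from_sum <- function(S, t, sigma_z, sigma_0) {
  pnorm(abs(S) / sqrt(t * sigma_z^2 + sigma_z^4 / sigma_0^2))
}
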