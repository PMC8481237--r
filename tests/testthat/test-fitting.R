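# choices of the zero-cost agent have right-choice probability
# Phi(sqrt(t) c / w_z); generating from that Bernoulli law is exactly
# equivalent to simulating the observation streams and taking the sign
bernoulli_choice_table <- function(n, w_z, seed,
                                   levels = c(0.016, 0.032, 0.064, 0.128,
                                              0.256, 0.512)) {
  set.seed(seed)
  coh <- sample(c(-levels, levels), n, replace = TRUE)
  t <- sample(10:90, n, replace = TRUE)
  p_right <- pnorm(sqrt(t) * coh / w_z)
  data.frame(coherence = coh, duration_steps = t, sure_shown = FALSE,
             choice = ifelse(runif(n) < p_right, "right", "left"))
}

test_that("fit_wz recovers the generating observation noise", {
  d <- bernoulli_choice_table(50000, w_z = 0.90, seed = 31)
  fit <- fit_wz(d)
  expect_lt(abs(fit$w_z_hat - 0.90) / 0.90, 0.02)
  expect_true(is.finite(fit$se) && fit$se < 0.05)
  expect_false(fit$boundary)
  # likelihood ordering: truth beats a doubled parameter
  negll <- function(w) {
    p <- pnorm(sqrt(d$duration_steps) * d$coherence / w)
    sum(dbinom(d$choice == "right", 1, p, log = TRUE))
  }
  expect_gt(negll(0.90), negll(1.80))
})

test_that("chance-level choices push w_z to the boundary with a warning", {
  set.seed(32)
  d <- data.frame(coherence = sample(c(-0.128, 0.128), 2000, TRUE),
                  duration_steps = 40L, sure_shown = FALSE,
                  choice = sample(c("left", "right"), 2000, TRUE))
  expect_warning(fit <- fit_wz(d), "boundary")
  expect_true(fit$boundary)
})

test_that("estimate_prior pools per-trial draws into a Gaussian MLE", {
  cfg <- task_config(n_trials = 50000L, seed = 33)
  tr <- generate_trials(cfg)
  est <- estimate_prior(tr, noise_sd = 0.9, seed = 34)
  # moment oracle: var(c) + E[w^2 / t]
  v_expect <- mean(tr$coherence^2) - mean(tr$coherence)^2 +
    mean(0.9^2 / tr$duration_steps)
  expect_lt(abs(est$sigma_0_hat - sqrt(v_expect)), 0.01)
  expect_lt(abs(est$mu_0_hat), 3 * sqrt(v_expect / nrow(tr)) + 1e-3)
  # deterministic variant matches the moment formula exactly and is
  # invariant to trial order
  det <- estimate_prior(tr, noise_sd = 0.9, deterministic = TRUE)
  expect_equal(det$sigma_0_hat, sqrt(v_expect), tolerance = 1e-12)
  perm <- tr[sample(nrow(tr)), ]
  expect_equal(estimate_prior(perm, 0.9, deterministic = TRUE)$sigma_0_hat,
               det$sigma_0_hat, tolerance = 1e-12)
  # degenerate single-coherence design: sigma_0 collapses to the noise scale
  tr0 <- data.frame(coherence = 0, duration_steps = 40L)[rep(1, 20000), ]
  est0 <- estimate_prior(tr0, noise_sd = 0.9, seed = 35)
  expect_lt(abs(est0$sigma_0_hat - 0.9 / sqrt(40)), 0.01)
  expect_lt(abs(est0$mu_0_hat), 0.01)
})

test_that("fit_sigma_z reduces to the flat-prior oracle when sigma_0 is huge", {
  d <- bernoulli_choice_table(20000, w_z = 0.90, seed = 36)
  fit <- fit_sigma_z(d, w_z = 0.90, sigma_0 = 1e8, seed = 37)
  # oracle with the sigma_0 term dropped entirely: Phi(S / (sigma_z sqrt(t)))
  set.seed(37)
  s <- rnorm(nrow(d), d$duration_steps * d$coherence,
             sqrt(d$duration_steps) * 0.90)
  y <- d$choice == "right"
  negll_flat <- function(sz) {
    p <- pmin(pmax(pnorm(s / (sz * sqrt(d$duration_steps))), 1e-12), 1 - 1e-12)
    -sum(dbinom(y, 1, p, log = TRUE))
  }
  oracle <- optimize(negll_flat, c(0.05, 20), tol = 1e-6)$minimum
  expect_equal(fit$sigma_z_hat, oracle, tolerance = 1e-3)
})

test_that("evidence-independent choices leave sigma_z unidentified", {
  set.seed(38)
  d <- data.frame(coherence = sample(c(-0.128, 0.128), 500, TRUE),
                  duration_steps = 40L,
                  choice = sample(c("left", "right"), 500, TRUE))
  expect_warning(fit_sigma_z(d, w_z = 1, sigma_0 = 1e6, seed = 39), "flat")
})

test_that("prior/noise iteration converges quickly and is seed-stable", {
  cfg <- task_config(n_trials = 30000L, seed = 40)
  sim <- simulate_fixed_duration(generate_trials(cfg), m1(), seed = 41)
  sim <- sim[!sim$sure_shown, ]
  fit <- iterate_prior_noise(sim, w_z = 0.90, seed = 42)
  expect_true(fit$converged)
  expect_lt(fit$n_iterations, 5)
  # basin check: different estimation seeds land on the same fixed point
  fit2 <- iterate_prior_noise(sim, w_z = 0.90, seed = 142)
  expect_lt(abs(fit2$sigma_0_hat - fit$sigma_0_hat) / fit$sigma_0_hat, 0.05)
  expect_lt(abs(fit2$sigma_z_hat - fit$sigma_z_hat) / fit$sigma_z_hat, 0.05)
  # a tight-tolerance rerun from the converged value exits immediately
  fit3 <- iterate_prior_noise(sim, w_z = 0.90, tol = 0.05, seed = 42)
  expect_lte(fit3$n_iterations, 2)
})

test_that("fit_utility_ratio recovers the wagering threshold", {
  p <- m1()  # true ratio 0.63
  cfg <- task_config(n_trials = 50000L, seed = 43)
  sim <- simulate_fixed_duration(generate_trials(cfg), p, seed = 44)
  fit <- fit_utility_ratio(sim, p)
  expect_lt(abs(fit$utility_ratio_hat - 0.63), 0.02)
  expect_error(fit_utility_ratio(sim[!sim$sure_shown, ], p), "sure")
  # a ratio at the confidence floor predicts (almost) no opt-outs
  thr <- surebet_thresholds_on_sum(p, utility_ratio = 0.5001, t = 40)[2]
  expect_lt(pnorm(thr, 0, sqrt(40) * p$w_z) - pnorm(-thr, 0, sqrt(40) * p$w_z),
            1e-3)
  # model-implied P(sure) falls with coherence and duration
  p_sure <- function(cc, t) {
    th <- surebet_thresholds_on_sum(p, t = t)[2]
    pnorm(th, t * cc, sqrt(t) * p$w_z) - pnorm(-th, t * cc, sqrt(t) * p$w_z)
  }
  expect_gt(p_sure(0.032, 40), p_sure(0.256, 40))
  expect_gt(p_sure(0.128, 20), p_sure(0.128, 80))
})

test_that("particle-filter likelihood converges to the zero-cost closed form", {
  p <- m1()
  p$utility_ratio <- NULL
  set.seed(45)
  d <- bernoulli_choice_table(2000, w_z = 0.90, seed = 45,
                              levels = c(0.064, 0.128, 0.256))
  d$duration_steps <- sample(c(20L, 40L), nrow(d), TRUE)
  pf <- particle_filter_loglik(d, p, n_particles = 20000L, seed = 46)
  p_cf <- pnorm(sqrt(d$duration_steps) * d$coherence / p$w_z)
  ll_cf <- sum(dbinom(d$choice == "right", 1, p_cf, log = TRUE))
  expect_lt(abs(pf$loglik - ll_cf) / abs(ll_cf), 0.01)
  # per-cell particle frequencies track the analytic probabilities
  cf_cell <- pnorm(sqrt(pf$by_cell$duration_steps) * pf$by_cell$coherence / p$w_z)
  expect_lt(max(abs(pf$by_cell$p_right - cf_cell)), 0.015)
  # estimator spread shrinks with the particle count
  lls <- function(np) vapply(1:6, function(s)
    particle_filter_loglik(d, p, n_particles = np, seed = 100 + s)$loglik,
    numeric(1))
  expect_lt(sd(lls(4000)), sd(lls(250)))
})

test_that("grid search places zero-cost data at the zero-cost corner", {
  d <- bernoulli_choice_table(4000, w_z = 0.90, seed = 47,
                              levels = c(0.064, 0.128, 0.256))
  d$duration_steps <- sample(c(20L, 40L, 60L), nrow(d), TRUE)
  fit <- grid_search_cost_model(d, cost_grid = c(0, 5e-4, 1e-3),
                                wz_grid = c(0.8, 0.9, 1.0),
                                n_particles = 4000L, seed = 48)
  expect_lte(fit$cost_hat, 5e-4)          # at or adjacent to the truth
  expect_lt(abs(fit$w_z_hat - 0.9), 0.11) # within one grid cell
  expect_equal(nrow(fit$surface), 9L)
  expect_true(all(is.finite(fit$surface$loglik)))
})

test_that("Vuong's statistic matches a hand-computed five-trial example", {
  ll1 <- c(-0.9, -1.2, -0.4, -1.1, -0.7)
  ll2 <- c(-1.0, -1.0, -0.6, -0.9, -1.1)
  # spreadsheet-style arithmetic, written out independently of the function
  llr <- c(0.1, -0.2, 0.2, -0.2, 0.4)
  lr_pen <- sum(llr) - 0.5 * (3 - 2) * log(5)
  w_manual <- sqrt(sum(llr^2) / 5 - mean(llr)^2)
  z_manual <- lr_pen / (sqrt(5) * w_manual)
  out <- vuong_test(ll1, ll2, K1 = 3, K2 = 2)
  expect_equal(out$Z, z_manual, tolerance = 1e-12)
  expect_equal(out$p, 2 * pnorm(-abs(z_manual)), tolerance = 1e-12)
  # unpenalised variant
  out_u <- vuong_test(ll1, ll2, K1 = 3, K2 = 2, penalized = FALSE)
  expect_equal(out_u$LR, sum(llr), tolerance = 1e-12)
  # equal totals with equal parameter counts give Z = 0
  expect_equal(vuong_test(c(-1, -2), c(-2, -1), 1, 1)$Z, 0)
  # identical pointwise likelihoods are degenerate
  expect_error(vuong_test(ll1, ll1, 1, 1), "degenerate")
})

test_that("Vuong's test rarely rejects when the smaller model is true", {
  # nested null: the extra mean parameter fits noise; with the unpenalised
  # ratio (the variant used for the zero- vs nonzero-cost comparison) the
  # larger model should not be preferred significantly
  set.seed(49)
  rejections <- replicate(40, {
    x <- rnorm(200)
    ll_small <- dnorm(x, 0, 1, log = TRUE)
    ll_big <- dnorm(x, mean(x), 1, log = TRUE)
    vuong_test(ll_big, ll_small, K1 = 1, K2 = 0, penalized = FALSE)$p < 0.05
  })
  expect_lt(mean(rejections), 0.2)
})
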