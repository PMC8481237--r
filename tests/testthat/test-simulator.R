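test_that("generate_trials is seed-reproducible with the designed marginals", {
  cfg <- task_config(n_trials = 20000L, seed = 5)
  tr <- generate_trials(cfg)
  expect_identical(tr, generate_trials(cfg))
  # 13 signed levels, each within 3 binomial s.e. of 1/13
  tab <- table(tr$coherence)
  expect_length(tab, 13L)
  se <- sqrt((1 / 13) * (12 / 13) / nrow(tr))
  expect_true(all(abs(tab / nrow(tr) - 1 / 13) < 3 * se))
  # sure bet offered on about half the trials
  expect_lt(abs(mean(tr$sure_shown) - 0.5), 3 * sqrt(0.25 / nrow(tr)))
  # durations are dt multiples inside the stated range
  expect_true(all(tr$duration_ms >= 100 & tr$duration_ms <= 900))
  expect_true(all(tr$duration_ms %% 10 == 0))
  expect_error(task_config(coherence_levels = numeric(0)), "non-empty")
})

test_that("truncated-exponential durations favour short stimuli", {
  cfg <- task_config(n_trials = 20000L, duration_distribution = "truncexp",
                     seed = 6)
  tr <- generate_trials(cfg)
  expect_lt(mean(tr$duration_ms), 500)  # uniform mean
  expect_true(all(tr$duration_ms >= 100 & tr$duration_ms <= 900))
})

test_that("observation streams have the generative moments", {
  z <- sample_observations(0.128, 10, w_z = 1e-9, seed = 1)
  expect_equal(z, rep(0.128, 10), tolerance = 1e-6)
  z <- sample_observations(0.128, 2e5, w_z = 0.9, seed = 2)
  expect_lt(abs(mean(z) - 0.128), 3 * 0.9 / sqrt(2e5))
  expect_lt(abs(sd(z) - 0.9), 3 * 0.9 / sqrt(2 * 2e5))
  # 40-step sums at c = 0.128, w_z = 0.9: mean 5.12, sd 5.692
  set.seed(3)
  sums <- replicate(3000, sum(sample_observations(0.128, 40, 0.9)))
  expect_lt(abs(mean(sums) - 40 * 0.128), 3 * sqrt(40) * 0.9 / sqrt(3000))
  expect_lt(abs(sd(sums) - sqrt(40) * 0.9), 0.25)
})

test_that("zero-cost fixed-duration choices are the sign of the evidence sum", {
  p <- m1()
  cfg <- task_config(n_trials = 4000L, seed = 8)
  sim <- simulate_fixed_duration(generate_trials(cfg), p, seed = 9)
  dirs <- sim$choice != "sure"
  expect_true(all(sim$decision_step[dirs] == sim$duration_steps[dirs]))
  expect_identical(sim$choice[dirs & sim$sum_z > 0],
                   rep("right", sum(dirs & sim$sum_z > 0)))
  expect_identical(sim$choice[dirs & sim$sum_z < 0],
                   rep("left", sum(dirs & sim$sum_z < 0)))
  # determinism contract
  sim2 <- simulate_fixed_duration(generate_trials(cfg), p, seed = 9)
  expect_identical(sim, sim2)
})

test_that("zero-cost accuracy matches the closed form cell by cell", {
  p <- m1()
  set.seed(10)
  trials <- data.frame(
    coherence = sample(c(-0.256, -0.064, 0.064, 0.256), 40000, TRUE),
    duration_steps = sample(c(20L, 60L), 40000, TRUE),
    sure_shown = FALSE)
  sim <- simulate_fixed_duration(trials, p, seed = 11)
  for (cc in c(0.064, 0.256)) {
    for (t in c(20L, 60L)) {
      i <- abs(sim$coherence) == cc & sim$duration_steps == t
      a <- accuracy_zero_cost(cc, t, p$w_z)
      expect_lt(abs(mean(sim$correct[i]) - a),
                3 * sqrt(a * (1 - a) / sum(i)))
    }
  }
})

test_that("zero-coherence trials are rewarded by a fair coin", {
  p <- m1()
  trials <- data.frame(coherence = 0, duration_steps = 30L,
                       sure_shown = FALSE)[rep(1, 20000), ]
  sim <- simulate_fixed_duration(trials, p, seed = 13)
  expect_lt(abs(mean(sim$correct) - 0.5), 3 * sqrt(0.25 / nrow(sim)))
})

test_that("the belief freezes at the termination bound in fixed duration", {
  p <- monkey_params("M1", cost = 1e-4)
  p$utility_ratio <- NULL
  pol <- compute_termination_bound(p, horizon = 40)
  sim <- simulate_fixed_duration(two_sided_trials(20000, 0.128, 40, seed = 14),
                                 p, pol, seed = 15)
  early <- sim$decision_step < 40
  expect_gt(mean(early), 0.5)  # early stops are common at this cost
  # frozen beliefs sit at or above the bound at their stop step
  gain <- (1 / p$sigma_z^2) / (sim$decision_step / p$sigma_z^2 + 1 / p$sigma_0^2)
  mu_dec <- sim$sum_z * gain
  expect_true(all(abs(mu_dec[early]) >= pol$bound_mu[sim$decision_step[early]] - 1e-9))
  # confidence recomputed from the frozen sum agrees
  expect_equal(sim$confidence,
               conf_from_sum(sim$sum_z, sim$decision_step, p$sigma_z, p$sigma_0),
               tolerance = 1e-9)
  # early stopping trims accuracy relative to the zero-cost closed form
  expect_lt(mean(sim$correct), accuracy_zero_cost(0.128, 40, p$w_z))
})

test_that("wagering follows the confidence/utility-ratio comparison", {
  p <- m1()
  cfg <- task_config(n_trials = 20000L, seed = 16)
  sim <- simulate_fixed_duration(generate_trials(cfg), p, seed = 17)
  expect_true(all(sim$choice[!sim$sure_shown] != "sure"))
  shown <- sim$sure_shown
  expect_identical(sim$choice[shown] == "sure",
                   sim$confidence[shown] <= p$utility_ratio)
  expect_true(all(is.na(sim$correct[sim$choice == "sure"])))
  # opt-out is more frequent on weak and short trials
  byc <- tapply(sim$choice[shown] == "sure", abs(sim$coherence[shown]), mean)
  expect_gt(byc[["0"]], byc[["0.512"]])
})

test_that("reaction-time simulation requires a finite bound", {
  p <- m1()  # zero cost
  expect_error(simulate_reaction_time(data.frame(coherence = 0.1), p),
               "cost > 0")
})

test_that("RT report modes coincide with zero non-decision time", {
  p <- model_params(w_z = 0.4, sigma_z = 0.75, sigma_0 = 5, cost = 2e-3,
                    horizon = 200L)
  pol <- compute_termination_bound(p)
  tr <- data.frame(coherence = rep(c(-0.128, 0.128, 0.512), each = 700))
  a <- simulate_reaction_time(tr, p, pol, non_decision_steps = 0L,
                              report_mode = "simultaneous", seed = 18)
  b <- simulate_reaction_time(tr, p, pol, non_decision_steps = 0L,
                              report_mode = "sequential", seed = 18)
  expect_identical(a, b)
})

test_that("post-decision evidence lowers error confidence, sometimes below 0.5", {
  p <- model_params(w_z = 0.4, sigma_z = 0.75, sigma_0 = 5, cost = 2e-3,
                    horizon = 200L)
  pol <- compute_termination_bound(p)
  tr <- data.frame(coherence = rep(c(-0.256, 0.256), each = 6000))
  sim0 <- simulate_reaction_time(tr, p, pol, report_mode = "simultaneous",
                                 seed = 19)
  sim1 <- simulate_reaction_time(tr, p, pol, report_mode = "sequential",
                                 seed = 19)
  expect_identical(sim0$choice, sim1$choice)  # choice never revised
  err <- !sim0$correct
  expect_gt(sum(err), 10)
  expect_lt(mean(sim1$confidence[err]), mean(sim0$confidence[err]))
  expect_gt(sum(sim1$confidence[err] < 0.5), 0)
  # decisions come faster on stronger stimuli
  expect_lt(mean(sim0$rt_ms[abs(sim0$coherence) == 0.256]),
            mean(simulate_reaction_time(
              data.frame(coherence = rep(c(-0.032, 0.032), each = 2000)),
              p, pol, report_mode = "simultaneous", seed = 20)$rt_ms))
})
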