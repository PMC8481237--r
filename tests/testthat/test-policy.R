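test_that("expected confidence gain is symmetric and monotone", {
  p <- model_params(w_z = 0.9, sigma_z = 2.0, sigma_0 = 1.0)
  mus <- c(0, 0.2, 0.5, 1, 2)
  g1 <- expected_confidence_gain(mus, t = 2, p)
  g1m <- expected_confidence_gain(-mus, t = 2, p)
  expect_equal(g1, g1m, tolerance = 1e-9)
  expect_true(all(g1 > -1e-8))
  # decreasing in |mu| at fixed t
  expect_true(all(diff(g1) < 0))
  # decreasing in t at fixed mu (the entropy argument)
  for (mu in c(0, 0.4)) {
    gt <- vapply(c(1, 3, 6, 12, 24), function(t)
      expected_confidence_gain(mu, t, p), numeric(1))
    expect_true(all(diff(gt) < 0))
  }
})

test_that("quadrature gain matches a Monte-Carlo oracle for both predictives", {
  for (pred in c("posterior", "plugin")) {
    p <- model_params(w_z = 0.9, sigma_z = 2.0, sigma_0 = 1.0,
                      predictive = pred)
    g <- expected_confidence_gain(0, t = 1, p)
    # brute-force oracle: sample the next observation from the model's own
    # predictive, apply the conjugate update, average the new confidence
    set.seed(99)
    n <- 1e6
    var1 <- 1 / (1 / p$sigma_z^2 + 1 / p$sigma_0^2)
    sd_pred <- if (pred == "posterior") sqrt(var1 + p$sigma_z^2) else p$sigma_z
    z <- rnorm(n, 0, sd_pred)
    mu2 <- var1 * z / (var1 + p$sigma_z^2)
    sd2 <- sqrt(1 / (2 / p$sigma_z^2 + 1 / p$sigma_0^2))
    conf2 <- pnorm(abs(mu2) / sd2)
    mc <- mean(conf2) - 0.5
    expect_lt(abs(g - mc), 3 * sd(conf2) / sqrt(n))
  }
})

test_that("zero cost gives no finite termination bound", {
  pol <- compute_termination_bound(m1(), horizon = 30)
  expect_true(all(is.infinite(pol$bound_mu)))
  expect_true(all(is.infinite(pol$bound_V)))
})

test_that("a constant cost yields a collapsing bound on the inferred mean", {
  p <- model_params(w_z = 0.9, sigma_z = 2.0, sigma_0 = 1.0, cost = 1e-3)
  pol <- compute_termination_bound(p, horizon = 40)
  expect_true(all(is.finite(pol$bound_mu)))
  expect_true(all(diff(pol$bound_mu) <= 1e-9))
  # the bound sits where the gain crosses the cost, on the decreasing flank
  mid <- 15
  expect_lt(expected_confidence_gain(pol$bound_mu[mid] + 1e-4, mid, p), 1e-3)
  expect_gt(expected_confidence_gain(pol$bound_mu[mid] - 1e-4, mid, p), 1e-3)
})

test_that("sure-bet thresholds on the sum invert the believed probability", {
  p <- m1()
  expect_equal(surebet_thresholds_on_sum(p, utility_ratio = 0.5, t = 10),
               c(0, 0))
  thr <- surebet_thresholds_on_sum(p, t = 40)
  # independent oracle: numeric root of believed_p_right - ratio
  root <- uniroot(function(s) believed_p_right(s, 40, p) - 0.63,
                  c(0, 50), tol = 1e-10)$root
  expect_equal(thr[2], root, tolerance = 1e-6)
  expect_equal(thr[2], 3.83, tolerance = 1e-3)
  expect_equal(thr[1], -thr[2])
  # higher stimulus variability pushes more mass beyond the fixed thresholds
  t <- 25; cc <- 0.064
  p_out <- function(w) {
    th <- surebet_thresholds_on_sum(p, t = t)[2]
    pnorm(-th, t * cc, sqrt(t) * w) + pnorm(th, t * cc, sqrt(t) * w,
                                            lower.tail = FALSE)
  }
  expect_gt(p_out(1.5), p_out(0.9))
})

test_that("the DDM decision variable is exactly the running observation sum", {
  p <- m1()
  expect_equal(ddm_from_belief(belief_from_sum(0, 10, p), p), 0)
  set.seed(3)
  z <- rnorm(50, 0.1, p$w_z)
  b <- initial_belief(p)
  for (i in seq_along(z)) {
    b <- update_belief(b, z[i], p)
    expect_equal(ddm_from_belief(b, p), sum(z[seq_len(i)]), tolerance = 1e-10)
  }
})

test_that("the DDM bound transform is exact and has the flat-prior limit", {
  p <- monkey_params("M1", cost = 1e-4)
  pol <- compute_termination_bound(p, horizon = 40)
  ddm <- ddm_bound_from_policy(pol, p)
  expect_equal(ddm$bound_V / pol$bound_mu,
               pol$step + p$sigma_z^2 / p$sigma_0^2, tolerance = 1e-12)
  # spot value: Theta'(40) = 0.1 maps to (40 + 2.56/0.2116) * 0.1
  expect_equal((40 + 1.6^2 / 0.46^2) * 0.1, 5.2101, tolerance = 1e-4)
  # sigma_0 -> Inf: Theta(t) -> t * Theta'(t)
  pf <- model_params(w_z = 0.9, sigma_z = 1.6, sigma_0 = 1e6, cost = 1e-4)
  polf <- compute_termination_bound(pf, horizon = 10)
  ddmf <- ddm_bound_from_policy(polf, pf)
  expect_equal(ddmf$bound_V, polf$step * polf$bound_mu, tolerance = 1e-6)
})

test_that("POMDP and mapped DDM stop at the same step with the same choice", {
  p <- monkey_params("M1", cost = 1e-4)
  tmax <- 40L
  pol <- compute_termination_bound(p, horizon = tmax)
  ddm <- ddm_bound_from_policy(pol, p)
  set.seed(21)
  n <- 10000
  coh <- sample(c(-0.128, 0.128), n, TRUE)
  gain <- (1 / p$sigma_z^2) / (seq_len(tmax) / p$sigma_z^2 + 1 / p$sigma_0^2)
  stops_pomdp <- integer(n); stops_ddm <- integer(n)
  choice_pomdp <- integer(n); choice_ddm <- integer(n)
  for (i in seq_len(n)) {
    z <- rnorm(tmax, coh[i], p$w_z)
    v <- cumsum(z)
    mu <- v * gain
    hp <- which(abs(mu) >= pol$bound_mu)
    hd <- which(abs(v) >= ddm$bound_V)
    stops_pomdp[i] <- if (length(hp)) hp[1] else tmax
    stops_ddm[i] <- if (length(hd)) hd[1] else tmax
    choice_pomdp[i] <- sign(mu[stops_pomdp[i]])
    choice_ddm[i] <- sign(v[stops_ddm[i]])
  }
  expect_identical(stops_pomdp, stops_ddm)
  expect_identical(choice_pomdp, choice_ddm)
})

test_that("one-step stopping beats every fixed-sample-size strategy", {
  # toy instance, H = 8; utilities evaluated under the decision maker's own
  # generative model (c from the prior, observations with sd sigma_z)
  p <- model_params(w_z = 1, sigma_z = 1, sigma_0 = 1, cost = 0.02,
                    horizon = 8L)
  H <- 8L
  pol <- compute_termination_bound(p, horizon = H)
  ddm <- ddm_bound_from_policy(pol, p)
  # fixed-k strategies in closed form: E[conf at k] - cost * k, with the
  # k-step sum marginally N(0, k sigma_z^2 + k^2 sigma_0^2)
  u_fixed <- vapply(1:H, function(k) {
    s_sd <- sqrt(k * p$sigma_z^2 + k^2 * p$sigma_0^2)
    f <- function(s) conf_from_sum(s, k, p$sigma_z, p$sigma_0) *
      dnorm(s, 0, s_sd)
    integrate(f, -8 * s_sd, 8 * s_sd, abs.tol = 1e-10)$value - p$cost * k
  }, numeric(1))
  # one-step policy by simulation under the same subjective model
  set.seed(23)
  n <- 2e5
  c_true <- rnorm(n, 0, p$sigma_0)
  util <- numeric(n)
  for (i in seq_len(n)) {
    v <- cumsum(rnorm(H, c_true[i], p$sigma_z))
    hit <- which(abs(v[1:(H - 1)]) >= ddm$bound_V[1:(H - 1)])
    ts <- if (length(hit)) hit[1] else H
    util[i] <- (sign(v[ts]) == sign(c_true[i])) - p$cost * ts
  }
  expect_gt(mean(util), max(u_fixed) - 3 * sd(util) / sqrt(n))
})

test_that("one-step look-ahead agrees with dynamic programming at the last decision", {
  # at t = H - 1 the look-ahead IS the full Bellman comparison, so the bound
  # must match a brute-force grid evaluation of stop-vs-continue there
  p <- model_params(w_z = 1, sigma_z = 1, sigma_0 = 1, cost = 0.02,
                    horizon = 8L)
  H <- 8L
  ddm <- ddm_bound_from_policy(compute_termination_bound(p, horizon = H), p)
  s_grid <- seq(0, 8, by = 0.01)
  t <- H - 1L
  k <- (1 / p$sigma_z^2) / (t / p$sigma_z^2 + 1 / p$sigma_0^2)
  var_t <- 1 / (t / p$sigma_z^2 + 1 / p$sigma_0^2)
  sd_pred <- sqrt(var_t + p$sigma_z^2)
  zg <- seq(-7 * sd_pred, 7 * sd_pred, length.out = 601)
  wq <- dnorm(zg, sd = sd_pred); wq <- wq / sum(wq)
  cont <- -p$cost + vapply(s_grid, function(s)
    sum(wq * conf_from_sum(s + k * s + zg, H, p$sigma_z, p$sigma_0)),
    numeric(1))
  stopv <- conf_from_sum(s_grid, t, p$sigma_z, p$sigma_0)
  grid_bound <- s_grid[min(which(stopv >= cont))]
  expect_lt(abs(grid_bound - ddm$bound_V[t]), 0.03)
})

test_that("policy maps serialise to tabular text and round-trip", {
  p <- monkey_params("M1", cost = 1e-4)
  pol <- compute_termination_bound(p, horizon = 12)
  path <- tempfile(fileext = ".csv")
  write_policy_map(pol, path)
  back <- read.csv(path)
  expect_equal(names(back), c("step", "bound_mu", "sure_threshold_mu", "bound_V"))
  expect_equal(back$bound_mu, pol$bound_mu, tolerance = 1e-12)
  expect_equal(back$sure_threshold_mu,
               qnorm(0.63) * sqrt(1 / (pol$step / p$sigma_z^2 + 1 / p$sigma_0^2)),
               tolerance = 1e-12)
})
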