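#' Maximum-likelihood estimate of the true observation noise
#'
#' On trials without the sure-bet target and zero observation cost, the
#' probability of a rightward choice is `Phi(sqrt(t) c / w_z)`; `w_z` is
#' estimated by a 1-D bounded MLE of the Bernoulli likelihood of the recorded
#' right-choices. Zero-coherence trials carry no information about `w_z`
#' (their right-choice probability is 0.5 for every `w_z`) and are excluded.
#'
#' @param trials Data frame with `coherence`, `duration_steps` and `choice`
#'   (`"left"`/`"right"`); sure-bet trials should be excluded by the caller.
#' @param interval Search interval for `w_z`.
#' @return A list with `w_z_hat`, `se` (from the observed information),
#'   `loglik`, `n`, and `boundary` (`TRUE` when the estimate sits at the
#'   search limit, flagging unidentifiable data).
#' @export
fit_wz <- function(trials, interval = c(0.05, 10)) {
  keep <- trials$coherence != 0 & trials$choice %in% c("left", "right")
  d <- trials[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("no informative trials for fitting w_z", call. = FALSE)
  y <- d$choice == "right"
  x <- sqrt(d$duration_steps) * d$coherence
  negll <- function(w) {
    p <- stats::pnorm(x / w)
    -sum(stats::dbinom(y, 1, pmin(pmax(p, 1e-12), 1 - 1e-12), log = TRUE))
  }
  opt <- stats::optimize(negll, interval, tol = 1e-7)
  w_hat <- opt$minimum
  boundary <- min(w_hat - interval[1], interval[2] - w_hat) <
    1e-3 * diff(interval)
  if (boundary) {
    warning("w_z estimate at the search boundary; data may be unidentifiable ",
            "(all-correct or all-chance choices)", call. = FALSE)
  }
  h <- 1e-4 * w_hat
  info <- (negll(w_hat + h) - 2 * opt$objective + negll(w_hat - h)) / h^2
  list(w_z_hat = w_hat,
       se = if (is.finite(info) && info > 0) 1 / sqrt(info) else NA_real_,
       loglik = -opt$objective, n = nrow(d), boundary = boundary)
}

#' Estimate the prior belief from the trial mix
#'
#' The prior over signed coherence is taken to be the distribution of
#' per-trial coherence estimates available to the decision maker: for each
#' trial with true coherence `c` and duration `t`, one draw from
#' `Normal(c, noise_sd / sqrt(t))` (the sampling distribution of the mean
#' observation); the pooled draws are fit by a Gaussian MLE.
#'
#' @param trials Data frame with `coherence` and `duration_steps`.
#' @param noise_sd Observation noise used for the draws: `w_z` on the first
#'   pass, the current `sigma_z` estimate on later refinement passes.
#' @param seed Optional seed for the per-trial draws.
#' @param deterministic If `TRUE`, skip the stochastic draws and moment-match
#'   the mixture directly (`mu_0 = mean(c)`,
#'   `sigma_0^2 = var(c) + mean(noise_sd^2 / t)`), a variance-reduced
#'   alternative. Default `FALSE` (one draw per trial).
#' @return A list with `mu_0_hat` and `sigma_0_hat`. The model clamps the
#'   prior mean to 0; `mu_0_hat` is reported for diagnostics only.
#' @export
estimate_prior <- function(trials, noise_sd, seed = NULL, deterministic = FALSE) {
  stopifnot(noise_sd > 0, nrow(trials) > 1L)
  if (deterministic) {
    m2 <- mean(noise_sd^2 / trials$duration_steps)
    mu <- mean(trials$coherence)
    s2 <- mean((trials$coherence - mu)^2) + m2
    return(list(mu_0_hat = mu, sigma_0_hat = sqrt(s2)))
  }
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(nrow(trials), mean = trials$coherence,
                    sd = noise_sd / sqrt(trials$duration_steps))
  list(mu_0_hat = mean(x), sigma_0_hat = sqrt(mean((x - mean(x))^2)))
}

#' Maximum-likelihood estimate of the learned observation noise
#'
#' The decision maker's believed probability of a rightward direction, given
#' an observation sum, is
#' `Phi(sigma_z^-2 sum(z) / sqrt(t sigma_z^-2 + sigma_0^-2))`. Since the
#' subject's internal observations are unavailable, each trial's sum is
#' simulated from the true generative model (`Normal(t c, sqrt(t) w_z)`), and
#' `sigma_z` is estimated by a 1-D MLE of the Bernoulli likelihood of the
#' recorded right-choices under that believed probability.
#'
#' @param trials Data frame with `coherence`, `duration_steps`, `choice`.
#' @param w_z True observation noise (fitted beforehand) used to simulate the
#'   observation sums.
#' @param sigma_0 Prior standard deviation (fixed during this fit).
#' @param seed Seed for the simulated sums (the fit is deterministic given it).
#' @param interval Search interval for `sigma_z`.
#' @return A list with `sigma_z_hat`, `loglik`, `n`, `flat` (`TRUE` when the
#'   likelihood is flat in `sigma_z`, i.e. choices carry no evidence signal).
#' @export
fit_sigma_z <- function(trials, w_z, sigma_0, seed = NULL,
                        interval = c(0.05, 20)) {
  keep <- trials$choice %in% c("left", "right")
  d <- trials[keep, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  t <- d$duration_steps
  s <- stats::rnorm(nrow(d), mean = t * d$coherence, sd = sqrt(t) * w_z)
  y <- d$choice == "right"
  negll <- function(sz) {
    p <- stats::pnorm(s / sqrt(t * sz^2 + sz^4 / sigma_0^2))
    -sum(stats::dbinom(y, 1, pmin(pmax(p, 1e-12), 1 - 1e-12), log = TRUE))
  }
  opt <- stats::optimize(negll, interval, tol = 1e-6)
  # choices carrying no evidence signal drive sigma_z upward without limit
  # (the believed probability flattens to 0.5); an optimum pinned at the top
  # of the search interval marks the fit as unidentifiable
  flat <- interval[2] - opt$minimum < 1e-3 * diff(interval) ||
    negll(interval[2]) - opt$objective < 1e-8 * max(1, opt$objective)
  if (flat) {
    warning("likelihood flat in sigma_z at the search boundary: choices ",
            "appear independent of the evidence", call. = FALSE)
  }
  list(sigma_z_hat = opt$minimum, loglik = -opt$objective, n = nrow(d),
       flat = flat)
}

#' Iterative refinement of the prior and learned noise
#'
#' Alternates [estimate_prior()] (re-drawing per-trial samples with the
#' current noise estimate) and [fit_sigma_z()] until the change in `sigma_0`
#' falls below `tol`. The first prior pass uses `w_z`; later passes use the
#' current `sigma_z`, which is what allows the pair to move away from the raw
#' first-pass values.
#'
#' @param trials Data frame with `coherence`, `duration_steps`, `choice`.
#' @param w_z True observation noise (fixed).
#' @param tol Convergence tolerance on `|delta sigma_0|` ("precision error").
#'   The default `NULL` sets it adaptively to `3 sigma_0 / sqrt(n)`, the
#'   scale of the Monte-Carlo noise the per-trial re-draws leave in the
#'   sigma_0 estimator, below which further changes are indistinguishable
#'   from sampling error.
#' @param max_iter Iteration guard.
#' @param seed Base seed; each pass derives its own sub-seed so the procedure
#'   is deterministic end to end.
#' @return A `pomdp_fit` list: `w_z_hat`, `sigma_0_hat`, `sigma_z_hat`,
#'   `mu_0_hat` (diagnostic), `loglik`, `n_iterations`, `converged`.
#' @export
iterate_prior_noise <- function(trials, w_z, tol = NULL, max_iter = 20L,
                                seed = 1L) {
  stopifnot(is.null(tol) || tol > 0, max_iter >= 1)
  pr <- estimate_prior(trials, w_z, seed = seed)
  sigma_0 <- pr$sigma_0_hat
  sigma_z <- NA_real_
  loglik <- NA_real_
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fz <- fit_sigma_z(trials, w_z, sigma_0, seed = seed + iter)
    sigma_z <- fz$sigma_z_hat
    loglik <- fz$loglik
    pr <- estimate_prior(trials, sigma_z, seed = seed + 1000L + iter)
    delta <- abs(pr$sigma_0_hat - sigma_0)
    sigma_0 <- pr$sigma_0_hat
    eff_tol <- if (is.null(tol)) 3 * sigma_0 / sqrt(nrow(trials)) else tol
    if (delta < eff_tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }
  structure(list(w_z_hat = w_z, sigma_0_hat = sigma_0, sigma_z_hat = sigma_z,
                 mu_0_hat = pr$mu_0_hat, loglik = loglik,
                 n_iterations = iter, converged = converged),
            class = "pomdp_fit")
}

#' @export
print.pomdp_fit <- function(x, ...) {
  cat("POMDP fit:\n")
  for (f in c("w_z_hat", "sigma_0_hat", "sigma_z_hat", "utility_ratio_hat",
              "cost_hat")) {
    if (!is.null(x[[f]]) && !is.na(x[[f]]))
      cat(sprintf("  %s = %.4g\n", f, x[[f]]))
  }
  cat(sprintf("  loglik = %.4f, iterations = %s, converged = %s\n",
              x$loglik, x$n_iterations, x$converged))
  invisible(x)
}

#' Maximum-likelihood estimate of the sure-bet utility ratio
#'
#' The model opts out when its confidence does not exceed the utility ratio,
#' which maps to the symmetric thresholds of [surebet_thresholds_on_sum()] on
#' the observation sum. Under the generative model the sum is
#' `Normal(t c, sqrt(t) w_z)`, so the opt-out probability has the closed form
#' `Phi((theta - tc)/(sqrt(t) w_z)) - Phi((-theta - tc)/(sqrt(t) w_z))`, and
#' the ratio is fit by a 1-D MLE on the sure-shown trials.
#'
#' @param trials Data frame with `coherence`, `duration_steps`, `sure_shown`,
#'   `choice`; only rows with `sure_shown` are used.
#' @param params A [model_params()] carrying the fitted `w_z`, `sigma_z`,
#'   `sigma_0`.
#' @param interval Search interval for the ratio, inside (0.5, 1).
#' @return A list with `utility_ratio_hat`, `loglik`, `n`.
#' @export
fit_utility_ratio <- function(trials, params, interval = c(0.501, 0.999)) {
  d <- trials[trials$sure_shown, , drop = FALSE]
  if (nrow(d) == 0L) stop("no sure-shown trials to fit the utility ratio",
                          call. = FALSE)
  y <- d$choice == "sure"
  t <- d$duration_steps
  m <- t * d$coherence
  s <- sqrt(t) * params$w_z
  scale_t <- sqrt(t * params$sigma_z^2 + params$sigma_z^4 / params$sigma_0^2)
  negll <- function(ratio) {
    theta <- stats::qnorm(ratio) * scale_t
    p <- stats::pnorm((theta - m) / s) - stats::pnorm((-theta - m) / s)
    -sum(stats::dbinom(y, 1, pmin(pmax(p, 1e-12), 1 - 1e-12), log = TRUE))
  }
  opt <- stats::optimize(negll, interval, tol = 1e-7)
  list(utility_ratio_hat = opt$minimum, loglik = -opt$objective, n = nrow(d))
}

#' Full zero-cost fitting pipeline
#'
#' Convenience wrapper chaining [fit_wz()], [iterate_prior_noise()] and
#' [fit_utility_ratio()] on a trial table, mirroring the estimation recipe
#' used for the monkey data.
#'
#' @param trials Simulated or recorded trial table.
#' @param seed Base seed for the stochastic estimation draws.
#' @param tol Convergence tolerance passed to [iterate_prior_noise()].
#' @return A `pomdp_fit` with all four estimates.
#' @export
fit_pipeline <- function(trials, seed = 1L, tol = NULL) {
  no_sure <- trials[!trials$sure_shown, , drop = FALSE]
  fw <- fit_wz(no_sure)
  it <- iterate_prior_noise(no_sure, fw$w_z_hat, tol = tol, seed = seed)
  pars <- model_params(w_z = fw$w_z_hat, sigma_z = it$sigma_z_hat,
                       sigma_0 = it$sigma_0_hat)
  fr <- fit_utility_ratio(trials, pars)
  structure(list(w_z_hat = fw$w_z_hat, w_z_se = fw$se,
                 sigma_0_hat = it$sigma_0_hat, sigma_z_hat = it$sigma_z_hat,
                 mu_0_hat = it$mu_0_hat,
                 utility_ratio_hat = fr$utility_ratio_hat,
                 loglik = fw$loglik + it$loglik + fr$loglik,
                 n_iterations = it$n_iterations, converged = it$converged),
            class = "pomdp_fit")
}

#' Particle-filter estimate of the choice log-likelihood under a bounded policy
#'
#' With a non-zero observation cost there is no closed form for the choice
#' probabilities, so they are estimated by forward-simulating observation
#' streams ("particles") through the bounded policy: for each unique
#' (coherence, duration) cell, `n_particles` streams are run to the bound (or
#' stimulus end) and the frequencies of left/right/sure outcomes estimate the
#' choice probabilities. The trial log-likelihood sums the log-probability of
#' each recorded choice; probabilities are floored at `eps` (logged per cell).
#'
#' @param trials Trial table with `coherence`, `duration_steps`, `choice`,
#'   and `sure_shown`.
#' @param params A [model_params()] (its `cost` defines the bound; its
#'   `utility_ratio` governs sure-bet predictions on sure-shown trials).
#' @param n_particles Streams per (coherence, duration) cell. Default 20000.
#' @param seed Seed for the particle streams.
#' @return A list with `loglik`, `by_cell` (data frame of cell probabilities),
#'   and `n_floored` (count of floored trial probabilities).
#' @export
particle_filter_loglik <- function(trials, params, n_particles = 20000L,
                                   seed = 1L, eps = 1e-6) {
  stopifnot(n_particles >= 1)
  set.seed(seed)
  policy <- compute_termination_bound(params,
                                      horizon = max(trials$duration_steps))
  cells <- unique(trials[, c("coherence", "duration_steps")])
  probs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    coh <- cells$coherence[i]
    d <- cells$duration_steps[i]
    g <- run_bounded_group(rep(coh, n_particles), d, params, policy$bound_mu)
    right <- g$mu_dec > 0
    p_sure_cell <- NA_real_
    p_right_sure <- NA_real_
    if (!is.null(params$utility_ratio)) {
      conf <- stats::pnorm(abs(g$mu_dec) / sqrt(posterior_var(g$tdec, params)))
      sure <- conf <= params$utility_ratio
      p_sure_cell <- mean(sure)
      p_right_sure <- mean(right & !sure)
    }
    probs[[i]] <- data.frame(coherence = coh, duration_steps = d,
                             p_right = mean(right),
                             p_sure = p_sure_cell,
                             p_right_no_sure = p_right_sure)
  }
  by_cell <- do.call(rbind, probs)
  key <- paste(trials$coherence, trials$duration_steps)
  idx <- match(key, paste(by_cell$coherence, by_cell$duration_steps))
  p <- numeric(nrow(trials))
  sure_shown <- trials$sure_shown
  has_ratio <- !is.null(params$utility_ratio)
  for (j in seq_len(nrow(trials))) {
    row <- by_cell[idx[j], ]
    p[j] <- if (has_ratio && sure_shown[j]) {
      switch(trials$choice[j],
             sure = row$p_sure,
             right = row$p_right_no_sure,
             left = 1 - row$p_sure - row$p_right_no_sure)
    } else {
      if (trials$choice[j] == "right") row$p_right else 1 - row$p_right
    }
  }
  floored <- p < eps
  p[floored] <- eps
  list(loglik = sum(log(p)), by_cell = by_cell, n_floored = sum(floored))
}

#' Grid search for the non-zero-cost model
#'
#' Maximises the particle-filter likelihood over a (cost, w_z) grid. At each
#' grid point the prior/learned-noise pair is re-estimated with
#' [iterate_prior_noise()] before the likelihood is evaluated. The published
#' grid resolutions are 1e-5 for cost and 0.01 for `w_z`; callers choose the
#' grid extents (and coarser test-scale grids).
#'
#' @param trials Trial table.
#' @param cost_grid,wz_grid Numeric grids.
#' @param n_particles Particles per cell per grid point.
#' @param seed Base seed.
#' @param refit_inner Re-estimate (`sigma_0`, `sigma_z`) per grid point
#'   (default) or once at the first `w_z`.
#' @return A `pomdp_fit` with `cost_hat`, `w_z_hat`, `sigma_0_hat`,
#'   `sigma_z_hat`, `loglik`, and the full likelihood `surface` data frame.
#' @export
grid_search_cost_model <- function(trials, cost_grid, wz_grid,
                                   n_particles = 2000L, seed = 1L,
                                   refit_inner = TRUE) {
  stopifnot(length(cost_grid) >= 1, length(wz_grid) >= 1,
            all(is.finite(cost_grid)), all(is.finite(wz_grid)))
  no_sure <- trials[!trials$sure_shown, , drop = FALSE]
  surface <- expand.grid(cost = cost_grid, w_z = wz_grid)
  surface$loglik <- NA_real_
  surface$sigma_0 <- NA_real_
  surface$sigma_z <- NA_real_
  inner0 <- NULL
  for (i in seq_len(nrow(surface))) {
    wz <- surface$w_z[i]
    inner <- if (refit_inner || is.null(inner0)) {
      iterate_prior_noise(no_sure, wz, seed = seed + i)
    } else inner0
    if (is.null(inner0)) inner0 <- inner
    pars <- model_params(w_z = wz, sigma_z = inner$sigma_z_hat,
                         sigma_0 = inner$sigma_0_hat,
                         cost = surface$cost[i],
                         utility_ratio = NULL)
    pf <- particle_filter_loglik(no_sure, pars, n_particles = n_particles,
                                 seed = seed + 10000L + i)
    surface$loglik[i] <- pf$loglik
    surface$sigma_0[i] <- inner$sigma_0_hat
    surface$sigma_z[i] <- inner$sigma_z_hat
  }
  best <- which.max(surface$loglik)
  structure(list(cost_hat = surface$cost[best], w_z_hat = surface$w_z[best],
                 sigma_0_hat = surface$sigma_0[best],
                 sigma_z_hat = surface$sigma_z[best],
                 loglik = surface$loglik[best], surface = surface,
                 n_iterations = nrow(surface), converged = TRUE),
            class = "pomdp_fit")
}

#' Vuong's closeness test for non-nested models
#'
#' Compares two fitted models from their pointwise log-likelihoods:
#' `Z = LR / (sqrt(N) w)` with
#' `LR = L1 - L2 - 0.5 (K1 - K2) log N` (the Schwarz-penalised form) or
#' `LR = L1 - L2` when `penalized = FALSE`, and `w` the sample standard
#' deviation (denominator `N`) of the pointwise log-likelihood ratios.
#' Under the null of equivalent models `Z` is asymptotically standard normal.
#'
#' @param ll1,ll2 Pointwise log-likelihood vectors of the two models (same
#'   trials, same order).
#' @param K1,K2 Parameter counts.
#' @param penalized Apply the parameter-count penalty (default `TRUE`).
#' @return A list with `Z`, `p` (two-sided), `LR`, `w`, `N`.
#' @export
vuong_test <- function(ll1, ll2, K1, K2, penalized = TRUE) {
  stopifnot(length(ll1) == length(ll2), length(ll1) > 1)
  llr <- ll1 - ll2
  N <- length(llr)
  w <- sqrt(mean(llr^2) - mean(llr)^2)
  if (w <= 0 || !is.finite(w)) {
    stop("degenerate Vuong test: pointwise log-likelihood ratios have zero ",
         "variance (identical models?)", call. = FALSE)
  }
  LR <- sum(llr) - if (penalized) 0.5 * (K1 - K2) * log(N) else 0
  Z <- LR / (sqrt(N) * w)
  list(Z = Z, p = 2 * stats::pnorm(-abs(Z)), LR = LR, w = w, N = N)
}
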