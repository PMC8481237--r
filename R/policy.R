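#' Expected confidence gain of one more observation
#'
#' For a belief `N(mu, sigma_t)` after `t` observations, the value of looking
#' once more is the expected confidence after absorbing the next observation
#' minus the current confidence,
#' \deqn{E_z[\Phi(|\mu_{t+1}|/\sigma_{t+1})] - \Phi(|\mu_t|/\sigma_t),}
#' where the decision maker draws the next observation from its own predictive
#' distribution: `Normal(mu_t, sqrt(sigma_t^2 + sigma_z^2))` for
#' `predictive = "posterior"` (the belief-conditional marginal) or
#' `Normal(mu_t, sigma_z)` for `"plugin"`. The expectation is evaluated by
#' adaptive quadrature (absolute tolerance 1e-8 on the gain).
#'
#' The gain is symmetric in `mu`, decreases with `|mu|` at fixed `t`, and
#' decreases with `t` at fixed `mu`: late in a trial, or with a strong inferred
#' coherence, another look barely moves the posterior.
#'
#' @param mu Inferred mean(s) of the current belief (vectorised).
#' @param t Number of observations already taken (`t >= 0`; scalar).
#' @param params A [model_params()] object.
#' @return Expected gain(s) in confidence, `>= 0` up to quadrature tolerance.
#' @examples
#' p <- model_params(w_z = 0.9, sigma_z = 2, sigma_0 = 1)
#' expected_confidence_gain(0, t = 1, p)
#' @export
expected_confidence_gain <- function(mu, t, params) {
  stopifnot(length(t) == 1L, t >= 0)
  var_t <- if (t == 0) params$sigma_0^2 else posterior_var(t, params)
  sd_next <- sqrt(posterior_var(t + 1, params))
  sz2 <- params$sigma_z^2
  sd_pred <- switch(params$predictive,
                    posterior = sqrt(var_t + sz2),
                    plugin = params$sigma_z)
  vapply(mu, function(m) {
    integrand <- function(z) {
      mu_next <- (var_t * z + sz2 * m) / (var_t + sz2)
      stats::pnorm(abs(mu_next) / sd_next) * stats::dnorm(z, m, sd_pred)
    }
    val <- tryCatch(
      stats::integrate(integrand, m - 8 * sd_pred, m + 8 * sd_pred,
                       abs.tol = 1e-10, rel.tol = 1e-8,
                       subdivisions = 200L)$value,
      error = function(e) stop(
        sprintf(paste0("quadrature failed for expected confidence gain at ",
                       "mu=%.4g, t=%d (interval +/- 8 predictive sd, ",
                       "abs.tol=1e-10): %s"), m, t, conditionMessage(e)),
        call. = FALSE)
    )
    val - stats::pnorm(abs(m) / sqrt(var_t))
  }, numeric(1))
}

#' Cost-based termination policy
#'
#' One-step look-ahead stopping rule: the model stops gathering observations
#' as soon as the expected confidence gain of the next observation is no
#' larger than its cost in units of the direction reward,
#' `cost / r_direction`. Because the gain falls monotonically with `|mu|`,
#' the rule is a time-varying symmetric bound `Theta'(t)` on the inferred
#' mean: the smallest `|mu|` whose gain is at or below the threshold, found
#' by bisection to `|d mu| < 1e-6`. A zero cost gives infinite bounds (the
#' model never stops early). For a static hidden state and non-decreasing
#' cost this one-step rule is the optimal POMDP policy.
#'
#' The returned map also carries, per step, the sure-bet threshold on `|mu|`
#' (where confidence equals the utility ratio, `qnorm(ratio) * sigma_t`) and
#' the equivalent drift-diffusion bound on the observation sum
#' (`bound_V = (t + sigma_z^2/sigma_0^2) * bound_mu`).
#'
#' @param params A [model_params()] object.
#' @param horizon Number of steps to tabulate (default `params$horizon`).
#' @return A `pomdp_policy`: a data frame with columns `step`, `bound_mu`,
#'   `sure_threshold_mu`, `bound_V`, plus the parameter snapshot as an
#'   attribute.
#' @examples
#' pol <- compute_termination_bound(monkey_params("M1", cost = 1e-4), horizon = 40)
#' head(pol)
#' @export
compute_termination_bound <- function(params, horizon = params$horizon) {
  stopifnot(horizon >= 1)
  steps <- seq_len(horizon)
  threshold <- params$cost / params$r_direction
  bound <- rep(Inf, horizon)
  if (params$cost > 0) {
    for (t in steps) {
      g0 <- expected_confidence_gain(0, t, params)
      if (g0 <= threshold) {
        bound[t] <- 0
        next
      }
      lo <- 0
      hi <- 2
      while (expected_confidence_gain(hi, t, params) > threshold) {
        hi <- hi * 2
        if (hi > 1e4) stop("no finite termination bound found; gain does not ",
                           "fall below cost", call. = FALSE)
      }
      while (hi - lo > 1e-6) {
        mid <- (lo + hi) / 2
        if (expected_confidence_gain(mid, t, params) > threshold) lo <- mid
        else hi <- mid
      }
      bound[t] <- (lo + hi) / 2
    }
  }
  sure_thr <- if (is.null(params$utility_ratio)) rep(NA_real_, horizon) else
    stats::qnorm(params$utility_ratio) * sqrt(posterior_var(steps, params))
  out <- data.frame(
    step = steps,
    bound_mu = bound,
    sure_threshold_mu = sure_thr,
    bound_V = (steps + params$sigma_z^2 / params$sigma_0^2) * bound
  )
  attr(out, "params") <- params
  class(out) <- c("pomdp_policy", "data.frame")
  out
}

#' Sure-bet thresholds on the observation sum
#'
#' Accepting or rejecting the sure bet is a comparison of confidence with the
#' utility ratio, and confidence is monotone in `|sum z|`; the rule therefore
#' maps to a symmetric pair of thresholds on the accumulated observation sum:
#' `+/- qnorm(ratio) * sqrt(t sigma_z^2 + sigma_z^4 / sigma_0^2)`. The sure
#' bet is taken when the sum lies between them.
#'
#' @param params A [model_params()] object.
#' @param utility_ratio Sure-bet to direction utility ratio in `[0.5, 1)`;
#'   defaults to `params$utility_ratio`.
#' @param t Number of observation steps (`>= 1`, vectorised).
#' @return For scalar `t`, a numeric pair `c(lower, upper)`; otherwise a
#'   matrix with one row per `t`.
#' @examples
#' surebet_thresholds_on_sum(monkey_params("M1"), t = 40)  # ~ +/- 3.83
#' @export
surebet_thresholds_on_sum <- function(params, utility_ratio = params$utility_ratio, t) {
  stopifnot(!is.null(utility_ratio), utility_ratio >= 0.5, utility_ratio < 1,
            all(t >= 1))
  theta <- stats::qnorm(utility_ratio) *
    sqrt(t * params$sigma_z^2 + params$sigma_z^4 / params$sigma_0^2)
  if (length(t) == 1L) c(-theta, theta) else cbind(lower = -theta, upper = theta)
}

#' Drift-diffusion decision variable of a belief
#'
#' The exact POMDP-to-DDM mapping: `mu_t / sigma_t^2 = sigma_z^-2 V_t`, so the
#' decision variable is `V_t = mu_t sigma_t^-2 sigma_z^2`, which equals the
#' raw running sum of the observations. The map is linear with positive slope
#' at fixed `t`, hence bijective.
#'
#' @param belief A `pomdp_belief` (or list of vectors `mu`, `sigma`).
#' @param params A [model_params()] object.
#' @return The decision-variable value(s) `V_t`.
#' @export
ddm_from_belief <- function(belief, params) {
  belief$mu / belief$sigma^2 * params$sigma_z^2
}

#' Drift-diffusion bound equivalent to a POMDP policy
#'
#' Transforms the termination bound on the inferred mean into the equivalent
#' time-varying bound on the accumulated evidence:
#' `Theta(t) = Theta'(t) / (sigma_z^-2 sigma_t^2) = (t + sigma_z^2/sigma_0^2) Theta'(t)`.
#' A DDM run with `Theta(t)` on a given observation stream stops at the same
#' step with the same choice as the POMDP with `Theta'(t)`.
#'
#' @param policy A `pomdp_policy` from [compute_termination_bound()].
#' @param params The same [model_params()] the policy was computed with.
#' @return A data frame with columns `step` and `bound_V`.
#' @export
ddm_bound_from_policy <- function(policy, params) {
  stopifnot(inherits(policy, "pomdp_policy"))
  data.frame(
    step = policy$step,
    bound_V = (policy$step + params$sigma_z^2 / params$sigma_0^2) * policy$bound_mu
  )
}

#' Write a policy map as delimited text
#'
#' @param policy A `pomdp_policy`.
#' @param path Output file path (CSV, UTF-8, dot decimal).
#' @return `path`, invisibly.
#' @export
write_policy_map <- function(policy, path) {
  stopifnot(inherits(policy, "pomdp_policy"))
  utils::write.csv(as.data.frame(policy), path, row.names = FALSE)
  invisible(path)
}
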