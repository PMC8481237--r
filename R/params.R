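#' Model parameters for the POMDP decision maker
#'
#' Bundles every scalar constant of the model: the true per-step observation
#' noise of the stimulus, the decision maker's learned observation noise and
#' prior, the per-observation cost, reward utilities, and the time base.
#'
#' Signed motion coherence is represented as a dimensionless fraction
#' (`0.128` corresponds to 12.8% coherent motion, positive = rightward), and
#' time as integer steps of `dt_ms` milliseconds (10 ms by default). Momentary
#' observations are draws from `Normal(c, w_z)`; the decision maker instead
#' attributes standard deviation `sigma_z` to them and starts each trial from
#' the prior belief `Normal(0, sigma_0)` over the signed coherence.
#'
#' @param w_z True observation standard deviation per step (> 0).
#' @param sigma_z Learned observation standard deviation the decision maker
#'   attributes to its inputs (> 0).
#' @param sigma_0 Standard deviation of the Gaussian prior belief (> 0).
#' @param mu_0 Prior mean; fixed at 0 for the symmetric task. A nonzero value
#'   is rejected: the model clamps the prior mean to 0 (estimation routines
#'   may report a nonzero sample mean, which is logged, not used).
#' @param cost Cost (negative utility) per observation taken, including the
#'   first; `0` means observations are free and the model never stops early.
#' @param r_direction Utility of a correct direction choice.
#' @param utility_ratio Ratio of the sure-bet utility to `r_direction`,
#'   in (0.5, 1); `NULL` when the task has no sure-bet option.
#' @param dt_ms Step duration in milliseconds.
#' @param horizon Maximum number of observation steps in a trial.
#' @param predictive Distribution the decision maker assumes for its next
#'   observation when evaluating whether another look is worth its cost:
#'   `"posterior"` (default) uses the belief-conditional marginal
#'   `Normal(mu_t, sqrt(sigma_t^2 + sigma_z^2))`; `"plugin"` uses
#'   `Normal(mu_t, sigma_z)`, i.e. plugs the posterior mean in as if it were
#'   the true coherence.
#'
#' @return An object of class `pomdp_params` (a validated list).
#' @examples
#' model_params(w_z = 0.90, sigma_z = 1.60, sigma_0 = 0.46, utility_ratio = 0.63)
#' @export
model_params <- function(w_z, sigma_z, sigma_0, mu_0 = 0, cost = 0,
                         r_direction = 1, utility_ratio = NULL,
                         dt_ms = 10, horizon = 90,
                         predictive = c("posterior", "plugin")) {
  predictive <- match.arg(predictive)
  stopifnot(
    is.numeric(w_z), length(w_z) == 1L, is.finite(w_z), w_z > 0,
    is.numeric(sigma_z), length(sigma_z) == 1L, is.finite(sigma_z), sigma_z > 0,
    is.numeric(sigma_0), length(sigma_0) == 1L, is.finite(sigma_0), sigma_0 > 0,
    is.numeric(cost), length(cost) == 1L, is.finite(cost), cost >= 0,
    is.numeric(r_direction), length(r_direction) == 1L, r_direction > 0,
    is.numeric(dt_ms), length(dt_ms) == 1L, dt_ms > 0,
    is.numeric(horizon), length(horizon) == 1L, horizon >= 1
  )
  if (!identical(mu_0, 0) && !(is.numeric(mu_0) && length(mu_0) == 1L && mu_0 == 0)) {
    stop("mu_0 must be 0: the symmetric task fixes the prior mean at zero", call. = FALSE)
  }
  if (!is.null(utility_ratio)) {
    stopifnot(is.numeric(utility_ratio), length(utility_ratio) == 1L,
              utility_ratio > 0, utility_ratio < 1)
    if (utility_ratio <= 0.5) {
      # confidence never falls below 0.5, so such a ratio makes the sure bet dead weight
      warning("utility_ratio <= 0.5: the sure-bet option will never be chosen",
              call. = FALSE)
    }
  }
  structure(
    list(w_z = w_z, sigma_z = sigma_z, sigma_0 = sigma_0, mu_0 = 0,
         cost = cost, r_direction = r_direction, utility_ratio = utility_ratio,
         dt_ms = dt_ms, horizon = as.integer(horizon), predictive = predictive),
    class = "pomdp_params"
  )
}

#' @export
print.pomdp_params <- function(x, ...) {
  cat("POMDP model parameters\n")
  cat(sprintf("  w_z = %.4g (true obs sd)   sigma_z = %.4g (learned obs sd)\n",
              x$w_z, x$sigma_z))
  cat(sprintf("  prior N(0, %.4g)   cost/obs = %.4g   r_direction = %.4g\n",
              x$sigma_0, x$cost, x$r_direction))
  if (!is.null(x$utility_ratio))
    cat(sprintf("  sure-bet utility ratio = %.4g\n", x$utility_ratio))
  cat(sprintf("  dt = %g ms, horizon = %d steps, predictive = %s\n",
              x$dt_ms, x$horizon, x$predictive))
  invisible(x)
}

#' Reference parameter sets fitted to the two monkeys
#'
#' Convenience constructors for the published parameter values used throughout
#' the simulation experiments: `w_z` 0.90/1.69, `sigma_z` 1.60/3.59, `sigma_0`
#' 0.46/0.87 and utility ratio 0.63/0.59 for subjects M1 and M2.
#'
#' @param subject `"M1"` or `"M2"`.
#' @param ... Overrides passed on to [model_params()] (e.g. `cost`).
#' @return A `pomdp_params` object.
#' @examples
#' monkey_params("M1", cost = 1e-4)
#' @export
monkey_params <- function(subject = c("M1", "M2"), ...) {
  subject <- match.arg(subject)
  defaults <- switch(subject,
    M1 = list(w_z = 0.90, sigma_z = 1.60, sigma_0 = 0.46, utility_ratio = 0.63),
    M2 = list(w_z = 1.69, sigma_z = 3.59, sigma_0 = 0.87, utility_ratio = 0.59)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(model_params, args)
}

# internal: posterior variance after t observations of the conjugate recursion
posterior_var <- function(t, params) {
  1 / (t / params$sigma_z^2 + 1 / params$sigma_0^2)
}

# internal: mu_t = gain(t) * sum(z_1..z_t) for a zero-mean prior
posterior_gain <- function(t, params) {
  (1 / params$sigma_z^2) * posterior_var(t, params)
}
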