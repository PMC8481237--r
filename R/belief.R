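#' Gaussian belief over signed motion coherence
#'
#' The decision maker's posterior over the signed coherence after `t`
#' observations is Gaussian with mean `mu` and standard deviation `sigma`.
#' The running observation sum `sum_z` is carried along because it is the
#' drift-diffusion decision variable under the exact POMDP-to-DDM mapping.
#'
#' @param params A [model_params()] object.
#' @return A `pomdp_belief` object: the prior belief `N(0, sigma_0)` at `t = 0`.
#' @examples
#' b <- initial_belief(monkey_params("M1"))
#' b <- update_belief(b, z = 0.4, monkey_params("M1"))
#' @export
initial_belief <- function(params) {
  structure(list(mu = 0, sigma = params$sigma_0, t = 0L, sum_z = 0),
            class = "pomdp_belief")
}

#' @export
print.pomdp_belief <- function(x, ...) {
  cat(sprintf("belief N(%.5g, %.5g) after %d observations (sum z = %.5g)\n",
              x$mu, x$sigma, x$t, x$sum_z))
  invisible(x)
}

#' Update the belief with one momentary observation
#'
#' Conjugate-Gaussian update: a Gaussian prior and Gaussian likelihood with
#' learned noise `sigma_z` give a Gaussian posterior. The recursive form
#' \deqn{\mu_t = \frac{\sigma_{t-1}^2 z_t + \sigma_z^2 \mu_{t-1}}
#'                    {\sigma_{t-1}^2 + \sigma_z^2}, \qquad
#'       \sigma_t^2 = \frac{\sigma_{t-1}^2 \sigma_z^2}
#'                         {\sigma_{t-1}^2 + \sigma_z^2}}
#' is algebraically identical to the closed form
#' \eqn{\mu_t = \sigma_z^{-2}\sum_j z_j / (t\sigma_z^{-2} + \sigma_0^{-2})},
#' \eqn{\sigma_t^2 = 1/(t\sigma_z^{-2} + \sigma_0^{-2})}; both are computed and
#' checked against each other to relative tolerance 1e-9.
#'
#' @param belief A `pomdp_belief`.
#' @param z A single finite momentary observation.
#' @param params A [model_params()] object.
#' @return The updated `pomdp_belief` with `t + 1` observations absorbed.
#' @export
update_belief <- function(belief, z, params) {
  stopifnot(inherits(belief, "pomdp_belief"))
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z)) {
    stop("observation z must be a single finite number", call. = FALSE)
  }
  v_prev <- belief$sigma^2
  sz2 <- params$sigma_z^2
  mu_rec <- (v_prev * z + sz2 * belief$mu) / (v_prev + sz2)
  var_rec <- v_prev * sz2 / (v_prev + sz2)
  t_new <- belief$t + 1L
  sum_new <- belief$sum_z + z
  mu_closed <- posterior_gain(t_new, params) * sum_new
  var_closed <- posterior_var(t_new, params)
  if (abs(mu_rec - mu_closed) > 1e-9 * max(1, abs(mu_closed)) ||
      abs(var_rec - var_closed) > 1e-9 * max(1, var_closed)) {
    stop("recursive and closed-form belief updates disagree beyond tolerance; ",
         "was the belief produced with the same parameters?", call. = FALSE)
  }
  structure(list(mu = mu_closed, sigma = sqrt(var_closed), t = t_new,
                 sum_z = sum_new),
            class = "pomdp_belief")
}

#' Reconstruct a belief from an observation sum
#'
#' Closed form of the conjugate recursion: the belief after `t` observations
#' depends on them only through their sum.
#'
#' @param sum_z Sum of the `t` observations (vectorised).
#' @param t Number of observations (vectorised, recycled against `sum_z`).
#' @param params A [model_params()] object.
#' @return A `pomdp_belief` when inputs are scalar, otherwise a list of
#'   vectors `mu`, `sigma`, `t`, `sum_z`.
#' @export
belief_from_sum <- function(sum_z, t, params) {
  stopifnot(all(t >= 0))
  n <- max(length(sum_z), length(t))
  scalar <- length(sum_z) == 1L && length(t) == 1L
  sum_z <- rep_len(sum_z, n)
  t <- rep_len(t, n)
  mu <- posterior_gain(pmax(t, 1), params) * sum_z
  sigma <- sqrt(posterior_var(pmax(t, 1), params))
  mu[t == 0] <- 0
  sigma[t == 0] <- params$sigma_0
  if (scalar) {
    structure(list(mu = mu, sigma = sigma, t = as.integer(t), sum_z = sum_z),
              class = "pomdp_belief")
  } else {
    list(mu = mu, sigma = sigma, t = as.integer(t), sum_z = sum_z)
  }
}

#' Confidence of a direction choice
#'
#' The posterior probability that the chosen direction (the sign of the
#' inferred mean) is correct: `Phi(|mu| / sigma)`, which lies in `[0.5, 1)`.
#'
#' @param belief A `pomdp_belief`, or a list with numeric `mu` and `sigma`
#'   (vectorised).
#' @return Probability in `[0.5, 1)`.
#' @examples
#' confidence(belief_from_sum(3.833, 40, monkey_params("M1")))
#' @export
confidence <- function(belief) {
  stats::pnorm(abs(belief$mu) / belief$sigma)
}

#' Believed probability that the direction is rightward
#'
#' `Phi(sigma_z^-2 sum_z / sqrt(t sigma_z^-2 + sigma_0^-2))`: the area of the
#' posterior belief over positive signed coherence. Equals [confidence()] when
#' `sum_z >= 0`, and its complement otherwise. At `t = 0` it is the prior
#' belief, 0.5.
#'
#' @param sum_z Observation sum(s).
#' @param t Number of observations (recycled).
#' @param params A [model_params()] object.
#' @return Probability vector.
#' @export
believed_p_right <- function(sum_z, t, params) {
  stopifnot(all(t >= 0))
  n <- max(length(sum_z), length(t))
  sum_z <- rep_len(sum_z, n)
  t <- rep_len(t, n)
  out <- stats::pnorm(sum_z / params$sigma_z^2 /
                        sqrt(pmax(t, 1) / params$sigma_z^2 +
                               1 / params$sigma_0^2))
  out[t == 0] <- 0.5
  out
}

#' Accuracy of the zero-cost model in closed form
#'
#' With free observations the model uses all `t` samples and chooses the sign
#' of their sum, so the probability of a correct direction choice at signed
#' coherence `c` is `Phi(sqrt(t) |c| / w_z)`. At `c = 0` no direction is
#' correct; ties are rewarded at random, giving 0.5.
#'
#' @param c Signed coherence (fraction; vectorised).
#' @param t Number of observation steps (recycled).
#' @param w_z True observation standard deviation.
#' @return Probability of a correct direction choice.
#' @examples
#' accuracy_zero_cost(0.128, t = 40, w_z = 0.90)  # ~0.816
#' @export
accuracy_zero_cost <- function(c, t, w_z) {
  stopifnot(all(t >= 1), w_z > 0)
  n <- max(length(c), length(t))
  c <- rep_len(c, n)
  t <- rep_len(t, n)
  out <- stats::pnorm(sqrt(t) * abs(c) / w_z)
  out[c == 0] <- 0.5
  out
}

#' Terminal action of the decision maker
#'
#' Utility comparison for the symmetric task: with the sure bet available the
#' model opts out whenever `confidence <= utility_ratio` (the tie goes to the
#' sure bet); otherwise it commits to the direction of the inferred mean. An
#' exactly zero mean is broken by a fair coin.
#'
#' @param belief A `pomdp_belief`.
#' @param params A [model_params()] object; `utility_ratio` must be set when
#'   `sure_available` is `TRUE`.
#' @param sure_available Is the sure-bet target present?
#' @return A list with `action` (`"left"`, `"right"` or `"sure"`) and
#'   `confidence` (the direction confidence; `NA` for the sure bet).
#' @export
select_terminal_action <- function(belief, params, sure_available = FALSE) {
  conf <- confidence(belief)
  if (sure_available) {
    if (is.null(params$utility_ratio)) {
      stop("sure bet offered but params$utility_ratio is NULL", call. = FALSE)
    }
    if (conf <= params$utility_ratio) {
      return(list(action = "sure", confidence = NA_real_))
    }
  }
  action <- if (belief$mu > 0) "right"
            else if (belief$mu < 0) "left"
            else sample(c("left", "right"), 1L)
  list(action = action, confidence = conf)
}
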