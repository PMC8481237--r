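#' Task configuration for the wagering experiment
#'
#' Describes the stimulus side of the direction-discrimination task: the set
#' of coherence magnitudes (sampled with both signs, zero included once), the
#' stimulus-duration distribution, and the probability that the sure-bet
#' target is offered.
#'
#' @param coherence_levels Coherence magnitudes as fractions. Default: the
#'   seven levels 0, 1.6, 3.2, 6.4, 12.8, 25.6 and 51.2%.
#' @param duration_range_ms Two-element range of stimulus durations in ms;
#'   both ends must be multiples of `dt_ms`.
#' @param duration_distribution `"uniform"` over dt-multiples in the range, or
#'   `"truncexp"`, a truncated exponential favouring short durations (the
#'   sampling scheme typical of this task family).
#' @param duration_mean_ms Mean parameter of the exponential before
#'   truncation (used by `"truncexp"` only).
#' @param p_sure_shown Probability the sure-bet target is offered (i.i.d.
#'   Bernoulli per trial).
#' @param n_trials Number of trials.
#' @param dt_ms Observation step in ms.
#' @param seed Optional integer seed making [generate_trials()] reproducible.
#' @return A `pomdp_task_config` list.
#' @export
task_config <- function(coherence_levels = c(0, 0.016, 0.032, 0.064, 0.128, 0.256, 0.512),
                        duration_range_ms = c(100, 900),
                        duration_distribution = c("uniform", "truncexp"),
                        duration_mean_ms = 300,
                        p_sure_shown = 0.5,
                        n_trials = 1000L,
                        dt_ms = 10,
                        seed = NULL) {
  duration_distribution <- match.arg(duration_distribution)
  if (length(coherence_levels) == 0L) {
    stop("coherence_levels must be non-empty", call. = FALSE)
  }
  stopifnot(all(coherence_levels >= 0), all(coherence_levels < 1),
            length(duration_range_ms) == 2L,
            duration_range_ms[1] <= duration_range_ms[2],
            p_sure_shown >= 0, p_sure_shown <= 1,
            n_trials >= 1, dt_ms > 0)
  if (any(duration_range_ms %% dt_ms != 0)) {
    stop("duration_range_ms must be multiples of dt_ms", call. = FALSE)
  }
  structure(list(coherence_levels = sort(unique(coherence_levels)),
                 duration_range_ms = duration_range_ms,
                 duration_distribution = duration_distribution,
                 duration_mean_ms = duration_mean_ms,
                 p_sure_shown = p_sure_shown,
                 n_trials = as.integer(n_trials),
                 dt_ms = dt_ms, seed = seed),
            class = "pomdp_task_config")
}

#' Generate the stimulus side of a trial set
#'
#' Samples signed coherences (each magnitude with both signs, equiprobable
#' over the signed levels), stimulus durations, and sure-bet availability
#' flags. Reproducible given `config$seed`.
#'
#' @param config A [task_config()].
#' @return A data frame with columns `trial`, `coherence`, `duration_ms`,
#'   `duration_steps`, `sure_shown`.
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "pomdp_task_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_trials
  mags <- config$coherence_levels
  signed <- sort(unique(c(mags, -mags)))
  coherence <- sample(signed, n, replace = TRUE)
  steps_range <- config$duration_range_ms / config$dt_ms
  steps <- switch(config$duration_distribution,
    uniform = sample(seq.int(steps_range[1], steps_range[2]), n, replace = TRUE),
    truncexp = {
      grid <- seq.int(steps_range[1], steps_range[2])
      w <- exp(-grid * config$dt_ms / config$duration_mean_ms)
      sample(grid, n, replace = TRUE, prob = w)
    })
  data.frame(
    trial = seq_len(n),
    coherence = coherence,
    duration_ms = steps * config$dt_ms,
    duration_steps = as.integer(steps),
    sure_shown = stats::runif(n) < config$p_sure_shown
  )
}

#' Sample a momentary-evidence stream
#'
#' `t` i.i.d. draws from `Normal(c, w_z)`, the per-step observations delivered
#' by a stimulus of signed coherence `c`.
#'
#' @param c Signed coherence.
#' @param t Number of steps (`>= 1`).
#' @param w_z True observation standard deviation.
#' @param seed Optional seed.
#' @return Numeric vector of length `t`.
#' @export
sample_observations <- function(c, t, w_z, seed = NULL) {
  stopifnot(t >= 1, w_z >= 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(t, mean = c, sd = w_z)
}

# internal: column-wise cumulative sums of a (t x n) matrix without apply()
col_cumsum <- function(m) {
  t <- nrow(m)
  n <- ncol(m)
  cs <- cumsum(as.vector(m))
  if (n > 1L) {
    offs <- c(0, cs[seq.int(t, by = t, length.out = n - 1L)])
    cs <- cs - rep(offs, each = t)
  }
  matrix(cs, nrow = t)
}

# internal: index of first TRUE per column of a logical matrix; 0 if none
first_true_row <- function(h) {
  hit <- colSums(h) > 0L
  idx <- max.col(t(h), ties.method = "first")
  ifelse(hit, idx, 0L)
}

# internal: core bounded-accumulation run for one duration group.
# Returns decision step (bound hit or tmax), frozen mu, post column sums.
run_bounded_group <- function(coh, tmax, params, bound_mu, extra_steps = 0L) {
  n <- length(coh)
  steps_total <- tmax + extra_steps
  z <- matrix(stats::rnorm(n * steps_total,
                           mean = rep(coh, each = steps_total),
                           sd = params$w_z),
              nrow = steps_total)
  cs <- col_cumsum(z)
  tgrid <- seq_len(tmax)
  gain <- posterior_gain(tgrid, params)
  mu <- cs[tgrid, , drop = FALSE] * gain
  b <- bound_mu[tgrid]
  finite_b <- is.finite(b)
  if (any(finite_b)) {
    h <- abs(mu) >= b
    h[!finite_b, ] <- FALSE
    first <- first_true_row(h)
  } else {
    first <- integer(n)
  }
  tdec <- ifelse(first > 0L, first, tmax)
  list(tdec = as.integer(tdec),
       mu_dec = mu[cbind(tdec, seq_len(n))],
       cs = cs)
}

#' Simulate the fixed-duration wagering task
#'
#' Runs the POMDP decision maker over each trial's observation stream. The
#' belief is updated every 10 ms step; if the inferred mean reaches the
#' termination bound the belief freezes (later observations are ignored) but
#' the trial still runs to its full duration, as the response is only cued at
#' the end. The direction choice and its confidence come from the frozen (or
#' final) belief; when the sure-bet target was shown, the model opts out if
#' that confidence does not exceed the utility ratio.
#'
#' @param trials Data frame from [generate_trials()] (needs `coherence`,
#'   `duration_steps`; `sure_shown` optional, defaulting to `FALSE`).
#' @param params A [model_params()] object.
#' @param policy Optional precomputed [compute_termination_bound()] map;
#'   computed on the fly otherwise.
#' @param seed Optional seed for the observation streams (and the c = 0
#'   reward coin).
#' @return The input data frame with columns `choice` (`"left"`, `"right"`,
#'   `"sure"`), `correct` (logical; a fair coin at `c = 0`; `NA` for sure-bet
#'   choices), `confidence` (direction confidence of the frozen belief, kept
#'   also on sure-bet trials), `decision_step`, and `sum_z` (observation sum
#'   at the decision step).
#' @export
simulate_fixed_duration <- function(trials, params, policy = NULL, seed = NULL) {
  stopifnot(is.data.frame(trials),
            all(c("coherence", "duration_steps") %in% names(trials)))
  if (!"sure_shown" %in% names(trials)) trials$sure_shown <- FALSE
  if (!is.null(seed)) set.seed(seed)
  tmax_all <- max(trials$duration_steps)
  if (params$cost > 0 && is.null(policy)) {
    policy <- compute_termination_bound(params, horizon = tmax_all)
  }
  bound <- if (is.null(policy)) rep(Inf, tmax_all) else policy$bound_mu
  if (length(bound) < tmax_all) {
    stop("policy horizon shorter than the longest trial", call. = FALSE)
  }
  n <- nrow(trials)
  tdec <- integer(n)
  mu_dec <- numeric(n)
  for (d in unique(trials$duration_steps)) {
    i <- which(trials$duration_steps == d)
    g <- run_bounded_group(trials$coherence[i], d, params, bound)
    tdec[i] <- g$tdec
    mu_dec[i] <- g$mu_dec
  }
  sigma_dec <- sqrt(posterior_var(tdec, params))
  conf <- stats::pnorm(abs(mu_dec) / sigma_dec)
  dir_right <- mu_dec > 0
  tie <- mu_dec == 0
  if (any(tie)) dir_right[tie] <- stats::runif(sum(tie)) < 0.5
  choice <- ifelse(dir_right, "right", "left")
  if (!is.null(params$utility_ratio)) {
    sure <- trials$sure_shown & conf <= params$utility_ratio
    choice[sure] <- "sure"
  }
  correct <- ifelse(choice == "sure", NA,
                    (dir_right & trials$coherence > 0) |
                      (!dir_right & trials$coherence < 0))
  zero <- trials$coherence == 0 & choice != "sure"
  if (any(zero)) correct[zero] <- stats::runif(sum(zero)) < 0.5
  trials$choice <- choice
  trials$correct <- as.logical(correct)
  trials$confidence <- conf
  trials$decision_step <- tdec
  trials$sum_z <- mu_dec / posterior_gain(tdec, params)
  trials
}

#' Simulate the reaction-time task
#'
#' The trial ends when the inferred mean reaches the termination bound (a
#' positive observation cost is required so the bound is finite; trials that
#' never cross within `params$horizon` are forced to decide there). Under the
#' `"simultaneous"` report mode, confidence is read out at the bound together
#' with the choice. Under `"sequential"` mode, observations arriving during
#' the non-decision time (sensory and motor delay) keep updating the belief,
#' and confidence in the already-committed choice is reported from the later
#' belief: it is the believed probability of the chosen direction and can fall
#' below 0.5 when post-decision evidence contradicts the choice. The choice
#' itself is never revised.
#'
#' @param trials Data frame with a `coherence` column (durations are under
#'   the subject's control here).
#' @param params A [model_params()] with `cost > 0`.
#' @param policy Optional precomputed policy map over `params$horizon` steps.
#' @param non_decision_steps Steps of post-decision stimulus still processed
#'   (default 25 steps = 250 ms at 10 ms resolution).
#' @param report_mode `"simultaneous"` or `"sequential"`.
#' @param seed Optional seed.
#' @return The input data frame plus `choice`, `correct`, `confidence`,
#'   `decision_step` (bound-crossing step), `rt_ms` (decision time plus
#'   non-decision time), and `forced` (horizon reached without crossing).
#' @export
simulate_reaction_time <- function(trials, params, policy = NULL,
                                   non_decision_steps = 25L,
                                   report_mode = c("simultaneous", "sequential"),
                                   seed = NULL) {
  report_mode <- match.arg(report_mode)
  stopifnot(is.data.frame(trials), "coherence" %in% names(trials),
            non_decision_steps >= 0)
  if (params$cost <= 0) {
    stop("reaction-time task requires cost > 0 (otherwise bounds are never ",
         "reached and no response is initiated)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  horizon <- params$horizon
  if (is.null(policy)) policy <- compute_termination_bound(params, horizon = horizon)
  if (!any(is.finite(policy$bound_mu))) {
    stop("policy has no finite bound; reaction-time task requires cost > 0",
         call. = FALSE)
  }
  n <- nrow(trials)
  tdec <- integer(n)
  mu_dec <- numeric(n)
  conf_seq <- numeric(n)
  nd <- as.integer(non_decision_steps)
  for (coh in unique(trials$coherence)) {
    i <- which(trials$coherence == coh)
    g <- run_bounded_group(rep(coh, length(i)), horizon, params,
                           policy$bound_mu, extra_steps = nd)
    tdec[i] <- g$tdec
    mu_dec[i] <- g$mu_dec
    t2 <- g$tdec + nd
    mu2 <- posterior_gain(t2, params) * g$cs[cbind(t2, seq_along(i))]
    sgn <- sign(g$mu_dec)
    sgn[sgn == 0] <- 1
    conf_seq[i] <- stats::pnorm(sgn * mu2 / sqrt(posterior_var(t2, params)))
  }
  forced <- !is.finite(policy$bound_mu[tdec]) |
    abs(mu_dec) < policy$bound_mu[tdec] - 1e-12
  dir_right <- mu_dec > 0
  tie <- mu_dec == 0
  if (any(tie)) dir_right[tie] <- stats::runif(sum(tie)) < 0.5
  conf_sim <- stats::pnorm(abs(mu_dec) / sqrt(posterior_var(tdec, params)))
  correct <- (dir_right & trials$coherence > 0) |
    (!dir_right & trials$coherence < 0)
  zero <- trials$coherence == 0
  if (any(zero)) correct[zero] <- stats::runif(sum(zero)) < 0.5
  trials$choice <- ifelse(dir_right, "right", "left")
  trials$correct <- correct
  trials$confidence <- if (report_mode == "simultaneous") conf_sim else conf_seq
  trials$decision_step <- tdec
  trials$rt_ms <- (tdec + nd) * params$dt_ms
  trials$forced <- forced
  trials
}
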