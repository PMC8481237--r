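#' Stimulus-response-confidence counts for binary ratings
#'
#' Tabulates trials into the eight cells of the equal-variance signal
#' detection layout for a two-choice task with a binary (low/high) confidence
#' rating: stimulus class (left/right) by response (left/right) by rating.
#'
#' @param stimulus Stimulus class per trial: `"left"`/`"right"`, or the sign
#'   of the signed coherence (negative = left).
#' @param choice Response per trial (`"left"`/`"right"`).
#' @param high Logical: high-confidence rating.
#' @return A `confusion_counts` object: a 2 x 4 integer matrix with rows
#'   `stim_left`, `stim_right` and columns `left_low`, `left_high`,
#'   `right_low`, `right_high`.
#' @export
confusion_counts <- function(stimulus, choice, high) {
  if (is.numeric(stimulus)) {
    stopifnot(all(stimulus != 0))
    stimulus <- ifelse(stimulus > 0, "right", "left")
  }
  stopifnot(all(stimulus %in% c("left", "right")),
            all(choice %in% c("left", "right")),
            is.logical(high), length(choice) == length(stimulus),
            length(high) == length(stimulus))
  cell <- paste0(choice, "_", ifelse(high, "high", "low"))
  cols <- c("left_low", "left_high", "right_low", "right_high")
  m <- matrix(0L, 2, 4,
              dimnames = list(c("stim_left", "stim_right"), cols))
  tab <- table(factor(stimulus, c("left", "right")), factor(cell, cols))
  m[] <- as.integer(tab)
  if (any(rowSums(m) == 0L)) {
    stop("both stimulus classes must be present", call. = FALSE)
  }
  structure(m, class = c("confusion_counts", "matrix"))
}

# internal: rate with the log-linear cell correction 1/(2n) applied to
# empty/full cells so probit transforms stay finite
corrected_rate <- function(k, n) {
  r <- k / n
  fix <- r <= 0 | r >= 1
  r[fix] <- (k[fix] + 0.5) / (n[fix] + 1)
  r
}

#' Type-1 sensitivity and criterion
#'
#' Equal-variance signal detection: `d' = z(HR) - z(FAR)` and
#' `c1 = -0.5 (z(HR) + z(FAR))`, with the hit rate the probability of a
#' rightward response to a rightward stimulus and the false-alarm rate the
#' same for a leftward stimulus. Empty or full cells are corrected by the
#' log-linear rule (add 1/2 to the cell, 1 to the class count).
#'
#' @param counts A [confusion_counts()] object.
#' @return A list with `d_prime`, `c1`, `hit_rate`, `fa_rate`.
#' @export
type1_dprime <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- rowSums(counts)
  right_resp <- counts[, "right_low"] + counts[, "right_high"]
  hr <- corrected_rate(right_resp["stim_right"], n["stim_right"])
  far <- corrected_rate(right_resp["stim_left"], n["stim_left"])
  list(d_prime = unname(stats::qnorm(hr) - stats::qnorm(far)),
       c1 = unname(-0.5 * (stats::qnorm(hr) + stats::qnorm(far))),
       hit_rate = unname(hr), fa_rate = unname(far))
}

#' Type-2 sensitivity (meta-d') for binary confidence ratings
#'
#' Finds the sensitivity an equal-variance SDT observer would need so that
#' ideal confidence ratings reproduce the observed confidence-conditional
#' rates `p(high | stimulus, response)`, holding the type-1 criterion at its
#' scaled position `meta_c1 = c1 * meta_d' / d'`. For each candidate meta-d',
#' the two type-2 criteria (one per response side) are profiled out by 1-D
#' likelihood maximisation, and meta-d' itself is a bounded scalar MLE of the
#' response-conditional binomial likelihood of the high/low counts. Degenerate
#' (0 or 1) observed type-2 rates are handled by the same cell correction as
#' [type1_dprime()].
#'
#' @param counts A [confusion_counts()] object.
#' @param interval Search interval for meta-d'.
#' @return A `meta_result` list: `d_prime`, `c1`, `meta_d_prime`, `ratio`
#'   (meta-d'/d', `NA` when `d_prime` is 0), `fit_loglik`, `c2` (the fitted
#'   type-2 criteria), and the observed type-2 rates.
#' @export
meta_dprime <- function(counts, interval = c(1e-3, 10)) {
  stopifnot(inherits(counts, "confusion_counts"))
  t1 <- type1_dprime(counts)
  if (t1$d_prime == 0) {
    warning("d' = 0: meta-d'/d' ratio undefined", call. = FALSE)
  }
  # counts per stimulus (rows: left, right)
  nRh <- counts[, "right_high"]
  nRl <- counts[, "right_low"]
  nLh <- counts[, "left_high"]
  nLl <- counts[, "left_low"]
  cfrac <- t1$c1 / t1$d_prime
  fit_c2 <- function(md) {
    mc1 <- if (t1$d_prime == 0) t1$c1 else cfrac * md
    mus <- c(-md / 2, md / 2)  # stim left, stim right
    nll_right <- function(c2) {
      p_r <- pmax(1 - stats::pnorm(mc1 - mus), 1e-12)
      ph <- pmin(pmax((1 - stats::pnorm(c2 - mus)) / p_r, 1e-9), 1 - 1e-9)
      -sum(nRh * log(ph) + nRl * log(1 - ph))
    }
    nll_left <- function(c2) {
      p_l <- pmax(stats::pnorm(mc1 - mus), 1e-12)
      ph <- pmin(pmax(stats::pnorm(c2 - mus) / p_l, 1e-9), 1 - 1e-9)
      -sum(nLh * log(ph) + nLl * log(1 - ph))
    }
    or <- stats::optimize(nll_right, c(mc1, mc1 + 12), tol = 1e-8)
    ol <- stats::optimize(nll_left, c(mc1 - 12, mc1), tol = 1e-8)
    list(nll = or$objective + ol$objective,
         c2 = c(left = ol$minimum, right = or$minimum))
  }
  opt <- stats::optimize(function(md) fit_c2(md)$nll, interval, tol = 1e-7)
  best <- fit_c2(opt$minimum)
  n_corr_right <- nRh["stim_right"] + nRl["stim_right"]
  n_err_right <- nRh["stim_left"] + nRl["stim_left"]
  structure(list(
    d_prime = t1$d_prime, c1 = t1$c1,
    meta_d_prime = opt$minimum,
    ratio = if (t1$d_prime != 0) opt$minimum / t1$d_prime else NA_real_,
    fit_loglik = -opt$objective,
    c2 = best$c2,
    p_high_correct = unname((nRh["stim_right"] + nLh["stim_left"]) /
      (nRh["stim_right"] + nRl["stim_right"] + nLh["stim_left"] + nLl["stim_left"])),
    p_high_incorrect = unname((nRh["stim_left"] + nLh["stim_right"]) /
      (nRh["stim_left"] + nRl["stim_left"] + nLh["stim_right"] + nLl["stim_right"]))
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("d' = %.3f (c1 = %.3f), meta-d' = %.3f, ratio = %.3f\n",
              x$d_prime, x$c1, x$meta_d_prime, x$ratio))
  cat(sprintf("P(high|correct) = %.3f, P(high|incorrect) = %.3f\n",
              x$p_high_correct, x$p_high_incorrect))
  invisible(x)
}

#' Metacognitive summary of a simulated trial table
#'
#' Convenience wrapper: thresholds confidence into binary ratings and returns
#' the full type-1/type-2 analysis.
#'
#' @param trials Simulated trial table with `coherence`, `choice`,
#'   `confidence` (sure-bet choices are excluded).
#' @param threshold High-confidence threshold applied to the belief.
#' @return A `meta_result` (see [meta_dprime()]) plus `accuracy` and `p_high`.
#' @export
metacognition_summary <- function(trials, threshold) {
  d <- trials[trials$choice %in% c("left", "right") & trials$coherence != 0, ,
              drop = FALSE]
  cc <- confusion_counts(d$coherence, d$choice, d$confidence >= threshold)
  res <- meta_dprime(cc)
  res$accuracy <- mean(d$correct)
  res$p_high <- mean(d$confidence >= threshold)
  res
}
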