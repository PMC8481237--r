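#' Write a trial table as delimited text
#'
#' Comma-separated, UTF-8, dot decimal. Durations and decision times are
#' stored in milliseconds; steps are recomputed on read.
#'
#' @param trials Trial data frame (simulated or recorded). Recognised
#'   columns: `coherence`, `duration_ms` (or `duration_steps`), `sure_shown`,
#'   `choice`, `correct`, `confidence`, `decision_step` (written as
#'   `decision_ms`).
#' @param path Output file path.
#' @param dt_ms Step duration used to convert steps to ms.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, dt_ms = 10) {
  stopifnot(is.data.frame(trials))
  out <- trials
  if (!"duration_ms" %in% names(out) && "duration_steps" %in% names(out)) {
    out$duration_ms <- out$duration_steps * dt_ms
  }
  if ("decision_step" %in% names(out)) {
    out$decision_ms <- out$decision_step * dt_ms
  }
  cols <- intersect(c("coherence", "duration_ms", "sure_shown", "choice",
                      "correct", "confidence", "decision_ms"), names(out))
  utils::write.csv(out[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a trial table
#'
#' Expects the header written by [write_trials()] (required columns
#' `coherence`, `duration_ms`, `sure_shown`, `choice`, `correct`; optional
#' `confidence`, `decision_ms`). Rows violating the schema - a duration that
#' is not a multiple of `dt_ms`, a coherence outside (-1, 1), an unknown
#' choice label, or a sure-bet choice on a trial where the sure target was
#' not shown - are dropped with a warning that lists their line numbers. An
#' empty file yields an empty table with a warning, not an error.
#'
#' @param path CSV file path.
#' @param dt_ms Step duration for the ms-to-steps conversion (must divide
#'   every duration exactly).
#' @return A validated data frame with `duration_steps` (and
#'   `decision_step`, when decision times are present) added.
#' @export
read_trials <- function(path, dt_ms = 10) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("coherence", "duration_ms", "sure_shown", "choice", "correct")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("trial table schema mismatch; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    warning("empty trial table: ", path, call. = FALSE)
    raw$duration_steps <- integer(0)
    return(raw)
  }
  raw$sure_shown <- as.logical(raw$sure_shown)
  raw$correct <- as.logical(raw$correct)
  problems <- character(0)
  bad <- logical(nrow(raw))
  flag <- function(rows, why) {
    if (any(rows)) {
      # +1 for the header: report physical line numbers in the file
      problems <<- c(problems,
                     paste0("line ", which(rows) + 1L, ": ", why))
      bad <<- bad | rows
    }
  }
  flag(!is.finite(raw$coherence) | abs(raw$coherence) >= 1,
       "coherence must be a signed fraction in (-1, 1)")
  flag(!is.finite(raw$duration_ms) | raw$duration_ms <= 0 |
         raw$duration_ms %% dt_ms != 0,
       sprintf("duration_ms must be a positive multiple of %g", dt_ms))
  flag(!raw$choice %in% c("left", "right", "sure"),
       "choice must be left, right or sure")
  flag(raw$choice == "sure" & !raw$sure_shown %in% TRUE,
       "choice is sure but the sure target was not shown")
  if (length(problems) > 0) {
    warning(sprintf("dropped %d invalid row(s):\n  %s", sum(bad),
                    paste(problems, collapse = "\n  ")), call. = FALSE)
  }
  out <- raw[!bad, , drop = FALSE]
  out$duration_steps <- as.integer(out$duration_ms / dt_ms)
  if ("decision_ms" %in% names(out)) {
    out$decision_step <- as.integer(round(out$decision_ms / dt_ms))
  }
  row.names(out) <- NULL
  out
}
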