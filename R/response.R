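#' Increment doses from cumulative readings
#'
#' Active dosemeters accumulate dose across successive irradiations; the dose
#' delivered in one run is the increment between the reading after the run
#' and the reading before it. Vectors must be aligned by dosemeter.
#'
#' @param pre Readings before the run, mSv.
#' @param post Readings after the run, mSv; `post[i] >= pre[i]` since an
#'   accumulated reading cannot decrease.
#' @return Element-wise `post - pre`, mSv.
#' @examples
#' increment_readings(c(1.00, 1.02), c(3.26, 3.30))  # 2.26 2.28
#' @export
increment_readings <- function(pre, post) {
  if (length(pre) != length(post))
    stop("'pre' and 'post' must be aligned by dosemeter (equal length)")
  if (any(!is.finite(pre)) || any(!is.finite(post)))
    stop("readings must be finite")
  if (any(post < pre))
    stop("negative increment: a cumulative reading cannot decrease")
  post - pre
}

#' Response of a single dosemeter in one run
#'
#' The dosemeter response B (mSv per mGy) is the calibrated reading per unit
#' delivered air kerma:
#' `Reading (mSv) x Calibration factor (mSv/mSv) / Reference dose (mGy)`.
#'
#' @param reading Reading in mSv, positive.
#' @param cf Calibration factor (dimensionless), positive.
#' @param reference_kerma Reference air kerma of the run in mGy, positive.
#' @return Response in mSv per mGy. Vectorised.
#' @examples
#' single_response(2.54, 1.00, 2.10)  # 1.2095, the standard-condition response
#' @export
single_response <- function(reading, cf, reference_kerma) {
  if (any(!is.finite(reading)) || any(reading <= 0))
    stop("'reading' must be positive (mSv)")
  if (any(!is.finite(cf)) || any(cf <= 0))
    stop("'cf' must be positive")
  if (any(!is.finite(reference_kerma)) || any(reference_kerma <= 0))
    stop("'reference_kerma' must be positive (mGy)")
  reading * cf / reference_kerma
}

#' Aggregate per-dosemeter responses into a mean response with uncertainty
#'
#' The mean response of a run is the arithmetic mean of the per-dosemeter
#' responses. Spread is summarised on the log scale, consistent with a
#' lognormal response distribution: `sd_log` is the sample standard deviation
#' (n - 1 denominator) of `log(values)` and the multiplicative 95%
#' uncertainty factor is `K = exp(1.96 * sd_log)`. With a single value the
#' spread is undefined and `sd_log`/`K` are `NA`.
#'
#' @param values Per-dosemeter responses in mSv per mGy, all positive.
#' @return A `response_value`: list with `mean_B`, `sd_log`, `K`, `n`.
#' @examples
#' aggregate_response(c(1.15, 1.20, 1.25, 1.20))
#' @export
aggregate_response <- function(values) {
  if (length(values) == 0L)
    stop("'values' must be non-empty")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all response values must be positive")
  n <- length(values)
  sd_log <- if (n >= 2L) stats::sd(log(values)) else NA_real_
  response_value(mean(values), sd_log, n)
}

#' Construct a response value
#'
#' Container for a mean dosemeter response with its log-scale spread. `K` is
#' always derived as `exp(1.96 * sd_log)` so the invariant `K >= 1` holds by
#' construction.
#'
#' @param mean_B Mean response, mSv per mGy, positive.
#' @param sd_log Standard deviation of log response (dimensionless,
#'   non-negative), or `NA` when unknown.
#' @param n Number of dosemeters the value summarises (may be `NA` for
#'   table-driven values).
#' @return Object of class `response_value`.
#' @export
response_value <- function(mean_B, sd_log = NA_real_, n = NA_integer_) {
  if (!is.finite(mean_B) || mean_B <= 0)
    stop("'mean_B' must be positive (mSv per mGy)")
  if (is.finite(sd_log) && sd_log < 0)
    stop("'sd_log' must be non-negative")
  structure(
    list(mean_B = mean_B, sd_log = sd_log,
         K = uncertainty_K(sd_log), n = n),
    class = "response_value")
}

#' Multiplicative 95% uncertainty factor from a log-scale SD
#'
#' @param sd_log Standard deviation of log response.
#' @return `exp(1.96 * sd_log)`; `NA` if `sd_log` is `NA`.
#' @export
uncertainty_K <- function(sd_log) {
  ifelse(is.na(sd_log), NA_real_, exp(1.96 * sd_log))
}

#' @export
print.response_value <- function(x, ...) {
  cat(sprintf("Mean response B = %.4f mSv/mGy  (sd_log = %s, K = %s, n = %s)\n",
              x$mean_B,
              if (is.na(x$sd_log)) "NA" else sprintf("%.4f", x$sd_log),
              if (is.na(x$K)) "NA" else sprintf("%.3f", x$K),
              if (is.na(x$n)) "NA" else x$n))
  invisible(x)
}

#' @export
as.data.frame.response_value <- function(x, ...) {
  data.frame(mean_B = x$mean_B, sd_log = x$sd_log, K = x$K, n = x$n)
}

#' Pooled standard deviation of individual deviation rates
#'
#' The measurement error of a dosemeter type is the standard deviation of the
#' individual deviation rates from the mean reading of each simultaneous
#' reading set: for a set of readings, the rates are
#' `(reading_i - mean) / mean`. Rates are pooled across all sets of a type
#' with the pooled (within-set) estimator,
#' `sqrt(sum(rates^2) / sum(n_set - 1))`, which is the sample SD for a
#' single set and remains an unbiased estimator of the noise variance when
#' many small sets are pooled (each set loses one degree of freedom to its
#' own mean).
#'
#' Sets with fewer than two readings carry no spread information and are
#' skipped with a warning.
#'
#' @param sets A list of numeric reading vectors (one per set), or a single
#'   numeric vector treated as one set.
#' @return Pooled standard deviation of deviation rates, in percent.
#' @examples
#' deviation_rate_sd(list(c(0.98, 1.02)))  # 2.77 %
#' @export
deviation_rate_sd <- function(sets) {
  if (is.numeric(sets)) sets <- list(sets)
  if (!is.list(sets) || length(sets) == 0L)
    stop("'sets' must be a non-empty list of reading vectors")
  keep <- vapply(sets, function(s) length(s) >= 2L, logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " set(s) with fewer than 2 readings skipped")
    sets <- sets[keep]
  }
  if (length(sets) == 0L)
    stop("no set with at least 2 readings")
  rates <- lapply(sets, function(s) (s - mean(s)) / mean(s))
  ss <- sum(unlist(rates, use.names = FALSE)^2)
  df <- sum(lengths(rates) - 1L)
  sqrt(ss / df) * 100
}

#' Per-type measurement-error summary from a readings table
#'
#' Groups a long readings table by dosemeter type and run and applies
#' [deviation_rate_sd()] to each type.
#'
#' @param readings Data frame with columns `run_id`, `dosemeter_type`,
#'   `reading_mSv`.
#' @return Named numeric vector: pooled deviation-rate SD (percent) per
#'   dosemeter type.
#' @export
deviation_rate_by_type <- function(readings) {
  stopifnot(all(c("run_id", "dosemeter_type", "reading_mSv") %in%
                  names(readings)))
  types <- unique(readings$dosemeter_type)
  out <- vapply(types, function(ty) {
    sub <- readings[readings$dosemeter_type == ty, ]
    deviation_rate_sd(split(sub$reading_mSv, sub$run_id))
  }, numeric(1))
  names(out) <- types
  out
}
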