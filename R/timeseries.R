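#' Ordered time-series of well or titre measurements
#'
#' The backbone container for optical-density growth curves and plaque-count
#' titre series. Times are stored in minutes and must be strictly increasing;
#' values are non-negative (OD units or pfu/ml). Blank-corrected OD readings
#' may legitimately dip below zero; by default they are clamped at zero, and
#' `allow_negative = TRUE` keeps them as-is.
#'
#' @param times numeric vector of times in minutes, strictly increasing,
#'   length >= 2.
#' @param values numeric vector of measurements, same length as `times`.
#' @param label free-text label attached to the series.
#' @param allow_negative keep negative values instead of clamping them to 0.
#' @return an object of class `phage_ts` with fields `times`, `values`,
#'   `label`.
#' @examples
#' phage_ts(c(0, 10, 20), c(0.1, 0.2, 0.3), label = "A1")
#' @export
phage_ts <- function(times, values, label = "", allow_negative = FALSE) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length")
  }
  if (length(times) < 2) {
    stop("a time series needs at least two points")
  }
  if (anyNA(times) || anyNA(values)) {
    stop("`times` and `values` must not contain missing values")
  }
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0) + 1L
    stop(
      "times must be strictly increasing; offending rows: ",
      paste(bad, collapse = ", ")
    )
  }
  clamped <- FALSE
  if (any(values < 0)) {
    if (allow_negative) {
      clamped <- FALSE
    } else {
      values[values < 0] <- 0
      clamped <- TRUE
    }
  }
  structure(
    list(times = times, values = values, label = as.character(label)[1]),
    clamped = clamped,
    class = "phage_ts"
  )
}

#' @export
print.phage_ts <- function(x, ...) {
  cat(
    sprintf(
      "<phage_ts> %s: %d points, t = [%g, %g] min, values in [%g, %g]\n",
      if (nzchar(x$label)) x$label else "(unlabelled)",
      length(x$times), min(x$times), max(x$times),
      min(x$values), max(x$values)
    )
  )
  invisible(x)
}

#' @export
length.phage_ts <- function(x) length(x$times)

#' Truncate a time series at a cut-off time
#'
#' Keeps all samples with `t <= t_end` and, when `t_end` falls strictly
#' between two samples, appends a linearly interpolated point at `t_end` so
#' that downstream integrals cover exactly `[t_start, t_end]`.
#'
#' @param x a [phage_ts()] object.
#' @param t_end cut-off time in minutes; must lie within the sampled range.
#' @return a `phage_ts` ending exactly at `t_end`.
#' @export
ts_truncate <- function(x, t_end) {
  stopifnot(inherits(x, "phage_ts"))
  if (t_end < x$times[1] || t_end > x$times[length(x$times)]) {
    stop("`t_end` outside the sampled time range")
  }
  keep <- x$times <= t_end
  times <- x$times[keep]
  values <- x$values[keep]
  if (times[length(times)] < t_end) {
    v <- stats::approx(x$times, x$values, xout = t_end)$y
    times <- c(times, t_end)
    values <- c(values, v)
  }
  if (length(times) < 2) stop("truncation left fewer than two points")
  phage_ts(times, values, label = x$label, allow_negative = TRUE)
}
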