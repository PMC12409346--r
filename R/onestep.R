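#' Locate the pre-burst minimum and burst maximum of a one-step curve
#'
#' The burst maximum is the global maximum of the titre series over the whole
#' measurement window; the pre-burst minimum is the minimum restricted to
#' times at or before that maximum. Ties are broken towards the earliest
#' time. A series whose maximum sits at the first timepoint carries no burst
#' signal: the minimum is then taken over the full series and a `no_burst`
#' flag is raised. When the maximum falls on the final sample the burst may
#' extend beyond the window, flagged as `truncated`.
#'
#' @param series a [phage_ts()] of titres (pfu/ml) starting at infection
#'   time 0, with at least 3 points.
#' @param median_filter apply a 3-point running median before locating
#'   extrema (off by default; extrema are located on the raw series).
#' @return list with `t_min`, `min_titre`, `t_max`, `max_titre`, `t0_titre`,
#'   `no_burst`, `truncated`.
#' @export
locate_extrema <- function(series, median_filter = FALSE) {
  stopifnot(inherits(series, "phage_ts"))
  if (length(series$times) < 3) stop("need at least 3 titre points")
  v <- series$values
  if (median_filter) v <- stats::runmed(v, 3)
  t <- series$times
  i_max <- which.max(v) # which.max takes the earliest tie
  no_burst <- i_max == 1L
  if (no_burst) {
    i_min <- which.min(v)
  } else {
    pre <- seq_len(i_max)
    i_min <- pre[which.min(v[pre])]
  }
  list(
    t_min = t[i_min], min_titre = v[i_min],
    t_max = t[i_max], max_titre = v[i_max],
    t0_titre = v[1],
    no_burst = no_burst,
    truncated = i_max == length(v)
  )
}

#' Burst size from one-step extrema
#'
#' New phages produced per infected cell:
#' `(max_titre - min_titre) / (t0_titre - min_titre)`, where the denominator
#' counts the cells infected (phages lost from the medium by the pre-burst
#' minimum). Undefined when no phage adsorbed (`t0 <= min`); returns `NA`
#' with a `not_adsorbed` flag.
#'
#' @param m extrema list from [locate_extrema()] (or an `onestep_metrics`).
#' @return list with `burst_size` and `not_adsorbed`.
#' @export
burst_size <- function(m) {
  if (m$t0_titre <= m$min_titre) {
    return(list(burst_size = NA_real_, not_adsorbed = TRUE))
  }
  list(
    burst_size = (m$max_titre - m$min_titre) / (m$t0_titre - m$min_titre),
    not_adsorbed = FALSE
  )
}

#' Adsorption fraction from one-step extrema
#'
#' Fraction of the initial phage population lost from the medium by the
#' pre-burst minimum: `(t0 - min) / t0`, clamped into [0, 1] with a flag when
#' measurement noise pushes the raw value outside.
#'
#' @param m extrema list from [locate_extrema()].
#' @return list with `adsorption_fraction` and `clamped`.
#' @export
adsorption_fraction <- function(m) {
  if (m$t0_titre <= 0) stop("t0 titre must be positive")
  raw <- (m$t0_titre - m$min_titre) / m$t0_titre
  clamped <- raw < 0 || raw > 1
  list(
    adsorption_fraction = min(max(raw, 0), 1),
    clamped = clamped
  )
}

#' Eclipse period from one-step extrema
#'
#' The eclipse period (infection to maturation of the first new intracellular
#' phage) is read off as the time of the pre-burst minimum. Missing when the
#' series shows no burst.
#'
#' @param m extrema list from [locate_extrema()].
#' @return eclipse period in minutes, or `NA` if no burst.
#' @export
eclipse_period <- function(m) {
  if (isTRUE(m$no_burst)) {
    return(NA_real_)
  }
  m$t_min
}

#' One-step growth metrics for a phage titre series
#'
#' Computes the three point-estimates of a one-step growth experiment --
#' burst size, adsorption fraction and eclipse period -- from the extrema of
#' the pfu/ml curve.
#'
#' @param series a [phage_ts()] of titres starting at infection time 0.
#' @param median_filter 3-point median filtering before extrema location.
#' @param label optional phage/replicate label.
#' @return object of class `onestep_metrics`.
#' @examples
#' s <- phage_ts(c(0, 20, 30, 60), c(4e6, 1e6, 1e6, 1e8))
#' onestep_metrics(s)
#' @export
onestep_metrics <- function(series, median_filter = FALSE, label = NULL) {
  ex <- locate_extrema(series, median_filter = median_filter)
  b <- burst_size(ex)
  a <- adsorption_fraction(ex)
  structure(
    c(
      ex,
      list(
        burst_size = b$burst_size,
        not_adsorbed = b$not_adsorbed,
        adsorption_fraction = a$adsorption_fraction,
        adsorption_clamped = a$clamped,
        eclipse_period = eclipse_period(ex),
        label = if (is.null(label)) series$label else label
      )
    ),
    class = "onestep_metrics"
  )
}

#' @export
print.onestep_metrics <- function(x, ...) {
  cat(sprintf(
    "One-step growth metrics%s\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else ""
  ))
  cat(sprintf(
    "  burst size          %s phage/cell\n",
    if (is.na(x$burst_size)) "NA (no adsorption)" else formatC(x$burst_size, digits = 4)
  ))
  cat(sprintf("  adsorption fraction %.3f%s\n", x$adsorption_fraction,
    if (x$adsorption_clamped) " (clamped)" else ""
  ))
  cat(sprintf(
    "  eclipse period      %s min\n",
    if (is.na(x$eclipse_period)) "NA (no burst)" else formatC(x$eclipse_period)
  ))
  cat(sprintf(
    "  t0 = %.3g, min = %.3g @ %g min, max = %.3g @ %g min\n",
    x$t0_titre, x$min_titre, x$t_min, x$max_titre, x$t_max
  ))
  if (x$no_burst) cat("  flag: no burst detected\n")
  if (x$truncated) {
    cat("  flag: maximum at final sample; burst may extend beyond window\n")
  }
  invisible(x)
}

#' @export
as.data.frame.onestep_metrics <- function(x, ...) {
  data.frame(
    label = x$label,
    burst_size = x$burst_size,
    adsorption_fraction = x$adsorption_fraction,
    eclipse_period = x$eclipse_period,
    t0_titre = x$t0_titre, min_titre = x$min_titre, max_titre = x$max_titre,
    t_min = x$t_min, t_max = x$t_max,
    no_burst = x$no_burst, truncated = x$truncated,
    stringsAsFactors = FALSE
  )
}
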