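#' Trapezoidal area under a growth curve
#'
#' Integrates OD (or any value) against time from the first sample to
#' `t_end`, interpolating linearly when `t_end` falls between samples. This
#' operator underlies every area-under-growth-curve (AUGC) quantity in the
#' package.
#'
#' @param series a [phage_ts()].
#' @param t_end upper limit in minutes; defaults to the last sample. Must lie
#'   within the sampled range.
#' @return the integral, in value units x minutes (e.g. OD.min).
#' @examples
#' auc_trapezoid(phage_ts(c(0, 100), c(0.5, 0.5))) # 50
#' @export
auc_trapezoid <- function(series, t_end = NULL) {
  stopifnot(inherits(series, "phage_ts"))
  if (is.null(t_end)) t_end <- series$times[length(series$times)]
  if (t_end < series$times[1]) stop("`t_end` precedes the first sample")
  if (t_end > series$times[length(series$times)]) {
    stop("`t_end` beyond the last sample")
  }
  s <- if (t_end < series$times[length(series$times)]) {
    ts_truncate(series, t_end)
  } else {
    series
  }
  dt <- diff(s$times)
  sum(dt * (s$values[-length(s$values)] + s$values[-1]) / 2)
}

#' Censoring time against resistant-mutant regrowth
#'
#' In dose-series virulence assays, phage-resistant mutants eventually
#' regrow; their expansion is fastest in the wells that were cleared
#' earliest, so late in the assay the highest-dose wells overtake lower-dose
#' wells and the area under the curve stops reflecting phage virulence. The
#' curves are therefore cut at the earliest time at which the replicate-mean
#' OD of the highest dose surpasses the mean of the second-highest dose, and
#' the comparison falls back to the third-highest dose when the top two
#' cannot be resolved (never differ by more than `resolve_tol` anywhere).
#'
#' A crossing only counts once the two doses have first separated in the
#' expected direction (comparison dose above highest dose by more than
#' `resolve_tol`); this guards against spurious "crossings" at early times
#' where all wells still read identically. With no crossing the full window
#' is kept.
#'
#' @param dose_series list, ordered from highest to lowest dose; each element
#'   is a list of replicate [phage_ts()] objects sharing one time grid.
#' @param resolve_tol OD tolerance below which two doses are considered
#'   unresolved (default 0.05).
#' @return list with `censor_time` (minutes), `comparison_dose` (2 or 3) and
#'   `crossed` (logical).
#' @export
censor_time <- function(dose_series, resolve_tol = 0.05) {
  if (length(dose_series) < 3) {
    stop("censoring requires at least 3 dose levels")
  }
  mean_curve <- function(reps) {
    if (inherits(reps, "phage_ts")) reps <- list(reps)
    t0 <- reps[[1]]$times
    for (r in reps) {
      if (length(r$times) != length(t0) || any(r$times != t0)) {
        stop("replicates must share a common time grid")
      }
    }
    rowMeans(vapply(reps, function(r) r$values, numeric(length(t0))))
  }
  times <- if (inherits(dose_series[[1]], "phage_ts")) {
    dose_series[[1]]$times
  } else {
    dose_series[[1]][[1]]$times
  }
  m1 <- mean_curve(dose_series[[1]])
  m2 <- mean_curve(dose_series[[2]])
  comparison <- 2L
  if (max(abs(m1 - m2)) <= resolve_tol) {
    m2 <- mean_curve(dose_series[[3]])
    comparison <- 3L
  }
  resolved_at <- which(m2 - m1 > resolve_tol)
  crossed <- FALSE
  t_cut <- times[length(times)]
  if (length(resolved_at)) {
    later <- which(m1 > m2)
    later <- later[later > resolved_at[1]]
    if (length(later)) {
      crossed <- TRUE
      t_cut <- times[later[1]]
    }
  }
  list(censor_time = t_cut, comparison_dose = comparison, crossed = crossed)
}

#' Local virulence at one phage dose
#'
#' `1 - AUC(phage) / AUC(control)` over the censored window. Equals 1 when
#' the phage abolishes growth entirely and 0 when growth matches the no-phage
#' control. Values below 0 (growth exceeding the control) are reported as-is.
#'
#' @param phage_series OD [phage_ts()] with phage added.
#' @param control_series no-phage control OD [phage_ts()].
#' @param t_end censoring time (minutes); default full window.
#' @return local virulence (dimensionless, unclamped).
#' @export
local_virulence <- function(phage_series, control_series, t_end = NULL) {
  if (is.null(t_end)) {
    t_end <- min(
      phage_series$times[length(phage_series$times)],
      control_series$times[length(control_series$times)]
    )
  }
  auc_control <- auc_trapezoid(control_series, t_end)
  if (auc_control <= 0) stop("control AUC must be positive")
  1 - auc_trapezoid(phage_series, t_end) / auc_control
}

#' Virulence index over a dilution series
#'
#' Integrates local virulence against log10(MOI) by the trapezoid rule and
#' normalizes by the theoretical maximum area (local virulence of 1 at every
#' MOI), giving a scalar in [0, 1]. Local virulence values are clamped into
#' [0, 1] for the index only; a flag records when clamping occurred.
#'
#' @param moi measured multiplicities of infection (> 0), at least 2.
#' @param local_virulence local virulence at each MOI (same length).
#' @return list with `virulence_index`, `clamped` and the `moi` order used.
#' @examples
#' virulence_index(c(1e-4, 1e-2), c(0, 1))$virulence_index # 0.5
#' @export
virulence_index <- function(moi, local_virulence) {
  if (length(moi) != length(local_virulence)) {
    stop("`moi` and `local_virulence` lengths differ")
  }
  if (length(moi) < 2) stop("virulence index needs at least 2 MOI values")
  if (any(moi <= 0)) stop("MOI values must be positive")
  o <- order(moi)
  x <- log10(moi[o])
  if (any(duplicated(x))) stop("MOI values must be distinct")
  y <- local_virulence[o]
  clamped <- any(y < 0) || any(y > 1)
  y <- pmin(pmax(y, 0), 1)
  area <- sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  list(
    virulence_index = area / (x[length(x)] - x[1]),
    clamped = clamped,
    moi = moi[o]
  )
}

#' Multiplicity of infection
#'
#' Ratio of phage to cell density at inoculation.
#' @param phage_titre pfu/ml.
#' @param cell_density cfu/ml, > 0.
#' @return dimensionless MOI.
#' @export
compute_moi <- function(phage_titre, cell_density) {
  if (any(cell_density <= 0)) stop("cell density must be positive")
  if (any(phage_titre < 0)) stop("phage titre must be non-negative")
  phage_titre / cell_density
}

#' Virulence profile of a phage from a dose-series plate
#'
#' Full dose-response workflow: determines the censoring time from the
#' replicate-mean OD curves (highest vs second-highest dose), computes local
#' virulence per replicate over the censored window against the mean no-phage
#' control area, summarizes each dose as mean and standard error, and
#' integrates the per-dose means into the scalar virulence index over
#' log10(MOI).
#'
#' @param plate a `plate_od` object from [read_od_table()].
#' @param phage phage id in the layout.
#' @param strain host strain id.
#' @param moi named numeric vector mapping dose labels to measured MOI; when
#'   `NULL`, dose labels themselves must be numeric MOIs.
#' @param control_dose dose label of the no-phage control (default "none").
#' @param resolve_tol see [censor_time()].
#' @param medium optional medium filter.
#' @return object of class `virulence_profile`.
#' @export
virulence_profile <- function(plate, phage, strain, moi = NULL,
                              control_dose = "none", resolve_tol = 0.05,
                              medium = NULL) {
  l <- plate$layout
  sel <- l$strain == strain & l$phage %in% c(phage, "none")
  if (!is.null(medium)) sel <- sel & l$medium == medium
  l <- l[sel, , drop = FALSE]
  doses <- setdiff(unique(l$dose), control_dose)
  if (is.null(moi)) {
    moi <- suppressWarnings(as.numeric(doses))
    if (anyNA(moi)) stop("dose labels are not numeric; supply `moi`")
    names(moi) <- doses
  }
  moi <- moi[doses]
  if (anyNA(moi)) stop("missing MOI for dose(s): ", paste(doses[is.na(moi)], collapse = ", "))
  doses <- doses[order(-moi)] # highest dose first
  moi <- moi[doses]

  series_for <- function(dose) {
    wells <- l$well[l$dose == dose]
    lapply(wells, function(w) od_series(plate, w))
  }
  by_dose <- lapply(doses, series_for)
  control <- series_for(control_dose)
  if (length(control) == 0) stop("no control wells (dose = ", control_dose, ")")

  cens <- if (length(by_dose) >= 3) {
    censor_time(by_dose, resolve_tol = resolve_tol)
  } else {
    list(
      censor_time = plate$times[length(plate$times)],
      comparison_dose = NA_integer_, crossed = FALSE
    )
  }
  t_end <- cens$censor_time
  control_augc <- mean(vapply(control, auc_trapezoid, numeric(1), t_end = t_end))
  if (control_augc <= 0) stop("control AUC must be positive")

  lv <- lapply(by_dose, function(reps) {
    vapply(reps, function(s) 1 - auc_trapezoid(s, t_end) / control_augc, numeric(1))
  })
  lv_mean <- vapply(lv, mean, numeric(1))
  lv_se <- vapply(lv, function(v) {
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))
  vi <- virulence_index(unname(moi), lv_mean)

  structure(
    list(
      phage = phage, strain = strain,
      moi_values = unname(moi), dose_labels = doses,
      local_virulence = lv_mean, local_virulence_se = lv_se,
      local_virulence_reps = lv,
      virulence_index = vi$virulence_index,
      lv_clamped = vi$clamped,
      censor_time = t_end, censor_crossed = cens$crossed,
      comparison_dose = cens$comparison_dose,
      control_augc = control_augc
    ),
    class = "virulence_profile"
  )
}

#' @export
print.virulence_profile <- function(x, ...) {
  cat(sprintf("Virulence profile: phage %s on strain %s\n", x$phage, x$strain))
  cat(sprintf(
    "  censored at %g min (%s)\n", x$censor_time,
    if (x$censor_crossed) {
      sprintf("dose 1 crossed dose %d", x$comparison_dose)
    } else {
      "no crossing; full window"
    }
  ))
  df <- data.frame(
    dose = x$dose_labels, MOI = signif(x$moi_values, 3),
    local_virulence = round(x$local_virulence, 4),
    se = round(x$local_virulence_se, 4)
  )
  print(df, row.names = FALSE)
  cat(sprintf(
    "  virulence index = %.4f%s\n", x$virulence_index,
    if (x$lv_clamped) " (local virulence clamped to [0,1] for the index)" else ""
  ))
  invisible(x)
}

#' @export
plot.virulence_profile <- function(x, ...) {
  graphics::plot(
    log10(x$moi_values), x$local_virulence,
    type = "b", pch = 19,
    xlab = "log10 MOI", ylab = "local virulence",
    ylim = range(c(0, 1, x$local_virulence)),
    main = sprintf(
      "%s on %s (virulence index %.3f)",
      x$phage, x$strain, x$virulence_index
    ), ...
  )
  se <- x$local_virulence_se
  ok <- !is.na(se)
  if (any(ok)) {
    graphics::arrows(
      log10(x$moi_values)[ok], (x$local_virulence - se)[ok],
      log10(x$moi_values)[ok], (x$local_virulence + se)[ok],
      angle = 90, code = 3, length = 0.03
    )
  }
  invisible(x)
}
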