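#' Normalized area under a growth curve
#'
#' AUGC of a well over the full measurement window, divided by a reference
#' AUGC -- conventionally the mean AUGC of the defence-system knock-out
#' strain grown without phage in the same medium.
#'
#' @param series OD [phage_ts()].
#' @param reference_augc positive reference area (OD.min).
#' @return dimensionless normalized AUGC.
#' @export
normalized_augc <- function(series, reference_augc) {
  if (reference_augc <= 0) stop("reference AUGC must be positive")
  auc_trapezoid(series) / reference_augc
}

#' Within-strain dose comparisons with FDR correction
#'
#' Welch t-tests between each pair of phage-dose levels on replicate
#' normalized AUGC values, with Benjamini-Hochberg adjustment across the
#' within-strain family of pairs.
#'
#' @param augc_by_dose named list of replicate normalized-AUGC vectors, e.g.
#'   `list(high = ..., low = ..., none = ...)`, >= 2 replicates per dose.
#' @return data.frame with `dose1`, `dose2`, `p_raw`, `p_adj`.
#' @export
dose_comparisons <- function(augc_by_dose) {
  if (length(augc_by_dose) < 2) stop("need at least two dose levels")
  if (is.null(names(augc_by_dose)) || any(!nzchar(names(augc_by_dose)))) {
    stop("`augc_by_dose` must be a named list")
  }
  pairs <- utils::combn(names(augc_by_dose), 2)
  p_raw <- apply(pairs, 2, function(pr) {
    welch_t(augc_by_dose[[pr[1]]], augc_by_dose[[pr[2]]])$p_value
  })
  data.frame(
    dose1 = pairs[1, ], dose2 = pairs[2, ],
    p_raw = p_raw, p_adj = bh_fdr(p_raw),
    stringsAsFactors = FALSE
  )
}

#' Classify a protection phenotype from dose-level AUGC
#'
#' A dose is "restored" when growth at that dose is similar to the no-phage
#' control: its mean normalized AUGC reaches at least
#' `restored_threshold` times the no-phage mean, OR it is statistically
#' indistinguishable from the no-phage control (FDR-adjusted p >= `alpha`).
#' The phenotype is `complete` when both high and low doses are restored,
#' `intermediate` when only the low dose is restored, and `none` when even
#' the low dose is not.
#'
#' @param augc_by_dose named list with elements `high`, `low`, `none` of
#'   replicate normalized AUGC values.
#' @param restored_threshold effect-size floor as a fraction of the no-phage
#'   mean (default 0.9).
#' @param alpha significance level for the adjusted p-values (default 0.05).
#' @return list with `phenotype`, `restored` (named logical), `means`,
#'   `comparisons` (from [dose_comparisons()]), and the thresholds used.
#' @export
classify_protection <- function(augc_by_dose, restored_threshold = 0.9,
                                alpha = 0.05) {
  need <- c("high", "low", "none")
  missing_doses <- setdiff(need, names(augc_by_dose))
  if (length(missing_doses)) {
    stop("missing dose level(s): ", paste(missing_doses, collapse = ", "))
  }
  augc_by_dose <- augc_by_dose[need]
  cmp <- dose_comparisons(augc_by_dose)
  means <- vapply(augc_by_dose, mean, numeric(1))
  p_vs_none <- function(dose) {
    row <- (cmp$dose1 == dose & cmp$dose2 == "none") |
      (cmp$dose1 == "none" & cmp$dose2 == dose)
    cmp$p_adj[row]
  }
  restored <- vapply(c("high", "low"), function(dose) {
    means[[dose]] >= restored_threshold * means[["none"]] ||
      p_vs_none(dose) >= alpha
  }, logical(1))
  phenotype <- if (restored[["high"]] && restored[["low"]]) {
    "complete"
  } else if (restored[["low"]]) {
    "intermediate"
  } else {
    "none"
  }
  list(
    phenotype = phenotype,
    restored = restored,
    means = means,
    comparisons = cmp,
    restored_threshold = restored_threshold,
    alpha = alpha
  )
}

#' Efficiency of plating
#'
#' Titre of a phage on a test strain divided by its titre on a permissive
#' reference strain; also returned on the log10 scale. A test titre below
#' detection yields an upper bound computed from the detection limit and is
#' flagged.
#'
#' @param titre_on_test pfu/ml on the test strain (0 if below detection).
#' @param titre_on_reference pfu/ml on the reference strain, > 0.
#' @param detection_limit smallest measurable titre (pfu/ml); required to
#'   bound a below-detection test titre.
#' @return list with `eop`, `log10_eop`, `censored`.
#' @export
efficiency_of_plating <- function(titre_on_test, titre_on_reference,
                                  detection_limit = NULL) {
  if (titre_on_reference <= 0) stop("reference titre must be positive")
  if (titre_on_test < 0) stop("test titre must be non-negative")
  if (titre_on_test == 0) {
    if (is.null(detection_limit) || detection_limit <= 0) {
      stop("below-detection test titre needs a positive `detection_limit`")
    }
    eop <- detection_limit / titre_on_reference
    return(list(eop = eop, log10_eop = log10(eop), censored = TRUE))
  }
  eop <- titre_on_test / titre_on_reference
  list(eop = eop, log10_eop = log10(eop), censored = FALSE)
}

#' Protection calls for every strain x phage x medium panel on a plate
#'
#' End-to-end protection workflow: normalizes each well's AUGC against the
#' mean AUGC of the reference (knock-out) strain without phage in the same
#' medium, runs the within-strain dose comparisons and classifies the
#' phenotype.
#'
#' @param plate a `plate_od` from [read_od_table()].
#' @param reference_strain strain id used for normalization (e.g. the
#'   CRISPR-Cas knock-out).
#' @param restored_threshold,alpha see [classify_protection()].
#' @return object of class `protection_calls`: a data.frame with one row per
#'   strain x phage x medium and columns for the normalized AUGC means,
#'   adjusted p-values and phenotype; replicate-level values are kept in
#'   `attr(, "replicates")`.
#' @export
protection_calls <- function(plate, reference_strain,
                             restored_threshold = 0.9, alpha = 0.05) {
  l <- plate$layout
  if (!reference_strain %in% l$strain) {
    stop("reference strain ", reference_strain, " not on the plate")
  }
  augc_for <- function(wells) {
    vapply(wells, function(w) auc_trapezoid(od_series(plate, w)), numeric(1))
  }
  panels <- unique(l[
    l$dose != "none" | l$phage != "none",
    c("strain", "phage", "medium")
  ])
  panels <- panels[panels$phage != "none", , drop = FALSE]
  rows <- list()
  reps <- list()
  for (i in seq_len(nrow(panels))) {
    strain <- panels$strain[i]
    phage <- panels$phage[i]
    medium <- panels$medium[i]
    ref_wells <- od_wells(plate,
      strain = reference_strain, dose = "none",
      medium = medium
    )
    if (length(ref_wells) == 0) {
      stop("no no-phage reference wells for medium ", medium)
    }
    ref_augc <- mean(augc_for(ref_wells))
    get_dose <- function(dose) {
      wells <- od_wells(plate,
        strain = strain, medium = medium,
        dose = dose, phage = if (dose == "none") NULL else phage
      )
      if (length(wells) == 0) {
        stop(sprintf(
          "missing dose level %s for strain %s (%s)", dose, strain, medium
        ))
      }
      augc_for(wells) / ref_augc
    }
    augc <- list(high = get_dose("high"), low = get_dose("low"),
                 none = get_dose("none"))
    cls <- classify_protection(augc,
      restored_threshold = restored_threshold, alpha = alpha
    )
    pick <- function(d1, d2) {
      cmp <- cls$comparisons
      row <- (cmp$dose1 == d1 & cmp$dose2 == d2) |
        (cmp$dose1 == d2 & cmp$dose2 == d1)
      cmp$p_adj[row]
    }
    rows[[i]] <- data.frame(
      strain = strain, phage = phage, medium = medium,
      augc_high = cls$means[["high"]], augc_low = cls$means[["low"]],
      augc_none = cls$means[["none"]],
      p_high_vs_none = pick("high", "none"),
      p_low_vs_none = pick("low", "none"),
      p_high_vs_low = pick("high", "low"),
      phenotype = cls$phenotype,
      restored_threshold_used = restored_threshold,
      stringsAsFactors = FALSE
    )
    reps[[paste(strain, phage, medium, sep = "|")]] <- augc
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- reps
  attr(out, "alpha") <- alpha
  class(out) <- c("protection_calls", "data.frame")
  out
}

#' @export
print.protection_calls <- function(x, ...) {
  cat("Protection phenotype calls (AUGC normalized to reference strain,",
      "no phage):\n")
  df <- as.data.frame(x)
  df$augc_high <- round(df$augc_high, 3)
  df$augc_low <- round(df$augc_low, 3)
  df$augc_none <- round(df$augc_none, 3)
  df$p_high_vs_none <- signif(df$p_high_vs_none, 3)
  df$p_low_vs_none <- signif(df$p_low_vs_none, 3)
  df$p_high_vs_low <- signif(df$p_high_vs_low, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
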