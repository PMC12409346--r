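#' Plate layout: mapping from wells to experimental conditions
#'
#' A layout maps each well id of a 96-well (or any) plate to the strain,
#' phage, dose level, growth medium and replicate number it carries. Dose
#' levels follow the high/low/none dosing design of liquid protection assays
#' (high: 1e8 pfu/ml stock diluted 1:100; low: 1e6 pfu/ml diluted 1:100;
#' none: PBS control), but arbitrary dose labels (e.g. MOI targets) are
#' accepted.
#'
#' @param df data.frame with columns `well`, `strain`, `phage`, `dose`,
#'   `medium`, `replicate`. `phage` may be `NA`/"none" for no-phage wells.
#' @return a `plate_layout` object (a validated data.frame).
#' @export
plate_layout <- function(df) {
  req <- c("well", "strain", "phage", "dose", "medium", "replicate")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("layout is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[req]
  df$well <- as.character(df$well)
  if (anyDuplicated(df$well)) {
    stop(
      "duplicate well ids in layout: ",
      paste(unique(df$well[duplicated(df$well)]), collapse = ", ")
    )
  }
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate)) || any(df$replicate < 1)) {
    stop("`replicate` must be an integer >= 1 for every well")
  }
  df$phage <- as.character(df$phage)
  df$phage[is.na(df$phage) | df$phage == ""] <- "none"
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' Read a plate layout CSV
#'
#' @param path CSV file with columns `well,strain,phage,dose,medium,replicate`.
#' @return a [plate_layout()] object.
#' @export
read_plate_layout <- function(path) {
  plate_layout(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a plate layout to CSV
#'
#' @param layout a [plate_layout()].
#' @param path output CSV path.
#' @export
write_plate_layout <- function(layout, path) {
  utils::write.csv(as.data.frame(layout), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide OD table and attach layout metadata
#'
#' The OD table is RFC-4180 CSV with a `time` column followed by one column
#' per well. Every well column must be present in the layout (wells listed in
#' the layout but absent from the table are tolerated and ignored). Times are
#' converted to minutes internally.
#'
#' @param path CSV file.
#' @param layout a [plate_layout()].
#' @param time_unit unit of the time column, `"min"` (default) or `"h"`.
#' @param blank_wells optional character vector of blank wells; their
#'   per-timepoint mean is subtracted from every other well before clamping.
#' @param allow_negative keep blank-corrected values below zero.
#' @return a `plate_od` object: list with `times` (minutes), `od` (matrix,
#'   timepoints x wells) and `layout` (restricted to the wells present).
#' @export
read_od_table <- function(path, layout, time_unit = c("min", "h"),
                          blank_wells = NULL, allow_negative = FALSE) {
  time_unit <- match.arg(time_unit)
  stopifnot(inherits(layout, "plate_layout"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"time" %in% names(raw)) stop("OD table must contain a `time` column")
  wells <- setdiff(names(raw), "time")
  unknown <- setdiff(wells, c(layout$well, blank_wells))
  if (length(unknown)) {
    stop(
      "well column(s) not present in layout: ",
      paste(unknown, collapse = ", ")
    )
  }
  times <- as.numeric(raw$time)
  if (time_unit == "h") times <- times * 60
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0) + 1L
    stop(
      "non-monotone time column; offending rows: ",
      paste(bad, collapse = ", ")
    )
  }
  od <- as.matrix(raw[wells])
  storage.mode(od) <- "double"
  if (!is.null(blank_wells)) {
    present <- intersect(blank_wells, wells)
    if (length(present) == 0) stop("none of the blank wells are in the table")
    blank_mean <- rowMeans(od[, present, drop = FALSE])
    od <- od - blank_mean
    od <- od[, setdiff(wells, present), drop = FALSE]
    wells <- colnames(od)
  }
  if (!allow_negative) od[od < 0] <- 0
  structure(
    list(
      times = times,
      od = od,
      layout = layout[layout$well %in% wells, , drop = FALSE]
    ),
    class = "plate_od"
  )
}

#' @export
print.plate_od <- function(x, ...) {
  cat(sprintf(
    "<plate_od> %d wells x %d timepoints, t = [%g, %g] min\n",
    ncol(x$od), length(x$times), min(x$times), max(x$times)
  ))
  cat(
    "strains:", paste(unique(x$layout$strain), collapse = ", "),
    "| phages:", paste(unique(x$layout$phage), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Write a plate_od object back to wide CSV
#'
#' Full-precision round-trip companion of [read_od_table()].
#' @param x a `plate_od` object.
#' @param path output CSV path.
#' @export
write_od_table <- function(x, path) {
  stopifnot(inherits(x, "plate_od"))
  df <- data.frame(time = x$times, check.names = FALSE)
  df[colnames(x$od)] <- as.data.frame(x$od)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one well as a time series
#'
#' @param x a `plate_od` object.
#' @param well well id.
#' @return a [phage_ts()].
#' @export
od_series <- function(x, well) {
  stopifnot(inherits(x, "plate_od"))
  if (!well %in% colnames(x$od)) stop("well ", well, " not in OD table")
  phage_ts(x$times, x$od[, well], label = well, allow_negative = TRUE)
}

#' Select wells matching a condition
#'
#' @param x a `plate_od` object.
#' @param strain,phage,dose,medium optional filters; `NULL` matches anything.
#' @return character vector of well ids, ordered by replicate.
#' @export
od_wells <- function(x, strain = NULL, phage = NULL, dose = NULL,
                     medium = NULL) {
  l <- x$layout
  keep <- rep(TRUE, nrow(l))
  if (!is.null(strain)) keep <- keep & l$strain %in% strain
  if (!is.null(phage)) keep <- keep & l$phage %in% phage
  if (!is.null(dose)) keep <- keep & l$dose %in% dose
  if (!is.null(medium)) keep <- keep & l$medium %in% medium
  l <- l[keep, , drop = FALSE]
  l$well[order(l$replicate)]
}

#' Read a long titre table
#'
#' Columns: `sample,time,dilution_exponent,spot_volume_ul,count` and an
#' optional `channel` column (free vs total-mature phage).
#' @param path CSV file.
#' @return data.frame with validated columns.
#' @export
read_titre_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample", "time", "dilution_exponent", "spot_volume_ul", "count")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("titre table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$spot_volume_ul <= 0)) stop("spot_volume_ul must be positive")
  if (any(df$dilution_exponent < 0)) stop("dilution_exponent must be >= 0")
  if (any(df$count < 0)) stop("plaque counts must be non-negative")
  df
}

#' Countable-spot filter for serial-dilution plaque counts
#'
#' Standard plaque-count practice: only spots with between `lo` and `hi`
#' plaques are reliable; below, counting noise dominates, above, plaques
#' merge. For each sample x time (x channel), keeps the records at the lowest
#' dilution whose counts are all countable; if no dilution qualifies, the
#' dilution whose mean count is closest to the countable range is kept so that
#' zero-count (below-detection) samples are still represented.
#'
#' @param records titre-record data.frame as from [read_titre_table()].
#' @param lo,hi countable range (default 3-100 plaques per spot).
#' @return filtered data.frame.
#' @export
countable_spots <- function(records, lo = 3, hi = 100) {
  key <- interaction(
    records$sample, records$time,
    if ("channel" %in% names(records)) records$channel else "",
    drop = TRUE
  )
  keep <- unlist(lapply(split(seq_len(nrow(records)), key), function(idx) {
    d <- records[idx, ]
    by_dil <- split(idx, d$dilution_exponent)
    ok <- vapply(by_dil, function(i) {
      all(records$count[i] >= lo & records$count[i] <= hi)
    }, logical(1))
    if (any(ok)) {
      by_dil[[which(ok)[1]]]
    } else {
      med <- vapply(by_dil, function(i) mean(records$count[i]), numeric(1))
      dist <- pmax(lo - med, med - hi, 0)
      by_dil[[which.min(dist)]]
    }
  }), use.names = FALSE)
  records[sort(keep), , drop = FALSE]
}

#' Titre estimate from spotted plaque counts
#'
#' Each 2 ul spot at dilution 10^-d carrying n plaques estimates a titre of
#' n x 10^d / 0.002 pfu/ml; the per-spot estimates are averaged. Zero counts
#' across all spots give 0 with a below-detection flag.
#'
#' @param count vector of plaque counts (one per spot).
#' @param dilution_exponent power-of-ten dilution of each spot (recycled).
#' @param spot_volume_ul spotted volume in microlitres (recycled; default 2).
#' @return list with `titre` (pfu/ml), `below_detection`, `n_spots`.
#' @examples
#' titre_from_counts(20, 4)$titre # 1e8 pfu/ml
#' @export
titre_from_counts <- function(count, dilution_exponent, spot_volume_ul = 2) {
  if (length(count) < 1) stop("need at least one plaque-count record")
  if (any(count < 0)) stop("plaque counts must be non-negative")
  if (any(spot_volume_ul <= 0)) stop("spot_volume_ul must be positive")
  if (any(dilution_exponent < 0)) stop("dilution_exponent must be >= 0")
  vol_ml <- spot_volume_ul / 1000
  per_spot <- count * 10^dilution_exponent / vol_ml
  list(
    titre = mean(per_spot),
    below_detection = all(count == 0),
    n_spots = length(count)
  )
}

#' Concentration after spiking a stock into a recipient volume
#'
#' `stock_conc * vol_added / (vol_added + vol_recipient)`. Works for any
#' per-ml concentration-like quantity (pfu/ml, cfu/ml, or an OD treated as a
#' concentration proxy).
#'
#' @param stock_conc concentration of the added stock (per ml).
#' @param vol_added volume added (ml), > 0.
#' @param vol_recipient recipient volume (ml), > 0.
#' @return final concentration (per ml).
#' @examples
#' final_concentration_after_spike(1e9, 0.1, 25) # ~4e6 pfu/ml
#' final_concentration_after_spike(2.6, 1, 25) # starting OD 0.1
#' @export
final_concentration_after_spike <- function(stock_conc, vol_added,
                                            vol_recipient) {
  if (any(vol_added <= 0) || any(vol_recipient <= 0)) {
    stop("volumes must be positive")
  }
  if (any(stock_conc < 0)) stop("stock concentration must be non-negative")
  stock_conc * vol_added / (vol_added + vol_recipient)
}

#' Assemble a pfu/ml time series from a titre table
#'
#' Applies the countable-spot rule, averages triplicate spots per timepoint
#' and returns one [phage_ts()] per sample (and channel, when present).
#'
#' @param records titre-record data.frame.
#' @param sample sample id to extract.
#' @param channel optional channel (`"free"` or `"total_mature"`).
#' @param countable apply [countable_spots()] first (default TRUE).
#' @return a [phage_ts()] of titres (pfu/ml) against time (minutes).
#' @export
titre_series <- function(records, sample, channel = NULL, countable = TRUE) {
  d <- records[records$sample == sample, , drop = FALSE]
  if (!is.null(channel)) {
    if (!"channel" %in% names(d)) stop("titre table has no `channel` column")
    d <- d[d$channel == channel, , drop = FALSE]
  }
  if (nrow(d) == 0) stop("no titre records for sample ", sample)
  if (countable) d <- countable_spots(d)
  times <- sort(unique(d$time))
  vals <- vapply(times, function(t) {
    r <- d[d$time == t, ]
    titre_from_counts(r$count, r$dilution_exponent, r$spot_volume_ul)$titre
  }, numeric(1))
  phage_ts(times, vals, label = sample)
}
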