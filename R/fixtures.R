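# Fixture writers: every input the analysis pipeline consumes can be
# generated synthetically from the mechanistic model, with the generating
# parameters (and derived ground truths) frozen next to the data as JSON.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a one-step growth fixture
#'
#' Simulates the canonical one-step growth design: phage are mixed with an
#' excess of exponentially growing cells (default MOI 0.01), allowed to
#' adsorb, and the culture is then diluted deeply into buffer so that
#' progeny released at burst neither re-adsorb nor meet regrowing hosts --
#' producing the classic single-cycle curve with adsorption dip, eclipse
#' plateau and burst rise. Plaque-count tables are written for both the
#' free-phage channel and the chloroform-lysed total-mature channel; counts
#' on post-dilution samples come from a larger plated aliquot
#' (`spot_volume_post` microlitres) and are referenced back to the
#' undiluted culture via the dilution exponent.
#'
#' @param params a [sim_params()]; sensible one-step settings are
#'   `sim_params(S0 = 4e8, P0 = 4e6, a = 2.5e-9, mu = 0, delta_P = 1e-3,
#'   B = ..., tau = ..., c = 0)`.
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed for the Poisson plaque counts.
#' @param sample_times sampling grid in minutes (default 0-120 every 10).
#' @param dilution_time,dilution_factor post-adsorption dilution into
#'   nutrient-free buffer; `dilution_factor` must be a power of 10.
#' @param spot_volume_post plated volume (ul) for post-dilution samples
#'   (default 100; pre-dilution samples use standard 2 ul spots).
#' @param noise Poisson counting noise (FALSE gives rounded expectations).
#' @param dt integrator step (min).
#' @return invisibly, a list with the file paths and the ground-truth list.
#' @export
write_onestep_fixture <- function(params, out_dir, seed = 1L,
                                  sample_times = seq(0, 120, by = 10),
                                  dilution_time = 5, dilution_factor = 1e6,
                                  spot_volume_post = 100,
                                  noise = TRUE, dt = 0.1) {
  stopifnot(inherits(params, "sim_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dil_exp <- round(log10(dilution_factor))
  if (!isTRUE(all.equal(10^dil_exp, dilution_factor))) {
    stop("`dilution_factor` must be a power of 10")
  }
  t_end <- max(sample_times)
  phase1 <- run_dynamics(params, t_end = dilution_time, dt = dt)
  y <- attr(phase1, "final_state")
  y_diluted <- y / dilution_factor
  y_diluted["N"] <- 0 # diluted into buffer: no host regrowth
  phase2 <- run_dynamics(params,
    t_end = t_end - dilution_time, dt = dt,
    init = y_diluted
  )
  phase2$t <- phase2$t + dilution_time
  scale2 <- c("S", "R", "P", "I_total", "I_m", "cells", "total_mature")
  phase2[scale2] <- phase2[scale2] * dilution_factor # culture-of-record units
  dense <- rbind(phase1[phase1$t < dilution_time, ], phase2)

  mature <- 0.5 * params$B * dense$I_m
  t_first_mat <- dense$t[which(mature >= 1e-4 * max(mature))[1]]
  i_max <- which.max(dense$total_mature)
  pre <- seq_len(i_max)
  i_min <- pre[which.min(dense$total_mature[pre])]
  truth <- list(
    params = unclass(params), seed = as.integer(seed),
    dilution_time = dilution_time, dilution_factor = dilution_factor,
    t_first_maturation = t_first_mat,
    t_min_dense = dense$t[i_min],
    t_max_dense = dense$t[i_max],
    adsorption_dense = (params$P0 - dense$P[i_min]) / params$P0,
    burst_dense = (dense$total_mature[i_max] - dense$total_mature[i_min]) /
      (params$P0 - dense$total_mature[i_min])
  )

  take <- vapply(sample_times, function(t) which.min(abs(dense$t - t)),
                 integer(1))
  records <- .with_seed(seed, {
    rows <- lapply(seq_along(sample_times), function(i) {
      t <- sample_times[i]
      diluted <- t >= dilution_time
      f <- if (diluted) dilution_factor else 1
      extra <- if (diluted) dil_exp else 0
      vol <- if (diluted) spot_volume_post else 2
      rbind(
        observe_titre(dense$total_mature[take[i]] / f,
          time = t,
          sample = "onestep", channel = "total_mature",
          spot_volume_ul = vol, extra_exponent = extra, noise = noise
        ),
        observe_titre(dense$P[take[i]] / f,
          time = t,
          sample = "onestep", channel = "free",
          spot_volume_ul = vol, extra_exponent = extra, noise = noise
        )
      )
    })
    do.call(rbind, rows)
  })
  titre_path <- file.path(out_dir, "titres.csv")
  utils::write.csv(records, titre_path, row.names = FALSE, quote = FALSE)
  truth_path <- file.path(out_dir, "truth.json")
  .write_json(truth, truth_path)
  invisible(list(
    titres = titre_path, truth_file = truth_path, truth = truth
  ))
}

#' Write a virulence dose-series fixture
#'
#' 23-hour OD growth curves for a ten-fold phage dilution series plus a
#' no-phage control, in replicate, on one host strain. Resistant mutants
#' arise mutationally (rate `mu`) during the run, so the highest-dose wells
#' -- cleared earliest -- regrow from mutants while lower doses are still
#' suppressed, reproducing the late crossing that motivates censoring.
#'
#' @param params host/phage [sim_params()]; `P0` is overridden per dose.
#' @param moi_grid nominal MOIs of the dilution series, highest first
#'   (default `10^(0:-4)`).
#' @param out_dir output directory.
#' @param seed RNG seed for OD noise.
#' @param replicates wells per condition (default 3).
#' @param noise_sd OD measurement noise (default 0.003).
#' @param t_end,sample_every,dt time grid (defaults: 23 h sampled every
#'   10 min, RK4 step 0.25 min).
#' @return invisibly, list with file paths and the ground truth.
#' @export
write_virulence_fixture <- function(params, moi_grid = 10^(0:-4),
                                    out_dir, seed = 1L, replicates = 3,
                                    noise_sd = 0.003, t_end = 23 * 60,
                                    sample_every = 10, dt = 0.25) {
  stopifnot(inherits(params, "sim_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  moi_grid <- sort(moi_grid, decreasing = TRUE)
  dose_labels <- c(paste0("d", seq_along(moi_grid)), "none")
  p0 <- c(params$S0 * moi_grid, 0)
  times <- seq(0, t_end, by = sample_every)
  curves <- lapply(p0, function(phage0) {
    p <- params
    p$P0 <- phage0
    traj <- run_dynamics(p, t_end = t_end, dt = dt,
                         record_every = sample_every)
    traj$cells
  })
  layout <- do.call(rbind, lapply(seq_along(dose_labels), function(i) {
    data.frame(
      well = paste0(LETTERS[i], seq_len(replicates)),
      strain = "WT",
      phage = ifelse(dose_labels[i] == "none", "none", "phage"),
      dose = dose_labels[i],
      medium = "high_nutrient",
      replicate = seq_len(replicates),
      stringsAsFactors = FALSE
    )
  }))
  od <- .with_seed(seed, {
    cols <- lapply(seq_along(dose_labels), function(i) {
      vapply(seq_len(replicates), function(r) {
        observe_od(curves[[i]], params$alpha_od, noise_sd)
      }, numeric(length(times)))
    })
    do.call(cbind, cols)
  })
  colnames(od) <- layout$well
  od_df <- data.frame(time = times)
  od_df[layout$well] <- as.data.frame(od)
  od_path <- file.path(out_dir, "od.csv")
  layout_path <- file.path(out_dir, "layout.csv")
  utils::write.csv(od_df, od_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(layout, layout_path, row.names = FALSE, quote = FALSE)
  truth <- list(
    params = unclass(params), seed = as.integer(seed),
    moi = stats::setNames(as.list(moi_grid), dose_labels[-length(dose_labels)]),
    replicates = replicates, noise_sd = noise_sd
  )
  truth_path <- file.path(out_dir, "truth.json")
  .write_json(truth, truth_path)
  invisible(list(
    od = od_path, layout = layout_path, truth_file = truth_path,
    truth = truth
  ))
}

#' Write a protection-assay fixture from a named scenario
#'
#' Simulates the high/low/no phage dosing design on a CRISPR-carrying
#' strain and its knock-out control, in one or two nutrient conditions, and
#' writes the wide OD table plus layout in the package's plate schema.
#'
#' @param scenario a scenario list, e.g. from [load_scenario()]: fields
#'   `phage` (adsorption/latency/burst parameters), `media` (named list of
#'   per-medium growth parameters including the interference probability
#'   `c` of the CRISPR strain), `S0`, `doses` (named `high`/`low`/`none`
#'   pfu/ml), `replicates` (per medium), `noise_sd`.
#' @param out_dir output directory.
#' @param seed RNG seed for OD noise.
#' @param t_end,sample_every,dt time grid, as in
#'   [write_virulence_fixture()].
#' @return invisibly, list with file paths and ground truth.
#' @export
write_protection_fixture <- function(scenario, out_dir, seed = 1L,
                                     t_end = 23 * 60, sample_every = 10,
                                     dt = 0.25) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  times <- seq(0, t_end, by = sample_every)
  phage_name <- if (!is.null(scenario$phage_name)) scenario$phage_name else "phage"
  layout_rows <- list()
  curve_cols <- list()
  well_i <- 0L
  for (medium in names(scenario$media)) {
    med <- scenario$media[[medium]]
    reps <- scenario$replicates[[medium]]
    for (strain in c("KO", "CRISPR")) {
      c_eff <- if (strain == "KO") 0 else med$c
      for (dose in names(scenario$doses)) {
        p <- sim_params(
          r_max = med$r_max, K_N = med$K_N, N0 = med$N0, Y = med$yield,
          a = scenario$phage$a, tau = scenario$phage$tau,
          m = scenario$phage$m, B = scenario$phage$B,
          c = c_eff, mu = scenario$phage$mu,
          delta_P = scenario$phage$delta_P,
          alpha_od = scenario$alpha_od %||% 1e-9,
          S0 = scenario$S0, P0 = scenario$doses[[dose]], seed = seed
        )
        traj <- run_dynamics(p, t_end = t_end, dt = dt,
                             record_every = sample_every)
        for (r in seq_len(reps)) {
          well_i <- well_i + 1L
          well <- sprintf("W%02d", well_i)
          layout_rows[[well_i]] <- data.frame(
            well = well, strain = strain,
            phage = ifelse(dose == "none", "none", phage_name),
            dose = dose, medium = medium, replicate = r,
            stringsAsFactors = FALSE
          )
          curve_cols[[well_i]] <- traj$cells
        }
      }
    }
  }
  layout <- do.call(rbind, layout_rows)
  alpha <- scenario$alpha_od %||% 1e-9
  od <- .with_seed(seed, {
    vapply(
      curve_cols,
      function(cells) observe_od(cells, alpha, scenario$noise_sd %||% 0.005),
      numeric(length(times))
    )
  })
  colnames(od) <- layout$well
  od_df <- data.frame(time = times)
  od_df[layout$well] <- as.data.frame(od)
  od_path <- file.path(out_dir, "od.csv")
  layout_path <- file.path(out_dir, "layout.csv")
  utils::write.csv(od_df, od_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(layout, layout_path, row.names = FALSE, quote = FALSE)
  truth <- list(scenario = scenario, seed = as.integer(seed))
  truth_path <- file.path(out_dir, "truth.json")
  .write_json(truth, truth_path)
  invisible(list(
    od = od_path, layout = layout_path, truth_file = truth_path,
    truth = truth
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a shipped simulation scenario
#'
#' Named parameterizations of the protection assay covering the qualitative
#' phenotype space: `dms3vir_complete` (full interference in both media),
#' `lbp1_intermediate_LB` (partial interference, high-nutrient medium),
#' `lbp1_complete_M9` (same phage, low-nutrient medium), `phikz_none` (no
#' effective interference).
#'
#' @param name scenario name, or `NULL` to list available names.
#' @param path optional path to a YAML scenario file; defaults to the file
#'   shipped with the package.
#' @return scenario list (or character vector of names).
#' @export
load_scenario <- function(name = NULL, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scenarios.yaml", package = "phagemetrics")
  }
  all <- yaml::read_yaml(path)
  if (is.null(name)) {
    return(names(all))
  }
  if (!name %in% names(all)) {
    stop(
      "unknown scenario `", name, "`; available: ",
      paste(names(all), collapse = ", ")
    )
  }
  sc <- all[[name]]
  sc$name <- name
  sc
}

#' Simulate a phylogeny with a binary trait
#'
#' A pure-birth (Yule) tree with either a trait evolved under a two-state
#' equal-rates Markov process, or -- with `clustered = TRUE` -- a trait
#' assigned deterministically by membership in the two clades of the
#' deepest (root) split, giving maximal phylogenetic signal. In clustered
#' mode, trees are resampled until both root clades hold at least a quarter
#' of the tips, so the trait is a genuine two-clade partition rather than a
#' rare-state artefact.
#'
#' @param n_tips number of tips (>= 4).
#' @param birth_rate Yule speciation rate (default 1).
#' @param trait_rate ER transition rate per unit branch length.
#' @param clustered assign the trait by root-clade membership instead.
#' @param seed optional RNG seed.
#' @param states state labels (default `sensitive`/`resistant`).
#' @return a [trait_tree()].
#' @export
simulate_trait_tree <- function(n_tips, birth_rate = 1, trait_rate = 0.3,
                                clustered = FALSE, seed = NULL,
                                states = c("sensitive", "resistant")) {
  if (n_tips < 4) stop("need at least 4 tips")
  .with_seed(seed, {
    root_clade <- function(tree) {
      kids <- tree$edge[tree$edge[, 1] == n_tips + 1L, 2]
      if (kids[1] <= n_tips) {
        tree$tip.label[kids[1]]
      } else {
        ape::extract.clade(tree, kids[1])$tip.label
      }
    }
    tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    if (clustered) {
      clade1 <- root_clade(tree)
      tries <- 0L
      while (min(length(clade1), n_tips - length(clade1)) < n_tips / 4 &&
               tries < 1000L) {
        tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
        clade1 <- root_clade(tree)
        tries <- tries + 1L
      }
      st <- ifelse(tree$tip.label %in% clade1, states[1], states[2])
      names(st) <- tree$tip.label
    } else {
      st <- as.character(ape::rTraitDisc(
        tree,
        model = "ER", k = 2, rate = trait_rate, states = states
      ))
      names(st) <- tree$tip.label
    }
    trait_tree(tree, st)
  })
}
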