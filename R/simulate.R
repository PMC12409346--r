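#' Parameters of the bacteria-phage-CRISPR population model
#'
#' Mechanistic generative model for liquid-culture infection assays. A
#' nutrient-limited host population (susceptible S, surface-resistant R)
#' grows at Monod rate `r(N) = r_max N / (K_N + N)`; free phage P adsorb to
#' cells at rate `a`; in CRISPR-carrying hosts a fraction `c` of injected
#' genomes is destroyed by interference (the cell survives); successful
#' infections pass through `m` sequential latent stages of total mean
#' duration `tau` (Erlang-distributed latent period) before lysing and
#' releasing `B` progeny. Surface-resistant mutants arise at fraction `mu`
#' per division and do not adsorb phage at all, mirroring the distinction
#' between receptor-mutation resistance and CRISPR interference.
#'
#' @param r_max maximum growth rate (1/min).
#' @param K_N nutrient half-saturation (a.u.).
#' @param N0 initial nutrient (a.u.); sets carrying capacity `Y * N0`.
#' @param Y yield (cells per nutrient a.u.).
#' @param a adsorption rate constant (ml/(cell.min)).
#' @param tau mean latent period (min).
#' @param m number of latent stages (integer >= 1).
#' @param B burst size (phage per lysed cell).
#' @param c CRISPR interference probability in [0, 1].
#' @param mu resistant-mutant fraction per division in [0, 1].
#' @param delta_P free-phage decay rate (1/min).
#' @param alpha_od OD units per cell/ml.
#' @param S0,P0 initial susceptible-cell and free-phage densities (per ml).
#' @param seed integer seed recorded alongside the parameters.
#' @return a `sim_params` list.
#' @export
sim_params <- function(r_max = 0.025, K_N = 0.5, N0 = 10, Y = 1e8,
                       a = 5e-9, tau = 30, m = 20L, B = 50, c = 0,
                       mu = 1e-5, delta_P = 0.002, alpha_od = 1e-9,
                       S0 = 1e7, P0 = 0, seed = 1L) {
  p <- list(
    r_max = r_max, K_N = K_N, N0 = N0, Y = Y, a = a, tau = tau,
    m = as.integer(m), B = B, c = c, mu = mu, delta_P = delta_P,
    alpha_od = alpha_od, S0 = S0, P0 = P0, seed = as.integer(seed)
  )
  scalar <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && !is.na(x),
                   logical(1))
  if (!all(scalar)) {
    stop(
      "parameters must be finite scalars; offending: ",
      paste(names(p)[!scalar], collapse = ", ")
    )
  }
  rates <- c(r_max = r_max, K_N = K_N, N0 = N0, Y = Y, a = a, tau = tau,
             B = B, delta_P = delta_P, alpha_od = alpha_od, S0 = S0, P0 = P0)
  if (any(rates < 0)) stop("rates, sizes and densities must be >= 0")
  if (c < 0 || c > 1) stop("`c` must lie in [0, 1]")
  if (mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]")
  if (p$m < 1) stop("`m` must be >= 1")
  if (tau <= 0) stop("`tau` must be positive")
  class(p) <- "sim_params"
  p
}

# Right-hand side. State layout: N, S, I_1..I_m, R, P, then cumulative
# bookkeeping integrals: ads_S (phage adsorbed to S), ads_I (to I),
# matured (phage released), decayed.
.sim_deriv <- function(y, p) {
  m <- p$m
  n_nut <- y[1]
  s <- y[2]
  i_stages <- y[3:(2 + m)]
  r_cells <- y[3 + m]
  phage <- y[4 + m]
  r <- p$r_max * n_nut / (p$K_N + n_nut)
  ads_s <- p$a * s * phage
  ads_i <- p$a * sum(i_stages) * phage
  hop <- m / p$tau
  d_i <- numeric(m)
  d_i[1] <- (1 - p$c) * ads_s - hop * i_stages[1]
  if (m > 1) {
    d_i[2:m] <- hop * (i_stages[1:(m - 1)] - i_stages[2:m])
  }
  matured <- p$B * hop * i_stages[m]
  c(
    -(1 / p$Y) * r * (s + r_cells),
    r * s * (1 - p$mu) - (1 - p$c) * ads_s,
    d_i,
    r * r_cells + r * s * p$mu,
    matured - ads_s - ads_i - p$delta_P * phage,
    ads_s, ads_i, matured, p$delta_P * phage
  )
}

.rk4_step <- function(y, p, dt) {
  k1 <- .sim_deriv(y, p)
  k2 <- .sim_deriv(y + dt / 2 * k1, p)
  k3 <- .sim_deriv(y + dt / 2 * k2, p)
  k4 <- .sim_deriv(y + dt * k3, p)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Advance the infection model by one time step
#'
#' Classical 4th-order Runge-Kutta with fixed step `dt`; a step that drives
#' a compartment negative is retried with successive halving (the final
#' value is clamped at 0 when the residual undershoot is within rounding of
#' the compartment scale, and an error is raised if halving cannot cure it).
#'
#' @param state named state vector `c(N, S, I1..Im, R, P)`; the bookkeeping
#'   entries (`ads_S`, `ads_I`, `matured`, `decayed`) are appended
#'   automatically when absent.
#' @param params a [sim_params()] object.
#' @param dt time step (min), > 0.
#' @return the state after `dt`, same layout.
#' @export
step_dynamics <- function(state, params, dt) {
  if (dt <= 0) stop("`dt` must be positive")
  y <- as.numeric(state)
  want <- params$m + 8L
  if (length(y) == params$m + 4L) y <- c(y, numeric(4))
  if (length(y) != want) {
    stop("state must have ", params$m + 4L, " compartments")
  }
  tol <- -1e-9 * max(1, max(abs(y)))
  advance <- function(y, dt, depth) {
    y1 <- .rk4_step(y, params, dt)
    if (all(y1 >= tol)) {
      y1[y1 < 0] <- 0
      return(y1)
    }
    if (depth >= 20) {
      stop("integration step keeps producing negative compartments")
    }
    y_half <- advance(y, dt / 2, depth + 1)
    advance(y_half, dt / 2, depth + 1)
  }
  y_new <- advance(y, dt, 0)
  names(y_new) <- .sim_state_names(params$m)
  y_new
}

.sim_state_names <- function(m) {
  c(
    "N", "S", paste0("I", seq_len(m)), "R", "P",
    "ads_S", "ads_I", "matured", "decayed"
  )
}

.sim_init_state <- function(params) {
  y <- c(
    params$N0, params$S0, numeric(params$m), 0, params$P0,
    0, 0, 0, 0
  )
  names(y) <- .sim_state_names(params$m)
  y
}

#' Integrate the infection model over a time window
#'
#' Fixed-step RK4 from `t = 0` (state `N0, S0, P0`, no infected or resistant
#' cells) to `t_end`, recording the trajectory every `record_every` minutes.
#'
#' @param params a [sim_params()].
#' @param t_end end time (min).
#' @param dt integrator step (min), default 0.1.
#' @param record_every output spacing (min); defaults to `dt`.
#' @param init optional initial state vector replacing the default.
#' @return data.frame with columns `t`, `N`, `S`, `I_total`, `I_m`, `R`,
#'   `P`, `cells` (S + I + R), `od` (noiseless alpha_od x cells),
#'   `total_mature` (free plus intracellular mature phage: P + 0.5 B I_m),
#'   and the cumulative bookkeeping columns `ads_S`, `ads_I`, `matured`,
#'   `decayed`.
#' @export
run_dynamics <- function(params, t_end, dt = 0.1, record_every = NULL,
                         init = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (dt <= 0) stop("`dt` must be positive")
  if (t_end <= 0) stop("`t_end` must be positive")
  if (is.null(record_every)) record_every <- dt
  n_steps <- ceiling(t_end / dt - 1e-9)
  rec_stride <- max(1L, round(record_every / dt))
  y <- if (is.null(init)) .sim_init_state(params) else init
  m <- params$m
  idx_rec <- seq(0, n_steps, by = rec_stride)
  out <- matrix(NA_real_, length(idx_rec), length(y) + 1)
  row <- 1L
  summarize <- function(t, y) c(t, y)
  out[row, ] <- summarize(0, y)
  for (step in seq_len(n_steps)) {
    this_dt <- min(dt, t_end - (step - 1) * dt)
    y <- step_dynamics(y, params, this_dt)
    if (step %% rec_stride == 0 || step == n_steps) {
      row <- row + 1L
      if (row > nrow(out)) out <- rbind(out, NA_real_)
      out[row, ] <- summarize(min(step * dt, t_end), y)
    }
  }
  out <- out[seq_len(row), , drop = FALSE]
  colnames(out) <- c("t", .sim_state_names(m))
  df <- as.data.frame(out)
  i_cols <- paste0("I", seq_len(m))
  df$I_total <- rowSums(df[i_cols])
  df$I_m <- df[[paste0("I", m)]]
  df$cells <- df$S + df$I_total + df$R
  df$od <- params$alpha_od * df$cells
  df$total_mature <- df$P + 0.5 * params$B * df$I_m
  df[i_cols] <- NULL
  attr(df, "params") <- params
  attr(df, "final_state") <- y
  df
}

#' Observed OD with measurement noise
#'
#' @param cells cell density (per ml), or vector.
#' @param alpha_od OD per cell/ml.
#' @param noise_sd Gaussian measurement noise (OD units).
#' @return OD values, clamped at 0.
#' @export
observe_od <- function(cells, alpha_od = 1e-9, noise_sd = 0) {
  od <- alpha_od * cells
  if (noise_sd > 0) od <- od + stats::rnorm(length(od), 0, noise_sd)
  pmax(od, 0)
}

#' Observed plaque counts for a phage concentration
#'
#' Emulates spotting `spot_volume_ul` of a serial ten-fold dilution series
#' in `n_spots` replicate spots; counts are Poisson around the expected
#' plaque number (or exact rounded expectations with `noise = FALSE`).
#'
#' @param concentration pfu/ml in the sampled tube.
#' @param time sample time (min) recorded in the output.
#' @param sample sample id.
#' @param channel measurement channel label ("free" or "total_mature").
#' @param dilutions powers of ten to spot (default 0:9).
#' @param spot_volume_ul spot volume (default 2 ul).
#' @param n_spots replicate spots per dilution (default 3).
#' @param extra_exponent added to the recorded dilution exponent (used when
#'   the sampled tube is itself a known dilution of the culture of record).
#' @param noise Poisson counting noise (default TRUE).
#' @return data.frame of titre records.
#' @export
observe_titre <- function(concentration, time, sample = "sample",
                          channel = "total_mature", dilutions = 0:9,
                          spot_volume_ul = 2, n_spots = 3,
                          extra_exponent = 0, noise = TRUE) {
  vol_ml <- spot_volume_ul / 1000
  rows <- lapply(dilutions, function(d) {
    expected <- concentration * vol_ml / 10^d
    counts <- if (noise) {
      stats::rpois(n_spots, expected)
    } else {
      rep(round(expected), n_spots)
    }
    data.frame(
      sample = sample, time = time, channel = channel,
      dilution_exponent = d + extra_exponent,
      spot_volume_ul = spot_volume_ul, count = counts,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Evaluate an expression under a temporary RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old)) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv())) {
      rm(".Random.seed", envir = globalenv())
    },
    add = TRUE
  )
  set.seed(seed)
  force(expr)
}
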