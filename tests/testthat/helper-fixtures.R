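# Shared builders for synthetic test inputs.

make_ts <- function(times, values, ...) phage_ts(times, values, ...)

# standard one-step simulator settings used in recovery tests
onestep_params <- function(B = 100, tau = 30, ...) {
  sim_params(
    S0 = 4e8, P0 = 4e6, a = 2.5e-9, mu = 0, delta_P = 1e-3,
    B = B, tau = tau, m = 20, c = 0, ...
  )
}

# a small wide OD plate written to disk; returns paths
write_tiny_plate <- function(dir = tempfile("plate")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layout <- data.frame(
    well = c("A1", "A2"), strain = "WT", phage = c("phi", "none"),
    dose = c("high", "none"), medium = "high_nutrient", replicate = 1L
  )
  od <- data.frame(time = c(0, 10, 20), A1 = c(0.1, 0.2, 0.3),
                   A2 = c(0.1, 0.25, 0.4))
  od_path <- file.path(dir, "od.csv")
  layout_path <- file.path(dir, "layout.csv")
  write.csv(od, od_path, row.names = FALSE, quote = FALSE)
  write.csv(layout, layout_path, row.names = FALSE, quote = FALSE)
  list(od = od_path, layout = layout_path)
}

# replicate list of phage_ts on a common grid from a matrix of values
ts_reps <- function(times, mat) {
  lapply(seq_len(ncol(mat)), function(j) phage_ts(times, mat[, j]))
}
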