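test_that("trapezoid AUC matches closed forms and a dense quadrature oracle", {
  expect_equal(auc_trapezoid(make_ts(c(0, 100), c(0.5, 0.5))), 50)
  expect_equal(auc_trapezoid(make_ts(c(0, 100), c(0, 1))), 50)
  # interpolated upper limit
  expect_equal(auc_trapezoid(make_ts(c(0, 100), c(0.5, 0.5)), t_end = 30), 15)
  expect_error(auc_trapezoid(make_ts(c(10, 20), c(1, 1)), t_end = 5),
               "precedes")
  expect_error(auc_trapezoid(make_ts(c(10, 20), c(1, 1)), t_end = 25),
               "beyond")

  # oracle: dense Riemann sum on the linear interpolant, >= 1e4 subintervals
  # (grid includes the sample knots, where the interpolant is not smooth)
  set.seed(71)
  for (rep in 1:5) {
    t <- sort(runif(50, 0, 1000))
    v <- runif(50, 0, 2)
    s <- make_ts(t, v)
    t_end <- runif(1, t[2], max(t))
    grid <- sort(unique(c(seq(t[1], t_end, length.out = 10001), t[t < t_end])))
    f <- approx(t, v, xout = grid)$y
    riemann <- sum(diff(grid) * (f[-1] + f[-length(f)]) / 2)
    expect_equal(auc_trapezoid(s, t_end), riemann, tolerance = 1e-9)
  }
})

test_that("censoring finds the dose crossing, with fallback rules", {
  t <- seq(0, 1000, by = 100)
  # highest dose crosses the second-highest at t = 600
  hi <- ifelse(t >= 600, 0.8, 0.05)
  mid <- ifelse(t >= 200, 0.5, 0.05)
  lo <- rep(0.9, length(t))
  ds <- list(
    list(make_ts(t, hi)), list(make_ts(t, mid)), list(make_ts(t, lo))
  )
  res <- censor_time(ds)
  expect_equal(res$censor_time, 600)
  expect_equal(res$comparison_dose, 2)
  expect_true(res$crossed)

  # no crossing anywhere: full window kept
  ds2 <- list(
    list(make_ts(t, rep(0.05, 11))), list(make_ts(t, mid)),
    list(make_ts(t, lo))
  )
  expect_equal(censor_time(ds2)$censor_time, 1000)
  expect_false(censor_time(ds2)$crossed)

  # two highest doses unresolved: comparison falls back to the third
  ds3 <- list(
    list(make_ts(t, mid + 0.01)), list(make_ts(t, mid)), list(make_ts(t, lo))
  )
  res3 <- censor_time(ds3)
  expect_equal(res3$comparison_dose, 3)

  expect_error(censor_time(ds[1:2]), "3 dose levels")
})

test_that("simulated resistant regrowth is censored where the brute-force scan crosses", {
  p <- sim_params(S0 = 1e7, B = 50, tau = 35, c = 0, mu = 1e-5)
  fx <- write_virulence_fixture(p,
    out_dir = tempfile("vir"), seed = 2,
    replicates = 3, dt = 0.5
  )
  plate <- read_od_table(fx$od, read_plate_layout(fx$layout))
  doses <- paste0("d", 1:5)
  by_dose <- lapply(doses, function(d) {
    lapply(od_wells(plate, dose = d), function(w) od_series(plate, w))
  })
  res <- censor_time(by_dose)
  expect_true(res$crossed)

  # independent exhaustive scan with the same operational definition
  mean_curve <- function(reps) rowMeans(sapply(reps, function(s) s$values))
  m1 <- mean_curve(by_dose[[1]])
  m2 <- mean_curve(by_dose[[2]])
  t <- plate$times
  t_resolved <- t[which(m2 - m1 > 0.05)[1]]
  cross <- t[t > t_resolved & m1 > m2][1]
  expect_lte(abs(res$censor_time - cross), 20) # two sampling intervals
})

test_that("local virulence is 1 with no growth, 0 at control growth, unclamped", {
  control <- make_ts(c(0, 100), c(1, 1))
  expect_equal(local_virulence(make_ts(c(0, 100), c(0, 0)), control), 1)
  expect_equal(local_virulence(control, control), 0)
  expect_equal(local_virulence(make_ts(c(0, 100), c(0.5, 0.5)), control), 0.5)
  # growth above the control gives a negative value, reported raw
  expect_lt(local_virulence(make_ts(c(0, 100), c(2, 2)), control), 0)
  expect_error(
    local_virulence(control, make_ts(c(0, 100), c(0, 0))),
    "positive"
  )
})

test_that("virulence index integrates local virulence over log10 MOI", {
  moi5 <- 10^seq(-4, 0)
  expect_equal(virulence_index(moi5, rep(1, 5))$virulence_index, 1)
  expect_equal(virulence_index(moi5, rep(0, 5))$virulence_index, 0)
  # closed-form trapezoid: LV (0, 1) at log10 MOI (-4, -2) -> 0.5
  expect_equal(
    virulence_index(c(1e-4, 1e-2), c(0, 1))$virulence_index, 0.5
  )
  expect_error(virulence_index(0.1, 1), "at least 2")
  # clamping applies to the index only, flagged
  vi <- virulence_index(moi5, c(-0.2, 0, 0.5, 1, 1.1))
  expect_true(vi$clamped)
  expect_gte(vi$virulence_index, 0)
  expect_lte(vi$virulence_index, 1)
})

test_that("virulence index depends only on MOI ratios", {
  moi <- 10^seq(-4, 0)
  lv <- c(0.1, 0.3, 0.5, 0.8, 0.95)
  expect_equal(
    virulence_index(moi, lv)$virulence_index,
    virulence_index(moi * 10, lv)$virulence_index
  )
})

test_that("pointwise weaker suppression never increases local virulence", {
  control <- make_ts(seq(0, 100, 10), rep(1, 11))
  set.seed(9)
  for (i in 1:20) {
    v <- runif(11, 0, 1)
    bump <- runif(11, 0, 0.5)
    lv1 <- local_virulence(make_ts(seq(0, 100, 10), v), control)
    lv2 <- local_virulence(make_ts(seq(0, 100, 10), v + bump), control)
    expect_lte(lv2, lv1)
  }
})

test_that("MOI is the phage:cell ratio", {
  expect_equal(compute_moi(4e6, 4e8), 0.01)
  expect_equal(compute_moi(1e8, 1e8), 1)
  expect_equal(compute_moi(0, 1e8), 0)
  expect_error(compute_moi(1e6, 0), "positive")
})

test_that("virulence index rises with generating burst size", {
  b_grid <- c(5, 10, 20, 50, 100)
  vi <- vapply(b_grid, function(B) {
    p <- sim_params(S0 = 1e7, B = B, tau = 35, c = 0, mu = 1e-5)
    fx <- write_virulence_fixture(p,
      out_dir = tempfile("virB"), seed = 3,
      replicates = 2, dt = 0.5
    )
    plate <- read_od_table(fx$od, read_plate_layout(fx$layout))
    virulence_profile(plate, "phage", "WT",
      moi = unlist(fx$truth$moi)
    )$virulence_index
  }, numeric(1))
  expect_gt(cor(b_grid, vi, method = "spearman"), 0)
})
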