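test_that("phage-free runs conserve nutrient-cell mass balance", {
  p <- sim_params(P0 = 0, S0 = 1e7)
  tr <- run_dynamics(p, t_end = 23 * 60, dt = 0.5, record_every = 60)
  final <- tr[nrow(tr), ]
  expect_equal(final$S + final$R, p$S0 + p$Y * p$N0, tolerance = 0.01)
  # growth is logistic-like: monotone to the cap
  expect_true(all(diff(tr$cells) >= -1e-6 * max(tr$cells)))
})

test_that("complete interference reduces phage to pure decay", {
  base <- sim_params(P0 = 0, S0 = 1e7, B = 50, tau = 35)
  immune <- sim_params(P0 = 1e6, S0 = 1e7, B = 50, tau = 35, c = 1)
  tr0 <- run_dynamics(base, t_end = 600, dt = 0.25, record_every = 30)
  tr1 <- run_dynamics(immune, t_end = 600, dt = 0.25, record_every = 30)
  expect_true(all(abs(tr1$S - tr0$S) <= 0.01 * tr0$S))
  expect_true(all(diff(tr1$P) <= 0)) # only decays (to numerical zero)
  expect_lt(tr1$P[nrow(tr1)], tr1$P[1])
  expect_equal(tr1$I_total[nrow(tr1)], 0)
})

test_that("free-phage losses are accounted by adsorption and decay", {
  p <- sim_params(P0 = 1e6, S0 = 1e7, B = 50, tau = 35, c = 0.5)
  tr <- run_dynamics(p, t_end = 400, dt = 0.25, record_every = 100)
  f <- tr[nrow(tr), ]
  balance <- p$P0 + f$matured - f$ads_S - f$ads_I - f$decayed
  expect_equal(f$P, balance, tolerance = 1e-6)
})

test_that("step integrator validates inputs", {
  p <- sim_params()
  y <- c(p$N0, p$S0, numeric(p$m), 0, p$P0)
  expect_error(step_dynamics(y, p, 0), "positive")
  expect_error(step_dynamics(y[1:3], p, 0.1), "compartments")
})

test_that("observation models are linear and Poisson-calibrated", {
  expect_equal(observe_od(2e8, alpha_od = 1e-9), 0.2)
  expect_equal(observe_od(4e8, alpha_od = 1e-9), 2 * observe_od(2e8, 1e-9))
  set.seed(77)
  zero <- observe_od(rep(0, 500), noise_sd = 0.01)
  expect_true(all(zero >= 0))
  expect_lt(mean(zero), 0.02)

  # expected count 20 at dilution 4 for 1e8 pfu/ml in 2 ul spots
  set.seed(78)
  rec <- do.call(rbind, replicate(34, # ~100 spots
    observe_titre(1e8, time = 0, dilutions = 4),
    simplify = FALSE
  ))
  expect_equal(mean(rec$count), 20, tolerance = 3 / 20)
  # noise-free counts are exact expectations
  exact <- observe_titre(1e8, time = 0, dilutions = 4, noise = FALSE)
  expect_true(all(exact$count == 20))
})

test_that("fixtures are deterministic given a seed and structurally correct", {
  p <- onestep_params(B = 50, tau = 25)
  d1 <- tempfile("fx1")
  d2 <- tempfile("fx2")
  f1 <- write_onestep_fixture(p, d1, seed = 9)
  f2 <- write_onestep_fixture(p, d2, seed = 9)
  expect_identical(readLines(f1$titres), readLines(f2$titres))

  pv <- sim_params(S0 = 1e7, B = 50, tau = 35, mu = 1e-5)
  v1 <- write_virulence_fixture(pv, out_dir = tempfile(), seed = 4,
                                replicates = 2, t_end = 60, dt = 0.5)
  v2 <- write_virulence_fixture(pv, out_dir = tempfile(), seed = 4,
                                replicates = 2, t_end = 60, dt = 0.5)
  expect_identical(readLines(v1$od), readLines(v2$od))

  # 5 ten-fold steps -> exactly 5 phage doses plus a no-phage control
  layout <- read_plate_layout(v1$layout)
  expect_setequal(unique(layout$dose), c(paste0("d", 1:5), "none"))
  expect_equal(length(unlist(v1$truth$moi)), 5)
})

test_that("trait-tree simulation is seeded and clusters when asked", {
  t1 <- simulate_trait_tree(16, clustered = TRUE, seed = 12)
  t2 <- simulate_trait_tree(16, clustered = TRUE, seed = 12)
  expect_identical(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  expect_identical(t1$states, t2$states)

  # clustered trait partitions the two root clades perfectly
  root <- 17L
  kids <- t1$tree$edge[t1$tree$edge[, 1] == root, 2]
  clade1 <- if (kids[1] <= 16) {
    t1$tree$tip.label[kids[1]]
  } else {
    ape::extract.clade(t1$tree, kids[1])$tip.label
  }
  st <- setNames(t1$state_levels[t1$states], t1$tree$tip.label)
  expect_length(unique(st[clade1]), 1)
  expect_length(unique(st[setdiff(t1$tree$tip.label, clade1)]), 1)
  expect_false(unique(st[clade1]) ==
                 unique(st[setdiff(t1$tree$tip.label, clade1)]))

  # fast trait evolution approaches independent coin flips
  t3 <- simulate_trait_tree(200, trait_rate = 60, seed = 13)
  tab <- table(t3$states)
  expect_gt(chisq.test(tab, p = c(0.5, 0.5))$p.value, 0.05)
})

test_that("scenario configs load and expose the documented fields", {
  names <- load_scenario()
  expect_setequal(
    names,
    c(
      "dms3vir_complete", "lbp1_intermediate_LB", "lbp1_complete_M9",
      "phikz_none"
    )
  )
  sc <- load_scenario("lbp1_intermediate_LB")
  expect_equal(sc$name, "lbp1_intermediate_LB")
  expect_true(all(c("phage", "media", "S0", "doses", "replicates") %in%
                    names(sc)))
  expect_lt(sc$media$high_nutrient$c, 1)
  expect_error(load_scenario("nope"), "unknown scenario")
})
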