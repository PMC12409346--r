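test_that("log transform triggers only across three decades", {
  wide <- maybe_log_transform(c(1, 10, 2000))
  expect_true(wide$transformed)
  expect_equal(wide$values, log10(c(1, 10, 2000)))
  expect_false(maybe_log_transform(c(1, 2, 3))$transformed)
  expect_false(maybe_log_transform(c(1, 999))$transformed)
  expect_true(maybe_log_transform(c(1, 1000))$transformed) # boundary
  expect_error(maybe_log_transform(c(-1, 5000)), "positive")
})

test_that("Welch t matches stats::t.test across random small samples", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  sep <- welch_t(c(1, 2, 3), c(11, 12, 13))
  expect_lt(sep$p_value, 0.01)

  set.seed(33)
  for (i in 1:200) {
    a <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:8, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    ref <- t.test(a, b) # Welch by default: the independent oracle
    mine <- welch_t(a, b)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
  }

  # zero-variance corner cases
  expect_equal(welch_t(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  expect_equal(welch_t(c(1, 1, 1), c(2, 2, 2))$p_value, 0)
})

test_that("Welch p-values are uniform under the null", {
  set.seed(101)
  p <- vapply(seq_len(10000), function(i) {
    welch_t(rnorm(5), rnorm(5))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("BH adjustment reproduces the hand-computed step-up and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))

  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_fdr(p), p.adjust(p, method = "BH"))
  }
})

test_that("BH is monotone, order-preserving and above raw", {
  set.seed(8)
  p <- sort(runif(15))
  adj <- bh_fdr(p)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # re-adjustment is not the identity (the step-up rescales any input),
  # but it must track the reference implementation under composition
  expect_equal(bh_fdr(adj), p.adjust(adj, method = "BH"))
})

test_that("one-way ANOVA F matches the sums-of-squares oracle and aov", {
  g3 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  same <- one_way_anova(g3)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # two groups: F equals the square of the pooled t statistic
  a <- c(1.2, 1.9, 2.4, 3.1)
  b <- c(2.0, 2.8, 3.5)
  f2 <- one_way_anova(list(a, b))
  t_pooled <- t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(f2$statistic, unname(t_pooled)^2, tolerance = 1e-10)

  set.seed(12)
  for (i in 1:25) {
    groups <- lapply(1:3, function(j) rnorm(sample(3:7, 1), mean = j / 2))
    mine <- one_way_anova(groups)
    # brute-force sums of squares, written out independently
    all_v <- unlist(groups)
    ss_tot <- sum((all_v - mean(all_v))^2)
    ss_w <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
    ss_b <- ss_tot - ss_w
    f_ref <- (ss_b / 2) / (ss_w / (length(all_v) - 3))
    expect_equal(mine$statistic, f_ref, tolerance = 1e-10)
    # and the fitted-model route
    df <- data.frame(
      y = all_v,
      g = factor(rep(seq_along(groups), lengths(groups)))
    )
    ref <- anova(aov(y ~ g, data = df))
    expect_equal(mine$statistic, ref[1, "F value"], tolerance = 1e-8)
    expect_equal(mine$p_value, ref[1, "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("Tukey HSD agrees with stats::TukeyHSD", {
  set.seed(21)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(5, mean = j * 0.4))
    names(groups) <- paste0("g", seq_len(k))
    mine <- tukey_hsd(groups)
    df <- data.frame(
      y = unlist(groups),
      g = factor(rep(names(groups), lengths(groups)))
    )
    ref <- TukeyHSD(aov(y ~ g, data = df))$g
    key <- paste(mine$group2, mine$group1, sep = "-")
    expect_equal(mine$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-6)
    expect_equal(mine$diff, unname(ref[key, "diff"]), tolerance = 1e-10)
  }
})
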