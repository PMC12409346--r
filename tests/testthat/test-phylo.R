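test_that("trait_tree validates tips, states and branch lengths", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  st <- c(a = "x", b = "x", c = "y", d = "y")
  tt <- trait_tree(tr, st)
  expect_equal(tt$k, 2)
  expect_false(tt$degenerate)
  expect_error(trait_tree(tr, st[-1]), "no state")
  expect_warning(
    trait_tree(ape::read.tree(text = "((a:1,b:0):1,(c:1,d:1):1);"), st),
    "replaced by eps"
  )
  same <- trait_tree(tr, c(a = "x", b = "x", c = "x", d = "x"))
  expect_true(same$degenerate)
  expect_error(delta_statistic(same), "degenerate|single state")
})

test_that("marginal probabilities sum to one and respect symmetry limits", {
  tt <- simulate_trait_tree(12, trait_rate = 0.5, seed = 2)
  probs <- marginal_ancestral_probs(tt)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-12))

  # cherry of matching states: the shared ancestor leans to that state
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  tt2 <- trait_tree(tr, c(a = "A", b = "A", c = "B", d = "B"))
  probs2 <- marginal_ancestral_probs(tt2, rate = 0.2)
  # node numbering: 5 = root, 6 = (a,b) ancestor, 7 = (c,d) ancestor
  expect_gt(probs2["6", "A"], 0.5)
  expect_gt(probs2["7", "B"], 0.5)

  # saturation: very long branches wash out to uniform 1/k
  tr_long <- ape::read.tree(text = "((a:500,b:500):500,(c:500,d:500):500);")
  tt3 <- trait_tree(tr_long, c(a = "A", b = "A", c = "B", d = "B"))
  probs3 <- marginal_ancestral_probs(tt3, rate = 1)
  expect_true(all(abs(probs3 - 0.5) < 1e-3))
})

test_that("marginals equal exhaustive enumeration over internal states", {
  # oracle: sum transition-probability products over every assignment of
  # states to internal nodes, then normalize per node
  brute_marginals <- function(tree, states_int, q, k) {
    prep <- phagemetrics:::.tt_prep(tree)
    nn <- prep$nnode
    grids <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
    pm <- function(t) {
      e <- exp(-k * q * t)
      m <- matrix((1 - e) / k, k, k)
      diag(m) <- (1 - e) / k + e
      m
    }
    lik <- apply(grids, 1, function(assign) {
      st <- c(states_int, assign)
      l <- 1 / k
      for (e in seq_len(nrow(prep$edge))) {
        l <- l * pm(prep$len[e])[st[prep$edge[e, 1]], st[prep$edge[e, 2]]]
      }
      l
    })
    out <- matrix(0, nn, k)
    for (j in seq_len(nn)) {
      for (s in seq_len(k)) out[j, s] <- sum(lik[grids[, j] == s])
    }
    out / rowSums(out)
  }
  set.seed(42)
  for (i in 1:5) {
    tt <- simulate_trait_tree(5, trait_rate = 1, seed = 40 + i)
    if (tt$degenerate) next
    for (q in c(0.1, 1, 5)) {
      mine <- marginal_ancestral_probs(tt, rate = q)
      ref <- brute_marginals(tt$tree, tt$states, q, tt$k)
      expect_lt(max(abs(unclass(mine) - ref)), 1e-8)
    }
  }
})

test_that("delta is nonnegative, zero at maximal uncertainty, label-invariant", {
  tt <- simulate_trait_tree(12, trait_rate = 1, seed = 3)
  expect_gte(delta_statistic(tt), 0)

  # uniform node vectors (full saturation) pin delta at its minimum, 0
  tr_long <- ape::read.tree(text = "((a:500,b:500):500,(c:500,d:500):500);")
  tt_sat <- trait_tree(tr_long, c(a = "A", b = "A", c = "B", d = "B"))
  expect_lt(delta_statistic(tt_sat, rate = 1), 1e-2)

  # relabeling the categories changes nothing
  flip <- c(A = "B", B = "A")
  st <- setNames(
    tt$state_levels[tt$states], tt$tree$tip.label
  )
  st_named <- setNames(ifelse(st == tt$state_levels[1], "A", "B"), names(st))
  tt_a <- trait_tree(tt$tree, st_named)
  tt_b <- trait_tree(tt$tree, setNames(flip[st_named], names(st_named)))
  expect_equal(delta_statistic(tt_a), delta_statistic(tt_b), tolerance = 1e-10)
})

test_that("delta grows as ancestral uncertainty falls", {
  # same topology, increasingly clock-stretched branches: short branches
  # resolve ancestors sharply, long ones do not
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  st <- c(a = "A", b = "A", c = "B", d = "B")
  deltas <- vapply(c(0.05, 0.5, 5), function(scale) {
    tr2 <- tr
    tr2$edge.length <- tr$edge.length * scale
    delta_statistic(trait_tree(tr2, st), rate = 1)
  }, numeric(1))
  expect_true(all(diff(deltas) < 0))
})

test_that("clade-segregating traits beat their permutation null", {
  tt <- simulate_trait_tree(16, clustered = TRUE, seed = 5)
  res <- delta_pvalue(tt, n_perm = 199, seed = 9)
  expect_gt(res$delta, quantile(res$perm_deltas, 0.95))
  expect_lt(res$p_value, 0.05)
})

test_that("permutation p-value follows the add-one formula and is reproducible", {
  tt <- simulate_trait_tree(10, trait_rate = 0.5, seed = 6)
  r1 <- delta_pvalue(tt, n_perm = 99, seed = 31)
  r2 <- delta_pvalue(tt, n_perm = 99, seed = 31)
  expect_identical(r1$perm_deltas, r2$perm_deltas)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(
    r1$p_value,
    (1 + sum(r1$perm_deltas >= r1$delta)) / (1 + 99)
  )
  # formula extremes
  expect_equal((1 + 0) / (1 + 99), 0.01)
  expect_error(delta_pvalue(tt, n_perm = 10), "at least 99")
})
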