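#' Couple a categorical tip trait to a phylogeny
#'
#' Validates a rooted tree with branch lengths against a tip-state table for
#' use in the phylogenetic-signal screen. Zero or missing branch lengths are
#' replaced by a small epsilon (the pruning algorithm requires positive
#' lengths), with a warning.
#'
#' @param tree an `ape::phylo` tree (e.g. from [ape::read.tree()]).
#' @param tip_states named vector (names = tip labels) of categorical
#'   states, or a data.frame with columns `tip` and `state`.
#' @param eps replacement for zero/absent branch lengths (default 1e-8).
#' @return object of class `trait_tree`.
#' @export
trait_tree <- function(tree, tip_states, eps = 1e-8) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape phylo object")
  if (is.data.frame(tip_states)) {
    if (!all(c("tip", "state") %in% names(tip_states))) {
      stop("trait table needs columns `tip` and `state`")
    }
    st <- stats::setNames(as.character(tip_states$state), tip_states$tip)
  } else {
    st <- tip_states
  }
  if (is.null(names(st))) stop("tip states must be named by tip label")
  missing_tips <- setdiff(tree$tip.label, names(st))
  if (length(missing_tips)) {
    stop("no state for tip(s): ", paste(missing_tips, collapse = ", "))
  }
  st <- st[tree$tip.label]
  if (anyNA(st)) stop("missing states are not allowed")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; all set to eps")
    tree$edge.length <- rep(eps, nrow(tree$edge))
  }
  if (any(tree$edge.length <= 0 | is.na(tree$edge.length))) {
    warning("non-positive/missing branch lengths replaced by eps")
    bad <- tree$edge.length <= 0 | is.na(tree$edge.length)
    tree$edge.length[bad] <- eps
  }
  if (length(tree$tip.label) < 4) stop("need at least 4 tips")
  f <- factor(as.character(st))
  structure(
    list(
      tree = tree,
      states = as.integer(f),
      state_levels = levels(f),
      k = nlevels(f),
      degenerate = nlevels(f) < 2
    ),
    class = "trait_tree"
  )
}

# Postorder traversal cache shared by the likelihood, marginal and
# permutation machinery.
.tt_prep <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(
    edge = tr$edge,
    len = tr$edge.length,
    ntip = length(tr$tip.label),
    nnode = tr$Nnode,
    root = tr$edge[nrow(tr$edge), 1],
    tip_label = tr$tip.label
  )
}

# Equal-rates (ER) Mk transition probabilities have the closed form
# P_ii = 1/k + (k-1)/k * exp(-k q t), P_ij = (1 - exp(-k q t)) / k.
.er_pmat <- function(q, t, k) {
  e <- exp(-k * q * t)
  p_off <- (1 - e) / k
  m <- matrix(p_off, k, k)
  diag(m) <- p_off + e
  m
}

# Felsenstein pruning: per-node conditional likelihoods of the tip data
# below each node, with per-node rescaling. Returns the matrix of scaled
# partials, the per-edge messages to the parent, and the total
# log-likelihood. Exploits the ER closed form P v = ((1-e)/k) sum(v) + e v
# with e = exp(-k q t), so no transition matrices are materialized.
.er_pass <- function(prep, states, q, k) {
  nmax <- prep$ntip + prep$nnode
  d <- matrix(1, nmax, k)
  d[seq_len(prep$ntip), ] <- 0
  d[cbind(seq_len(prep$ntip), states)] <- 1
  msg <- matrix(NA_real_, nrow(prep$edge), k)
  ev <- exp(-k * q * prep$len)
  logl <- 0
  for (i in seq_len(nrow(prep$edge))) {
    par <- prep$edge[i, 1]
    ch <- prep$edge[i, 2]
    v <- d[ch, ]
    m <- ((1 - ev[i]) / k) * sum(v) + ev[i] * v
    s <- max(m)
    if (s <= 0) {
      return(list(logl = -Inf))
    }
    m <- m / s
    logl <- logl + log(s)
    msg[i, ] <- m
    d[par, ] <- d[par, ] * m
  }
  logl <- logl + log(sum(d[prep$root, ] / k))
  list(d = d, msg = msg, logl = logl)
}

# Scalar specialization of the pruning pass for binary traits (the common
# case in interference phenotyping); avoids matrix-row indexing overhead in
# the permutation loops.
.er_pass2 <- function(prep, states, q) {
  nmax <- prep$ntip + prep$nnode
  ntip <- prep$ntip
  da <- rep(1, nmax)
  db <- rep(1, nmax)
  da[seq_len(ntip)] <- as.numeric(states == 1L)
  db[seq_len(ntip)] <- as.numeric(states == 2L)
  ne <- nrow(prep$edge)
  msga <- numeric(ne)
  msgb <- numeric(ne)
  ev <- exp(-2 * q * prep$len)
  epar <- prep$edge[, 1]
  ech <- prep$edge[, 2]
  logl <- 0
  for (i in seq_len(ne)) {
    ch <- ech[i]
    va <- da[ch]
    vb <- db[ch]
    half <- (1 - ev[i]) * 0.5 * (va + vb)
    ma <- half + ev[i] * va
    mb <- half + ev[i] * vb
    s <- if (ma > mb) ma else mb
    if (s <= 0) {
      return(list(logl = -Inf))
    }
    ma <- ma / s
    mb <- mb / s
    logl <- logl + log(s)
    msga[i] <- ma
    msgb[i] <- mb
    par <- epar[i]
    da[par] <- da[par] * ma
    db[par] <- db[par] * mb
  }
  logl <- logl + log((da[prep$root] + db[prep$root]) / 2)
  list(
    d = cbind(da, db), msg = cbind(msga, msgb), logl = logl
  )
}

.er_loglik <- function(prep, states, q, k) {
  if (k == 2L) {
    return(.er_pass2(prep, states, q)$logl)
  }
  .er_pass(prep, states, q, k)$logl
}

# ML fit of the single ER rate by golden-section search on log(q). The rate
# is capped at ~4 expected changes per median branch: beyond that the model
# is saturated (transition probabilities uniform to machine precision) and
# the likelihood flat, so an uncapped fit would park permuted datasets at an
# arbitrary boundary where node posteriors -- and hence the signal statistic
# -- tie exactly.
.er_fit_rate <- function(prep, states, k) {
  q_max <- 4 / stats::median(prep$len)
  f <- function(lq) -.er_loglik(prep, states, exp(lq), k)
  opt <- stats::optimize(f,
    interval = c(log(1e-7), log(q_max)), tol = 1e-3
  )
  exp(opt$minimum)
}

# Marginal ancestral probabilities by the up-down algorithm: combine each
# node's downward partial with the likelihood of the data outside its
# subtree.
.er_marginals <- function(prep, states, q, k) {
  pass <- if (k == 2L) {
    .er_pass2(prep, states, q)
  } else {
    .er_pass(prep, states, q, k)
  }
  if (!is.finite(pass$logl)) stop("zero likelihood; check the rate")
  d <- pass$d
  msg <- pass$msg
  nmax <- prep$ntip + prep$nnode
  u <- matrix(NA_real_, nmax, k)
  u[prep$root, ] <- 1 / k
  edges_from <- split(seq_len(nrow(prep$edge)), prep$edge[, 1])
  ev <- exp(-k * q * prep$len)
  # children were filled in postorder; walking edges in reverse gives a
  # valid preorder (parents before children)
  for (i in rev(seq_len(nrow(prep$edge)))) {
    par <- prep$edge[i, 1]
    ch <- prep$edge[i, 2]
    if (ch <= prep$ntip) next
    w <- u[par, ] # product of the sibling messages, excluding this edge
    for (j in edges_from[[as.character(par)]]) {
      if (j != i) w <- w * msg[j, ]
    }
    # symmetric P: w %*% P has the same ER closed form
    uc <- ((1 - ev[i]) / k) * sum(w) + ev[i] * w
    u[ch, ] <- uc / max(uc)
  }
  nodes <- (prep$ntip + 1):nmax
  probs <- u[nodes, , drop = FALSE] * d[nodes, , drop = FALSE]
  probs <- probs / rowSums(probs)
  rownames(probs) <- nodes
  probs
}

#' Marginal ancestral state probabilities under an equal-rates Mk model
#'
#' Fits the single rate of a k-state equal-rates Markov model to the tip
#' states by maximum likelihood, then computes, for every internal node, the
#' marginal posterior probability of each state by combining the pruning
#' (downward) partial likelihoods with the complementary upward partials.
#'
#' @param tt a [trait_tree()].
#' @param rate optional fixed rate; fitted by ML when `NULL`.
#' @return matrix (internal nodes x states) of probabilities, each row
#'   summing to 1, with the fitted rate in `attr(, "rate")` and the tip
#'   log-likelihood in `attr(, "loglik")`.
#' @export
marginal_ancestral_probs <- function(tt, rate = NULL) {
  stopifnot(inherits(tt, "trait_tree"))
  if (tt$degenerate) {
    stop("all tips share one state; ancestral probabilities are degenerate")
  }
  prep <- .tt_prep(tt$tree)
  states <- tt$states[match(prep$tip_label, tt$tree$tip.label)]
  k <- tt$k
  if (is.null(rate)) rate <- .er_fit_rate(prep, states, k)
  probs <- .er_marginals(prep, states, rate, k)
  colnames(probs) <- tt$state_levels
  attr(probs, "rate") <- rate
  attr(probs, "loglik") <- .er_loglik(prep, states, rate, k)
  probs
}

.entropies <- function(probs) {
  apply(probs, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
}

#' Phylogenetic signal of a categorical trait (delta statistic)
#'
#' Summarizes how decisively the phylogeny resolves the ancestral states of
#' a categorical tip trait. Each internal node contributes the Shannon
#' entropy H_i of its marginal ancestral state distribution; delta is the
#' entropy-ratio
#' \deqn{\delta = \sum_i (H_{max} - H_i) / \sum_i H_i,}{delta = sum(Hmax - H_i) / sum(H_i),}
#' with H_max = log k. Uniform (maximally uncertain) node distributions give
#' delta = 0; delta grows without bound as ancestral-state uncertainty
#' vanishes, i.e. when trait similarity tracks phylogenetic relatedness.
#' Values near 0 indicate no correlation between phylogeny and trait. The
#' statistic is invariant to relabeling of the state categories.
#'
#' @param tt a [trait_tree()] with a non-degenerate trait.
#' @param rate optional fixed ER rate (ML-fitted when `NULL`).
#' @return non-negative delta value.
#' @export
delta_statistic <- function(tt, rate = NULL) {
  probs <- marginal_ancestral_probs(tt, rate = rate)
  h <- .entropies(probs)
  hmax <- log(ncol(probs))
  sum(hmax - h) / max(sum(h), 1e-9)
}

#' Permutation p-value for the delta statistic
#'
#' Recomputes delta on `n_perm` random permutations of the tip states
#' (rate refitted each time) and returns the add-one permutation p-value
#' `(1 + #{delta_perm >= delta_obs}) / (1 + n_perm)`.
#'
#' @param tt a [trait_tree()].
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed optional integer seed; the caller's RNG state is restored on
#'   exit, and results are reproducible bit-for-bit for a fixed seed.
#' @return object of class `delta_signal`: list with `delta`, `p_value`,
#'   `n_perm`, `perm_deltas`, `rate`.
#' @export
delta_pvalue <- function(tt, n_perm = 999, seed = NULL) {
  stopifnot(inherits(tt, "trait_tree"))
  if (n_perm < 99) stop("use at least 99 permutations")
  if (tt$degenerate) stop("trait is degenerate (single state)")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit(
      if (!is.null(old)) assign(".Random.seed", old, globalenv()),
      add = TRUE
    )
    set.seed(seed)
  }
  prep <- .tt_prep(tt$tree)
  states <- tt$states[match(prep$tip_label, tt$tree$tip.label)]
  k <- tt$k
  hmax <- log(k)
  delta_of <- function(st) {
    q <- .er_fit_rate(prep, st, k)
    h <- .entropies(.er_marginals(prep, st, q, k))
    list(delta = sum(hmax - h) / max(sum(h), 1e-9), rate = q)
  }
  obs <- delta_of(states)
  perm <- vapply(seq_len(n_perm), function(i) {
    delta_of(sample(states))$delta
  }, numeric(1))
  structure(
    list(
      delta = obs$delta,
      p_value = (1 + sum(perm >= obs$delta)) / (1 + n_perm),
      n_perm = n_perm,
      perm_deltas = perm,
      rate = obs$rate
    ),
    class = "delta_signal"
  )
}

#' @export
print.delta_signal <- function(x, ...) {
  cat("Categorical phylogenetic signal (entropy-ratio delta)\n")
  cat(sprintf(
    "  delta = %.4g, permutation p = %.4g (%d permutations)\n",
    x$delta, x$p_value, x$n_perm
  ))
  cat(sprintf(
    "  ML equal-rates transition rate = %.4g per unit branch length\n",
    x$rate
  ))
  invisible(x)
}
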