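# Inferential procedures implemented from their defining formulas so that
# every statistical step in the pipeline is transparent and unit-testable
# against independent references.

#' Conditional log10 transform for wide-ranging data
#'
#' Values ranging over three powers of ten or more (max/min >= 1000) are
#' log10-transformed to normalize residuals before testing; narrower data are
#' returned unchanged.
#'
#' @param values numeric vector.
#' @return list with `values` and `transformed` flag.
#' @export
maybe_log_transform <- function(values) {
  if (length(values) == 0) stop("empty input")
  if (anyNA(values)) stop("missing values not allowed")
  rng_ok <- all(values > 0)
  ratio <- if (rng_ok) max(values) / min(values) else Inf
  if (ratio >= 1000) {
    if (!rng_ok) {
      stop("log transform triggered but values are not all positive")
    }
    list(values = log10(values), transformed = TRUE)
  } else {
    list(values = values, transformed = FALSE)
  }
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value. Two zero-variance samples with equal means give p = 1;
#' with different means the statistic is infinite and p = 0.
#'
#' @param a,b numeric samples (length >= 2 each).
#' @return a `test_result` list: `statistic`, `df`, `p_value`, `method`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  na <- length(a)
  nb <- length(b)
  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  delta <- mean(a) - mean(b)
  if (va + vb == 0) {
    if (delta == 0) {
      return(test_result(0, NA_real_, 1, "Welch two-sample t-test"))
    }
    return(test_result(
      sign(delta) * Inf, NA_real_, 0,
      "Welch two-sample t-test"
    ))
  }
  t_stat <- delta / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  test_result(t_stat, df, p, "Welch two-sample t-test")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up rule: order the m p-values increasingly, multiply the i-th by
#' m / i, enforce monotonicity by a reverse cumulative minimum, cap at 1 and
#' restore the input order.
#'
#' @param pvalues numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  if (m <= 1) {
    return(pvalues)
  }
  o <- order(pvalues)
  scaled <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' One-way analysis of variance
#'
#' F statistic from between-group and within-group sums of squares with an
#' upper-tail p-value from the F distribution.
#'
#' @param groups list of >= 2 numeric samples.
#' @return a `test_result` with `statistic` (F), `df` (c(df1, df2)),
#'   `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("`groups` must be a list of at least two samples")
  }
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) stop("each group needs >= 2 values")
  k <- length(groups)
  all_vals <- unlist(groups)
  grand <- mean(all_vals)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(
    seq_len(k),
    function(i) sum((groups[[i]] - means[i])^2), numeric(1)
  ))
  df1 <- k - 1
  df2 <- sum(n) - k
  ms_between <- ss_between / df1
  ms_within <- ss_within / df2
  if (ms_within == 0) {
    f_stat <- if (ms_between == 0) 0 else Inf
    p <- if (ms_between == 0) 1 else 0
  } else {
    f_stat <- ms_between / ms_within
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  res <- test_result(f_stat, c(df1, df2), p, "One-way ANOVA")
  res$ss_between <- ss_between
  res$ss_within <- ss_within
  res
}

#' Tukey honest-significant-difference post hoc comparisons
#'
#' For each pair of groups, the studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt((MSE / 2) (1/n_i + 1/n_j))` is referred to
#' the studentized-range distribution with `k` groups and the ANOVA residual
#' degrees of freedom (Tukey-Kramer for unbalanced designs).
#'
#' @param groups named list of >= 2 numeric samples.
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`,
#'   `q`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  aov_res <- one_way_anova(groups)
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  means <- vapply(groups, mean, numeric(1))
  df2 <- sum(n) - k
  mse <- aov_res$ss_within / df2
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    stringsAsFactors = FALSE
  )
  se <- sqrt((mse / 2) * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  out$q <- abs(out$diff) / se
  out$q[se == 0 & out$diff == 0] <- 0
  out$p_adj <- ifelse(
    is.finite(out$q),
    stats::ptukey(out$q, nmeans = k, df = df2, lower.tail = FALSE),
    0
  )
  out$p_adj[out$q == 0] <- 1
  rownames(out) <- NULL
  out
}

test_result <- function(statistic, df, p_value, method) {
  structure(
    list(
      statistic = statistic, df = df,
      p_value = p_value, method = method
    ),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(
    "  statistic =", formatC(x$statistic, digits = 5),
    " df =", paste(formatC(x$df, digits = 4), collapse = ", "),
    " p =", format.pval(x$p_value, digits = 4), "\n"
  )
  invisible(x)
}
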