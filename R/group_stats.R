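test_result <- function(test_name, statistic, df, p_value, tail,
                        degenerate = FALSE) {
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, tail = tail, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s (%s): statistic = %.6g, df = %s, p = %.6g%s\n",
              x$test_name, x$tail, x$statistic,
              if (is.null(x$df) || is.na(x$df)) "NA" else format(x$df),
              x$p_value, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

match_tail <- function(tail) {
  match.arg(tail, c("one_tailed_less", "one_tailed_greater", "two_tailed"))
}

#' Welch's t-test with a caller-specified tail
#'
#' Two-sample t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom), used to compare cell velocity
#' and persistence between genotype groups.  The tail is stated by the
#' caller: `one_tailed_less` tests whether the first sample's mean is
#' smaller (e.g. mutant persistence below wild type when the mutant sample
#' is passed first).
#'
#' If both samples have zero variance the t statistic is undefined; equal
#' means give a flagged degenerate result with p = 0.5 (one-tailed) and
#' perfectly separated means give p of 0 or 1 according to the tail.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 2 finite
#'   values.
#' @param tail `"one_tailed_less"`, `"one_tailed_greater"` (direction of
#'   `sample_a` relative to `sample_b`) or `"two_tailed"`.
#' @return A `test_result` with fields `statistic`, `df`, `p_value`,
#'   `test_name`, `tail`, `degenerate`.
#' @export
welch_t_one_tailed <- function(sample_a, sample_b, tail = "one_tailed_less") {
  tail <- match_tail(tail)
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    input_error("each sample needs at least 2 values")
  }
  if (!all(is.finite(sample_a)) || !all(is.finite(sample_b))) {
    input_error("samples must be finite")
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    d <- mean(sample_a) - mean(sample_b)
    if (d == 0) {
      p <- if (tail == "two_tailed") 1 else 0.5
      return(test_result("welch_t", 0, NA_real_, p, tail, degenerate = TRUE))
    }
    p <- switch(tail,
                two_tailed = 0,
                one_tailed_less = as.numeric(d > 0),
                one_tailed_greater = as.numeric(d < 0))
    return(test_result("welch_t", sign(d) * Inf, NA_real_, p, tail,
                       degenerate = TRUE))
  }
  alt <- switch(tail, one_tailed_less = "less", one_tailed_greater = "greater",
                two_tailed = "two.sided")
  fit <- stats::t.test(sample_a, sample_b, alternative = alt, var.equal = FALSE)
  test_result("welch_t", unname(fit$statistic), unname(fit$parameter),
              fit$p.value, tail)
}

#' Pearson chi-square test of independence
#'
#' Classic R x C test (no continuity correction): expected counts from the
#' margins, statistic sum((O - E)^2 / E), df (R-1)(C-1), upper-tail p.
#' Used on the binned deviation-angle distributions of two groups.
#'
#' @param table Matrix of non-negative counts; every row and column sum
#'   must be positive.
#' @return A `test_result`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(!is.finite(table))) {
    input_error("counts must be finite and non-negative")
  }
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0)) input_error(sprintf("row %d has zero total", which(rs == 0)[1]))
  if (any(cs == 0)) input_error(sprintf("column %d has zero total", which(cs == 0)[1]))
  fit <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  test_result("chi_square_independence", unname(fit$statistic),
              unname(fit$parameter), fit$p.value, "two_tailed")
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on the hypergeometric distribution of the
#' top-left cell given the margins.  The two-tailed p-value follows the
#' probability-mass convention: the sum of the probabilities of all tables
#' (same margins) no more likely than the observed one, with a small
#' relative tolerance (1e-7) when comparing probabilities so floating-point
#' ties count as ties.  One-tailed p-values are the lower/upper
#' hypergeometric tails of the observed cell.
#'
#' @param table 2x2 matrix of non-negative counts, grand total >= 1.
#' @param tail See [welch_t_one_tailed()]; `one_tailed_less` puts the mass
#'   on tables with a smaller top-left cell.
#' @return A `test_result`; `statistic` is the observed top-left count.
#' @export
fisher_exact <- function(table, tail = "two_tailed") {
  tail <- match_tail(tail)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) input_error("table must be 2x2")
  if (any(table < 0) || any(table != round(table)) || any(!is.finite(table))) {
    input_error("counts must be non-negative integers")
  }
  if (sum(table) < 1) input_error("grand total must be >= 1")
  a <- table[1, 1]
  m <- sum(table[1, ])
  n2 <- sum(table[2, ])
  k <- sum(table[, 1])
  p <- switch(
    tail,
    one_tailed_less = stats::phyper(a, m, n2, k),
    one_tailed_greater = stats::phyper(a - 1, m, n2, k, lower.tail = FALSE),
    two_tailed = {
      support <- max(0, k - n2):min(k, m)
      probs <- stats::dhyper(support, m, n2, k)
      p_obs <- probs[support == a]
      sum(probs[probs <= p_obs * (1 + 1e-7)])
    })
  test_result("fisher_exact", a, NA_real_, min(p, 1), tail)
}

#' Tukey-Kramer all-pairs comparison of group means
#'
#' For k groups (possibly unbalanced), computes the pooled within-group
#' mean square MSE on N - k degrees of freedom and, for every pair, the
#' studentized-range statistic
#' `q = |mean_a - mean_b| / sqrt(MSE/2 * (1/n_a + 1/n_b))`,
#' with the adjusted p-value from the studentized-range distribution with
#' k means and N - k df (`ptukey`).  This is the multiple-comparison
#' procedure used on pouch and ceratobranchial scores across genotypes.
#'
#' If MSE is 0 (no within-group variation), pairs with equal means get
#' p = 1 and pairs with different means p = 0, flagged in the `degenerate`
#' attribute.
#'
#' @param groups Named list of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 finite values).
#' @return A data frame of class `pairwise_comparisons`: `group_a`,
#'   `group_b`, `mean_diff` (a minus b), `q_statistic`, `p_adjusted`;
#'   attributes `mse` and `df`.
#' @export
tukey_kramer <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups)) ||
      any(!nzchar(names(groups)))) {
    input_error("groups must be a named list of at least 2 numeric vectors")
  }
  ns <- lengths(groups)
  if (any(ns < 2L)) input_error("every group needs at least 2 values")
  if (!all(vapply(groups, function(g) all(is.finite(g)), logical(1)))) {
    input_error("group values must be finite")
  }
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- N - k
  mse <- sse / df
  pairs <- utils::combn(k, 2L)
  degenerate <- mse == 0
  rows <- apply(pairs, 2L, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- means[i] - means[j]
    if (degenerate) {
      q <- if (d == 0) 0 else Inf
      p <- if (d == 0) 1 else 0
    } else {
      q <- abs(d) / sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }
    data.frame(group_a = names(groups)[i], group_b = names(groups)[j],
               mean_diff = unname(d), q_statistic = unname(q),
               p_adjusted = unname(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("pairwise_comparisons", "data.frame"),
            mse = mse, df = df, degenerate = degenerate)
}

#' Chi-square comparison of two angle histograms
#'
#' Stacks the two count vectors into a 2 x n_bins table and tests
#' independence of group and direction bin.  Bins empty in both groups are
#' dropped first (the df shrinks accordingly) so no expected count is 0/0.
#'
#' @param hist_a,hist_b `angle_histogram` objects on identical bin edges.
#' @return A `test_result` from [chi_square_independence()].
#' @export
compare_angle_distributions <- function(hist_a, hist_b) {
  if (!inherits(hist_a, "angle_histogram") || !inherits(hist_b, "angle_histogram")) {
    input_error("both arguments must be angle_histogram objects")
  }
  if (length(hist_a$bin_edges_deg) != length(hist_b$bin_edges_deg) ||
      any(abs(hist_a$bin_edges_deg - hist_b$bin_edges_deg) > 1e-9)) {
    input_error("histograms have mismatched bin edges")
  }
  tab <- rbind(hist_a$counts, hist_b$counts)
  keep <- colSums(tab) > 0
  if (sum(keep) < 2L) {
    input_error("fewer than 2 bins contain counts; nothing to compare")
  }
  chi_square_independence(tab[, keep, drop = FALSE])
}
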