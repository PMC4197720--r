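test_that("Welch test handles symmetric, separated and degenerate samples", {
  x <- c(1.1, 2.0, 2.9, 4.2)
  same <- welch_t_one_tailed(x, x, "one_tailed_less")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 0.5)
  jit <- c(1e-9, -1e-9)
  sep <- welch_t_one_tailed(c(0, 0) + jit, c(1, 1) + jit, "one_tailed_less")
  expect_lt(sep$p_value, 1e-6)
  # both samples constant: t undefined, flagged
  deg <- welch_t_one_tailed(c(2, 2), c(2, 2), "one_tailed_less")
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0.5)
  deg2 <- welch_t_one_tailed(c(0, 0), c(1, 1), "one_tailed_less")
  expect_true(deg2$degenerate)
  expect_equal(deg2$p_value, 0)
  expect_error(welch_t_one_tailed(1, c(1, 2)), "2 values")
})

test_that("Welch one-tailed p agrees with a label-permutation oracle", {
  a <- c(1.2, 1.9, 2.1, 2.8)
  b <- c(2.9, 3.1, 3.8)
  res <- welch_t_one_tailed(a, b, "one_tailed_less")
  pool <- c(a, b)
  tstat <- function(x, y) {
    (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
  }
  set.seed(42)
  perm <- vapply(1:50000, function(i) {
    idx <- sample(7, 4)
    tstat(pool[idx], pool[-idx])
  }, numeric(1))
  p_perm <- mean(perm <= res$statistic)
  # with n = 7 the permutation null resolves p only to multiples of
  # 1/choose(7,4); agreement is asserted at that granularity plus MC error
  expect_lt(abs(res$p_value - p_perm), 1 / choose(7, 4) + 3 * sd(perm <= res$statistic) / sqrt(50000))
})

test_that("Welch rejection under the null is calibrated at the 5% level", {
  rej <- vapply(1:2000, function(i) {
    set.seed(i)
    welch_t_one_tailed(rnorm(20), rnorm(20), "one_tailed_less")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("chi-square independence matches the direct formula and corners", {
  flat <- matrix(10, 2, 2)
  res <- chi_square_independence(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  prop <- rbind(c(2, 4, 6), c(3, 6, 9))  # proportional rows
  expect_equal(chi_square_independence(prop)$statistic, 0, tolerance = 1e-12)
  # 2 x 8 angle-bin style table against a from-scratch expected-count oracle
  set.seed(12)
  tab <- matrix(rpois(16, 20) + 1, 2, 8)
  res2 <- chi_square_independence(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res2$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(res2$df, 7)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "row 1")
  expect_error(chi_square_independence(rbind(c(0, 1), c(0, 2))), "column 1")
})

test_that("Fisher's exact test matches enumeration and its symmetries", {
  expect_equal(fisher_exact(matrix(5, 2, 2))$p_value, 1)
  tab <- matrix(c(1, 9, 11, 3), 2, 2, byrow = TRUE)
  expect_equal(fisher_exact(tab)$p_value,
               stats::fisher.test(tab)$p.value, tolerance = 1e-12)
  # row+column swap leaves the table's evidence unchanged
  swapped <- tab[2:1, 2:1]
  expect_equal(fisher_exact(swapped)$p_value, fisher_exact(tab)$p_value,
               tolerance = 1e-12)
  # one-tailed p-values are hypergeometric tails
  expect_equal(fisher_exact(tab, "one_tailed_less")$p_value,
               stats::fisher.test(tab, alternative = "less")$p.value,
               tolerance = 1e-12)
  expect_equal(fisher_exact(tab, "one_tailed_greater")$p_value,
               stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_error(fisher_exact(matrix(0, 2, 2)), "grand total")
  expect_error(fisher_exact(matrix(1:6, 2, 3)), "2x2")
})

test_that("Tukey-Kramer reduces to the pooled t-test for two groups", {
  set.seed(5)
  a <- rnorm(6)
  b <- rnorm(9, 1)
  tk <- tukey_kramer(list(a = a, b = b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(tk$p_adjusted, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey-Kramer agrees with TukeyHSD on unbalanced groups", {
  set.seed(5)
  g <- list(x = rnorm(5), y = rnorm(7, 0.8), z = rnorm(4, 1.5))
  tk <- tukey_kramer(g)
  df <- data.frame(v = unlist(g), gr = rep(names(g), lengths(g)))
  hsd <- stats::TukeyHSD(stats::aov(v ~ gr, df))$gr
  expect_equal(tk$p_adjusted, unname(hsd[c("y-x", "z-x", "z-y"), "p adj"]),
               tolerance = 1e-8)
  expect_equal(tk$mean_diff, -unname(hsd[c("y-x", "z-x", "z-y"), "diff"]),
               tolerance = 1e-10)
})

test_that("Tukey-Kramer degenerates predictably and is monotone", {
  same <- tukey_kramer(list(a = c(3, 3), b = c(3, 3), c = c(3, 3)))
  expect_true(all(same$q_statistic == 0))
  expect_true(all(same$p_adjusted == 1))
  # inflating one group mean strictly shrinks its pairwise p-values
  base <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  p0 <- tukey_kramer(base)
  shifted <- base
  shifted$c <- shifted$c + 2
  p1 <- tukey_kramer(shifted)
  idx <- p0$group_a == "c" | p0$group_b == "c"
  expect_true(all(p1$p_adjusted[idx] < p0$p_adjusted[idx]))
  expect_error(tukey_kramer(list(a = 1:3)), "2")
  expect_error(tukey_kramer(list(a = 1, b = 1:3)), "at least 2 values")
})

test_that("angle-distribution comparison drops empty bins and checks edges", {
  h1 <- bin_angles(c(-10, 5, 20, 40), 8, "g1")
  expect_equal(compare_angle_distributions(h1, h1)$p_value, 1)
  h2 <- bin_angles(c(-100, -50, 100, 170), 8, "g2")
  res <- compare_angle_distributions(h1, h2)
  occupied <- sum(colSums(rbind(h1$counts, h2$counts)) > 0)
  expect_equal(res$df, occupied - 1)
  h4 <- bin_angles(c(-10, 5), 4, "g4")
  expect_error(compare_angle_distributions(h1, h4), "bin edges")
})

test_that("label swaps reflect the tail and leave two-tailed p unchanged", {
  set.seed(9)
  a <- rnorm(8)
  b <- rnorm(10, 0.5)
  expect_equal(welch_t_one_tailed(a, b, "two_tailed")$p_value,
               welch_t_one_tailed(b, a, "two_tailed")$p_value)
  expect_equal(welch_t_one_tailed(a, b, "one_tailed_less")$p_value +
                 welch_t_one_tailed(b, a, "one_tailed_less")$p_value,
               1, tolerance = 1e-10)
  tab <- matrix(c(3, 7, 8, 2), 2, 2)
  expect_equal(fisher_exact(tab, "one_tailed_less")$p_value +
                 fisher_exact(tab[2:1, ], "one_tailed_less")$p_value,
               1 + stats::dhyper(tab[1, 1], sum(tab[1, ]), sum(tab[2, ]),
                                 sum(tab[, 1])),
               tolerance = 1e-12)
})
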