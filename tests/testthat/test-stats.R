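test_that("exact Mann-Whitney matches brute-force enumeration and R", {
  set.seed(31)
  cases <- list(c(3, 4), c(5, 5), c(6, 6), c(4, 7))
  for (ns in cases) {
    x <- rnorm(ns[1]); y <- rnorm(ns[2])  # continuous: no ties
    got <- mann_whitney_exact(x, y)
    expect_true(got$exact)
    expect_equal(got$p_value, brute_mwu_two_sided(x, y))
    expect_equal(got$p_value, wilcox.test(x, y, exact = TRUE)$p.value)
    expect_equal(got$p_denominator, choose(sum(ns), ns[1]))
  }
  # balanced U: p = 1
  even <- mann_whitney_exact(c(1, 4), c(2, 3))
  expect_equal(even$statistic, 2)
  expect_equal(even$p_value, 1)
  expect_error(mann_whitney_exact(numeric(0), 1:3), "empty")
  # ties fall back to the corrected normal approximation
  tied <- mann_whitney_exact(c(1, 2, 2, 3), c(2, 3, 4, 5))
  expect_false(tied$exact)
  expect_equal(tied$p_value,
               wilcox.test(c(1, 2, 2, 3), c(2, 3, 4, 5),
                           exact = FALSE, correct = TRUE)$p.value)
})

test_that("exact Mann-Whitney is conservative under the null", {
  set.seed(55)
  reps <- 4000
  rej <- 0
  dist <- mwu_count_distribution(6, 6)
  denom <- choose(12, 6)
  cum <- cumsum(dist)
  for (r in seq_len(reps)) {
    x <- rnorm(6); y <- rnorm(6)
    p <- mann_whitney_exact(x, y)$p_value
    rej <- rej + (p <= 0.05)
  }
  expect_lte(rej / reps, 0.05)
  # and the discrete null makes that conservatism exact: the attainable
  # size at alpha = 0.05 computed from the U distribution itself
  us <- 0:36
  p_at <- pmin(1, 2 * cum[pmin(us, 36 - us) + 1] / denom)
  alpha_eff <- sum(dist[p_at <= 0.05]) / denom
  expect_lte(alpha_eff, 0.05)
})

test_that("exact signed-rank enumeration matches hand counts and R", {
  all_pos <- wilcoxon_signed_rank_exact(c(0.3, 1.2, 2.1, 0.7, 5),
                                        alternative = "greater")
  expect_equal(all_pos$p_value, 1 / 32)
  expect_equal(wilcoxon_signed_rank_exact(c(0.3, 1.2, 2.1, 0.7, 5))$p_value,
               0.0625)
  neg8 <- wilcoxon_signed_rank_exact(-(1:8), alternative = "less")
  expect_equal(neg8$p_value, 1 / 256)
  expect_equal(neg8$p_numerator, 1)
  expect_equal(neg8$p_denominator, 256)

  # antisymmetric differences: W+ sits at the center, two-sided p = 1
  expect_equal(wilcoxon_signed_rank_exact(c(-2, -1, 1, 2))$p_value, 1)
  expect_equal(wilcoxon_signed_rank_exact(c(-3, -1, 1, 4, -4, 3))$p_value, 1)

  set.seed(77)
  for (n in c(6, 10, 15)) {
    d <- rnorm(n)
    got <- wilcoxon_signed_rank_exact(d)
    expect_true(got$exact)
    expect_equal(got$p_value, wilcox.test(d, exact = TRUE)$p.value)
  }
  expect_error(wilcoxon_signed_rank_exact(c(0, 0)), "all differences zero")
  # zero differences are dropped before ranking
  expect_equal(wilcoxon_signed_rank_exact(c(0, 1, 2, 3))$p_value,
               wilcoxon_signed_rank_exact(c(1, 2, 3))$p_value)
})

test_that("exact Fisher test enumerates the hypergeometric tail", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  sep <- fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(sep$p_value, 2 / 184756)
  set.seed(13)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    two <- fisher_exact_2x2(tab)$p_value
    expect_equal(two, fisher.test(tab)$p.value, tolerance = 1e-10)
    one <- min(fisher_exact_2x2(tab, "less")$p_value,
               fisher_exact_2x2(tab, "greater")$p_value)
    expect_lte(one, two + 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("Spearman correlation matches the rank formula and bootstraps", {
  x <- c(10, 20, 30, 40, 50)
  y <- c(3, 1, 4, 1.5, 9)
  got <- spearman_test(x, y)
  d <- rank(x) - rank(y)
  rho_formula <- 1 - 6 * sum(d^2) / (5 * (25 - 1))
  expect_equal(got$statistic, rho_formula)
  expect_equal(got$p_value,
               cor.test(x, y, method = "spearman", exact = FALSE)$p.value)

  mono <- spearman_test(1:10, exp(1:10), bootstrap = list(B = 200, seed = 1))
  expect_equal(mono$statistic, 1)
  expect_equal(mono$boot_ci, c(1, 1))
  expect_equal(spearman_test(1:10, -(1:10))$statistic, -1)
  expect_error(spearman_test(1:5, rep(2, 5)), "constant")
})

test_that("Cohen's d pools variances with n-1 weights", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(0.5, 1.5, 0.8, 1.2); b <- c(-0.5, 0.5, -0.2, 0.2)
  sp <- sqrt((3 * var(a) + 3 * var(b)) / 6)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_error(cohens_d(1, 1:3), "n >= 2")
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled")
})
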