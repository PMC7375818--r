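test_that("chi-squared statistic follows the marginal-product expectation", {
  flat <- chi2_contingency(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  tr <- chi2_contingency(rbind(c(10, 20), c(20, 10)))
  expect_equal(tr$statistic, 4 * 25 / 15)   # all E_ij = 15
  expect_equal(round_half_up(tr$statistic, 3), 6.667)
  expect_equal(tr$df, 1)
  expect_identical(tr$n_basis, "synapses")
  expect_identical(tr$alpha, 0.001)

  # E_ij row sums reproduce the row totals exactly, for arbitrary tables
  set.seed(2)
  for (i in 1:10) {
    tab <- matrix(rpois(12, 40) + 1, 3, 4)
    e <- chi2_contingency(tab)$expected
    expect_equal(rowSums(e), rowSums(tab), tolerance = 1e-12)
    expect_equal(colSums(e), colSums(tab), tolerance = 1e-12)
    # agreement with the uncorrected reference implementation
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    mine <- chi2_contingency(tab)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    # invariance under row/column permutation
    perm <- chi2_contingency(tab[sample(3), sample(4)])
    expect_equal(perm$statistic, mine$statistic, tolerance = 1e-12)
  }
  expect_error(chi2_contingency(matrix(0, 2, 2)), "all-zero")
})

test_that("pairwise post-hoc chi-squared runs 2x2 sub-tables", {
  tab <- rbind(AS = c(SO = 2648, dSP = 3849, sSP = 5183),
               SS = c(166, 281, 196))
  pw <- suppressWarnings(chi2_posthoc_pairwise(tab))
  expect_identical(nrow(pw), 3L)
  ref <- suppressWarnings(chisq.test(tab[, c("dSP", "sSP")],
                                     correct = FALSE))
  row <- pw[pw$group1 == "dSP" & pw$group2 == "sSP", ]
  expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_true(row$significant)   # dSP vs sSP AS share differs strongly
})

test_that("identical samples yield null results across the battery", {
  x <- c(1.2, 3.4, 2.2, 5.5, 4.1)
  ks <- suppressWarnings(ks_two_sample(x, x))
  expect_equal(ks$statistic, 0)
  mw <- mann_whitney(x, x)
  expect_equal(mw$p, 1)
  an <- anova_tukey(list(a = c(1, 2, 3), b = c(2, 1, 3), c = c(3, 2, 1)))
  expect_equal(an$statistic, 0, tolerance = 1e-12)
  expect_identical(nrow(an$pairwise), 3L)
})

test_that("Mann-Whitney p matches exhaustive rank-permutation enumeration", {
  set.seed(7)
  cases <- list(c(3, 4), c(4, 4), c(5, 3), c(6, 5), c(8, 7))
  for (sz in cases) {
    x <- round(runif(sz[1], 0, 100), 3)
    y <- round(runif(sz[2], 20, 120), 3)
    got <- mann_whitney(x, y)$p
    expect_equal(got, mw_exact_enum(x, y), tolerance = 1e-9)
  }
})

test_that("size-distribution fits recover parameters and rank families", {
  set.seed(91)
  x <- rlnorm(5000, 11.0, 0.9)
  fit <- fit_size_distribution(x, "lognormal")
  expect_lt(abs(fit$params["meanlog"] - 11.0), 3 * 0.9 / sqrt(5000))
  expect_lt(abs(fit$params["sdlog"] - 0.9), 3 * 0.9 / sqrt(2 * 5000))
  expect_true(fit$ks >= 0 && fit$ks <= 1)

  # log-logistic MLE recovers its own parameters
  u <- runif(5000)
  y <- 6e4 * (u / (1 - u))^(1 / 4)
  fll <- fit_size_distribution(y, "loglogistic")
  expect_lt(abs(fll$params["scale"] - 6e4) / 6e4, 0.05)
  expect_lt(abs(fll$params["shape"] - 4) / 4, 0.05)

  # on log-normal data, AIC prefers the log-normal family
  fln <- fit_size_distribution(x, "lognormal")
  fll2 <- fit_size_distribution(x, "loglogistic")
  expect_lt(fln$aic, fll2$aic)

  expect_error(fit_size_distribution(c(-1, 2, rep(3, 10))), "positive")
  expect_error(fit_size_distribution(rep(5, 20)), "constant")
  expect_error(fit_size_distribution(c(1, 2, 3)), "at least 10")
})

test_that("R-squared is the squared Pearson correlation, sign-free", {
  x <- 1:10
  expect_equal(r_squared(x, 2 * x + 1), 1)
  expect_equal(r_squared(x, -x + 0.001 * rnorm(10)), 1, tolerance = 1e-4)
  x4 <- c(1, 2, 4, 7); y4 <- c(2, 3, 9, 11)
  direct <- (sum((x4 - mean(x4)) * (y4 - mean(y4))))^2 /
    (sum((x4 - mean(x4))^2) * sum((y4 - mean(y4))^2))
  expect_equal(r_squared(x4, y4), direct, tolerance = 1e-12)
  expect_error(r_squared(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("dual significance thresholds attach to the sampling basis", {
  expect_equal(significance_alpha("subjects"), 0.05)
  expect_equal(significance_alpha("synapses"), 0.001)
  tr <- mann_whitney(rnorm(5), rnorm(5) + 10)
  expect_identical(tr$alpha, 0.05)
  expect_identical(tr$significant, tr$p < 0.05)
})
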