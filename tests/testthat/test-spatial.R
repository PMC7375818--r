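test_that("nearest-neighbour distances match the pairwise oracle", {
  g <- cube10()
  two <- point_pattern(rbind(c(1000, 1000, 1000), c(1000, 1000, 1100)), g)
  expect_equal(nn_distances(two), c(100, 100))
  expect_error(nn_distances(point_pattern(matrix(1, 1, 3), g)), "at least 2")

  pts <- generate_csr_points(g, NULL, n = 200, seed = 17)
  pat <- point_pattern(pts, g)
  expect_equal(nn_distances(pat), naive_nn(pts), tolerance = 1e-12)

  # adding a remote point can only decrease or keep others' distances
  pts2 <- rbind(pts, c(9999, 9999, 9999))
  nn2 <- naive_nn(pts2)
  expect_true(all(nn2[1:200] <= naive_nn(pts) + 1e-12))

  # CSR mean nearest-neighbour distance matches the closed form
  # E = gamma(4/3) * (4 pi lambda / 3)^(-1/3), checked on interior points
  # (border distance > 2000 nm) to avoid edge truncation
  lam <- 0.67
  pool_d <- c(); pool_b <- c()
  for (s in 1:3) {
    p <- generate_csr_points(g, lam, seed = 40 + s)
    pool_d <- c(pool_d, nn_distances(point_pattern(p, g)))
    pool_b <- c(pool_b, pmin(p[, 1], 10000 - p[, 1], p[, 2], 10000 - p[, 2],
                             p[, 3], 10000 - p[, 3]))
  }
  interior <- pool_b > 2000
  d_int <- pool_d[interior]
  theo <- gamma(4 / 3) * (4 * pi * lam * 1e-9 / 3)^(-1 / 3)
  expect_lt(abs(mean(d_int) - theo), 3 * sd(d_int) / sqrt(length(d_int)))
})

test_that("G, F and K estimators agree with CSR theory and basic laws", {
  g <- cube10()
  pat <- point_pattern(generate_csr_points(g, NULL, n = 1000, seed = 23), g)

  G <- estimate_G(pat)
  F_ <- estimate_F(pat)
  K <- estimate_K(pat)
  for (res in list(G, F_, K)) {
    expect_equal(res$obs[1], 0)       # r = 0
    expect_equal(res$theo[1], 0)
    d <- diff(res$obs[!is.na(res$obs)])
    expect_true(all(d >= -1e-12))     # nondecreasing
  }
  expect_true(all(G$obs >= 0 & G$obs <= 1, na.rm = TRUE))
  expect_true(all(F_$obs >= 0 & F_$obs <= 1, na.rm = TRUE))
  expect_true(all(K$obs >= 0, na.rm = TRUE))

  # observed curves track the CSR theory closely at n = 1000
  expect_lt(max(abs(G$obs - G$theo), na.rm = TRUE), 0.05)
  expect_lt(max(abs(F_$obs - F_$theo), na.rm = TRUE), 0.05)
  rel_k <- abs(K$obs[-1] - K$theo[-1]) / pmax(K$theo[-1], 1e5)
  expect_lt(stats::median(rel_k, na.rm = TRUE), 0.25)

  # r grid beyond the half-diagonal is truncated with a warning
  expect_warning(estimate_G(pat, r = seq(0, 2e4, length.out = 10)),
                 "truncat")
})

test_that("hard-core patterns show an empty G below the inhibition radius", {
  g <- cube10()
  hc <- generate_hardcore_points(g, 500, min_dist = 500, seed = 7)
  pat <- point_pattern(hc, g)
  expect_gte(min(nn_distances(pat)), 500)
  G <- estimate_G(pat, r = seq(0, 2500, length.out = 50))
  expect_true(all(G$obs[G$r < 500] == 0, na.rm = TRUE))
  # well below the CSR expectation just under the hard-core distance
  k_at <- max(which(G$r < 500))
  expect_lt(G$obs[k_at], G$theo[k_at])
})

test_that("CSR envelopes are reproducible and degrade gracefully", {
  g <- cube10()
  pat <- point_pattern(generate_csr_points(g, NULL, n = 300, seed = 3), g)

  e1 <- csr_envelope(pat, "G", n_sim = 19, seed = 101)
  e2 <- csr_envelope(pat, "G", n_sim = 19, seed = 101)
  expect_identical(e1$lo, e2$lo)
  expect_identical(e1$hi, e2$hi)
  expect_identical(e1$verdict, e2$verdict)

  # a single pointwise simulation collapses the envelope onto that curve
  e3 <- csr_envelope(pat, "K", n_sim = 1, seed = 5, type = "pointwise")
  expect_identical(e3$lo, e3$hi)

  # the global band is symmetric around theory and contains it
  e4 <- csr_envelope(pat, "K", n_sim = 19, seed = 6)
  expect_true(all(e4$lo <= e4$theo & e4$theo <= e4$hi))

  df <- as.data.frame(e1)
  expect_named(df, c("r", "observed", "theoretical", "lo", "hi"))
  expect_identical(nrow(df), length(e1$r))
})
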