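test_that("CSR generator is contained, reproducible and Poisson-calibrated", {
  g <- cube10()
  expect_identical(nrow(generate_csr_points(g, 0, seed = 1)), 0L)
  expect_error(generate_csr_points(g, -1), "intensity")

  pts <- generate_csr_points(g, 0.67, seed = 3)
  expect_true(all(pts >= 0))
  expect_true(all(pts[, 1] < 10000 & pts[, 2] < 10000 & pts[, 3] < 10000))
  expect_identical(pts, generate_csr_points(g, 0.67, seed = 3))
  expect_false(identical(pts, generate_csr_points(g, 0.67, seed = 4)))

  # mean count over 200 seeds vs Poisson(0.67 * 1000) = 670
  counts <- vapply(1:200, function(s)
    nrow(generate_csr_points(g, 0.67, seed = s)), numeric(1))
  se <- sqrt(670 / 200)
  expect_lt(abs(mean(counts) - 670), 3 * se)
})

test_that("population mixes converge to the profile probabilities", {
  profs <- ca1_layer_profiles()
  # SO: 94.10% AS; volume chosen so that n ~ 10,000
  g <- stack_geometry(30000, 30000, 30000 / 1.215)
  pop <- generate_population(g, profs$SO, seed = 11)
  n <- nrow(pop)
  expect_gt(n, 5000)
  p_hat <- mean(pop$polarity == "AS")
  se <- sqrt(0.9410 * 0.0590 / n)
  expect_lt(abs(p_hat - 0.9410), 3 * se)

  # log-normal SAS area calibrated to the AS mean of the pooled profile
  as_rows <- pop$polarity == "AS"
  m <- profs$SO$size_model$AS
  true_mean <- exp(m$meanlog + m$sdlog^2 / 2)
  true_sd <- true_mean * sqrt(exp(m$sdlog^2) - 1)
  se_mean <- true_sd / sqrt(sum(as_rows))
  expect_lt(abs(mean(pop$sas_area_nm2[as_rows]) - true_mean), 3 * se_mean)

  # chi-squared goodness of fit of sampled categoricals at n ~ 50,000
  g2 <- stack_geometry(50000, 50000, 50000 / 2.75)
  pop2 <- generate_population(g2, profs$SO, seed = 12)
  as2 <- pop2[pop2$polarity == "AS", ]
  obs <- table(factor(as2$target, levels = names(profs$SO$target_probs$AS)))
  gof <- suppressWarnings(
    chisq.test(obs, p = profs$SO$target_probs$AS))
  expect_gt(gof$p.value, 0.001)
  obs_sh <- table(factor(as2$shape_class,
                         levels = names(profs$SO$shape_probs$AS)))
  gof_sh <- suppressWarnings(
    chisq.test(obs_sh, p = profs$SO$shape_probs$AS))
  expect_gt(gof_sh$p.value, 0.001)

  # record invariants
  expect_true(all(pop$sas_area_nm2 > 0))
  expect_true(all(pop$sas_perimeter_nm > 0))
  expect_true(all(pop$sas_curvature >= 0 & pop$sas_curvature < 1))
  expect_true(all(pop$layer == "SO"))

  # zero intensity -> empty table
  empty <- generate_population(g, toy_profile(intensity = 0), seed = 1)
  expect_identical(nrow(empty), 0L)

  # invalid probability vector rejected
  bad <- toy_profile()
  expect_error(layer_profile("SO", 0.5, 0.9,
    target_probs = list(AS = c(spine_head = 0.9, spine_neck = 0.2,
                               shaft_spiny = 0, shaft_aspiny = 0,
                               unknown = 0),
                        SS = bad$target_probs$SS),
    shape_probs = bad$shape_probs, size_model = bad$size_model),
    "sum to 1")
})

test_that("artifact masks hit the target fraction on the stack voxel grid", {
  g <- stack_geometry(5000, 5000, 2000, voxel_xy = 50, voxel_z = 40)
  expect_identical(dim(generate_artifact_mask(g, 0)), c(100L, 100L, 50L))
  expect_true(all(generate_artifact_mask(g, 0) == 0L))

  m <- generate_artifact_mask(g, 0.12, seed = 5)
  expect_identical(dim(m), c(100L, 100L, 50L))
  frac <- mean(m > 0)
  expect_gte(frac, 0.11)
  expect_lte(frac, 0.13)
  expect_identical(m, generate_artifact_mask(g, 0.12, seed = 5))
  expect_error(generate_artifact_mask(g, 0.7), "fraction")
})

test_that("semithin label images match the requested volume fractions", {
  half <- generate_semithin_labels(c(a = 50, b = 50), c(128L, 128L), seed = 2)
  expect_equal(half$vv_true, c(50, 50))

  # pyramidal-layer-like profile: neurons occupy 4.23%
  sp <- generate_semithin_labels(
    c(blood_vessels = 4.79, glia = 0.87, neurons = 4.23, neuropil = 90.11),
    c(512L, 512L), seed = 7)
  expect_equal(sum(sp$vv_true), 100)
  expect_gte(sp$vv_true[3], 3.73)
  expect_lte(sp$vv_true[3], 4.73)
  expect_error(generate_semithin_labels(c(a = 60, b = 50)), "sum to 100")
})
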