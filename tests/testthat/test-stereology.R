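test_that("Cavalieri point counting recovers known pixel shares", {
  # half/half image split down the middle, grid points off the boundary
  labels <- cbind(matrix(1L, 64, 32), matrix(2L, 64, 32))
  vv <- cavalieri_vv(labels, grid_spec((4 * 250)^2), pixel_size = 250)
  expect_equal(unname(vv$vv), c(50, 50))
  expect_equal(sum(vv$vv), 100)

  # remainder class by complement equals 100 minus the others
  img <- generate_semithin_labels(c(vessels = 7, glia = 2, neuropil = 91),
                                  c(256L, 256L), seed = 4)
  vv2 <- cavalieri_vv(img, grid_spec((3 * 250)^2), pixel_size = 250,
                      remainder_class = "neuropil")
  expect_equal(unname(vv2$vv["neuropil"]),
               100 - sum(vv2$vv[c("vessels", "glia")]))

  # a ~12% blob sampled at 4 px spacing lands within 1 percentage point
  img12 <- generate_semithin_labels(c(blob = 12, rest = 88), c(256L, 256L),
                                    seed = 9)
  vv3 <- cavalieri_vv(img12, grid_spec((4 * 250)^2), pixel_size = 250)
  expect_lt(abs(vv3$vv["blob"] - img12$vv_true[1]), 1)

  # grid spacing at 1 px converges to the exhaustive pixel count
  vv4 <- cavalieri_vv(img12, grid_spec(250^2, offset = c(125, 125)),
                      pixel_size = 250)
  expect_lt(max(abs(vv4$vv - img12$vv_true)), 0.1)

  expect_error(cavalieri_vv(matrix(1L, 2, 2), grid_spec(1e12),
                            pixel_size = 250), "spacing")
})

test_that("artifact fraction estimation by section sampling", {
  # 200 sections at 20 nm, sampled every 20th, as in real stacks
  g <- stack_geometry(8000, 8000, 4000, voxel_xy = 100, voxel_z = 20)
  grid <- grid_spec(4e5)
  zero <- array(0L, dim = c(80, 80, 200))
  expect_equal(estimate_artifact_fraction(zero, grid, 20, voxel_xy = 100), 0)
  ones <- array(1L, dim = c(80, 80, 200))
  expect_equal(estimate_artifact_fraction(ones, grid, 20, voxel_xy = 100), 1)

  m <- generate_artifact_mask(g, 0.15, seed = 21)
  est <- estimate_artifact_fraction(m, grid_spec(250^2), 20, voxel_xy = 100)
  expect_gte(est, 0.12)
  expect_lte(est, 0.18)

  expect_warning(
    estimate_artifact_fraction(zero[, , 1:10, drop = FALSE], grid, 20,
                               voxel_xy = 100),
    "middle section")
})

test_that("shrinkage factors follow the pre/post measurement definitions", {
  sf <- shrinkage_factors(100, 93.3, 1, 0.901)
  expect_equal(round_half_up(sf$p2, 3), 0.933)
  expect_equal(round_half_up(sf$p, 3), 0.966)
  expect_equal(sf$pz, 0.901)
  expect_equal(sf$s_vol, sf$p2 * sf$pz)
  expect_equal(sf$p, sqrt(sf$p2), tolerance = 1e-12)

  none <- shrinkage_factors(50, 50, 2, 2)
  expect_equal(unlist(none[c("p2", "p", "pz", "s_vol")]),
               c(p2 = 1, p = 1, pz = 1, s_vol = 1))

  expect_warning(shrinkage_factors(100, 105), "swelling")
  expect_error(shrinkage_factors(0, 1), "> 0")
  expect_error(as_shrinkage_factors(p2 = 0.933, p = 0.98), "sqrt")
})

test_that("correction arithmetic restores pre-processing scales", {
  sf <- as_shrinkage_factors(p2 = 0.933, pz = 0.901, p = 0.966)
  expect_equal(round_half_up(apply_correction(717.55, "length", sf), 2),
               742.81)
  expect_equal(round_half_up(apply_correction(79993.18, "area", sf), 2),
               85737.60)

  idf <- no_shrinkage()
  for (k in c("length", "area", "volume", "density"))
    expect_equal(apply_correction(123.4, k, idf), 123.4)

  # corrected length/area never below measured when factors <= 1
  vals <- c(0, 1, 250, 9e4)
  expect_true(all(apply_correction(vals, "length", sf) >= vals))
  expect_true(all(apply_correction(vals, "area", sf) >= vals))

  # density increases with the artifact fraction
  d <- vapply(c(0, 0.05, 0.1, 0.2),
              function(a) apply_correction(0.5, "density", idf, a),
              numeric(1))
  expect_true(all(diff(d) > 0))
  expect_error(apply_correction(1, "mass", sf))
  expect_error(apply_correction(-1, "length", sf), ">= 0")
})
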