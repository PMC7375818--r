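test_that("area and perimeter on hand-built meshes", {
  tri <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                  rbind(c(1, 2, 3)))
  expect_equal(sas_area(tri), 0.5)

  sq <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                 rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(sas_area(sq), 1)
  expect_equal(sas_perimeter(sq), 4)

  # closed surface (tetrahedron) has no boundary: not a SAS
  tet <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
  expect_error(sas_perimeter(tet), "no boundary")

  # two-component mesh: measurements are additive
  one <- generate_sas_mesh(sas_shape_spec("disk", list(r = 300)))$mesh
  two <- generate_sas_mesh(sas_shape_spec("fragment_set",
                                          list(r = 300,
                                               n_fragments = 2)))$mesh
  expect_equal(sas_area(two), 2 * sas_area(one), tolerance = 1e-12)
  expect_equal(sas_perimeter(two), 2 * sas_perimeter(one), tolerance = 1e-12)
})

test_that("closed-form agreement on parametric surfaces", {
  disk <- generate_sas_mesh(sas_shape_spec("disk", list(r = 500)), seed = 1)
  expect_lt(abs(sas_area(disk$mesh) - pi * 500^2) / (pi * 500^2), 0.005)
  expect_lt(abs(sas_perimeter(disk$mesh) - 2 * pi * 500) / (2 * pi * 500),
            0.005)
  expect_lt(sas_curvature(disk$mesh), 1e-6)

  hemi <- generate_sas_mesh(
    sas_shape_spec("spherical_cap", list(radius = 500, height = 500),
                   mesh_resolution = 20), seed = 2)
  expect_equal(hemi$truth$curvature, 0.5)
  expect_lt(abs(sas_curvature(hemi$mesh) - 0.5), 0.005)

  cap <- generate_sas_mesh(
    sas_shape_spec("spherical_cap", list(radius = 500, height = 250),
                   mesh_resolution = 20), seed = 3)
  expect_equal(cap$truth$curvature, 0.25)
  expect_lt(abs(sas_curvature(cap$mesh) - 0.25), 0.0025)

  ann <- generate_sas_mesh(
    sas_shape_spec("annulus", list(r_in = 200, r_out = 500)), seed = 4)
  p_true <- 2 * pi * (200 + 500)
  expect_lt(abs(sas_perimeter(ann$mesh) - p_true) / p_true, 0.005)

  expect_error(sas_shape_spec("disk", list(r = 0)), "r > 0")
  expect_error(sas_shape_spec("spherical_cap",
                              list(radius = 100, height = 150)), "<=")
})

test_that("morphometry is invariant under rigid motion", {
  base <- generate_sas_mesh(
    sas_shape_spec("horseshoe_band", list(r_in = 200, r_out = 500)))
  m0 <- sas_morphometry(base$mesh)
  for (s in c(11, 12, 13)) {
    moved <- generate_sas_mesh(
      sas_shape_spec("horseshoe_band", list(r_in = 200, r_out = 500)),
      seed = s)
    m1 <- sas_morphometry(moved$mesh)
    expect_equal(m1$area, m0$area, tolerance = 1e-9)
    expect_equal(m1$perimeter, m0$perimeter, tolerance = 1e-9)
    expect_equal(m1$curvature, m0$curvature, tolerance = 1e-7)
    expect_identical(m1$shape_class, m0$shape_class)
  }
})

test_that("area always dominates projected area (curvature >= 0)", {
  fams <- list(
    list("disk", list(r = 350)),
    list("spherical_cap", list(radius = 400, height = 300)),
    list("annulus", list(r_in = 120, r_out = 420)),
    list("horseshoe_band", list(r_in = 180, r_out = 450)),
    list("fragment_set", list(r = 250, n_fragments = 2)))
  for (i in seq_along(fams)) {
    gt <- generate_sas_mesh(sas_shape_spec(fams[[i]][[1]], fams[[i]][[2]]),
                            seed = 100 + i)
    cv <- sas_curvature(gt$mesh)
    expect_gte(cv, 0)
    expect_lt(cv, 1)
  }
})

test_that("the four junction shapes are classified by the decision cascade", {
  expect_identical(
    classify_shape(generate_sas_mesh(
      sas_shape_spec("fragment_set", list(r = 250)), seed = 1)$mesh),
    "fragmented")
  expect_identical(
    classify_shape(generate_sas_mesh(
      sas_shape_spec("annulus", list(r_in = 150, r_out = 450)),
      seed = 2)$mesh),
    "perforated")
  expect_identical(
    classify_shape(generate_sas_mesh(
      sas_shape_spec("disk", list(r = 400)), seed = 3)$mesh),
    "macular")
  expect_identical(
    classify_shape(generate_sas_mesh(
      sas_shape_spec("horseshoe_band", list(r_in = 200, r_out = 500)),
      seed = 4)$mesh),
    "horseshoe")
  # stability under refinement of the same parametric surface
  for (res in c(60, 30, 15)) {
    gt <- generate_sas_mesh(
      sas_shape_spec("horseshoe_band", list(r_in = 200, r_out = 500),
                     mesh_resolution = res), seed = 5)
    expect_identical(classify_shape(gt$mesh), "horseshoe")
  }
})
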