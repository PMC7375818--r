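test_that("mesh validation rejects malformed surfaces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_s3_class(tri_mesh(v, rbind(c(1, 2, 3), c(2, 4, 3))), "tri_mesh")
  expect_error(tri_mesh(v, rbind(c(1, 2, 5))), "out of range")
  expect_error(tri_mesh(v, rbind(c(1, 1, 2))), "degenerate")
  # three triangles sharing one edge: non-manifold
  v5 <- rbind(v, c(0.5, 0.5, 1))
  expect_error(tri_mesh(v5, rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))),
               "non-manifold")
})

test_that("topology counts components and holes", {
  disk <- generate_sas_mesh(sas_shape_spec("disk", list(r = 400)))$mesh
  expect_identical(mesh_n_components(disk), 1L)
  expect_identical(mesh_n_holes(disk), 0L)

  ann <- generate_sas_mesh(sas_shape_spec("annulus",
                                          list(r_in = 150, r_out = 400)))$mesh
  expect_identical(mesh_n_components(ann), 1L)
  expect_identical(mesh_n_holes(ann), 1L)
  expect_length(mesh_boundary_loops(ann), 2L)

  fr <- generate_sas_mesh(sas_shape_spec("fragment_set",
                                         list(r = 200, n_fragments = 3)))$mesh
  expect_identical(mesh_n_components(fr), 3L)
  expect_identical(mesh_n_holes(fr), 0L)
})

test_that("PLY and OFF round trips preserve geometry and morphometry", {
  gt <- generate_sas_mesh(sas_shape_spec("annulus",
                                         list(r_in = 200, r_out = 500)),
                          seed = 31)
  m0 <- sas_morphometry(gt$mesh)
  for (fmt in c("ply", "off")) {
    path <- file.path(tempdir(), paste0("sas.", fmt))
    if (fmt == "ply") write_ply(gt$mesh, path) else write_off(gt$mesh, path)
    back <- if (fmt == "ply") read_ply(path) else read_off(path)
    expect_identical(back$triangles, gt$mesh$triangles)
    expect_equal(back$vertices, gt$mesh$vertices, tolerance = 1e-5)
    m1 <- sas_morphometry(back)
    expect_equal(m1$area, m0$area, tolerance = 1e-5)
    expect_equal(m1$perimeter, m0$perimeter, tolerance = 1e-5)
    expect_identical(m1$shape_class, m0$shape_class)
  }
})

test_that("label TIFF round trips 2D images and 3D masks", {
  img <- generate_semithin_labels(c(a = 30, b = 70), c(32L, 48L), seed = 2)
  p2 <- file.path(tempdir(), "labels.tif")
  write_label_tiff(img$labels, p2)
  expect_identical(read_label_tiff(p2), img$labels)

  g <- stack_geometry(1000, 800, 400, voxel_xy = 50, voxel_z = 40)
  mask <- generate_artifact_mask(g, 0.1, seed = 3)
  p3 <- file.path(tempdir(), "mask.tif")
  write_label_tiff(mask, p3)
  expect_identical(read_label_tiff(p3), mask)
})
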