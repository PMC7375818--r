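test_that("counting-frame inclusion follows the brick rule on centroids", {
  g <- cube10()
  fr <- counting_frame(g, c(1000, 1000, 1000), c(9000, 9000, 9000))
  rec <- data.frame(
    id = 1:5,
    cx_nm = c(5000, 1000, 9000, 999, 9001),
    cy_nm = c(5000, 5000, 5000, 5000, 5000),
    cz_nm = c(5000, 5000, 5000, 5000, 5000))
  inc <- counting_frame_filter(rec, fr)
  # interior in; exactly on exclusion (min) face out; on inclusion (max)
  # face in; outside out
  expect_identical(inc$id, c(1L, 3L))
  expect_identical(attr(inc, "counting_rule"), "centroid")

  expect_error(counting_frame(g, c(-1, 0, 0), c(5000, 5000, 5000)),
               "outside")
  expect_error(counting_frame(g, c(2, 2, 2), c(2, 5000, 5000)), "empty")

  # monotone: shrinking the frame never adds records
  fr2 <- counting_frame(g, c(2000, 2000, 2000), c(8000, 8000, 8000))
  pop <- generate_population(g, toy_profile(intensity = 0.6), seed = 8)
  big <- counting_frame_filter(pop, fr)
  small <- counting_frame_filter(pop, fr2)
  expect_true(all(small$id %in% big$id))
})

test_that("counting-frame density estimation is unbiased under CSR", {
  lambda <- 0.5
  g <- stack_geometry(15000, 15000, 15000)
  dens <- vapply(1:200, function(s) {
    pop <- generate_population(g, toy_profile(intensity = lambda), seed = s)
    o <- runif(3, 0, 7000)
    fr <- counting_frame(g, o, o + 8000)
    nrow(counting_frame_filter(pop, fr)) / frame_volume_um3(fr)
  }, numeric(1))
  se <- sqrt(lambda / (8^3) / 200)  # Poisson variance of a per-frame density
  expect_lt(abs(mean(dens) - lambda), 3 * se)
})

test_that("synaptic density arithmetic and reporting", {
  d <- synaptic_density(2814, 6221)
  expect_equal(round_half_up(d$density, 2), 0.45)
  expect_false(d$corrected)

  expect_equal(synaptic_density(0, 10)$density, 0)
  expect_error(synaptic_density(10, 0), "> 0")

  # artifact 0.2 with identity shrinkage: n / (0.8 V)
  d2 <- synaptic_density(100, 10, no_shrinkage(), 0.2)
  expect_equal(d2$density, 100 / 8)
  expect_true(d2$corrected)

  # density x volume returns the count exactly
  expect_equal(d2$density * d2$cf_volume, 100)
  expect_equal(d$density * d$cf_volume, 2814)
})
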