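# shared fixtures for the test suite

cube10 <- function() stack_geometry(10000, 10000, 10000)

# a minimal valid profile with controllable intensity / mix
toy_profile <- function(layer = "SO", intensity = 0.5, as_fraction = 0.9) {
  layer_profile(
    layer = layer, intensity = intensity, as_fraction = as_fraction,
    target_probs = list(
      AS = c(spine_head = 0.5, spine_neck = 0.05, shaft_spiny = 0.1,
             shaft_aspiny = 0.05, unknown = 0.3),
      SS = c(spine_head = 0.05, spine_neck = 0.05, shaft_spiny = 0.5,
             shaft_aspiny = 0.3, unknown = 0.1)),
    shape_probs = list(
      AS = c(macular = 0.86, horseshoe = 0.045, perforated = 0.08,
             fragmented = 0.015),
      SS = c(macular = 0.81, horseshoe = 0.12, perforated = 0.05,
             fragmented = 0.02)),
    size_model = list(
      AS = list(family = "lognormal", meanlog = 11.1, sdlog = 0.7),
      SS = list(family = "lognormal", meanlog = 11.0, sdlog = 0.75)))
}

# brute-force O(n^2) nearest-neighbour oracle
naive_nn <- function(pts) {
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

# exact two-sided Mann-Whitney p by exhaustive rank enumeration (no ties)
mw_exact_enum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  r_all <- seq_len(nx + ny)
  u_all <- apply(idx, 2, function(s) sum(r_all[s])) - nx * (nx + 1) / 2
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}
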