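#' 3D point pattern in a bounded window
#'
#' Couples a set of 3D points (nm) with its observation window (a stack
#' geometry). The intensity lambda is derived as n / volume.
#'
#' @param points n x 3 numeric matrix of coordinates in nm.
#' @param geom the observation window, a \code{\link{stack_geometry}}.
#' @return object of class \code{point_pattern} with fields \code{points},
#'   \code{geom}, \code{n}, \code{lambda_um3} (points per um^3) and
#'   \code{lambda_nm3}.
#' @export
point_pattern <- function(points, geom) {
  stopifnot(inherits(geom, "stack_geometry"))
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("'points' must be n x 3", call. = FALSE)
  if (nrow(points) && !all(points_in_box(points, geom)))
    stop("all points must lie inside the window", call. = FALSE)
  n <- nrow(points)
  structure(list(points = points, geom = geom, n = n,
                 lambda_um3 = n / stack_volume_um3(geom),
                 lambda_nm3 = n / prod(geom$extent)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points, %.3f points/um^3 in a %.1f um^3 window\n",
              x$n, x$lambda_um3, stack_volume_um3(x$geom)))
  invisible(x)
}

#' Nearest-neighbour (intersynaptic) distances
#'
#' Euclidean 3D distance from every point to its nearest other point. For
#' synapse centroids this is the intersynaptic distance.
#'
#' @param pattern a \code{\link{point_pattern}} (n >= 2).
#' @return numeric vector of distances in nm, one per point.
#' @export
nn_distances <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n < 2)
    stop("nearest-neighbour distances need at least 2 points", call. = FALSE)
  nn_dist_cpp(pattern$points)
}

# distance from each point to the nearest window face
border_distances <- function(points, geom) {
  ex <- geom$extent
  pmin(points[, 1], ex[["x"]] - points[, 1],
       points[, 2], ex[["y"]] - points[, 2],
       points[, 3], ex[["z"]] - points[, 3])
}

# default distance grid: 50 radii from 0 to a quarter of the shortest edge
default_r_grid <- function(geom, n_r = 50L) {
  seq(0, min(geom$extent) / 4, length.out = n_r)
}

check_r_grid <- function(r, geom) {
  half_diag <- sqrt(sum(geom$extent^2)) / 2
  if (max(r) > half_diag) {
    warning("r grid exceeds the window half-diagonal; truncating")
    r <- r[r <= half_diag]
  }
  sort(unique(r))
}

# F-function test locations: regular lattice of ceiling(n^(1/3))^3 points
f_test_grid <- function(geom, n, n_side = NULL) {
  if (is.null(n_side)) n_side <- max(2L, ceiling(n^(1 / 3)))
  g <- (seq_len(n_side) - 0.5) / n_side
  as.matrix(expand.grid(x = g * geom$extent[["x"]],
                        y = g * geom$extent[["y"]],
                        z = g * geom$extent[["z"]]))
}

# reduced-sample (minus-sampling) CDF estimate: at each radius only
# points/locations farther than r from every face contribute
reduced_sample_cdf <- function(dists, bdists, r) {
  vapply(r, function(rk) {
    ok <- bdists > rk
    if (!any(ok)) return(NA_real_)
    mean(dists[ok] <= rk)
  }, numeric(1))
}

# one estimated curve (no envelope); shared by the exported estimators
estimate_curve <- function(fn, pattern, r, n_test_side = NULL) {
  pts <- pattern$points
  geom <- pattern$geom
  switch(fn,
    G = {
      nnd <- nn_dist_cpp(pts)
      reduced_sample_cdf(nnd, border_distances(pts, geom), r)
    },
    F = {
      tg <- f_test_grid(geom, pattern$n, n_test_side)
      d <- cross_nn_dist_cpp(tg, pts)
      reduced_sample_cdf(d, border_distances(tg, geom), r)
    },
    K = {
      counts <- pair_count_cpp(pts, r)
      b <- border_distances(pts, geom)
      vapply(seq_along(r), function(k) {
        ok <- b > r[k]
        if (!any(ok)) return(NA_real_)
        mean(counts[ok, k]) / pattern$lambda_nm3
      }, numeric(1))
    })
}

csr_theory <- function(fn, r, lambda_nm3) {
  vol <- 4 / 3 * pi * r^3
  switch(fn,
    G = 1 - exp(-lambda_nm3 * vol),
    F = 1 - exp(-lambda_nm3 * vol),
    K = vol)
}

make_spatial_fn <- function(fn, r, obs, theo, lo = NULL, hi = NULL,
                            n_sim = 0L, verdict = NA, pattern = NULL) {
  structure(list(fn = fn, r = r, obs = obs, theo = theo,
                 lo = lo, hi = hi, n_sim = n_sim,
                 verdict = verdict, n = pattern$n,
                 lambda_um3 = pattern$lambda_um3),
            class = "spatial_fn")
}

#' Spatial summary functions G, F and K with CSR reference curves
#'
#' \code{estimate_G} is the nearest-neighbour distance distribution function,
#' \code{estimate_F} the empty-space function (distances from a regular grid
#' of test locations to the nearest point), and \code{estimate_K} Ripley's K
#' (mean number of further points within distance r, scaled by 1/lambda).
#' All use the reduced-sample (minus-sampling) border correction: at radius r
#' only points (or test locations) farther than r from every window face
#' contribute. The CSR reference curves are
#' G_th(r) = F_th(r) = 1 - exp(-lambda 4/3 pi r^3) and K_th(r) = 4/3 pi r^3.
#'
#' @param pattern a \code{\link{point_pattern}}; fewer than 10 points triggers
#'   a warning (estimates are unstable).
#' @param r radius grid in nm (default: 50 values from 0 to a quarter of the
#'   shortest window edge). Radii beyond the window half-diagonal are
#'   truncated with a warning.
#' @param n_test_side for \code{estimate_F}: test lattice side (default
#'   \code{ceiling(n^(1/3))}).
#' @return object of class \code{spatial_fn} with the r grid, observed
#'   values, and the theoretical CSR curve.
#' @export
estimate_G <- function(pattern, r = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n < 10) warning("fewer than 10 points: unstable estimate")
  if (is.null(r)) r <- default_r_grid(pattern$geom)
  r <- check_r_grid(r, pattern$geom)
  make_spatial_fn("G", r, estimate_curve("G", pattern, r),
                  csr_theory("G", r, pattern$lambda_nm3), pattern = pattern)
}

#' @rdname estimate_G
#' @export
estimate_F <- function(pattern, r = NULL, n_test_side = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n < 10) warning("fewer than 10 points: unstable estimate")
  if (is.null(r)) r <- default_r_grid(pattern$geom)
  r <- check_r_grid(r, pattern$geom)
  make_spatial_fn("F", r, estimate_curve("F", pattern, r, n_test_side),
                  csr_theory("F", r, pattern$lambda_nm3), pattern = pattern)
}

#' @rdname estimate_G
#' @export
estimate_K <- function(pattern, r = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n < 10) warning("fewer than 10 points: unstable estimate")
  if (is.null(r)) r <- default_r_grid(pattern$geom)
  r <- check_r_grid(r, pattern$geom)
  make_spatial_fn("K", r, estimate_curve("K", pattern, r),
                  csr_theory("K", r, pattern$lambda_nm3), pattern = pattern)
}

#' Monte-Carlo CSR envelope and verdict for a spatial summary function
#'
#' Simulates \code{n_sim} CSR patterns with the same number of points in the
#' same window, estimates the chosen summary function for each, and builds an
#' acceptance envelope. The verdict is \code{TRUE} (pattern compatible with
#' CSR) iff the observed curve lies within the envelope at every radius.
#'
#' Two envelope constructions are offered. The default \code{"global"}
#' envelope is a constant-width band around the theoretical CSR curve whose
#' half-width is the largest supremum deviation
#' \eqn{\sup_r |\hat{f}_i(r) - f_{th}(r)|} among the simulated curves; the
#' resulting test has exact Monte-Carlo level \code{1/(n_sim + 1)} (1\% for
#' the conventional 99 simulations) over the whole r grid. The
#' \code{"pointwise"} envelope is the classic pointwise min/max of the
#' simulated curves; its pointwise two-sided level is \code{2/(n_sim + 1)}
#' but its global level over a fine r grid is considerably inflated by
#' multiplicity, so it is provided for display rather than as a calibrated
#' test.
#'
#' @param pattern a \code{\link{point_pattern}}.
#' @param fn one of \code{"G"}, \code{"F"}, \code{"K"}.
#' @param n_sim number of CSR simulations (default 99).
#' @param r radius grid (default as in \code{\link{estimate_G}}).
#' @param seed optional integer seed for the simulations.
#' @param type \code{"global"} (default) or \code{"pointwise"}.
#' @return a \code{spatial_fn} with envelope bounds \code{lo}, \code{hi} and
#'   a logical \code{verdict}.
#' @export
csr_envelope <- function(pattern, fn = c("G", "F", "K"), n_sim = 99L,
                         r = NULL, seed = NULL,
                         type = c("global", "pointwise")) {
  fn <- match.arg(fn)
  type <- match.arg(type)
  stopifnot(inherits(pattern, "point_pattern"), n_sim >= 1L)
  if (is.null(r)) r <- default_r_grid(pattern$geom)
  r <- check_r_grid(r, pattern$geom)
  obs <- estimate_curve(fn, pattern, r)
  theo <- csr_theory(fn, r, pattern$lambda_nm3)
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      p <- point_pattern(generate_csr_points(pattern$geom, NULL,
                                             n = pattern$n), pattern$geom)
      estimate_curve(fn, p, r)
    }, numeric(length(r)))
  })
  if (type == "global") {
    crit <- max(apply(abs(sims - theo), 2, max, na.rm = TRUE))
    lo <- theo - crit
    hi <- theo + crit
    if (fn %in% c("G", "F")) {
      lo <- pmax(lo, 0)
      hi <- pmin(hi, 1)
    } else {
      lo <- pmax(lo, 0)
    }
    usable <- !is.na(obs)
    verdict <- max(abs(obs[usable] - theo[usable])) <= crit + 1e-9
  } else {
    lo <- apply(sims, 1, min, na.rm = TRUE)
    hi <- apply(sims, 1, max, na.rm = TRUE)
    usable <- !is.na(obs) & is.finite(lo) & is.finite(hi)
    verdict <- all(obs[usable] >= lo[usable] - 1e-9 &
                   obs[usable] <= hi[usable] + 1e-9)
  }
  make_spatial_fn(fn, r, obs, theo, lo, hi, n_sim, verdict, pattern)
}

#' @export
print.spatial_fn <- function(x, ...) {
  cat(sprintf("%s function: %d radii up to %.0f nm, n = %d points\n",
              x$fn, length(x$r), max(x$r), x$n))
  if (x$n_sim > 0)
    cat(sprintf("  CSR envelope from %d simulations; within envelope: %s\n",
                x$n_sim, x$verdict))
  invisible(x)
}

#' Plot a spatial summary function with its CSR envelope
#' @param x a \code{spatial_fn}.
#' @param ... passed to \code{plot}.
#' @export
plot.spatial_fn <- function(x, ...) {
  ylim <- range(c(x$obs, x$theo, x$lo, x$hi), na.rm = TRUE)
  plot(x$r, x$obs, type = "n", xlab = "r (nm)",
       ylab = sprintf("%s(r)", x$fn), ylim = ylim, ...)
  if (!is.null(x$lo))
    graphics::polygon(c(x$r, rev(x$r)), c(x$lo, rev(x$hi)),
                      col = "grey85", border = NA)
  graphics::lines(x$r, x$theo, lty = 2)
  graphics::lines(x$r, x$obs, lwd = 2)
  invisible(x)
}

#' Convert a spatial summary result to a data frame
#' @param x a \code{spatial_fn}.
#' @param row.names,optional,... standard \code{as.data.frame} arguments.
#' @export
as.data.frame.spatial_fn <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(r = x$r, observed = x$obs, theoretical = x$theo,
             lo = if (is.null(x$lo)) NA_real_ else x$lo,
             hi = if (is.null(x$hi)) NA_real_ else x$hi)
}
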