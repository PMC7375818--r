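#' Simulate a completely spatially random (CSR) point pattern
#'
#' Draws a homogeneous Poisson process in the stack box: the number of points
#' is Poisson(intensity x volume) and coordinates are i.i.d. uniform. CSR is
#' the null model against which observed synapse centroid patterns are
#' tested.
#'
#' @param geom a \code{\link{stack_geometry}}.
#' @param intensity points per um^3; >= 0.
#' @param seed optional integer seed for reproducibility.
#' @param n optional fixed number of points; overrides the Poisson draw
#'   (used for conditional simulation in envelope tests).
#' @return numeric matrix with columns \code{x}, \code{y}, \code{z} (nm).
#' @examples
#' g <- stack_geometry(10000, 10000, 10000)
#' pts <- generate_csr_points(g, intensity = 0.67, seed = 1)
#' @export
generate_csr_points <- function(geom, intensity, seed = NULL, n = NULL) {
  stopifnot(inherits(geom, "stack_geometry"))
  if (is.null(n)) {
    stop_if_not_scalar_num(intensity, "intensity")
    if (intensity < 0) stop("'intensity' must be >= 0", call. = FALSE)
  }
  with_seed(seed, {
    if (is.null(n)) n <- rpois(1, intensity * stack_volume_um3(geom))
    m <- cbind(x = runif(n, 0, geom$extent[["x"]]),
               y = runif(n, 0, geom$extent[["y"]]),
               z = runif(n, 0, geom$extent[["z"]]))
    m
  })
}

#' Simulate a hard-core (minimum-distance) point pattern
#'
#' Simple sequential inhibition: uniform proposals are accepted only if at
#' least \code{min_dist} nm from every accepted point. Used as a regular
#' (anti-clustered) alternative when validating the CSR tests.
#'
#' @param geom a \code{\link{stack_geometry}}.
#' @param n number of points to place.
#' @param min_dist hard-core distance in nm.
#' @param seed optional integer seed.
#' @param max_tries proposals allowed per accepted point before giving up.
#' @return matrix of coordinates as in \code{\link{generate_csr_points}}.
#' @export
generate_hardcore_points <- function(geom, n, min_dist, seed = NULL,
                                     max_tries = 5000) {
  stopifnot(inherits(geom, "stack_geometry"))
  with_seed(seed, {
    pts <- matrix(NA_real_, n, 3)
    placed <- 0L
    tries <- 0L
    while (placed < n) {
      p <- c(runif(1, 0, geom$extent[["x"]]),
             runif(1, 0, geom$extent[["y"]]),
             runif(1, 0, geom$extent[["z"]]))
      ok <- placed == 0L ||
        min(sqrt(colSums((t(pts[seq_len(placed), , drop = FALSE]) - p)^2))) >=
          min_dist
      if (ok) {
        placed <- placed + 1L
        pts[placed, ] <- p
        tries <- 0L
      } else {
        tries <- tries + 1L
        if (tries > max_tries)
          stop("hard-core packing failed: min_dist too large for n",
               call. = FALSE)
      }
    }
    colnames(pts) <- c("x", "y", "z")
    pts
  })
}

#' Simulate a clustered (Thomas-like) point pattern
#'
#' Parents are uniform in the box; each point is a Gaussian displacement
#' (SD \code{sigma} nm per axis) from a randomly chosen parent, resampled
#' until inside the box. Produces strong aggregation for small \code{sigma},
#' used as the clustered alternative when validating the CSR tests.
#'
#' @param geom a \code{\link{stack_geometry}}.
#' @param n number of points.
#' @param n_parents number of cluster centers.
#' @param sigma cluster spread in nm.
#' @param seed optional integer seed.
#' @return matrix of coordinates.
#' @export
generate_clustered_points <- function(geom, n, n_parents = 20, sigma = 300,
                                      seed = NULL) {
  stopifnot(inherits(geom, "stack_geometry"))
  with_seed(seed, {
    parents <- cbind(runif(n_parents, 0, geom$extent[["x"]]),
                     runif(n_parents, 0, geom$extent[["y"]]),
                     runif(n_parents, 0, geom$extent[["z"]]))
    pts <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      repeat {
        p <- parents[sample.int(n_parents, 1), ] + rnorm(3, 0, sigma)
        if (p[1] >= 0 && p[1] < geom$extent[["x"]] &&
            p[2] >= 0 && p[2] < geom$extent[["y"]] &&
            p[3] >= 0 && p[3] < geom$extent[["z"]]) break
      }
      pts[i, ] <- p
    }
    colnames(pts) <- c("x", "y", "z")
    pts
  })
}

# draw from the SAS size model of one polarity
sample_sas_area <- function(size_model, n) {
  if (size_model$family == "lognormal") {
    rlnorm(n, size_model$meanlog, size_model$sdlog)
  } else {
    u <- runif(n)
    size_model$scale * (u / (1 - u))^(1 / size_model$shape)
  }
}

#' Generate a synthetic synapse population for one stack
#'
#' Simulates a table of reconstructed synapses with CSR centroid positions at
#' the profile's intensity, AS/SS polarity drawn as Bernoulli(as_fraction),
#' postsynaptic target and shape class from the profile's conditional
#' multinomials, SAS area from the per-polarity size model, SAS perimeter
#' from the equal-area-circle model with multiplicative log-normal noise, and
#' SAS curvature from the per-polarity Beta model.
#'
#' @param geom a \code{\link{stack_geometry}}.
#' @param profile a \code{\link{layer_profile}}.
#' @param seed optional integer seed.
#' @param id_offset integer added to the running synapse ids.
#' @return data.frame with columns \code{id}, \code{layer}, \code{polarity},
#'   \code{target}, \code{shape_class}, \code{cx_nm}, \code{cy_nm},
#'   \code{cz_nm}, \code{sas_area_nm2}, \code{sas_perimeter_nm},
#'   \code{sas_curvature}.
#' @examples
#' g <- stack_geometry(10000, 8000, 5000)
#' pop <- generate_population(g, ca1_layer_profiles()$SO, seed = 7)
#' head(pop)
#' @export
generate_population <- function(geom, profile, seed = NULL, id_offset = 0L) {
  stopifnot(inherits(geom, "stack_geometry"),
            inherits(profile, "layer_profile"))
  with_seed(seed, {
    xyz <- generate_csr_points(geom, profile$intensity)
    n <- nrow(xyz)
    if (n == 0L) return(empty_population())
    polarity <- ifelse(runif(n) < profile$as_fraction, "AS", "SS")
    target <- character(n)
    shape <- character(n)
    area <- numeric(n)
    perim <- numeric(n)
    curv <- numeric(n)
    for (pol in c("AS", "SS")) {
      idx <- which(polarity == pol)
      if (!length(idx)) next
      target[idx] <- sample(SYNAPSE_TARGETS, length(idx), replace = TRUE,
                            prob = profile$target_probs[[pol]])
      shape[idx] <- sample(SYNAPSE_SHAPES, length(idx), replace = TRUE,
                           prob = profile$shape_probs[[pol]])
      area[idx] <- sample_sas_area(profile$size_model[[pol]], length(idx))
      pm <- profile$perimeter_model[[pol]]
      if (is.null(pm)) pm <- list(shape_factor = 1.4, sdlog = 0.15)
      perim[idx] <- pm$shape_factor * 2 * sqrt(pi * area[idx]) *
        exp(rnorm(length(idx), 0, pm$sdlog))
      cm <- profile$curvature_model[[pol]]
      if (is.null(cm)) cm <- list(alpha = 1.5, beta = 28.5)
      curv[idx] <- pmin(rbeta(length(idx), cm$alpha, cm$beta), 1 - 1e-9)
    }
    data.frame(id = id_offset + seq_len(n), layer = profile$layer,
               polarity = polarity, target = target, shape_class = shape,
               cx_nm = xyz[, 1], cy_nm = xyz[, 2], cz_nm = xyz[, 3],
               sas_area_nm2 = area, sas_perimeter_nm = perim,
               sas_curvature = curv, stringsAsFactors = FALSE)
  })
}

empty_population <- function() {
  data.frame(id = integer(), layer = character(), polarity = character(),
             target = character(), shape_class = character(),
             cx_nm = numeric(), cy_nm = numeric(), cz_nm = numeric(),
             sas_area_nm2 = numeric(), sas_perimeter_nm = numeric(),
             sas_curvature = numeric(), stringsAsFactors = FALSE)
}

#' Generate a 3D fixation-artifact mask with a target volume fraction
#'
#' Builds a binary voxel volume (dimensions given by the stack's voxel grid)
#' whose occupied share matches \code{fraction} to within one voxel, shaped
#' as a union of balls around random centers: the Euclidean-distance field to
#' the centers is thresholded at the exact voxel-count quantile. The blob
#' shape itself is arbitrary; only the occupied fraction matters downstream.
#'
#' @param geom a \code{\link{stack_geometry}} (keep the voxel grid modest;
#'   masks are dense arrays).
#' @param fraction target occupied fraction, in [0, 0.5].
#' @param seed optional integer seed.
#' @param blob_radius nominal artifact radius in nm (default 600: swollen
#'   neuronal/glial processes are sub-micrometre, so an artifact field is
#'   many small blobs rather than a few large cavities).
#' @return 3D integer array (nx x ny x nz) of 0/1 voxel labels.
#' @export
generate_artifact_mask <- function(geom, fraction, seed = NULL,
                                   blob_radius = 600) {
  stopifnot(inherits(geom, "stack_geometry"))
  stop_if_not_scalar_num(fraction, "fraction")
  if (fraction < 0 || fraction > 0.5)
    stop("'fraction' must be in [0, 0.5]", call. = FALSE)
  dims <- unname(voxel_grid_dim(geom))
  nvox <- prod(dims)
  if (nvox > 5e7)
    stop("voxel grid too large for a dense mask; coarsen the voxel sizes",
         call. = FALSE)
  if (fraction == 0) return(array(0L, dim = dims))
  vol <- prod(geom$extent)
  ball_vol <- 4 / 3 * pi * blob_radius^3
  n_blobs <- max(1L, ceiling(fraction * vol / ball_vol))
  with_seed(seed, {
    cx <- runif(n_blobs, 0, geom$extent[["x"]])
    cy <- runif(n_blobs, 0, geom$extent[["y"]])
    cz <- runif(n_blobs, 0, geom$extent[["z"]])
    xs <- (seq_len(dims[1]) - 0.5) * geom$voxel_xy
    ys <- (seq_len(dims[2]) - 0.5) * geom$voxel_xy
    zs <- (seq_len(dims[3]) - 0.5) * geom$voxel_z
    k <- max(1L, round(fraction * nvox))
    # distance field to the nearest center, updated only inside each ball's
    # bounding box; the cap radius grows until the k-th smallest distance
    # (the exact-fraction threshold) is covered
    r_cap <- 2 * blob_radius
    repeat {
      d2min <- array(Inf, dim = dims)
      for (b in seq_len(n_blobs)) {
        ix <- which(abs(xs - cx[b]) <= r_cap)
        iy <- which(abs(ys - cy[b]) <= r_cap)
        iz <- which(abs(zs - cz[b]) <= r_cap)
        if (!length(ix) || !length(iy) || !length(iz)) next
        d2 <- outer(outer((xs[ix] - cx[b])^2, (ys[iy] - cy[b])^2, "+"),
                    (zs[iz] - cz[b])^2, "+")
        d2min[ix, iy, iz] <- pmin(d2min[ix, iy, iz], d2)
      }
      covered <- sum(d2min < Inf)
      if (covered >= k) break
      r_cap <- r_cap * 1.5
    }
    thr <- sort.int(d2min[d2min < Inf], partial = k)[k]
    mask <- array(0L, dim = dims)
    mask[d2min <= thr] <- 1L
    mask
  })
}

#' Generate a 2D semithin-section label image with known volume fractions
#'
#' Emulates a toluidine-blue semithin section segmented into tissue classes
#' (e.g. blood vessels, glia, neurons, neuropil) whose pixel shares match the
#' requested volume fractions essentially exactly: each non-remainder class
#' claims its quota of pixels nearest to its random seeds, and the last class
#' takes the remainder. Ground truth is returned alongside the image.
#'
#' @param classes named numeric vector of target volume fractions in percent;
#'   must sum to 100 (within 1e-6). The last element is the remainder class.
#' @param image_dim integer (ny, nx) pixel dimensions.
#' @param seed optional integer seed.
#' @return list with \code{labels} (integer matrix, codes 1..K in the order
#'   of \code{classes}), \code{classes}, \code{vv_target} and \code{vv_true}
#'   (achieved pixel shares in percent, summing to exactly 100).
#' @examples
#' img <- generate_semithin_labels(
#'   c(blood_vessels = 5, glia = 1.5, neurons = 4.23, neuropil = 89.27),
#'   seed = 3)
#' img$vv_true
#' @export
generate_semithin_labels <- function(classes, image_dim = c(512L, 512L),
                                     seed = NULL) {
  if (is.null(names(classes)) || any(!nzchar(names(classes))))
    stop("'classes' must be a named vector of percent shares", call. = FALSE)
  if (any(classes < 0) || abs(sum(classes) - 100) > 1e-6)
    stop("class shares must be nonnegative and sum to 100", call. = FALSE)
  ny <- as.integer(image_dim[1]); nx <- as.integer(image_dim[2])
  npix <- ny * nx
  K <- length(classes)
  with_seed(seed, {
    labels <- matrix(0L, ny, nx)
    px <- rep(seq_len(nx), each = ny)
    py <- rep(seq_len(ny), times = nx)
    unassigned <- rep(TRUE, npix)
    quota <- round(classes / 100 * npix)
    # fix rounding drift on the remainder class
    quota[K] <- npix - sum(quota[-K])
    for (k in seq_len(K - 1)) {
      if (quota[k] == 0) next
      nseed <- max(1L, round(1 + classes[k] / 5))
      sx <- runif(nseed, 1, nx); sy <- runif(nseed, 1, ny)
      d2 <- rep(Inf, npix)
      for (s in seq_len(nseed))
        d2 <- pmin(d2, (px - sx[s])^2 + (py - sy[s])^2)
      d2[!unassigned] <- Inf
      take <- order(d2)[seq_len(min(quota[k], sum(unassigned)))]
      labels[take] <- k
      unassigned[take] <- FALSE
    }
    labels[unassigned] <- K
    counts <- tabulate(labels, nbins = K)
    list(labels = labels, classes = names(classes),
         vv_target = unname(classes), vv_true = 100 * counts / npix)
  })
}
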