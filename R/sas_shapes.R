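SAS_FAMILIES <- c("disk", "spherical_cap", "annulus", "horseshoe_band",
                  "fragment_set")

#' Specification of a parametric SAS validation surface
#'
#' Describes one of five parametric surface families with closed-form area,
#' perimeter and curvature, used to validate the morphometry pipeline and the
#' shape classifier: \code{disk} (macular), \code{spherical_cap} (curved
#' macular), \code{annulus} (perforated), \code{horseshoe_band} (C-shaped
#' annular sector), and \code{fragment_set} (several disjoint disks).
#'
#' @param family one of the five family names.
#' @param dimensions named list of lengths in nm (and \code{span} in radians
#'   for the horseshoe): \code{disk}: \code{r}; \code{spherical_cap}:
#'   \code{radius}, \code{height} (height <= radius); \code{annulus}:
#'   \code{r_in}, \code{r_out}; \code{horseshoe_band}: \code{r_in},
#'   \code{r_out}, optional \code{span} (default 3*pi/2);
#'   \code{fragment_set}: \code{r}, optional \code{n_fragments} (default 2).
#' @param mesh_resolution target edge length in nm (default 30).
#' @return an object of class \code{sas_shape_spec}.
#' @export
sas_shape_spec <- function(family, dimensions, mesh_resolution = 30) {
  family <- match.arg(family, SAS_FAMILIES)
  stop_if_not_scalar_num(mesh_resolution, "mesh_resolution", positive = TRUE)
  d <- dimensions
  bad <- function(msg) stop(msg, call. = FALSE)
  switch(family,
    disk = if (is.null(d$r) || d$r <= 0) bad("disk needs r > 0"),
    spherical_cap = {
      if (is.null(d$radius) || is.null(d$height) ||
          d$radius <= 0 || d$height <= 0) bad("cap needs radius, height > 0")
      if (d$height > d$radius) bad("cap height must be <= sphere radius")
    },
    annulus = {
      if (is.null(d$r_in) || is.null(d$r_out) ||
          d$r_in <= 0 || d$r_out <= d$r_in)
        bad("annulus needs 0 < r_in < r_out")
    },
    horseshoe_band = {
      if (is.null(d$r_in) || is.null(d$r_out) ||
          d$r_in <= 0 || d$r_out <= d$r_in)
        bad("horseshoe needs 0 < r_in < r_out")
      if (is.null(d$span)) d$span <- 3 * pi / 2
      if (d$span <= 0 || d$span >= 2 * pi)
        bad("horseshoe span must be in (0, 2*pi)")
    },
    fragment_set = {
      if (is.null(d$r) || d$r <= 0) bad("fragment_set needs r > 0")
      if (is.null(d$n_fragments)) d$n_fragments <- 2L
      if (d$n_fragments < 2) bad("fragment_set needs n_fragments >= 2")
    })
  structure(list(family = family, dimensions = d,
                 mesh_resolution = mesh_resolution),
            class = "sas_shape_spec")
}

# --- canonical (z = 0 plane) meshers ------------------------------------

# radial grid disk/annulus/sector mesher. closed = full 2*pi sweep.
mesh_radial <- function(r0, r1, span, res, closed) {
  n_r <- max(if (r0 == 0) 2L else 1L, ceiling((r1 - r0) / res))
  m <- max(16L, ceiling(span * r1 / res))
  radii <- r0 + (r1 - r0) * seq(0, n_r) / n_r
  if (closed) {
    ang <- 2 * pi * (seq_len(m) - 1) / m
    ncol_ <- m
  } else {
    ang <- span * seq(0, m) / m
    ncol_ <- m + 1L
  }
  has_center <- r0 == 0
  verts <- if (has_center) matrix(0, 1, 3) else NULL
  ring_start <- integer(length(radii))
  for (i in seq_along(radii)) {
    if (has_center && i == 1L) { ring_start[i] <- 1L; next }
    ring_start[i] <- if (is.null(verts)) 1L else nrow(verts) + 1L
    verts <- rbind(verts, cbind(radii[i] * cos(ang), radii[i] * sin(ang), 0))
  }
  idx <- function(i, j) {  # ring i (1-based), slot j (wraps if closed)
    if (has_center && i == 1L) return(1L)
    j <- if (closed) ((j - 1L) %% ncol_) + 1L else j
    ring_start[i] + j - 1L
  }
  tris <- list()
  nslot <- if (closed) ncol_ else ncol_ - 1L
  for (i in seq_len(length(radii) - 1L)) {
    for (j in seq_len(nslot)) {
      a <- idx(i, j); b <- idx(i, j + 1L)
      c_ <- idx(i + 1L, j); d_ <- idx(i + 1L, j + 1L)
      if (has_center && i == 1L) {
        tris[[length(tris) + 1L]] <- c(a, c_, d_)
      } else {
        tris[[length(tris) + 1L]] <- c(a, c_, d_)
        tris[[length(tris) + 1L]] <- c(a, d_, b)
      }
    }
  }
  tri_mesh(verts, do.call(rbind, tris))
}

mesh_spherical_cap <- function(R, h, res) {
  theta_max <- acos(1 - h / R)
  n_t <- max(3L, ceiling(R * theta_max / res))
  m <- max(16L, ceiling(2 * pi * R * sin(theta_max) / res))
  ang <- 2 * pi * (seq_len(m) - 1) / m
  verts <- matrix(c(0, 0, R), 1, 3)  # pole
  ring_start <- integer(n_t)
  for (i in seq_len(n_t)) {
    th <- theta_max * i / n_t
    ring_start[i] <- nrow(verts) + 1L
    verts <- rbind(verts, cbind(R * sin(th) * cos(ang),
                                R * sin(th) * sin(ang),
                                R * cos(th)))
  }
  idx <- function(i, j) ring_start[i] + ((j - 1L) %% m)
  tris <- list()
  for (j in seq_len(m))  # pole fan
    tris[[length(tris) + 1L]] <- c(1L, idx(1L, j), idx(1L, j + 1L))
  if (n_t > 1L) for (i in seq_len(n_t - 1L)) for (j in seq_len(m)) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    c_ <- idx(i + 1L, j); d_ <- idx(i + 1L, j + 1L)
    tris[[length(tris) + 1L]] <- c(a, c_, d_)
    tris[[length(tris) + 1L]] <- c(a, d_, b)
  }
  tri_mesh(verts, do.call(rbind, tris))
}

# random rotation (uniform via QR of Gaussian matrix) + translation
random_rigid_motion <- function(mesh) {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- runif(3, 0, 1e5)
  mesh$vertices <- sweep(mesh$vertices %*% t(q), 2, shift, "+")
  mesh
}

#' Generate a parametric SAS mesh with analytic ground truth
#'
#' Meshes the requested surface family and returns it together with its
#' closed-form area, perimeter, curvature (1 - projected area / area),
#' component count, hole count and true shape class. When a seed is given the
#' mesh is placed at a random rigid pose (rotation + translation), which the
#' morphometry must be invariant to.
#'
#' @param spec a \code{\link{sas_shape_spec}}.
#' @param seed optional integer seed; \code{NULL} keeps the canonical pose in
#'   the z = 0 plane (cap apex on +z).
#' @return list with \code{mesh} (a \code{tri_mesh}) and \code{truth} (list
#'   of analytic values).
#' @examples
#' gt <- generate_sas_mesh(sas_shape_spec("disk", list(r = 500)))
#' gt$truth$area   # pi * 500^2
#' @export
generate_sas_mesh <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sas_shape_spec"))
  d <- spec$dimensions
  res <- spec$mesh_resolution
  built <- switch(spec$family,
    disk = list(
      mesh = mesh_radial(0, d$r, 2 * pi, res, closed = TRUE),
      truth = list(area = pi * d$r^2, perimeter = 2 * pi * d$r,
                   curvature = 0, n_components = 1L, n_holes = 0L,
                   shape_class = "macular")),
    spherical_cap = {
      a2 <- d$height * (2 * d$radius - d$height)
      list(
        mesh = mesh_spherical_cap(d$radius, d$height, res),
        truth = list(area = 2 * pi * d$radius * d$height,
                     perimeter = 2 * pi * sqrt(a2),
                     curvature = d$height / (2 * d$radius),
                     n_components = 1L, n_holes = 0L,
                     shape_class = "macular"))
    },
    annulus = list(
      mesh = mesh_radial(d$r_in, d$r_out, 2 * pi, res, closed = TRUE),
      truth = list(area = pi * (d$r_out^2 - d$r_in^2),
                   perimeter = 2 * pi * (d$r_in + d$r_out),
                   curvature = 0, n_components = 1L, n_holes = 1L,
                   shape_class = "perforated")),
    horseshoe_band = list(
      mesh = mesh_radial(d$r_in, d$r_out, d$span, res, closed = FALSE),
      truth = list(area = d$span / 2 * (d$r_out^2 - d$r_in^2),
                   perimeter = d$span * (d$r_in + d$r_out) +
                     2 * (d$r_out - d$r_in),
                   curvature = 0, n_components = 1L, n_holes = 0L,
                   shape_class = "horseshoe")),
    fragment_set = {
      k <- as.integer(d$n_fragments)
      base <- mesh_radial(0, d$r, 2 * pi, res, closed = TRUE)
      verts <- NULL; tris <- NULL
      for (i in seq_len(k)) {
        off <- nrow(verts %||% matrix(0, 0, 3))
        v <- base$vertices
        v[, 1] <- v[, 1] + (i - 1) * 3 * d$r
        verts <- rbind(verts, v)
        tris <- rbind(tris, base$triangles + off)
      }
      list(mesh = tri_mesh(verts, tris),
           truth = list(area = k * pi * d$r^2,
                        perimeter = k * 2 * pi * d$r,
                        curvature = 0, n_components = k, n_holes = 0L,
                        shape_class = "fragmented"))
    })
  built$truth$family <- spec$family
  built$truth$dimensions <- d
  if (!is.null(seed))
    built$mesh <- with_seed(seed, random_rigid_motion(built$mesh))
  built
}

`%||%` <- function(a, b) if (is.null(a)) b else a
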