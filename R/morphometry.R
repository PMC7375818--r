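#' SAS area of a mesh
#'
#' Total surface area in nm^2: the sum of triangle areas over all connected
#' components.
#'
#' @param mesh a \code{\link{tri_mesh}}.
#' @return area in nm^2.
#' @export
sas_area <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  sum(triangle_areas(mesh))
}

#' SAS perimeter of a mesh
#'
#' Total length in nm of all boundary edges: outer outlines and hole rims of
#' every component. A closed surface (no boundary) is not a valid synaptic
#' apposition surface and is rejected.
#'
#' @param mesh a \code{\link{tri_mesh}}.
#' @return perimeter in nm.
#' @export
sas_perimeter <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  be <- mesh_boundary_edges(mesh)
  if (nrow(be) == 0)
    stop("mesh has no boundary: closed surfaces are not SAS meshes",
         call. = FALSE)
  seg <- mesh$vertices[be[, 1], , drop = FALSE] -
         mesh$vertices[be[, 2], , drop = FALSE]
  sum(sqrt(rowSums(seg^2)))
}

# orthogonal-regression best-fit plane to the vertex cloud.
# returns centroid and in-plane basis (u, v); rejects (near-)collinear sets.
fit_plane <- function(mesh) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  cv <- crossprod(sweep(v, 2, ctr)) / nrow(v)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] <= 1e-12 * max(eg$values[1], 1))
    stop("vertex set is collinear: no projection plane", call. = FALSE)
  list(center = ctr, u = eg$vectors[, 1], v = eg$vectors[, 2],
       normal = eg$vectors[, 3])
}

# project vertices into plane coordinates (n x 2)
project_to_plane <- function(vertices, plane) {
  d <- sweep(vertices, 2, plane$center)
  cbind(d %*% plane$u, d %*% plane$v)
}

shoelace_area <- function(xy) {
  n <- nrow(xy)
  j <- c(2:n, 1)
  abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
}

# projected area of the outline-filled region: per component, the projected
# outer loop's polygon area minus projected hole-loop areas.
projected_outline_area <- function(mesh, plane = fit_plane(mesh)) {
  loops <- mesh_boundary_loops(mesh)
  if (!length(loops))
    stop("mesh has no boundary loops", call. = FALSE)
  comp <- mesh_vertex_components(mesh)
  loop_comp <- vapply(loops, function(l) comp[l[1]], integer(1))
  areas <- vapply(loops, function(l)
    shoelace_area(project_to_plane(mesh$vertices[l, , drop = FALSE], plane)),
    numeric(1))
  total <- 0
  for (cid in unique(loop_comp)) {
    a <- sort(areas[loop_comp == cid], decreasing = TRUE)
    total <- total + max(0, a[1] - sum(a[-1]))
  }
  total
}

#' SAS curvature of a mesh
#'
#' Curvature is defined as 1 minus the ratio of the projected area of the SAS
#' to its surface area: 0 for a flat surface, approaching 1 as the surface
#' curves. The projection plane is the orthogonal-regression best-fit plane
#' to the vertices; the projected area is that of the outline-filled region
#' (outer boundary polygon minus hole polygons, per component). The result is
#' clamped to [0, 1).
#'
#' @param mesh a \code{\link{tri_mesh}}.
#' @return dimensionless curvature in [0, 1).
#' @examples
#' cap <- generate_sas_mesh(sas_shape_spec("spherical_cap",
#'   list(radius = 500, height = 500), mesh_resolution = 20))
#' sas_curvature(cap$mesh)  # hemisphere: ~0.5
#' @export
sas_curvature <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  plane <- fit_plane(mesh)
  a <- sas_area(mesh)
  p <- projected_outline_area(mesh, plane)
  min(max(1 - p / a, 0), 1 - 1e-12)
}

#' Classify a synaptic junction shape from its SAS mesh
#'
#' Decision cascade over the four canonical junction shapes: two or more
#' connected components is \emph{fragmented}; otherwise one or more interior
#' holes is \emph{perforated}; otherwise an indented outline — projected
#' outline solidity (outline polygon area / its convex-hull area) below the
#' threshold — is \emph{horseshoe}; otherwise \emph{macular}.
#'
#' @param mesh a \code{\link{tri_mesh}}.
#' @param indentation_threshold solidity below which a simply connected
#'   outline counts as horseshoe-shaped (default 0.85; the published shape
#'   taxonomy was assigned visually, so the numeric threshold is a declared
#'   convention, not an inferred one).
#' @return one of \code{"macular"}, \code{"horseshoe"}, \code{"perforated"},
#'   \code{"fragmented"}.
#' @export
classify_shape <- function(mesh, indentation_threshold = 0.85) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (mesh_n_components(mesh) >= 2L) return("fragmented")
  if (mesh_n_holes(mesh) >= 1L) return("perforated")
  plane <- fit_plane(mesh)
  loops <- mesh_boundary_loops(mesh)
  areas <- vapply(loops, function(l)
    shoelace_area(project_to_plane(mesh$vertices[l, , drop = FALSE], plane)),
    numeric(1))
  outer <- loops[[which.max(areas)]]
  xy <- project_to_plane(mesh$vertices[outer, , drop = FALSE], plane)
  hull <- grDevices::chull(xy)
  solidity <- max(areas) / shoelace_area(xy[hull, , drop = FALSE])
  if (solidity < indentation_threshold) "horseshoe" else "macular"
}

#' Full SAS morphometry of a mesh
#'
#' Computes area, perimeter, curvature, component and hole counts, and the
#' shape class in one pass.
#'
#' @param mesh a \code{\link{tri_mesh}}.
#' @param indentation_threshold passed to \code{\link{classify_shape}}.
#' @return object of class \code{sas_morphometry}: list with \code{area},
#'   \code{perimeter}, \code{curvature}, \code{n_components},
#'   \code{n_holes}, \code{shape_class}.
#' @export
sas_morphometry <- function(mesh, indentation_threshold = 0.85) {
  stopifnot(inherits(mesh, "tri_mesh"))
  structure(list(
    area = sas_area(mesh),
    perimeter = sas_perimeter(mesh),
    curvature = sas_curvature(mesh),
    n_components = mesh_n_components(mesh),
    n_holes = mesh_n_holes(mesh),
    shape_class = classify_shape(mesh, indentation_threshold)
  ), class = "sas_morphometry")
}

#' @export
print.sas_morphometry <- function(x, ...) {
  cat(sprintf("SAS morphometry: area %.1f nm^2, perimeter %.1f nm, curvature %.4f\n",
              x$area, x$perimeter, x$curvature))
  cat(sprintf("  %d component(s), %d hole(s) -> %s\n",
              x$n_components, x$n_holes, x$shape_class))
  invisible(x)
}
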