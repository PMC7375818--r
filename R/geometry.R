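#' Bounded 3D sampling volume of an image stack
#'
#' Describes the geometry of one FIB/SEM stack: physical extents in nm, voxel
#' sizes (in-plane nm/pixel and nm/section along z), and optionally the
#' fraction of the stack volume occupied by fixation artifacts. Coordinates
#' inside a stack are 0-based and live in the half-open box
#' \code{[0, extent)} along each axis.
#'
#' @param extent_x,extent_y,extent_z physical extents in nm; all > 0.
#' @param voxel_xy in-plane resolution in nm/pixel (default 5, the usual
#'   FIB/SEM imaging resolution).
#' @param voxel_z section thickness in nm (default 20, the usual milling
#'   step).
#' @param artifact_fraction fraction of the stack volume occupied by fixation
#'   artifacts, in [0, 1); typically 0 to 0.2.
#' @return an object of class \code{stack_geometry}.
#' @examples
#' g <- stack_geometry(10000, 10000, 10000)  # a 10 x 10 x 10 um cube
#' stack_volume_um3(g)
#' @export
stack_geometry <- function(extent_x, extent_y, extent_z,
                           voxel_xy = 5, voxel_z = 20,
                           artifact_fraction = 0) {
  for (nm in c("extent_x", "extent_y", "extent_z", "voxel_xy", "voxel_z"))
    stop_if_not_scalar_num(get(nm), nm, positive = TRUE)
  stop_if_not_scalar_num(artifact_fraction, "artifact_fraction")
  if (artifact_fraction < 0 || artifact_fraction >= 1)
    stop("'artifact_fraction' must be in [0, 1)", call. = FALSE)
  structure(
    list(extent = c(x = extent_x, y = extent_y, z = extent_z),
         voxel_xy = voxel_xy, voxel_z = voxel_z,
         artifact_fraction = artifact_fraction),
    class = "stack_geometry"
  )
}

#' @export
print.stack_geometry <- function(x, ...) {
  cat(sprintf("stack geometry: %.0f x %.0f x %.0f nm (%.1f um^3)\n",
              x$extent[1], x$extent[2], x$extent[3], stack_volume_um3(x)))
  cat(sprintf("  voxels: %.1f nm/px (xy), %.1f nm/section (z); grid %d x %d x %d\n",
              x$voxel_xy, x$voxel_z,
              voxel_grid_dim(x)[1], voxel_grid_dim(x)[2], voxel_grid_dim(x)[3]))
  if (x$artifact_fraction > 0)
    cat(sprintf("  fixation-artifact fraction: %.3f\n", x$artifact_fraction))
  invisible(x)
}

#' Stack volume in cubic micrometres
#' @param geom a \code{stack_geometry}.
#' @return volume in um^3.
#' @export
stack_volume_um3 <- function(geom) {
  stopifnot(inherits(geom, "stack_geometry"))
  nm3_to_um3(prod(geom$extent))
}

# voxel grid dimensions (nx, ny, nz) implied by the geometry
voxel_grid_dim <- function(geom) {
  c(nx = max(1L, floor(geom$extent[["x"]] / geom$voxel_xy)),
    ny = max(1L, floor(geom$extent[["y"]] / geom$voxel_xy)),
    nz = max(1L, floor(geom$extent[["z"]] / geom$voxel_z)))
}

# check an n x 3 coordinate matrix against the half-open box
points_in_box <- function(xyz, geom) {
  xyz[, 1] >= 0 & xyz[, 1] < geom$extent[["x"]] &
  xyz[, 2] >= 0 & xyz[, 2] < geom$extent[["y"]] &
  xyz[, 3] >= 0 & xyz[, 3] < geom$extent[["z"]]
}
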