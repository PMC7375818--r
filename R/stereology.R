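#' Stereological point grid specification
#'
#' A square point grid for Cavalieri point counting: each point carries an
#' associated area, and the grid spacing is the square root of that area.
#' Semithin-section work typically uses 400 um^2 per point; FIB/SEM artifact
#' estimation uses 400,000 nm^2 per point.
#'
#' @param area_per_point associated area per grid point, in nm^2 (use
#'   4e5 for the FIB/SEM grid, 4e8 for the 400 um^2 light-microscopy grid).
#' @param offset 2D origin offset of the grid in nm (default half a spacing,
#'   placing points away from the image border).
#' @return an object of class \code{grid_spec} with derived \code{spacing}.
#' @export
grid_spec <- function(area_per_point, offset = NULL) {
  stop_if_not_scalar_num(area_per_point, "area_per_point", positive = TRUE)
  spacing <- sqrt(area_per_point)
  if (is.null(offset)) offset <- c(spacing / 2, spacing / 2)
  structure(list(area_per_point = area_per_point, spacing = spacing,
                 offset = as.numeric(offset)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("point grid: %.0f nm^2/point (spacing %.1f nm)\n",
              x$area_per_point, x$spacing))
  invisible(x)
}

# grid point -> pixel index lookup for one section. labels is a matrix
# indexed [row=y, col=x]; points on a pixel boundary take floor(coordinate).
grid_hits <- function(labels, grid, pixel_size) {
  ny <- nrow(labels); nx <- ncol(labels)
  xmax <- nx * pixel_size - 1e-9
  ymax <- ny * pixel_size - 1e-9
  gx <- if (grid$offset[1] > xmax) numeric(0)
        else seq(grid$offset[1], xmax, by = grid$spacing)
  gy <- if (grid$offset[2] > ymax) numeric(0)
        else seq(grid$offset[2], ymax, by = grid$spacing)
  if (!length(gx) || !length(gy))
    stop("grid spacing exceeds the image extent: no grid points fall inside",
         call. = FALSE)
  ix <- pmin(floor(gx / pixel_size) + 1L, nx)
  iy <- pmin(floor(gy / pixel_size) + 1L, ny)
  as.vector(labels[iy, ix])
}

#' Cavalieri point-counting volume fractions
#'
#' Overlays the point grid on a 2D label image and estimates the volume
#' fraction V_v of each class as the share of grid points hitting it, in
#' percent. When a \code{remainder_class} is designated (e.g. neuropil), its
#' V_v is obtained by complement: 100 minus the sum of the other classes.
#'
#' @param labels integer matrix of class labels (rows = y, cols = x), or the
#'   list returned by \code{\link{generate_semithin_labels}}.
#' @param grid a \code{\link{grid_spec}}.
#' @param pixel_size pixel size in nm (default 250, a typical 40x
#'   light-microscope digitization; pass the image's own scale).
#' @param class_names optional names for the label codes.
#' @param remainder_class optional name or code of the complement class.
#' @return object of class \code{vv_estimate}: per-class point counts,
#'   per-class V_v in percent (summing to 100), and the total point count.
#' @export
cavalieri_vv <- function(labels, grid, pixel_size = 250,
                         class_names = NULL, remainder_class = NULL) {
  if (is.list(labels) && !is.null(labels$labels)) {
    if (is.null(class_names)) class_names <- labels$classes
    labels <- labels$labels
  }
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.matrix(labels) || !length(labels))
    stop("'labels' must be a nonempty matrix", call. = FALSE)
  hits <- grid_hits(labels, grid, pixel_size)
  codes <- sort(unique(as.vector(labels)))
  counts <- vapply(codes, function(k) sum(hits == k), numeric(1))
  nm <- if (!is.null(class_names)) class_names[codes] else paste0("class", codes)
  names(counts) <- nm
  total <- sum(counts)
  vv <- 100 * counts / total
  if (!is.null(remainder_class)) {
    rc <- if (is.character(remainder_class)) remainder_class else nm[remainder_class]
    vv[rc] <- 100 - sum(vv[setdiff(names(vv), rc)])
  }
  structure(list(counts = counts, vv = vv, total_points = total),
            class = "vv_estimate")
}

#' @export
print.vv_estimate <- function(x, ...) {
  cat(sprintf("Cavalieri V_v over %d grid points:\n", x$total_points))
  for (nm in names(x$vv))
    cat(sprintf("  %-14s %6.2f %%  (%d hits)\n", nm,
                round_half_up(x$vv[[nm]], 2), x$counts[[nm]]))
  invisible(x)
}

#' Estimate the fixation-artifact volume fraction of a stack
#'
#' Point counting on every \code{section_step}-th section of a binary
#' artifact mask (the Cavalieri estimate of the artifact volume fraction,
#' as applied to each FIB/SEM stack before density correction).
#'
#' @param mask 3D binary array (x, y, z voxel order) as returned by
#'   \code{\link{generate_artifact_mask}}.
#' @param grid a \code{\link{grid_spec}} (the conventional choice is
#'   400,000 nm^2 per point).
#' @param section_step sample every this-many sections (default 20). If the
#'   step exceeds the stack depth the single middle section is used, with a
#'   warning.
#' @param voxel_xy in-plane voxel size in nm of the mask grid.
#' @return occupied fraction in [0, 1].
#' @export
estimate_artifact_fraction <- function(mask, grid, section_step = 20L,
                                       voxel_xy = 5) {
  stopifnot(inherits(grid, "grid_spec"), length(dim(mask)) == 3L)
  nz <- dim(mask)[3]
  secs <- if (nz >= section_step) seq(section_step, nz, by = section_step)
          else integer(0)
  if (!length(secs)) {
    warning("section step exceeds stack depth; using the middle section")
    secs <- max(1L, nz %/% 2L)
  }
  hits <- unlist(lapply(secs, function(s)
    grid_hits(t(mask[, , s]), grid, voxel_xy)))
  mean(hits > 0)
}

#' Tissue shrinkage factors from pre-/post-processing measurements
#'
#' Osmication and plastic embedding shrink the tissue; measurements taken in
#' the processed block must be rescaled to pre-processing (fresh) values.
#' The area shrinkage factor p^2 is the processed-to-fresh surface-area
#' ratio; the linear in-plane factor p is its square root; the z-axis factor
#' p_z is the processed-to-fresh thickness ratio; the volume factor is
#' p^2 * p_z.
#'
#' @param pre_area,post_area section surface area before/after processing.
#' @param pre_thickness,post_thickness section thickness before/after.
#' @return object of class \code{shrinkage_factors} with fields \code{p2},
#'   \code{p}, \code{pz}, \code{s_vol}.
#' @examples
#' sf <- shrinkage_factors(100, 93.3, 1, 0.901)
#' sf$p   # 0.966
#' @export
shrinkage_factors <- function(pre_area, post_area,
                              pre_thickness = 1, post_thickness = 1) {
  for (nm in c("pre_area", "post_area", "pre_thickness", "post_thickness"))
    stop_if_not_scalar_num(get(nm), nm, positive = TRUE)
  if (post_area > pre_area || post_thickness > pre_thickness)
    warning("post-processing measurement exceeds pre-processing (swelling); ",
            "computing the ratio anyway")
  p2 <- post_area / pre_area
  pz <- post_thickness / pre_thickness
  structure(list(p2 = p2, p = sqrt(p2), pz = pz, s_vol = p2 * pz),
            class = "shrinkage_factors")
}

#' Shrinkage factors from reported values
#'
#' Builds a \code{shrinkage_factors} object directly from factor values as
#' reported in a publication (typically at 3-decimal precision). Reported
#' workflows apply the rounded factors as printed, so \code{p} may be given
#' explicitly (e.g. p = 0.966 alongside p^2 = 0.933); it must agree with
#' sqrt(p2) to the printed precision (|p - sqrt(p2)| < 5e-4).
#'
#' @param p2 area shrinkage factor in (0, 1].
#' @param pz z-axis shrinkage factor in (0, 1].
#' @param p in-plane linear factor; default \code{sqrt(p2)}.
#' @return a \code{shrinkage_factors} object.
#' @examples
#' as_shrinkage_factors(p2 = 0.933, pz = 0.901, p = 0.966)
#' @export
as_shrinkage_factors <- function(p2, pz = 1, p = NULL) {
  stop_if_not_scalar_num(p2, "p2", positive = TRUE)
  stop_if_not_scalar_num(pz, "pz", positive = TRUE)
  if (p2 > 1 || pz > 1)
    warning("shrinkage factors above 1 imply swelling")
  if (is.null(p)) p <- sqrt(p2)
  if (abs(p - sqrt(p2)) >= 5e-4)
    stop("'p' must equal sqrt(p2) at the reported precision", call. = FALSE)
  structure(list(p2 = p2, p = p, pz = pz, s_vol = p2 * pz),
            class = "shrinkage_factors")
}

#' Identity (no-shrinkage) factors
#' @return a \code{shrinkage_factors} object with all factors 1.
#' @export
no_shrinkage <- function() shrinkage_factors(1, 1, 1, 1)

#' @export
print.shrinkage_factors <- function(x, ...) {
  cat(sprintf("shrinkage factors: p^2 = %.3f, p = %.3f, p_z = %.3f, volume = %.3f\n",
              x$p2, x$p, x$pz, x$s_vol))
  invisible(x)
}

#' Apply shrinkage / fixation-artifact corrections to a measurement
#'
#' Rescales a processed-tissue measurement to its pre-processing value:
#' lengths are divided by p, areas by p^2. Volumes are first discounted for
#' the fixation-artifact fraction (artifacts are measured in the processed
#' stack) and then divided by the volume factor p^2 * p_z. Densities
#' (count per volume) are recomputed against the corrected volume, i.e.
#' multiplied by s_vol / (1 - artifact_fraction).
#'
#' @param value nonnegative measured value.
#' @param kind one of \code{"length"}, \code{"area"}, \code{"volume"},
#'   \code{"density"}.
#' @param factors a \code{\link{shrinkage_factors}}.
#' @param artifact_fraction fixation-artifact volume fraction in [0, 1);
#'   only volumes and densities use it.
#' @return the corrected value.
#' @examples
#' sf <- shrinkage_factors(100, 93.3, 1, 0.901)
#' apply_correction(717.55, "length", sf)      # 742.81 nm
#' apply_correction(79993.18, "area", sf)      # 85737.60 nm^2
#' @export
apply_correction <- function(value, kind = c("length", "area", "volume",
                                             "density"),
                             factors, artifact_fraction = 0) {
  kind <- match.arg(kind)
  stopifnot(inherits(factors, "shrinkage_factors"))
  if (any(value < 0)) stop("'value' must be >= 0", call. = FALSE)
  stop_if_not_scalar_num(artifact_fraction, "artifact_fraction")
  if (artifact_fraction < 0 || artifact_fraction >= 1)
    stop("'artifact_fraction' must be in [0, 1)", call. = FALSE)
  switch(kind,
    length = value / factors$p,
    area = value / factors$p2,
    volume = value * (1 - artifact_fraction) / factors$s_vol,
    density = value * factors$s_vol / (1 - artifact_fraction))
}
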