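#' Unbiased 3D counting frame (brick rule)
#'
#' An inner sampling box inside a stack with three inclusion faces and three
#' exclusion faces, so that each particle is countable in exactly one frame
#' when frames tile space. The exclusion faces are fixed at the minimum-x,
#' minimum-y and minimum-z faces (open boundaries); the inclusion faces are
#' the maxima (closed boundaries).
#'
#' @param geom the parent \code{\link{stack_geometry}}.
#' @param min_xyz,max_xyz numeric length-3 vectors: the inner box corners in
#'   nm. Defaults to a margin inset from the stack faces.
#' @param margin inset in nm used when corners are not given (default 0).
#' @return an object of class \code{counting_frame}.
#' @export
counting_frame <- function(geom, min_xyz = NULL, max_xyz = NULL, margin = 0) {
  stopifnot(inherits(geom, "stack_geometry"))
  if (is.null(min_xyz)) min_xyz <- rep(margin, 3)
  if (is.null(max_xyz)) max_xyz <- unname(geom$extent) - margin
  min_xyz <- as.numeric(min_xyz); max_xyz <- as.numeric(max_xyz)
  if (any(max_xyz <= min_xyz))
    stop("counting frame is empty", call. = FALSE)
  if (any(min_xyz < 0) || any(max_xyz > unname(geom$extent) + 1e-9))
    stop("counting frame extends outside the stack", call. = FALSE)
  structure(list(geom = geom, min = min_xyz, max = max_xyz,
                 exclusion_faces = c("x_min", "y_min", "z_min"),
                 inclusion_faces = c("x_max", "y_max", "z_max")),
            class = "counting_frame")
}

#' Counting-frame volume in cubic micrometres
#' @param frame a \code{\link{counting_frame}}.
#' @return volume in um^3.
#' @export
frame_volume_um3 <- function(frame) {
  stopifnot(inherits(frame, "counting_frame"))
  nm3_to_um3(prod(frame$max - frame$min))
}

#' @export
print.counting_frame <- function(x, ...) {
  cat(sprintf("counting frame: [%.0f,%.0f] x [%.0f,%.0f] x [%.0f,%.0f] nm (%.1f um^3)\n",
              x$min[1], x$max[1], x$min[2], x$max[2], x$min[3], x$max[3],
              frame_volume_um3(x)))
  cat("  exclusion faces (open): minimum x/y/z; inclusion faces (closed): maximum x/y/z\n")
  invisible(x)
}

#' Filter synapse records through an unbiased counting frame
#'
#' With centroid-only records (the usual case) the brick rule degrades to
#' centroid-in-box with open exclusion boundaries: a record is included iff
#' its centroid satisfies \code{min < c <= max} on every axis, so a centroid
#' lying exactly on an exclusion face is discarded while one on an inclusion
#' face is kept. The returned table carries the inclusion rule used as
#' attributes (\code{counting_rule}, \code{frame}).
#'
#' @param records a synapse table with columns \code{cx_nm}, \code{cy_nm},
#'   \code{cz_nm} (as produced by \code{\link{generate_population}}).
#' @param frame a \code{\link{counting_frame}}.
#' @return the included subset of \code{records}.
#' @export
counting_frame_filter <- function(records, frame) {
  stopifnot(inherits(frame, "counting_frame"))
  need <- c("cx_nm", "cy_nm", "cz_nm")
  if (!all(need %in% names(records)))
    stop("records must have centroid columns cx_nm, cy_nm, cz_nm",
         call. = FALSE)
  keep <- records$cx_nm > frame$min[1] & records$cx_nm <= frame$max[1] &
          records$cy_nm > frame$min[2] & records$cy_nm <= frame$max[2] &
          records$cz_nm > frame$min[3] & records$cz_nm <= frame$max[3]
  out <- records[keep, , drop = FALSE]
  attr(out, "counting_rule") <- "centroid"
  attr(out, "frame") <- frame
  out
}

#' Synaptic density from a count and a counting-frame volume
#'
#' Density in synapses per um^3, optionally corrected for shrinkage and the
#' fixation-artifact fraction (the count is divided by the corrected volume).
#' The identity density x volume = count holds exactly for the volume
#' convention used.
#'
#' @param n number of included synapses.
#' @param volume counting-frame volume in um^3 (as measured, i.e. processed
#'   tissue).
#' @param factors optional \code{\link{shrinkage_factors}}; identity if
#'   omitted.
#' @param artifact_fraction fixation-artifact fraction in [0, 1).
#' @return object of class \code{density_estimate} with \code{n_included},
#'   \code{cf_volume} (the volume used in the division), \code{density}, and
#'   a \code{corrected} flag.
#' @examples
#' synaptic_density(2814, 6221)   # 0.45 synapses/um^3
#' @export
synaptic_density <- function(n, volume, factors = NULL,
                             artifact_fraction = 0) {
  stop_if_not_scalar_num(volume, "volume", positive = TRUE)
  if (n < 0) stop("'n' must be >= 0", call. = FALSE)
  corrected <- !is.null(factors) || artifact_fraction > 0
  if (is.null(factors)) factors <- no_shrinkage()
  v_used <- apply_correction(volume, "volume", factors, artifact_fraction)
  structure(list(n_included = n, cf_volume = v_used,
                 density = n / v_used, corrected = corrected),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("synaptic density: %.2f synapses/um^3 (%d synapses in %.1f um^3%s)\n",
              round_half_up(x$density, 2), x$n_included, x$cf_volume,
              if (x$corrected) ", corrected" else ""))
  invisible(x)
}
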