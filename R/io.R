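SYNAPSE_COLUMNS <- c("id", "layer", "polarity", "target", "shape_class",
                     "cx_nm", "cy_nm", "cz_nm", "sas_area_nm2",
                     "sas_perimeter_nm", "sas_curvature")

#' Read or write a synapse table as CSV
#'
#' The exchange format is one row per reconstructed synapse with columns
#' id, layer, polarity, target, shape_class, cx_nm, cy_nm, cz_nm,
#' sas_area_nm2, sas_perimeter_nm, sas_curvature. \code{read_synapse_csv}
#' validates the record invariants (positive areas and perimeters, curvature
#' in [0, 1), known category levels).
#'
#' @param path file path.
#' @return \code{read_synapse_csv} returns a validated data.frame.
#' @export
read_synapse_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SYNAPSE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df)) {
    if (any(df$sas_area_nm2 <= 0) || any(df$sas_perimeter_nm <= 0))
      stop("SAS areas and perimeters must be positive", call. = FALSE)
    if (any(df$sas_curvature < 0 | df$sas_curvature >= 1))
      stop("SAS curvature must be in [0, 1)", call. = FALSE)
    if (!all(df$layer %in% SYNAPSE_LAYERS))
      stop("unknown layer labels", call. = FALSE)
    if (!all(df$polarity %in% c("AS", "SS")))
      stop("polarity must be AS or SS", call. = FALSE)
  }
  df[, union(SYNAPSE_COLUMNS, names(df))]
}

#' @rdname read_synapse_csv
#' @param records a synapse data.frame.
#' @export
write_synapse_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read or write label volumes as TIFF
#'
#' Single-page TIFF for 2D label images; multi-page for 3D masks (one page
#' per section). Labels are stored as 8-bit values, so at most 255 classes.
#'
#' @param path file path.
#' @return \code{read_label_tiff} returns an integer matrix (2D) or a 3D
#'   array (x, y, z) for multi-page files.
#' @export
read_label_tiff <- function(path) {
  img <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(img) == 1L) return(matrix(as.integer(img[[1]]), nrow(img[[1]])))
  arr <- array(0L, dim = c(ncol(img[[1]]), nrow(img[[1]]), length(img)))
  for (k in seq_along(img)) arr[, , k] <- as.integer(t(img[[k]]))
  arr
}

#' @rdname read_label_tiff
#' @param labels integer matrix (2D image) or 3D array (x, y, z).
#' @export
write_label_tiff <- function(labels, path) {
  to_page <- function(m) m / 255
  pages <- if (is.matrix(labels)) {
    to_page(labels)
  } else {
    lapply(seq_len(dim(labels)[3]), function(k) to_page(t(labels[, , k])))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Percentage with explicit denominator, table-style rounding
#'
#' @param n numerator count.
#' @param total denominator; zero yields NA.
#' @param digits decimals (half-up rounding); default 2.
#' @return percentage, or NA if the denominator is zero.
#' @examples
#' proportion_pct(18138, 19269)  # 94.13
#' @export
proportion_pct <- function(n, total, digits = 2) {
  if (length(total) == 1 && total == 0) return(NA_real_)
  round_half_up(100 * n / total, digits)
}
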