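#' Embryo trunk geometry for lateral-view images
#'
#' Describes the coordinate frame shared by the synthetic generator and the
#' quantification modules. Rows increase dorsal to ventral, columns increase
#' anterior to posterior, and all indices are 1-based. An axon has "grown
#' beyond" the horizontal myoseptum (HM) when its tip row is strictly greater
#' than `hm_row` (plus a small margin, see [classify_hm()]).
#'
#' @param pixel_size Pixel edge length in micrometres per pixel.
#' @param shape Integer vector `c(rows, cols)` of the image.
#' @param exit_row Row of the ventral edge of the spinal cord, where motor
#'   axons exit.
#' @param hm_row Row of the horizontal myoseptum.
#' @param ventral_extent_row Most ventral myotome row an axon can reach.
#' @param exit_cols Strictly increasing columns of the eight spinal exit
#'   points, one per scored hemisegment (somites 7-14).
#'
#' @return An object of class `embryo_geometry`.
#' @examples
#' geom <- embryo_geometry()
#' geom$hm_row
#' @export
embryo_geometry <- function(pixel_size = 1,
                            shape = c(140L, 360L),
                            exit_row = 20L,
                            hm_row = 48L,
                            ventral_extent_row = 120L,
                            exit_cols = seq(40L, by = 40L, length.out = 8L)) {
  stopifnot(length(shape) == 2, shape >= 1, pixel_size > 0)
  if (!(exit_row < hm_row && hm_row < ventral_extent_row)) {
    stop("require exit_row < hm_row < ventral_extent_row")
  }
  if (length(exit_cols) != 8L || any(diff(exit_cols) <= 0)) {
    stop("exit_cols must be 8 strictly increasing column indices")
  }
  if (ventral_extent_row > shape[1] || max(exit_cols) > shape[2] ||
      exit_row < 1 || min(exit_cols) < 1) {
    stop("geometry indices must lie inside the image")
  }
  structure(list(
    pixel_size = pixel_size,
    shape = as.integer(shape),
    exit_row = as.integer(exit_row),
    hm_row = as.integer(hm_row),
    ventral_extent_row = as.integer(ventral_extent_row),
    exit_cols = as.integer(exit_cols)
  ), class = "embryo_geometry")
}

#' @export
print.embryo_geometry <- function(x, ...) {
  cat("embryo_geometry:", x$shape[1], "x", x$shape[2], "px @",
      x$pixel_size, "um/px\n")
  cat("  exit_row", x$exit_row, "| hm_row", x$hm_row,
      "| ventral_extent_row", x$ventral_extent_row, "\n")
  cat("  exit_cols:", paste(x$exit_cols, collapse = " "), "\n")
  invisible(x)
}

#' Serialize / restore geometry as plain lists (for JSON sidecars)
#' @noRd
geometry_to_list <- function(geom) unclass(geom)

#' @noRd
geometry_from_list <- function(x) {
  embryo_geometry(pixel_size = x$pixel_size, shape = unlist(x$shape),
                  exit_row = x$exit_row, hm_row = x$hm_row,
                  ventral_extent_row = x$ventral_extent_row,
                  exit_cols = unlist(x$exit_cols))
}
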