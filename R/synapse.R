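# Synaptic puncta quantification at the horizontal myoseptum: a fixed square
# ROI per hemisegment, background subtraction, percent-of-maximum threshold,
# connected-component puncta statistics, and pre/post overlap.

#' Extract the square ROI around the myoseptum for one hemisegment
#'
#' The ROI is a square of `side_um` (default 20 um, i.e. 400 um^2) centred on
#' `(hm_row, exit_col[hemisegment])`. An ROI that would exceed the image
#' bounds raises an error rather than being clipped.
#'
#' @param channel 2-D image matrix.
#' @param geometry An [embryo_geometry()].
#' @param hemisegment Hemisegment index (1-8).
#' @param side_um ROI side length in um.
#' @return The square sub-image (side_px = `round(side_um / pixel_size)`).
#' @export
extract_roi <- function(channel, geometry, hemisegment, side_um = 20) {
  stopifnot(is.matrix(channel), hemisegment >= 1,
            hemisegment <= length(geometry$exit_cols))
  side <- round(side_um / geometry$pixel_size)
  r0 <- geometry$hm_row - floor(side / 2)
  c0 <- geometry$exit_cols[hemisegment] - floor(side / 2)
  rows <- (r0 + 1):(r0 + side)
  cols <- (c0 + 1):(c0 + side)
  if (min(rows) < 1 || max(rows) > nrow(channel) ||
      min(cols) < 1 || max(cols) > ncol(channel)) {
    stop("ROI for hemisegment ", hemisegment, " exceeds image bounds")
  }
  channel[rows, cols]
}

#' Background subtraction by morphological top-hat
#'
#' Subtracts the grayscale opening with a disk of radius `radius_um` (the
#' rolling-ball analogue); structures larger than the disk are treated as
#' background. The result is non-negative by construction.
#'
#' @param roi ROI matrix.
#' @param radius_um Disk radius in um; must exceed the punctum radius scale.
#' @param pixel_size um per pixel.
#' @return Background-corrected ROI.
#' @export
subtract_background <- function(roi, radius_um = 10, pixel_size = 1) {
  if (radius_um <= 0) stop("radius_um must be positive")
  r_px <- max(1L, round(radius_um / pixel_size))
  kern <- EBImage::makeBrush(2L * r_px + 1L, "disc")
  out <- EBImage::imageData(EBImage::whiteTopHat(roi, kern))
  pmax(matrix(out, nrow(roi), ncol(roi)), 0)
}

#' Percent-of-maximum binarisation
#'
#' A pixel is foreground when its value is at least `fraction` of the ROI
#' maximum. An all-zero ROI yields an empty mask.
#'
#' @param roi ROI matrix (typically background-subtracted).
#' @param fraction Threshold fraction in (0, 1); default 0.30.
#' @return Logical mask of the same shape.
#' @export
binarize <- function(roi, fraction = 0.30) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  m <- max(roi)
  if (m <= 0) return(matrix(FALSE, nrow(roi), ncol(roi)))
  roi >= fraction * m
}

#' Puncta statistics from a binary mask
#'
#' 8-connected components of at least `min_size_px` pixels are puncta. Area is
#' the retained foreground pixel count times `pixel_size^2`; mean intensity is
#' the mean of `roi` over punctum pixels (undefined, `NA`, when there are no
#' puncta).
#'
#' @param mask Logical mask.
#' @param roi Intensity image congruent with `mask`.
#' @param pixel_size um per pixel.
#' @param min_size_px Minimal punctum size in pixels (default 2).
#' @return A `puncta_stats` list: `puncta_count`, `total_area_um2`,
#'   `mean_intensity`.
#' @export
quantify_puncta <- function(mask, roi, pixel_size = 1, min_size_px = 2) {
  if (!all(dim(mask) == dim(roi))) stop("mask and roi shapes differ")
  lab <- .label8(mask != 0)
  if (max(lab) == 0) {
    return(structure(list(puncta_count = 0L, total_area_um2 = 0,
                          mean_intensity = NA_real_), class = "puncta_stats"))
  }
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_size_px)
  if (!length(keep)) {
    return(structure(list(puncta_count = 0L, total_area_um2 = 0,
                          mean_intensity = NA_real_), class = "puncta_stats"))
  }
  inpunct <- lab %in% keep
  structure(list(
    puncta_count = length(keep),
    total_area_um2 = sum(sizes[keep]) * pixel_size^2,
    mean_intensity = mean(roi[inpunct])
  ), class = "puncta_stats")
}

#' @export
print.puncta_stats <- function(x, ...) {
  cat("puncta_stats: count", x$puncta_count, "| area",
      round(x$total_area_um2, 2), "um^2 | mean intensity",
      if (is.na(x$mean_intensity)) "NA" else round(x$mean_intensity, 4), "\n")
  invisible(x)
}

#' Overlap (synaptic-area) statistics of pre- and postsynaptic masks
#'
#' The overlap of the two thresholded compartments represents the synaptic
#' area; statistics are computed with [quantify_puncta()] on the intersection
#' mask.
#'
#' @param pre_mask,post_mask Congruent logical masks.
#' @param pre_roi Intensity image for the overlap intensity read-out.
#' @inheritParams quantify_puncta
#' @return A `puncta_stats` list.
#' @export
overlap_stats <- function(pre_mask, post_mask, pre_roi, pixel_size = 1,
                          min_size_px = 2) {
  if (!all(dim(pre_mask) == dim(post_mask))) stop("mask shapes differ")
  quantify_puncta(pre_mask & post_mask, pre_roi, pixel_size, min_size_px)
}

#' Per-embryo synapse measurement
#'
#' Runs the per-hemisegment chain (extract ROI, subtract background, threshold,
#' quantify, both channels plus their overlap) over the requested hemisegments
#' and averages the statistics per embryo. Embryos with fewer than four valid
#' hemisegment ROIs are flagged unusable.
#'
#' @param image 3-D array with the presynaptic label in channel 2 and the
#'   postsynaptic label in channel 3.
#' @param geometry An [embryo_geometry()].
#' @param hemisegments Hemisegment indices to measure (default 1:5).
#' @param fraction Binarisation fraction (default 0.30).
#' @param radius_um Background-subtraction disk radius (default 10 um).
#' @param min_size_px Minimal punctum size (default 2 px).
#' @param intensity_on Measure punctum intensity on the background-subtracted
#'   (default) or raw ROI.
#' @return A `synapse_measurement`: averaged `pre`, `post`, `overlap`
#'   statistics, `n_hemisegments`, `usable`, and the per-hemisegment table.
#' @export
measure_embryo <- function(image, geometry, hemisegments = 1:5,
                           fraction = 0.30, radius_um = 10, min_size_px = 2,
                           intensity_on = c("subtracted", "raw")) {
  intensity_on <- match.arg(intensity_on)
  stopifnot(length(dim(image)) == 3L, dim(image)[3] >= 3L)
  ps <- geometry$pixel_size
  per <- list()
  for (h in hemisegments) {
    res <- tryCatch({
      pre_roi <- extract_roi(image[, , 2], geometry, h)
      post_roi <- extract_roi(image[, , 3], geometry, h)
      pre_bs <- subtract_background(pre_roi, radius_um, ps)
      post_bs <- subtract_background(post_roi, radius_um, ps)
      pre_mask <- binarize(pre_bs, fraction)
      post_mask <- binarize(post_bs, fraction)
      pre_int <- if (intensity_on == "subtracted") pre_bs else pre_roi
      post_int <- if (intensity_on == "subtracted") post_bs else post_roi
      s_pre <- quantify_puncta(pre_mask, pre_int, ps, min_size_px)
      s_post <- quantify_puncta(post_mask, post_int, ps, min_size_px)
      s_ov <- overlap_stats(pre_mask, post_mask, pre_int, ps, min_size_px)
      data.frame(hemisegment = h,
                 compartment = c("pre", "post", "overlap"),
                 puncta_count = c(s_pre$puncta_count, s_post$puncta_count,
                                  s_ov$puncta_count),
                 total_area_um2 = c(s_pre$total_area_um2, s_post$total_area_um2,
                                    s_ov$total_area_um2),
                 mean_intensity = c(s_pre$mean_intensity, s_post$mean_intensity,
                                    s_ov$mean_intensity))
    }, error = function(e) NULL)
    if (!is.null(res)) per[[length(per) + 1]] <- res
  }
  tab <- do.call(rbind, per)
  n_valid <- length(per)
  avg <- function(comp) {
    sub <- tab[tab$compartment == comp, , drop = FALSE]
    structure(list(
      puncta_count = mean(sub$puncta_count),
      total_area_um2 = mean(sub$total_area_um2),
      mean_intensity = if (all(is.na(sub$mean_intensity))) NA_real_ else
        mean(sub$mean_intensity, na.rm = TRUE)
    ), class = "puncta_stats")
  }
  usable <- n_valid >= 4
  if (!usable) warning("embryo unusable: only ", n_valid,
                       " valid hemisegment ROIs (need >= 4)")
  structure(list(
    pre = if (n_valid) avg("pre") else NULL,
    post = if (n_valid) avg("post") else NULL,
    overlap = if (n_valid) avg("overlap") else NULL,
    n_hemisegments = n_valid,
    usable = usable,
    per_hemisegment = tab
  ), class = "synapse_measurement")
}

#' @export
print.synapse_measurement <- function(x, ...) {
  cat("synapse_measurement over", x$n_hemisegments, "hemisegments",
      if (!x$usable) "(UNUSABLE)" else "", "\n")
  for (comp in c("pre", "post", "overlap")) {
    s <- x[[comp]]
    if (is.null(s)) next
    cat(sprintf("  %-8s count %5.2f  area %7.2f um^2  intensity %s\n",
                comp, s$puncta_count, s$total_area_um2,
                if (is.na(s$mean_intensity)) "NA" else
                  sprintf("%.4f", s$mean_intensity)))
  }
  invisible(x)
}
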