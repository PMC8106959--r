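# Automated CaP motor-axon tracing and phenotype scoring from the reporter
# channel. The original assay traced axons manually from the spinal exit
# point to the tip; this module is the automated stand-in: Otsu binarisation
# within a hemisegment window, Zhang-Suen skeletonisation, and geodesic
# main-path selection on the skeleton graph.

#' Trace one CaP axon from its spinal exit point
#'
#' Binarises the hemisegment window around `exit_col` (Otsu threshold),
#' skeletonises it, and extracts the main axon as the geodesic path from the
#' skeleton pixel nearest the exit point to the skeleton endpoint at maximal
#' geodesic distance (ties broken toward the more ventral endpoint, the
#' biological growth direction).
#'
#' @param channel 2-D numeric matrix (motor-neuron reporter channel).
#' @param geometry An [embryo_geometry()].
#' @param exit_col Column of the spinal exit point.
#' @param window_halfwidth_um Half-width of the hemisegment window, in um.
#'   Defaults to half the exit-point spacing.
#' @param capture_radius_um Maximal distance between the exit point and the
#'   nearest skeleton pixel for the axon to count as present (default 5 um).
#' @param min_component_px Skeleton components smaller than this are ignored.
#' @return An object of class `axon_trace`: `exit_point`, `path` (n x 2
#'   matrix of absolute row/col), `tip`, `length_um`, `present`,
#'   `hm_status` (`"stalled"`/`"crossed"`, at the default 2 um margin).
#' @seealso [axon_length()], [classify_hm()], [count_branches()]
#' @export
trace_axon <- function(channel, geometry, exit_col,
                       window_halfwidth_um = NULL,
                       capture_radius_um = 5,
                       min_component_px = 5) {
  stopifnot(is.matrix(channel), inherits(geometry, "embryo_geometry"))
  ps <- geometry$pixel_size
  exit_row <- geometry$exit_row
  if (exit_col < 1 || exit_col > ncol(channel) ||
      exit_row < 1 || exit_row > nrow(channel)) {
    stop("exit point (", exit_row, ", ", exit_col, ") outside image")
  }
  hw <- round((window_halfwidth_um %||%
                 (min(diff(geometry$exit_cols)) * ps / 2)) / ps)
  rows <- max(1L, exit_row - 6L):nrow(channel)
  cols <- max(1L, exit_col - hw):min(ncol(channel), exit_col + hw)
  win <- channel[rows, cols, drop = FALSE]

  absent <- function() {
    structure(list(exit_point = c(exit_row, exit_col), exit_col = exit_col,
                   path = matrix(numeric(0), 0, 2), tip = c(NA, NA),
                   length_um = 0, present = FALSE, hm_status = "stalled"),
              class = "axon_trace")
  }

  # presence gate: demand signal clearly above the window's noise floor.
  # MAD estimates the noise spread; on noise-free images (MAD 0) fall back to
  # the spread of the background (sub-90th-percentile) pixels, and on fully
  # flat fallbacks simply ask for any pixel above the median.
  med <- stats::median(win)
  s <- stats::mad(win)
  if (s == 0) s <- stats::sd(win[win <= stats::quantile(win, 0.9)])
  if (!is.finite(s) || s == 0) {
    if (max(win) <= med) return(absent())
  } else if (max(win) < med + 5 * s) {
    return(absent())
  }

  rng <- range(win)
  w01 <- (win - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(w01))
  mask <- w01 > th
  sk <- .zhang_suen(mask)
  sg <- .skeleton_graph(sk)
  if (is.null(sg)) return(absent())

  # skeleton pixel nearest the exit point (window coordinates)
  e_r <- exit_row - rows[1] + 1L
  e_c <- exit_col - cols[1] + 1L
  d2 <- (sg$coords[, 1] - e_r)^2 + (sg$coords[, 2] - e_c)^2
  start <- which.min(d2)
  if (sqrt(d2[start]) * ps > capture_radius_um) return(absent())

  comp <- igraph::components(sg$graph)
  members <- which(comp$membership == comp$membership[start])
  if (length(members) < min_component_px) return(absent())

  gd <- igraph::distances(sg$graph, v = start, to = members)[1, ]
  ncnt <- .skel_neighbour_count(sk)
  deg <- ncnt[sg$coords[members, , drop = FALSE]]
  cand <- members[deg <= 1]
  if (!length(cand)) cand <- members
  gd_c <- gd[match(cand, members)]
  best <- cand[gd_c == max(gd_c)]
  if (length(best) > 1) best <- best[which.max(sg$coords[best, 1])]

  sp <- igraph::shortest_paths(sg$graph, from = start, to = best)$vpath[[1]]
  path_w <- sg$coords[as.integer(sp), , drop = FALSE]
  len_px <- max(gd[match(best, members)])

  # the assay measures from the spinal exit point: include the gap between
  # the exit point and the first skeleton pixel
  len_px <- len_px + sqrt(d2[start])

  # skeleton endpoint correction: thresholding and thinning both erode line
  # ends, so extend the tip along its final direction to the visible end of
  # the signal (a permissive mask at half the Otsu threshold)
  lo_mask <- w01 > 0.5 * th
  k <- nrow(path_w)
  if (k >= 3) {
    dirn <- sign(path_w[k, ] - path_w[k - 2, ])
    p <- path_w[k, ]
    if (!all(dirn == 0)) {
      for (step in 1:6) {
        q <- p + dirn
        if (q[1] < 1 || q[1] > nrow(lo_mask) || q[2] < 1 ||
            q[2] > ncol(lo_mask) || !lo_mask[q[1], q[2]]) break
        path_w <- rbind(path_w, q)
        len_px <- len_px + sqrt(sum(dirn^2))
        p <- q
      }
    }
  }

  path <- cbind(path_w[, 1] + rows[1] - 1L, path_w[, 2] + cols[1] - 1L)
  len <- len_px * ps

  tr <- structure(list(
    exit_point = c(exit_row, exit_col), exit_col = exit_col,
    path = path, tip = path[nrow(path), ],
    length_um = len, present = TRUE, hm_status = NA_character_
  ), class = "axon_trace")
  tr$hm_status <- classify_hm(tr, geometry)
  attr(tr, "window") <- list(rows = rows, cols = cols, skeleton = sk,
                             path_w = path_w)
  tr
}

#' @export
print.axon_trace <- function(x, ...) {
  if (!x$present) {
    cat("axon_trace: absent (exit col", x$exit_col, ")\n")
  } else {
    cat("axon_trace: exit col", x$exit_col, "| length",
        round(x$length_um, 2), "um |", x$hm_status, "\n")
  }
  invisible(x)
}

#' Total path length of a traced axon
#'
#' Sum of Euclidean step lengths along the traced path (1 or sqrt(2) pixels
#' per 8-connected step) times the pixel size.
#'
#' @param trace An `axon_trace`.
#' @param pixel_size um per pixel.
#' @return Length in micrometres; 0 (with a warning) for an absent axon.
#' @export
axon_length <- function(trace, pixel_size = 1) {
  stopifnot(inherits(trace, "axon_trace"))
  if (!trace$present || nrow(trace$path) < 2) {
    if (!trace$present) warning("absent axon: length is 0")
    return(0)
  }
  d <- diff(trace$path)
  sum(sqrt(d[, 1]^2 + d[, 2]^2)) * pixel_size
}

#' Classify myoseptum crossing of a traced axon
#'
#' An axon has crossed the horizontal myoseptum when its tip lies more than
#' `margin_um` ventral of `hm_row`; the margin makes the visual "beyond the
#' HM" call reproducible at the boundary. Absent axons are stalled.
#'
#' @inheritParams axon_length
#' @param geometry An [embryo_geometry()].
#' @param margin_um Crossing margin in um (default 2).
#' @return `"crossed"` or `"stalled"`.
#' @export
classify_hm <- function(trace, geometry, margin_um = 2) {
  stopifnot(inherits(trace, "axon_trace"), margin_um >= 0)
  if (!trace$present) return("stalled")
  if (trace$tip[1] > geometry$hm_row + margin_um / geometry$pixel_size)
    "crossed" else "stalled"
}

#' Count side branches crossing offset lines at +-offset_um from the main axon
#'
#' Reproduces the line-crossing counting rule of the assay: two lines are
#' drawn parallel to the main axon, offset `offset_um` anterior and posterior;
#' skeleton branches attached to the main axon that reach either line are
#' counted (once per side they cross). Filopodia shorter than the offset never
#' reach a line and are excluded.
#'
#' @param channel Reporter channel matrix (used if the trace carries no cached
#'   window skeleton).
#' @inheritParams classify_hm
#' @param offset_um Offset of the counting lines (default 8 um).
#' @return Integer branch count (0 for an absent axon).
#' @export
count_branches <- function(channel, trace, geometry, offset_um = 8) {
  stopifnot(inherits(trace, "axon_trace"), offset_um > 0)
  if (!trace$present) return(0L)
  w <- attr(trace, "window")
  if (is.null(w)) {
    tr2 <- trace_axon(channel, geometry, trace$exit_col)
    if (!tr2$present) return(0L)
    w <- attr(tr2, "window")
  }
  sk <- w$skeleton
  pw <- w$path_w
  off_px <- offset_um / geometry$pixel_size

  pmask <- matrix(FALSE, nrow(sk), ncol(sk))
  pmask[pw] <- TRUE
  rest <- sk & !pmask
  if (!any(rest)) return(0L)

  # main-axon column per row (mean over path pixels in that row)
  mc <- tapply(pw[, 2], pw[, 1], mean)
  mrows <- as.integer(names(mc))

  # components of the residual skeleton that touch the main path
  near <- EBImage::imageData(EBImage::dilate(pmask * 1,
                                             EBImage::makeBrush(3, "box"))) > 0
  lab <- .label8(rest)
  nlab <- max(lab)
  count <- 0L
  for (l in seq_len(nlab)) {
    px <- which(lab == l, arr.ind = TRUE)
    if (!any(near[px])) next   # not attached to this axon
    ref <- if (length(mrows) < 2) rep(mc[1], nrow(px)) else
      mc[findInterval(px[, 1], mrows, all.inside = TRUE)]
    offs <- (px[, 2] - ref)[!is.na(ref)]
    if (!length(offs)) next
    if (max(offs) >= off_px) count <- count + 1L   # posterior line crossed
    if (min(offs) <= -off_px) count <- count + 1L  # anterior line crossed
  }
  count
}

#' Quantify all eight CaP axons of one embryo
#'
#' Runs [trace_axon()] on every exit point, measures length, crossing status
#' and (optionally) branch counts, and returns the per-embryo axon table that
#' downstream scoring and screen statistics consume.
#'
#' @param image 3-D array (`rows x cols x channels`) or a 2-D reporter matrix.
#' @param geometry An [embryo_geometry()].
#' @param branches Count branches as well (slightly slower).
#' @param ... Passed to [trace_axon()].
#' @return data.frame: `axon_id`, `exit_col`, `present`, `length_um`,
#'   `hm_status`, `branch_count`.
#' @export
quantify_axons <- function(image, geometry, branches = TRUE, ...) {
  channel <- if (length(dim(image)) == 3L) image[, , 1] else image
  rows <- lapply(seq_along(geometry$exit_cols), function(a) {
    tr <- trace_axon(channel, geometry, geometry$exit_cols[a], ...)
    data.frame(
      axon_id = a, exit_col = geometry$exit_cols[a], present = tr$present,
      length_um = tr$length_um, hm_status = tr$hm_status,
      branch_count = if (branches)
        count_branches(channel, tr, geometry) else NA_integer_)
  })
  do.call(rbind, rows)
}

#' Abnormality rules for normal/abnormal axon scoring
#'
#' An axon is abnormal when it is missing, truncated (shorter than
#' `min_normal_length_um`) or carries ectopic branches (more than
#' `max_normal_branch_count` branches crossing the offset lines). The default
#' minimal normal length is the exit-to-myoseptum distance plus 10 um: at the
#' stage scored, a normal axon has passed the myoseptum.
#'
#' @param geometry An [embryo_geometry()] (used for the length default).
#' @param min_normal_length_um Minimal normal length, um.
#' @param max_normal_branch_count Branch count above which the axon is
#'   ectopically branched (default 0).
#' @return An `abnormality_rules` list.
#' @export
abnormality_rules <- function(geometry,
                              min_normal_length_um =
                                (geometry$hm_row - geometry$exit_row) *
                                geometry$pixel_size + 10,
                              max_normal_branch_count = 0L) {
  stopifnot(min_normal_length_um > 0, max_normal_branch_count >= 0)
  structure(list(min_normal_length_um = min_normal_length_um,
                 max_normal_branch_count = as.integer(max_normal_branch_count)),
            class = "abnormality_rules")
}

#' Score axons of one embryo as normal or abnormal
#'
#' @param axons Per-embryo axon table from [quantify_axons()] (needs columns
#'   `present`, `length_um`, `branch_count`).
#' @param rules An [abnormality_rules()] object.
#' @return List with `axons` (input plus logical `abnormal`) and
#'   `percent_abnormal` (100 x abnormal / scored).
#' @export
score_abnormal <- function(axons, rules) {
  stopifnot(inherits(rules, "abnormality_rules"))
  if (!is.data.frame(axons) || nrow(axons) == 0) {
    stop("no axons to score")
  }
  if (nrow(axons) > 8) warning("more than 8 axons supplied for one embryo")
  bc <- axons$branch_count
  bc[is.na(bc)] <- 0L
  abn <- !axons$present |
    axons$length_um < rules$min_normal_length_um |
    bc > rules$max_normal_branch_count
  axons$abnormal <- abn
  list(axons = axons, percent_abnormal = 100 * mean(abn))
}
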