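# Rasterisation of axon paths and synaptic puncta. Axons are built as
# 8-connected pixel chains; the recorded true length of an axon is the
# Euclidean step sum of its chain (1 or sqrt(2) px per step), so that a
# perfect tracer recovers the truth exactly on noise-free renderings.

#' 8-connected Bresenham segment between two pixels (inclusive)
#' @noRd
.bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  n <- max(dr, dc)
  if (n == 0) return(cbind(r0, c0))
  # supercover-free integer rounding keeps steps 8-connected
  rows <- round(seq(r0, r1, length.out = n + 1))
  cols <- round(seq(c0, c1, length.out = n + 1))
  cbind(rows, cols)
}

#' Rasterise a polyline (continuous waypoints) into an 8-connected chain
#' @noRd
.polyline_chain <- function(pts) {
  pts <- round(pts)
  segs <- vector("list", nrow(pts) - 1)
  for (i in seq_len(nrow(pts) - 1)) {
    s <- .bresenham(pts[i, 1], pts[i, 2], pts[i + 1, 1], pts[i + 1, 2])
    if (i > 1) s <- s[-1, , drop = FALSE]
    segs[[i]] <- s
  }
  ch <- do.call(rbind, segs)
  keep <- c(TRUE, rowSums(abs(diff(ch))) > 0)
  ch[keep, , drop = FALSE]
}

#' Euclidean step lengths of a chain, in pixels
#' @noRd
.chain_steps <- function(chain) {
  if (nrow(chain) < 2) return(numeric(0))
  d <- diff(chain)
  sqrt(d[, 1]^2 + d[, 2]^2)
}

#' Cut a chain so its cumulative length is as close as possible to target_px
#' @noRd
.cut_chain <- function(chain, target_px) {
  cum <- c(0, cumsum(.chain_steps(chain)))
  i <- which(cum >= target_px)[1]
  if (is.na(i)) return(chain)
  if (i > 1 && (cum[i] - target_px) > (target_px - cum[i - 1])) i <- i - 1
  chain[seq_len(max(i, 2)), , drop = FALSE]
}

#' Continuous arc length of x(r) = A sin(pi m r / D) over r in [0, D]
#' @noRd
.sine_arc <- function(A, m, D) {
  r <- seq(0, D, length.out = 4 * ceiling(D) + 1)
  dx <- A * (pi * m / D) * cos(pi * m * r / D)
  h <- D / (length(r) - 1)
  sum(sqrt(1 + dx^2)) * h
}

#' Build the pixel chain of one axon.
#'
#' Crossed axons run ventrally with a gentle sinusoidal wobble and stop when
#' the target path length is reached (tip well beyond the HM). Stalled axons
#' longer than the exit-to-HM distance descend with a gentle curve and spend
#' their residual length growing along the myoseptum in one direction (the
#' geometry stays self-avoiding, so a skeleton tracer can follow it);
#' truncated axons simply stop dorsal to the HM.
#' @noRd
.make_axon_chain <- function(geom, exit_col, target_um, crossed, phase = 0) {
  ps <- geom$pixel_size
  target_px <- target_um / ps
  D <- geom$hm_row - geom$exit_row          # exit-to-HM drop, px
  if (crossed) {
    target_px <- max(target_px, D + 4)      # a crossed axon must pass the HM
    depth <- min(ceiling(target_px) + 2, geom$ventral_extent_row - geom$exit_row)
    r <- seq(0, depth, by = 0.5)
    x <- 1.5 * sin(2 * pi * r / 45 + phase)
    pts <- cbind(geom$exit_row + r, exit_col + x)
    chain <- .cut_chain(.polyline_chain(pts), target_px)
  } else if (target_px <= D - 1) {
    depth <- max(target_px, 2)
    r <- seq(0, depth, by = 0.5)
    x <- 1.0 * sin(pi * r / depth)
    pts <- cbind(geom$exit_row + r, exit_col + x)
    chain <- .cut_chain(.polyline_chain(pts), target_px)
  } else {
    Dd <- D - 1                             # stop one row dorsal of the HM
    D2 <- Dd - 4                            # bump depth; 4 rows feed the chamfer
    arc_target <- min(target_px, 1.12 * D2)
    # single smooth lateral bump x = A sin^2(pi r / D2): the path leaves the
    # exit vertically and arrives vertically, so the rendered line has no
    # steep end caps for the tracer to lose; a 45-degree chamfer then leads
    # into the residual growth along the myoseptum
    arc_bump <- function(a) {
      r <- seq(0, D2, length.out = 4 * ceiling(D2) + 1)
      dx <- a * pi / D2 * sin(2 * pi * r / D2)
      sum(sqrt(1 + dx^2)) * D2 / (length(r) - 1)
    }
    f <- function(a) arc_bump(a) - arc_target
    A <- if (arc_target <= D2 + 0.2) 0 else if (f(12) <= 0) 12 else
      stats::uniroot(f, c(0, 12))$root
    r <- seq(0, D2, by = 0.5)
    s <- if (sin(phase) >= 0) 1 else -1     # excursion side
    x <- s * A * sin(pi * r / D2)^2
    tail_len <- 15                          # residual growth along the HM
    pts <- rbind(cbind(geom$exit_row + r, exit_col + x),
                 cbind(geom$exit_row + D2 + 1:4, exit_col + s * 1:4),
                 cbind(geom$exit_row + Dd, exit_col + s * (4 + seq(1, tail_len))))
    chain <- .cut_chain(.polyline_chain(pts), target_px)
  }
  # clip to image bounds (defensive; geometry margins normally suffice)
  chain[, 1] <- pmin(pmax(chain[, 1], 1L), geom$shape[1])
  chain[, 2] <- pmin(pmax(chain[, 2], 1L), geom$shape[2])
  list(chain = chain,
       length_um = sum(.chain_steps(chain)) * ps,
       tip = chain[nrow(chain), ])
}

#' Build a side-branch chain from an attachment point on the main chain.
#' Lateral extent is the column offset from the attachment, in um.
#' @noRd
.make_branch_chain <- function(geom, main_chain, attach_frac, side, extent_um) {
  ps <- geom$pixel_size
  ext_px <- extent_um / ps
  ai <- max(2, round(attach_frac * nrow(main_chain)))
  a <- main_chain[ai, ]
  tip <- c(a[1] + round(0.4 * ext_px), a[2] + side * round(ext_px))
  tip[1] <- min(max(tip[1], 1L), geom$shape[1])
  tip[2] <- min(max(tip[2], 1L), geom$shape[2])
  .bresenham(a[1], a[2], tip[1], tip[2])
}

#' Paint a chain mask, thickened to the given width, into a matrix
#' @noRd
.paint_chains <- function(shape, chains, width_px = 2) {
  mask <- matrix(0, shape[1], shape[2])
  for (ch in chains) mask[ch] <- 1
  if (width_px == 2) {
    # 2x2 thickening (no odd-kernel equivalent exists)
    mask <- pmax(mask, .shift_mat(mask, 1, 0), .shift_mat(mask, 0, 1),
                 .shift_mat(mask, 1, 1))
  } else if (width_px > 2) {
    kern <- EBImage::makeBrush(max(3L, 2L * (width_px %/% 2L) + 1L), "box")
    mask <- EBImage::imageData(EBImage::dilate(mask, kern))
  }
  mask
}

#' Add a Gaussian spot to an image matrix (in place semantics via return)
#' @noRd
.add_spot <- function(img, row, col, sigma_px, amplitude) {
  ext <- ceiling(4 * sigma_px)
  r <- max(1, floor(row - ext)):min(nrow(img), ceiling(row + ext))
  c <- max(1, floor(col - ext)):min(ncol(img), ceiling(col + ext))
  if (!length(r) || !length(c)) return(img)
  d2 <- outer((r - row)^2, (c - col)^2, `+`)
  img[r, c] <- img[r, c] + amplitude * exp(-d2 / (2 * sigma_px^2))
  img
}

#' Render the three channels of an embryo from its ground truth
#'
#' Channel 1 holds the motor-neuron reporter (axons), channels 2 and 3 the
#' pre- and postsynaptic labels. Additive Gaussian noise has standard
#' deviation `amplitude / snr` per channel (`snr = Inf` disables noise);
#' values are clipped to `[0, 1]`.
#'
#' @param truth An `embryo_truth` object (see [generate_embryo()]).
#' @param snr Signal-to-noise ratio override; defaults to the preset's value.
#' @return A numeric array `rows x cols x 3`.
#' @export
render_embryo <- function(truth, snr = NULL) {
  stopifnot(inherits(truth, "embryo_truth"))
  p <- truth$params
  snr <- snr %||% p$snr
  geom <- geometry_from_list(truth$geometry)
  shape <- geom$shape

  chains <- truth$chains
  ax <- .paint_chains(shape, chains, p$axon$width_px)
  ax <- EBImage::imageData(EBImage::gblur(ax, sigma = 0.5))
  ch1 <- p$axon$amplitude * pmin(ax, 1)

  ch2 <- matrix(0, shape[1], shape[2])
  ch3 <- matrix(0, shape[1], shape[2])
  for (h in seq_along(truth$puncta)) {
    ph <- truth$puncta[[h]]
    for (i in seq_len(nrow(ph$pre))) {
      ch2 <- .add_spot(ch2, ph$pre$row[i], ph$pre$col[i],
                       ph$pre$sigma_um[i] / geom$pixel_size, ph$pre$amplitude[i])
    }
    for (i in seq_len(nrow(ph$post))) {
      ch3 <- .add_spot(ch3, ph$post$row[i], ph$post$col[i],
                       ph$post$sigma_um[i] / geom$pixel_size, ph$post$amplitude[i])
    }
  }

  amps <- c(p$axon$amplitude, p$puncta$pre$amplitude, p$puncta$post$amplitude)
  # the reporter channel sits on a fixed tissue background; the antibody
  # channels carry an autofluorescence floor that scales with the label
  # amplitude, as does the noise
  bgs <- c(p$background, 0.15 * amps[2], 0.15 * amps[3])
  img <- array(0, c(shape[1], shape[2], 3L))
  img[, , 1] <- ch1; img[, , 2] <- ch2; img[, , 3] <- ch3
  for (k in 1:3) {
    x <- img[, , k] + bgs[k]
    if (is.finite(snr) && snr > 0) {
      # PSF-correlated noise: white noise filtered with the optical blur,
      # rescaled so the marginal SD is amplitude / snr
      nf <- matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
      nf <- EBImage::imageData(EBImage::gblur(nf, sigma = 0.5))
      x <- x + nf * (amps[k] / snr) / stats::sd(nf)
    }
    img[, , k] <- pmin(pmax(x, 0), 1)
  }
  if (truth$toxicity == "death") {
    # dead embryos image as opaque: high uniform signal in all channels
    img[] <- pmin(img + 0.6, 1)
  }
  img
}
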