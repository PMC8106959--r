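# Synthetic embryo generation: draws per-axon and per-punctum parameters from
# a preset, builds pixel-chain ground truth, and renders images. Cohort
# simulation optionally stratifies the continuous and binary draws so that a
# calibration cohort's realized group means sit tight on the preset's nominal
# values (systematic sampling; every draw remains random, only the group-level
# variance is reduced).

.ABN_MODES <- c("missing", "truncated", "ectopic")

#' Sample all stochastic parameters for a cohort of embryos
#' @noRd
.sample_cohort_params <- function(preset, n, stratified) {
  geom <- geometry_from_list(preset$geometry)
  ax <- preset$axon; abn <- preset$abnormal; pc <- preset$puncta
  M <- n * 8L
  lower <- if (abn$rate > 0) max(ax$min_length_um, abn$min_healthy_length_um) else
    ax$min_length_um

  u <- if (stratified) stratified_unif(M) else stats::runif(M)
  len <- qtruncn(u, ax$mean_length_um, ax$sd_length_um, lower, ax$max_length_um)
  len <- matrix(len, nrow = n, byrow = TRUE)

  if (stratified) {
    ncross <- allocate_counts(round(M * ax$p_crossed), n, 8L)
  } else {
    ncross <- stats::rbinom(n, 8L, ax$p_crossed)
  }

  if (abn$rate > 0) {
    if (stratified) {
      nabn <- allocate_counts(round(M * abn$rate), n, 8L)
      Ka <- sum(nabn)
      mode_counts <- round(Ka * abn$modes)
      while (sum(mode_counts) > Ka) mode_counts[which.max(mode_counts)] <-
        mode_counts[which.max(mode_counts)] - 1L
      while (sum(mode_counts) < Ka) mode_counts[which.max(abn$modes)] <-
        mode_counts[which.max(abn$modes)] + 1L
      mode_pool <- sample(rep(.ABN_MODES, mode_counts))
    } else {
      nabn <- NULL # drawn per axon below
      mode_pool <- NULL
    }
  } else {
    nabn <- rep.int(0L, n); mode_pool <- NULL
  }

  embryos <- vector("list", n)
  pool_i <- 0L
  geomO <- geometry_from_list(preset$geometry)
  # a crossed axon must at least reach past the myoseptum
  min_crossed <- (geomO$hm_row - geomO$exit_row + 5) * geomO$pixel_size
  u <- matrix(u, nrow = n, byrow = TRUE)
  for (e in seq_len(n)) {
    lengths <- len[e, ]
    crossed <- rep(FALSE, 8L)
    if (ncross[e] > 0) crossed[sample.int(8L, ncross[e])] <- TRUE
    # crossed lengths are drawn from the same distribution conditioned on
    # reaching beyond the myoseptum (stalled lengths stay unconditional, so
    # the stalled mean calibrates to the preset mean)
    if (any(crossed)) {
      lengths[crossed] <- qtruncn(u[e, crossed], ax$mean_length_um,
                                  ax$sd_length_um, max(lower, min_crossed),
                                  ax$max_length_um)
    }

    abnormal <- rep(FALSE, 8L); mode <- rep(NA_character_, 8L)
    if (abn$rate > 0) {
      if (is.null(nabn)) {
        abnormal <- stats::runif(8L) < abn$rate
        if (any(abnormal)) mode[abnormal] <-
            sample(.ABN_MODES, sum(abnormal), replace = TRUE, prob = abn$modes)
      } else if (nabn[e] > 0) {
        idx <- sample.int(8L, nabn[e])
        abnormal[idx] <- TRUE
        mode[idx] <- mode_pool[pool_i + seq_len(nabn[e])]
        pool_i <- pool_i + nabn[e]
      }
    }

    present <- rep(TRUE, 8L)
    branches <- vector("list", 8L)
    phases <- stats::runif(8L, 0, 2 * pi)
    for (a in 1:8) {
      if (abnormal[a] && mode[a] == "missing") {
        present[a] <- FALSE; lengths[a] <- 0; crossed[a] <- FALSE
        next
      }
      if (abnormal[a] && mode[a] == "truncated") {
        lengths[a] <- stats::runif(1, abn$truncated_range_um[1],
                                   abn$truncated_range_um[2])
        crossed[a] <- FALSE
      }
      if (abnormal[a] && mode[a] == "ectopic") crossed[a] <- TRUE
      nb <- min(stats::rpois(1, ax$branch_rate), 3L)
      ext <- if (nb > 0) stats::runif(nb, ax$branch_extent_um[1],
                                      ax$branch_extent_um[2]) else numeric(0)
      if (abnormal[a] && mode[a] == "ectopic") {
        ext <- c(ext, stats::runif(1, abn$ectopic_extent_um[1],
                                   abn$ectopic_extent_um[2]))
      }
      nb <- length(ext)
      branches[[a]] <- if (nb > 0) data.frame(
        extent_um = ext,
        side = sample(c(-1L, 1L), nb, replace = TRUE),
        attach_frac = stats::runif(nb, 0.3, 0.7)) else
          data.frame(extent_um = numeric(0), side = integer(0),
                     attach_frac = numeric(0))
    }

    embryos[[e]] <- list(lengths = lengths, crossed = crossed,
                         abnormal = abnormal, mode = mode, present = present,
                         branches = branches, phases = phases,
                         puncta = .sample_puncta(pc, geom))
  }
  embryos
}

#' Sample punctum centres, sizes and amplitudes for every hemisegment
#' @noRd
.sample_puncta <- function(pc, geom) {
  ps <- geom$pixel_size
  side_px <- round(20 / ps)
  r0 <- geom$hm_row - floor(side_px / 2)
  out <- vector("list", pc$n_hemisegments)
  for (h in seq_len(pc$n_hemisegments)) {
    c0 <- geom$exit_cols[h] - floor(side_px / 2)
    ch <- list()
    for (comp in c("pre", "post")) {
      chpar <- pc[[comp]]
      k <- chpar$n
      anchors <- .PUNCTA_ANCHORS[[as.character(k)]]
      if (is.null(anchors)) stop("no punctum layout for n = ", k)
      jit <- matrix(stats::runif(2 * k, -0.5, 0.5), ncol = 2)
      cen <- (anchors + jit) / ps   # local px
      amp <- chpar$amplitude * pmin(pmax(1 + pc$amp_cv * stats::rnorm(k), 0.8), 1.2)
      if (comp == "post") {
        n_shared <- min(floor(pc$shared_frac * k), nrow(ch$pre))
        if (n_shared > 0) cen[seq_len(n_shared), ] <-
            cbind(ch$pre$row[seq_len(n_shared)] - r0,
                  ch$pre$col[seq_len(n_shared)] - c0)
      }
      ch[[comp]] <- data.frame(row = r0 + cen[, 1], col = c0 + cen[, 2],
                               sigma_um = chpar$sigma_um, amplitude = amp)
    }
    out[[h]] <- ch
  }
  out
}

#' Assemble an embryo_truth object (chains + per-axon table) from sampled draws
#' @noRd
.build_truth <- function(preset, draw, seed, toxicity) {
  geom <- geometry_from_list(preset$geometry)
  chains <- list()
  ax_rows <- vector("list", 8L)
  for (a in 1:8) {
    if (!draw$present[a]) {
      ax_rows[[a]] <- data.frame(
        axon_id = a, exit_col = geom$exit_cols[a], present = FALSE,
        crossed_hm = FALSE, abnormal = TRUE, mode = "missing",
        target_length_um = 0, true_length_um = 0, tip_row = NA_integer_,
        n_branches = 0L, n_branches_ge_8um = 0L)
      next
    }
    main <- .make_axon_chain(geom, geom$exit_cols[a], draw$lengths[a],
                             draw$crossed[a], draw$phases[a])
    chains[[length(chains) + 1L]] <- main$chain
    br <- draw$branches[[a]]
    for (b in seq_len(nrow(br))) {
      chains[[length(chains) + 1L]] <-
        .make_branch_chain(geom, main$chain, br$attach_frac[b], br$side[b],
                           br$extent_um[b])
    }
    ax_rows[[a]] <- data.frame(
      axon_id = a, exit_col = geom$exit_cols[a], present = TRUE,
      crossed_hm = draw$crossed[a],
      abnormal = isTRUE(draw$abnormal[a]),
      mode = if (draw$abnormal[a]) draw$mode[a] else NA_character_,
      target_length_um = draw$lengths[a],
      true_length_um = main$length_um,
      tip_row = main$tip[1],
      n_branches = nrow(br),
      n_branches_ge_8um = sum(br$extent_um >= 8))
  }
  axons <- do.call(rbind, ax_rows)
  rownames(axons) <- NULL
  branches <- do.call(rbind, lapply(1:8, function(a) {
    br <- draw$branches[[a]]
    if (is.null(br) || nrow(br) == 0) return(NULL)
    cbind(axon_id = a, br)
  }))
  structure(list(
    preset = preset$name, seed = seed, toxicity = toxicity,
    geometry = preset$geometry, axons = axons,
    branches = branches %||%
      data.frame(axon_id = integer(0), extent_um = numeric(0),
                 side = integer(0), attach_frac = numeric(0)),
    puncta = draw$puncta, chains = chains,
    params = preset
  ), class = "embryo_truth")
}

#' @export
print.embryo_truth <- function(x, ...) {
  cat("embryo_truth (preset ", x$preset, ", seed ", x$seed, ")\n", sep = "")
  cat("  toxicity:", x$toxicity, "| axons present:", sum(x$axons$present),
      "| crossed HM:", sum(x$axons$crossed_hm),
      "| abnormal:", sum(x$axons$abnormal), "\n")
  invisible(x)
}

#' Generate one synthetic embryo
#'
#' Draws axon lengths, myoseptum-crossing status, branches, abnormality modes
#' and synaptic puncta from the named preset, then renders the three-channel
#' lateral-view image. The same `(preset, seed)` pair always yields the
#' identical image and ground truth.
#'
#' @param preset Preset name (see [list_presets()]).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param render If `FALSE`, skip image rendering (`image` is `NULL`).
#' @param snr Signal-to-noise override (`Inf` = noise-free rendering).
#' @param toxicity One of `"none"`, `"death"`, `"delayed"`, `"malformed"`.
#' @return A list with elements `image` (array or `NULL`) and `truth`
#'   (an `embryo_truth` with the per-axon table, branch table, puncta fields
#'   and geometry).
#' @examples
#' e <- generate_embryo("chodl-DMSO", seed = 1, render = FALSE)
#' e$truth$axons[, c("axon_id", "crossed_hm", "true_length_um")]
#' @export
generate_embryo <- function(preset, seed, render = TRUE, snr = NULL,
                            toxicity = c("none", "death", "delayed", "malformed")) {
  toxicity <- match.arg(toxicity)
  p <- get_preset(preset)
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is required")
  set.seed(as.integer(seed))
  draw <- .sample_cohort_params(p, 1L, stratified = FALSE)[[1]]
  truth <- .build_truth(p, draw, as.integer(seed), toxicity)
  img <- if (render && toxicity != "delayed") render_embryo(truth, snr = snr) else NULL
  list(image = img, truth = truth)
}

#' Simulate a cohort of embryos under one condition
#'
#' Generates `n` embryos from a preset using a single random stream. With
#' `stratified = TRUE` (the default) the per-axon length quantiles and the
#' crossing/abnormality counts are allocated systematically across the cohort,
#' so the realized cohort means track the preset's nominal values closely;
#' with `stratified = FALSE` every embryo is an independent draw (this is what
#' [generate_embryo()] does).
#'
#' @param preset Preset name.
#' @param n Number of embryos.
#' @param seed Integer seed.
#' @inheritParams generate_embryo
#' @param stratified Use systematic (variance-controlled) sampling.
#' @return List of `n` elements as returned by [generate_embryo()].
#' @export
simulate_cohort <- function(preset, n, seed, render = TRUE, stratified = TRUE,
                            snr = NULL) {
  p <- get_preset(preset)
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  draws <- .sample_cohort_params(p, as.integer(n), stratified = stratified)
  lapply(seq_len(n), function(e) {
    truth <- .build_truth(p, draws[[e]], as.integer(seed), "none")
    truth$embryo_index <- e
    img <- if (render) render_embryo(truth, snr = snr) else NULL
    list(image = img, truth = truth)
  })
}

#' Write an embryo to disk: multi-channel TIFF plus JSON ground-truth sidecar
#'
#' @param embryo A list from [generate_embryo()] (must contain an image).
#' @param dir Output directory (created if needed).
#' @param id Embryo identifier used in file names.
#' @return Invisibly, the two file paths written.
#' @export
write_embryo <- function(embryo, dir, id = "embryo001") {
  if (is.null(embryo$image)) stop("embryo has no rendered image")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(id, ".tif"))
  js <- file.path(dir, paste0(id, "_truth.json"))
  tiff::writeTIFF(embryo$image, tif, bits.per.sample = 32L)
  write_ground_truth(embryo$truth, js)
  invisible(c(image = tif, truth = js))
}

#' Serialize ground truth to JSON (pixel chains are derived data and omitted;
#' they regenerate from the recorded preset and seed)
#' @export
#' @rdname write_embryo
#' @param truth,path Ground truth object and JSON path.
write_ground_truth <- function(truth, path) {
  x <- unclass(truth)
  x$chains <- NULL
  x$params <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#' @param path JSON path.
#' @return A list mirroring the serialized `embryo_truth` fields.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a multi-channel embryo TIFF as a rows x cols x 3 array
#' @param path TIFF path.
#' @export
read_embryo_image <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  img
}
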