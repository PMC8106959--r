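# Plate-structured screen simulation and first-stage analysis. A screen is
# laid out on 96-well plates (three embryos per well, six embryos per
# compound); the DMSO internal control occupies the first two wells, four
# wells in the middle of the plate and the last two wells, so control drift
# over the imaging session can be checked.

#' Describe a simulated compound screen
#'
#' @param n_compounds Number of compounds (>= 1).
#' @param embryos_per_compound Embryos per compound (default 6).
#' @param n_active Number of true actives.
#' @param active_ri Nominal rescue index of the actives (crossing probability
#'   = control probability x `active_ri`, capped at 1).
#' @param n_toxic Named integer vector `c(death=, delayed=, malformed=)`.
#' @param control_preset Preset supplying the internal-control crossing
#'   probability and (in rendered mode) control images.
#' @param concentration_uM Screening concentration recorded in the manifest.
#' @param seed Integer seed used to place actives/toxics among the compounds.
#' @return A `screen_design` with a `compounds` truth table.
#' @export
screen_design <- function(n_compounds, embryos_per_compound = 6,
                          n_active = 0, active_ri = 3.5,
                          n_toxic = c(death = 0, delayed = 0, malformed = 0),
                          control_preset = "chodl-DMSO",
                          concentration_uM = 10, seed = 1) {
  if (n_compounds < 1) stop("n_compounds must be >= 1")
  if (embryos_per_compound < 1) stop("embryos_per_compound must be >= 1")
  n_toxic <- n_toxic[c("death", "delayed", "malformed")]
  n_toxic[is.na(n_toxic)] <- 0
  if (n_active + sum(n_toxic) > n_compounds) {
    stop("more active/toxic compounds than compounds")
  }
  get_preset(control_preset) # validate name early
  set.seed(child_seed(seed, 0))
  ids <- sprintf("C%04d", seq_len(n_compounds))
  class_v <- rep("inactive", n_compounds)
  special <- sample.int(n_compounds, n_active + sum(n_toxic))
  if (n_active > 0) class_v[special[seq_len(n_active)]] <- "active"
  tox_v <- rep("none", n_compounds)
  off <- n_active
  for (ct in names(n_toxic)) {
    kt <- n_toxic[[ct]]
    if (kt > 0) {
      idx <- special[off + seq_len(kt)]
      class_v[idx] <- "toxic"
      tox_v[idx] <- ct
      off <- off + kt
    }
  }
  structure(list(
    n_compounds = as.integer(n_compounds),
    embryos_per_compound = as.integer(embryos_per_compound),
    axons_per_embryo = 8L,
    active_ri = active_ri,
    control_preset = control_preset,
    concentration_uM = concentration_uM,
    seed = as.integer(seed),
    compounds = data.frame(compound_id = ids, class = class_v,
                           true_ri = ifelse(class_v == "active", active_ri,
                                            ifelse(class_v == "toxic", NA, 1)),
                           toxicity = tox_v)
  ), class = "screen_design")
}

#' @noRd
.well_label <- function(i) {
  paste0(LETTERS[ceiling(i / 12)], ((i - 1) %% 12) + 1)
}

#' Simulate a plate-structured screen
#'
#' In score-only mode (the default) no images are rendered: each embryo's
#' per-axon myoseptum-crossing truth is drawn directly (binomial over the
#' 8 scoreable axons), which makes screens of hundreds of compounds fast to
#' simulate. Toxic compounds' embryos are flagged by their toxicity class and
#' never enter the scoreable set.
#'
#' @param design A [screen_design()].
#' @param score_only Skip image rendering (default `TRUE`).
#' @param dir If given (rendered mode), write per-embryo TIFF + truth files.
#' @return A `cap_screen` list: `design`, `records` (one row per embryo,
#'   compound and control), `manifest`.
#' @export
generate_screen <- function(design, score_only = TRUE, dir = NULL) {
  stopifnot(inherits(design, "screen_design"))
  set.seed(child_seed(design$seed, 1))
  ctrl <- get_preset(design$control_preset)
  p_ctrl <- ctrl$axon$p_crossed
  epc <- design$embryos_per_compound
  wells_per_compound <- ceiling(epc / 3)
  n_ctrl_wells <- 8L
  cpp <- max(1L, (96L - n_ctrl_wells) %/% wells_per_compound)
  n_plates <- ceiling(design$n_compounds / cpp)

  recs <- list()
  eid <- 0L
  for (pl in seq_len(n_plates)) {
    comp_idx <- ((pl - 1) * cpp + 1):min(pl * cpp, design$n_compounds)
    ctrl_wells <- sort(c(1L, 2L, sample(37:60, 4), 95L, 96L))
    free_wells <- setdiff(seq_len(96L), ctrl_wells)
    add <- function(compound_id, role, toxicity, wells, n_embryos, p) {
      per_well <- rep(wells, each = 3)[seq_len(n_embryos)]
      for (j in seq_len(n_embryos)) {
        eid <<- eid + 1L
        scoreable <- toxicity == "none"
        recs[[eid]] <<- data.frame(
          embryo_id = sprintf("E%05d", eid), plate = pl,
          well = .well_label(per_well[j]), compound_id = compound_id,
          role = role, concentration_uM = design$concentration_uM,
          orientation = "lateral",
          acquisition_time = sprintf("00:%02d:%02d",
                                     (eid * 7) %/% 60 %% 60, (eid * 7) %% 60),
          toxicity = toxicity,
          n_scored = if (scoreable) 8L else 0L,
          n_crossed = if (scoreable) stats::rbinom(1, 8L, p) else NA_integer_)
      }
    }
    add("DMSO-control", "control", "none", ctrl_wells, n_ctrl_wells * 3L, p_ctrl)
    for (ci in seq_along(comp_idx)) {
      cmp <- design$compounds[comp_idx[ci], ]
      wells <- free_wells[((ci - 1) * wells_per_compound + 1):
                            (ci * wells_per_compound)]
      p <- if (cmp$class == "active") min(1, p_ctrl * cmp$true_ri) else p_ctrl
      add(cmp$compound_id, "compound", cmp$toxicity, wells, epc, p)
    }
  }
  records <- do.call(rbind, recs)

  if (!score_only) {
    dir.create(dir %||% stop("dir required when rendering"), showWarnings = FALSE,
               recursive = TRUE)
    for (i in seq_len(nrow(records))) {
      e <- generate_embryo(design$control_preset,
                           seed = child_seed(design$seed, 100 + i),
                           toxicity = records$toxicity[i])
      if (!is.null(e$image)) write_embryo(e, dir, records$embryo_id[i])
    }
  }

  manifest <- records[, c("embryo_id", "well", "compound_id",
                          "concentration_uM", "orientation",
                          "acquisition_time")]
  structure(list(design = design, records = records, manifest = manifest),
            class = "cap_screen")
}

#' @export
print.cap_screen <- function(x, ...) {
  cat("cap_screen:", x$design$n_compounds, "compounds,",
      sum(x$records$role == "compound"), "compound embryos,",
      sum(x$records$role == "control"), "control embryos\n")
  invisible(x)
}

#' First-stage screen analysis: rescue index and hit calling per compound
#'
#' Pools each plate's internal-control wells into one control group, computes
#' every compound's rescue index against its own plate's control, excludes
#' toxic compounds, and calls hits at the threshold. A non-blocking control
#' drift check (first wells vs last wells, Mann-Whitney) is reported per
#' plate.
#'
#' @param screen A `cap_screen` from [generate_screen()], or any data.frame
#'   shaped like its `records`.
#' @param threshold Hit threshold on the rescue index (default 2.5).
#' @param method Rescue-index aggregation, see [rescue_index()].
#' @return A `screen_result`: `compounds` (rescue_index, excluded_reason,
#'   hit), `toxicity` summary, `drift` table, `threshold`.
#' @export
analyse_screen <- function(screen, threshold = 2.5,
                           method = c("pooled", "per_embryo")) {
  method <- match.arg(method)
  records <- if (inherits(screen, "cap_screen")) screen$records else screen
  stopifnot(all(c("compound_id", "role", "toxicity", "n_scored", "n_crossed")
                %in% names(records)))
  if (!"plate" %in% names(records)) records$plate <- 1L

  tox <- exclude_toxic(records[records$role == "compound", ])

  out <- list(); drift <- list()
  for (pl in unique(records$plate)) {
    rp <- records[records$plate == pl, ]
    ctrl <- rp[rp$role == "control", ]
    if (!nrow(ctrl)) stop("plate ", pl, " has no internal control wells")
    # drift: first-position vs last-position control wells (non-blocking)
    cw <- sort(unique(ctrl$well))
    frac <- ctrl$n_crossed / ctrl$n_scored
    first <- frac[ctrl$well %in% utils::head(cw, 2)]
    last <- frac[ctrl$well %in% utils::tail(cw, 2)]
    dp <- if (length(first) >= 2 && length(last) >= 2) {
      suppressWarnings(stats::wilcox.test(first, last, exact = FALSE)$p.value)
    } else NA_real_
    drift[[length(drift) + 1]] <- data.frame(plate = pl, drift_p = dp)

    for (cid in unique(rp$compound_id[rp$role == "compound"])) {
      rc <- rp[rp$compound_id == cid, ]
      toxic <- any(rc$toxicity != "none")
      ri <- if (toxic) NA_real_ else
        rescue_index(rc[, c("n_scored", "n_crossed")],
                     ctrl[, c("n_scored", "n_crossed")], method = method)
      out[[length(out) + 1]] <- data.frame(
        compound_id = cid, plate = pl, n_embryos = nrow(rc),
        rescue_index = as.numeric(ri),
        excluded_reason = if (toxic) rc$toxicity[rc$toxicity != "none"][1]
        else NA_character_)
    }
  }
  compounds <- call_hits(do.call(rbind, out), threshold = threshold)
  structure(list(compounds = compounds, toxicity = tox$summary,
                 drift = do.call(rbind, drift), threshold = threshold),
            class = "screen_result")
}

#' Summarise a screen: toxicity breakdown and hit-rate arithmetic
#'
#' @param result A `screen_result` from [analyse_screen()], or a list with
#'   elements `n_compounds`, `n_hits` (and optionally `n_stage2`,
#'   `toxicity`).
#' @param n_stage2 Number of compounds confirmed in the second stage
#'   (significant axon-length increase), if available.
#' @return A `screen_report` list with `n_compounds`, `n_hits`,
#'   `hit_rate_pct` (first stage), `stage2_rate_pct` (if applicable),
#'   `toxicity` and a preformatted `summary_text`.
#' @export
screen_report <- function(result, n_stage2 = NA) {
  if (inherits(result, "screen_result")) {
    n_comp <- nrow(result$compounds)
    n_hits <- sum(result$compounds$hit)
    tox <- result$toxicity
  } else {
    n_comp <- result$n_compounds
    n_hits <- result$n_hits
    tox <- result$toxicity %||% NULL
    if (is.na(n_stage2) && !is.null(result$n_stage2)) n_stage2 <- result$n_stage2
  }
  hit_rate <- round(100 * n_hits / n_comp, 2)
  stage2_rate <- if (!is.na(n_stage2)) round(100 * n_stage2 / n_comp, 2) else NA
  txt <- c(
    sprintf("Compounds screened: %d", n_comp),
    if (!is.null(tox)) sprintf(
      "Toxic (excluded): %d (%.1f%%)",
      tox$n_compounds[tox$category == "total_excluded"],
      tox$percent[tox$category == "total_excluded"]),
    sprintf("First-stage hits: %d (hit rate %.2f%%)", n_hits, hit_rate),
    if (!is.na(n_stage2)) sprintf(
      "Second-stage confirmed: %d (hit rate %.2f%%)", n_stage2, stage2_rate))
  structure(list(n_compounds = n_comp, n_hits = n_hits,
                 hit_rate_pct = hit_rate, n_stage2 = n_stage2,
                 stage2_rate_pct = stage2_rate, toxicity = tox,
                 summary_text = txt),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(x$summary_text, sep = "\n")
  invisible(x)
}
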