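# Preset registry: each preset encodes one experimental condition of the
# chodl / UBA1 screening study as generator parameters. Reported group means
# (lengths, effect ratios, abnormality increases) are taken from the study's
# published figures and results; spreads are artifact choices (means +- s.e.m.
# were reported, not SDs) and default to 20% of the mean.

# Reported calibration constants (see the methods vignette for provenance):
.CHODL_MEAN_LENGTH_UM <- 35.06   # mean CaP axon length, chodl-mutant DMSO controls
.WT_MEAN_LENGTH_UM    <- 56.0    # wild-type mean length; not reported, artifact choice
.P_CROSSED_CONTROL    <- 2 / 8   # "one or two" of 8 axons beyond the HM in controls
.PRESYN_AREA_RATIO    <- 1.58    # chodl presynaptic puncta area vs wild type (+58%)
.PRESYN_INT_RATIO     <- 1.83    # chodl presynaptic labelling intensity (+83%)
.POSTSYN_COUNT_RATIO  <- 0.63    # chodl postsynaptic puncta count (-37%)
.UBA1_ABN_MULT        <- 2.17    # UBEI-41 abnormal-axon increase (+117%)
.UBA1_DIP_MULT        <- 0.69    # dipyridamole decrease on UBEI-41 (-31%)
.WT_ABN_RATE          <- 0.12    # baseline abnormal fraction in DMSO wild type (artifact)

# Percent-of-control length ratios for validated hits at screening concentration.
.LENGTH_RATIOS <- c(
  "dipyridamole-10uM" = 1.35, "dipyridamole-30uM" = 1.33,
  "iox1-10uM" = 1.39, "iox1-50uM" = 1.58,
  "mg132-10uM" = 1.18
)

.base_axon <- function(mean_um, p_crossed, sd_frac = 0.2, min_um = 10,
                       branch_rate = 1, branch_extent_um = c(2, 5.5)) {
  list(mean_length_um = mean_um,
       sd_length_um = sd_frac * mean_um,
       min_length_um = min_um,
       max_length_um = 95,
       p_crossed = p_crossed,
       branch_rate = branch_rate,
       branch_extent_um = branch_extent_um,
       amplitude = 0.8,
       width_px = 3)
}

.base_abnormal <- function(rate = 0) {
  list(rate = rate,
       modes = c(missing = 0.2, truncated = 0.5, ectopic = 0.3),
       truncated_range_um = c(14, 30),
       ectopic_extent_um = c(11, 16),
       min_healthy_length_um = 42)
}

# Puncta anchor layouts (local ROI coordinates, 20x20 um ROI) chosen so that
# thresholded spots stay separated; centers get +-0.5 px uniform jitter.
.PUNCTA_ANCHORS <- list(
  `1` = cbind(10.5, 10.5),
  `2` = cbind(c(7, 14), c(13, 7)),
  `3` = cbind(c(7, 14, 9), c(7, 8, 14)),
  `4` = cbind(c(7, 7, 13.5, 13.5), c(7, 13.5, 7, 13.5)),
  `5` = cbind(c(6.5, 6.5, 14, 14, 10.3), c(6.5, 14, 6.5, 14, 10.3))
)

.base_puncta <- function(pre_n = 4, pre_sigma = 1.1, pre_amp = 0.35,
                         post_n = 4, post_sigma = 1.1, post_amp = 0.30) {
  list(pre = list(n = pre_n, sigma_um = pre_sigma, amplitude = pre_amp),
       post = list(n = post_n, sigma_um = post_sigma, amplitude = post_amp),
       amp_cv = 0.05,      # relative punctum-to-punctum amplitude jitter
       shared_frac = 0.75, # fraction of post puncta co-centred with pre puncta
       n_hemisegments = 5) # hemisegments that receive rendered puncta
}

.make_preset <- function(name, description, axon, abnormal, puncta,
                         notes = character()) {
  list(name = name, description = description,
       geometry = geometry_to_list(embryo_geometry()),
       axon = axon, abnormal = abnormal, puncta = puncta,
       snr = 10, background = 0.05, notes = notes)
}

.build_registry <- function() {
  reg <- list()

  reg[["wild-type-DMSO"]] <- .make_preset(
    "wild-type-DMSO",
    "Wild-type embryo, DMSO vehicle: all 8 CaP axons grown beyond the HM.",
    axon = .base_axon(.WT_MEAN_LENGTH_UM, p_crossed = 1),
    abnormal = .base_abnormal(.WT_ABN_RATE),
    puncta = .base_puncta(),
    notes = c(
      p_crossed = "control embryos typically have all axons beyond the HM",
      abnormal_rate = "baseline abnormal fraction in vehicle controls; artifact choice",
      mean_length = "wild-type mean length not reported; artifact choice"))

  # sigma encodes the TOTAL-area effect. Under a percent-of-maximum threshold
  # at fraction f, the measured area of a Gaussian punctum is
  # pi * (2 ln(1/f) sigma^2 + 1/6): the 1/6 px^2 term is the subpixel
  # peak-sampling correction (the brightest pixel sits E[d^2] = 1/6 px^2 off
  # the true maximum). Preset sigmas invert this response so the realized
  # total-area ratio equals the nominal one at the default f = 0.30.
  area_resp <- function(sigma) 2 * log(1 / 0.30) * sigma^2 + 1 / 6
  sigma_for <- function(total_ratio, n_wt, n_mut, sigma_wt = 1.1) {
    sqrt((total_ratio * n_wt / n_mut * area_resp(sigma_wt) - 1 / 6) /
           (2 * log(1 / 0.30)))
  }
  chodl_puncta <- .base_puncta(
    pre_n = 3,
    pre_sigma = sigma_for(.PRESYN_AREA_RATIO, 4, 3),
    pre_amp = 0.35 * .PRESYN_INT_RATIO,
    post_n = round(4 * .POSTSYN_COUNT_RATIO),
    post_sigma = sigma_for(1, 4, 3),  # postsynaptic total area unchanged
    post_amp = 0.30)

  reg[["chodl-DMSO"]] <- .make_preset(
    "chodl-DMSO",
    "chodl-/- mutant, DMSO vehicle: the screen's internal control.",
    axon = .base_axon(.CHODL_MEAN_LENGTH_UM, p_crossed = .P_CROSSED_CONTROL,
                      branch_rate = 0.2),
    abnormal = .base_abnormal(0),
    puncta = chodl_puncta,
    notes = c(
      mean_length = "reported mean CaP axon length in chodl-mutant DMSO controls (35.06 um)",
      p_crossed = "one or two of eight axons beyond the HM in internal controls",
      presyn_area = "presynaptic puncta area enlarged 58% vs wild type",
      presyn_intensity = "presynaptic labelling intensity increased 83% vs wild type",
      postsyn_count = "postsynaptic puncta count reduced 37% vs wild type"))

  # Validated hits on the chodl background: length scaled by the reported
  # percent-of-control ratio; crossing probability scaled by the nominal
  # rescue index (capped at 1). Presynaptic rescue pattern per condition.
  hit_ri <- c("dipyridamole-10uM" = 2.5, "dipyridamole-30uM" = 2.5,
              "iox1-10uM" = 2.5, "iox1-50uM" = 3.0, "mg132-10uM" = 2.2)
  for (nm in names(.LENGTH_RATIOS)) {
    p <- reg[["chodl-DMSO"]]
    p$name <- nm
    p$description <- paste0("chodl-/- mutant treated with ", sub("-", " ", nm),
                            " (validated hit).")
    p$axon$mean_length_um <- .CHODL_MEAN_LENGTH_UM * .LENGTH_RATIOS[[nm]]
    p$axon$sd_length_um <- 0.2 * p$axon$mean_length_um
    p$axon$p_crossed <- min(1, .P_CROSSED_CONTROL * hit_ri[[nm]])
    p$notes <- c(
      mean_length = sprintf(
        "percent-of-control axon length %d%% applied to the chodl control mean",
        round(100 * .LENGTH_RATIOS[[nm]])),
      p_crossed = "crossing probability = control probability x nominal rescue index")
    if (startsWith(nm, "dipyridamole")) {
      # presynaptic total area rescued; puncta count and intensity not rescued
      p$puncta$pre$sigma_um <- sigma_for(1, 4, 3)
      p$notes <- c(p$notes, presyn = "presynaptic area rescued; count and intensity not")
    }
    if (startsWith(nm, "iox1")) {
      # full presynaptic rescue
      p$puncta$pre <- .base_puncta()$pre
      p$notes <- c(p$notes, presyn = "presynaptic area, count and intensity rescued")
    }
    reg[[nm]] <- p
  }

  uba1 <- .make_preset(
    "uba1",
    "Wild-type embryo treated with the UBA1 inhibitor UBEI-41 (SMA model).",
    axon = .base_axon(.WT_MEAN_LENGTH_UM, p_crossed = 1),
    abnormal = .base_abnormal(.WT_ABN_RATE * .UBA1_ABN_MULT),
    puncta = .base_puncta(),
    notes = c(abnormal_rate =
      "117% increase in abnormal axons over vehicle controls"))
  reg[["uba1"]] <- uba1

  uba1_dip <- uba1
  uba1_dip$name <- "uba1+dipyridamole"
  uba1_dip$description <-
    "UBEI-41 plus 10 uM dipyridamole: partial rescue of abnormal axons."
  uba1_dip$abnormal$rate <- uba1$abnormal$rate * .UBA1_DIP_MULT
  uba1_dip$notes <- c(abnormal_rate =
    "31% decrease in abnormal axons relative to UBEI-41 alone")
  reg[["uba1+dipyridamole"]] <- uba1_dip

  uba1_qc <- uba1
  uba1_qc$name <- "uba1+quercetin"
  uba1_qc$description <-
    "UBEI-41 plus 50 uM quercetin: rescue to near-control levels (positive control)."
  uba1_qc$abnormal$rate <- 0.13
  uba1_qc$notes <- c(abnormal_rate =
    "rescued to levels not significantly different from controls; artifact choice")
  reg[["uba1+quercetin"]] <- uba1_qc

  reg
}

.PRESETS <- .build_registry()

#' List registered synthetic-embryo presets
#'
#' Each preset encodes one experimental condition (genotype x treatment) as
#' generator parameters: axon length distribution, myoseptum-crossing
#' probability, branch statistics, abnormality rates and synaptic puncta
#' fields. The `notes` element of every preset records, in plain words, which
#' reported group statistic each calibrated parameter encodes; spreads are
#' artifact choices.
#'
#' @return A data.frame with columns `name`, `mean_length_um`, `p_crossed`,
#'   `abnormal_rate` and `description`.
#' @examples
#' list_presets()
#' @export
list_presets <- function() {
  data.frame(
    name = vapply(.PRESETS, `[[`, "", "name"),
    mean_length_um = vapply(.PRESETS, function(p) p$axon$mean_length_um, 0),
    p_crossed = vapply(.PRESETS, function(p) p$axon$p_crossed, 0),
    abnormal_rate = vapply(.PRESETS, function(p) p$abnormal$rate, 0),
    description = vapply(.PRESETS, `[[`, "", "description"),
    row.names = NULL
  )
}

#' Fetch a preset by name
#'
#' @param name Preset name, one of `list_presets()$name`.
#' @return The preset parameter list.
#' @export
get_preset <- function(name) {
  if (!is.character(name) || length(name) != 1 || !name %in% names(.PRESETS)) {
    stop("unknown preset ", deparse(name), "; available presets: ",
         paste(names(.PRESETS), collapse = ", "))
  }
  .PRESETS[[name]]
}
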