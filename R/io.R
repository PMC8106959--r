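# Formats, configuration and the pipeline driver: plate-manifest CSVs in the
# imager's output dialect, a declarative YAML run configuration, and the
# end-to-end screen pipeline with reproducible, config-hashed reports.

.MANIFEST_COLS <- c("embryo_id", "well", "compound_id", "concentration_uM",
                    "orientation", "acquisition_time")

#' @noRd
.valid_wells <- function(format = c("96", "24")) {
  format <- match.arg(format)
  if (format == "96") {
    as.vector(outer(LETTERS[1:8], 1:12, paste0))
  } else {
    as.vector(outer(LETTERS[1:4], 1:6, paste0))
  }
}

#' Read and validate a plate manifest CSV
#'
#' The manifest mirrors the imaging platform's output tables: one row per
#' embryo with well location, compound, concentration, orientation and
#' acquisition time. Malformed rows are reported with their line numbers.
#'
#' @param path CSV path.
#' @param plate_format `"96"` (default) or `"24"` well-label dialect
#'   (letters are rows, numbers are columns, 1-based).
#' @return The validated manifest data.frame.
#' @export
read_manifest <- function(path, plate_format = c("96", "24")) {
  plate_format <- match.arg(plate_format)
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.MANIFEST_COLS, names(m))
  if (length(missing)) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- duplicated(m$embryo_id)
  if (any(dup)) {
    stop("duplicate embryo_id at line(s) ",
         paste(which(dup) + 1L, collapse = ", "))
  }
  badwell <- !m$well %in% .valid_wells(plate_format)
  if (any(badwell)) {
    stop("invalid well label for ", plate_format, "-well plate at line(s) ",
         paste(which(badwell) + 1L, collapse = ", "))
  }
  max_rows <- if (plate_format == "96") 96L * 3L else 24L * 6L
  if (length(unique(m$plate %||% 1L)) == 1L && nrow(m) > max_rows) {
    stop("manifest has ", nrow(m), " rows, more than one ", plate_format,
         "-well plate can hold (", max_rows, ")")
  }
  m
}

#' Write a plate manifest CSV
#' @param manifest Manifest data.frame.
#' @param path Output path.
#' @export
#' @rdname read_manifest
write_manifest <- function(manifest, path) {
  stopifnot(all(.MANIFEST_COLS %in% names(manifest)))
  utils::write.csv(manifest, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Construct a validated run configuration
#'
#' Collects every tunable of the pipeline in one declarative object:
#' geometry scale, scoring thresholds, screen design and seed. All outputs of
#' [run_pipeline()] are reproducible from the configuration alone.
#'
#' @param seed Integer seed for every stochastic stage.
#' @param pixel_size um per pixel.
#' @param hm_margin_um Myoseptum-crossing margin ([classify_hm()]).
#' @param binarize_fraction Puncta threshold fraction ([binarize()]).
#' @param min_punctum_px Minimal punctum size ([quantify_puncta()]).
#' @param ri_threshold Hit threshold ([call_hits()]).
#' @param alpha Significance level for group statistics.
#' @param n_compounds,embryos_per_compound,n_active,active_ri,n_toxic Screen
#'   design parameters ([screen_design()]).
#' @param control_preset Internal-control preset name.
#' @param score_only Simulate scores only (no images).
#' @param outdir Output directory for reports.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, pixel_size = 1, hm_margin_um = 2,
                       binarize_fraction = 0.30, min_punctum_px = 2,
                       ri_threshold = 2.5, alpha = 0.05,
                       n_compounds = 20, embryos_per_compound = 6,
                       n_active = 2, active_ri = 3.5,
                       n_toxic = c(death = 0, delayed = 0, malformed = 0),
                       control_preset = "chodl-DMSO", score_only = TRUE,
                       outdir = tempfile("capscreen_run")) {
  stopifnot(pixel_size > 0, hm_margin_um >= 0,
            binarize_fraction > 0, binarize_fraction < 1,
            min_punctum_px >= 1, ri_threshold > 0,
            alpha > 0, alpha < 1, n_compounds >= 1)
  structure(list(seed = as.integer(seed), pixel_size = pixel_size,
                 hm_margin_um = hm_margin_um,
                 binarize_fraction = binarize_fraction,
                 min_punctum_px = as.integer(min_punctum_px),
                 ri_threshold = ri_threshold, alpha = alpha,
                 n_compounds = as.integer(n_compounds),
                 embryos_per_compound = as.integer(embryos_per_compound),
                 n_active = as.integer(n_active), active_ri = active_ri,
                 n_toxic = as.list(n_toxic),
                 control_preset = control_preset,
                 score_only = isTRUE(score_only), outdir = outdir),
            class = "run_config")
}

#' Write / read a run configuration as YAML (lossless round trip)
#' @param config A `run_config`.
#' @param path YAML path.
#' @export
#' @rdname run_config
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
#' @rdname run_config
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, c(x[setdiff(names(x), "n_toxic")],
                        list(n_toxic = unlist(x$n_toxic))))
}

#' FNV-1a hash of an R object's serialized bytes (config fingerprinting)
#' @noRd
.object_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (v in b) {
    h <- bitwXor(as.integer(h %% 2^31), v)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the two-step screening pipeline from a configuration
#'
#' Simulates the plate-structured screen, computes per-compound rescue
#' indices, excludes toxic compounds, calls hits, and writes the report
#' bundle (screen results CSV, plate manifest CSV, JSON summary embedding the
#' configuration hash and seed). Identical configurations produce
#' byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `screen`, `result`, `report` and `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  design <- screen_design(
    n_compounds = config$n_compounds,
    embryos_per_compound = config$embryos_per_compound,
    n_active = config$n_active, active_ri = config$active_ri,
    n_toxic = unlist(config$n_toxic),
    control_preset = config$control_preset, seed = config$seed)
  screen <- generate_screen(design, score_only = config$score_only,
                            dir = if (config$score_only) NULL else
                              file.path(config$outdir, "images"))
  result <- analyse_screen(screen, threshold = config$ri_threshold)
  report <- screen_report(result)

  f_res <- file.path(config$outdir, "screen_results.csv")
  f_man <- file.path(config$outdir, "manifest.csv")
  f_sum <- file.path(config$outdir, "summary.json")
  utils::write.csv(result$compounds, f_res, row.names = FALSE)
  write_manifest(screen$manifest, f_man)
  jsonlite::write_json(list(
    config_hash = .object_hash(unclass(config)),
    seed = config$seed,
    n_compounds = report$n_compounds,
    n_hits = report$n_hits,
    hit_rate_pct = report$hit_rate_pct,
    toxicity = result$toxicity,
    threshold = config$ri_threshold
  ), f_sum, auto_unbox = TRUE, digits = NA)

  invisible(list(screen = screen, result = result, report = report,
                 files = c(results = f_res, manifest = f_man, summary = f_sum)))
}
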