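#' Pipeline configuration
#'
#' Validated settings for [run_pipeline()]. Unknown keys are rejected,
#' numeric parameters are range-checked.
#'
#' @param input_dir Directory holding `counts.csv` and optionally
#'   `dilution.csv`, `leucine.csv`, `bands.csv`.
#' @param out_dir Output directory.
#' @param burst_size Burst size for lysis conversion (default 27).
#' @param stimulation_mode "relative" (default) or "absolute".
#' @param vp_correction Host-dilution correction: "b_over_B" (default)
#'   or "B_over_b".
#' @param band_tolerance Band-matching tolerance in pixels (default 5).
#' @param detection_floor Relative-intensity presence floor (default 0).
#' @param alpha Significance threshold (default 0.05).
#' @param seed Optional integer seed recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir, burst_size = 27,
                            stimulation_mode = "relative",
                            vp_correction = "b_over_B",
                            band_tolerance = 5, detection_floor = 0,
                            alpha = 0.05, seed = NULL) {
  stopifnot(burst_size > 0, band_tolerance > 0,
            detection_floor >= 0, detection_floor < 1,
            alpha > 0, alpha < 1)
  stimulation_mode <- match.arg(stimulation_mode, c("relative", "absolute"))
  vp_correction <- match.arg(vp_correction, c("b_over_B", "B_over_b"))
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 burst_size = burst_size,
                 stimulation_mode = stimulation_mode,
                 vp_correction = vp_correction,
                 band_tolerance = band_tolerance,
                 detection_floor = detection_floor,
                 alpha = alpha, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Run the full microcosm analysis pipeline
#'
#' Reads a bundle directory and executes every stage in order: growth
#' and loss kinetics, viral production and lysis mortality, bacterial
#' production, stimulation statistics, and (when a band file is
#' present) the DGGE fingerprint analysis. Writes `rates.csv`,
#' `lysis.csv`, `bp.csv`, `stimulation.csv`, `commonality.csv`,
#' `similarity.csv`, `tree.nwk` and a `manifest.yaml` recording the
#' configuration and package version. Deterministic: identical inputs
#' and configuration give byte-identical outputs.
#'
#' @param config A `pipeline_config` (or path handled by
#'   [read_config()]).
#' @return Invisibly, a list of the computed tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[microloop] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  bundle <- stage("read", read_bundle(config$input_dir))
  out <- list()

  log_msg("kinetics: growth and loss rates")
  out$rates <- stage("kinetics", rate_table(bundle$counts))
  utils::write.csv(out$rates, file.path(config$out_dir, "rates.csv"),
                   row.names = FALSE)

  if (length(bundle$dilution_assays)) {
    log_msg("viral activity: %d dilution assays", length(bundle$dilution_assays))
    out$lysis <- stage("viral_activity",
      viral_activity_table(bundle$dilution_assays,
                           burst_size = config$burst_size,
                           correction = config$vp_correction))
    utils::write.csv(out$lysis, file.path(config$out_dir, "lysis.csv"),
                     row.names = FALSE)
  } else log_msg("viral activity skipped: no dilution assays")

  if (!is.null(bundle$leucine)) {
    log_msg("bacterial production from leucine incorporation")
    out$bp <- stage("bacterial_production",
                    bacterial_production_table(bundle$leucine))
    utils::write.csv(out$bp, file.path(config$out_dir, "bp.csv"),
                     row.names = FALSE)
  } else log_msg("bacterial production skipped: no leucine file")

  log_msg("stimulation statistics")
  out$stimulation <- stage("stimulation",
    stimulation_table(bundle$counts, mode = config$stimulation_mode))
  utils::write.csv(out$stimulation,
                   file.path(config$out_dir, "stimulation.csv"),
                   row.names = FALSE)

  if (!is.null(bundle$bands)) {
    log_msg("fingerprint: band matching and clustering")
    bm <- stage("fingerprint",
                match_bands(bundle$bands, tolerance = config$band_tolerance))
    lanes <- rownames(bm$intensity)
    lane_map <- stats::setNames(sub("_.*$", "", lanes), lanes)
    out$commonality <- tryCatch(
      commonality_table(bm, lane_map, floor = config$detection_floor),
      error = function(e) {
        log_msg("commonality skipped: %s", conditionMessage(e)); NULL
      })
    if (!is.null(out$commonality)) {
      ct <- out$commonality
      utils::write.csv(
        data.frame(statistic = c("total", names(ct$counts)),
                   count = c(ct$total, unname(ct$counts)),
                   percent = c(100, unname(ct$percent))),
        file.path(config$out_dir, "commonality.csv"), row.names = FALSE)
    }
    sim <- similarity_matrix(bm)
    utils::write.csv(sim, file.path(config$out_dir, "similarity.csv"))
    if (nrow(sim) >= 2) {
      tree <- cluster_lanes(bm)
      writeLines(tree$newick, file.path(config$out_dir, "tree.nwk"))
      out$tree <- tree
    }
    out$band_matrix <- bm
  } else log_msg("fingerprint skipped: no band file")

  manifest <- unclass(config)
  manifest$package_version <- as.character(utils::packageVersion("microloop"))
  manifest$r_version <- as.character(getRversion())
  yaml::write_yaml(manifest[!vapply(manifest, is.null, logical(1))],
                   file.path(config$out_dir, "manifest.yaml"))
  invisible(out)
}
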