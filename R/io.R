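#' Read a long-format count series file
#'
#' Expects the header `experiment,treatment,replicate,variable,time_h,
#' value`. Rows with non-positive counts and duplicate
#' (series key, time) rows are rejected with their line numbers.
#'
#' @param path Path to a CSV file.
#' @return Validated long-format data frame.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("experiment", "treatment", "replicate", "variable", "time_h",
            "value")
  if (!identical(names(df), want))
    stop("malformed header in ", path, "; expected ",
         paste(want, collapse = ","), call. = FALSE)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  bad <- which(!is.finite(df$value) | df$value <= 0)
  if (length(bad))
    stop("non-positive counts at line(s) ",
         paste(line[bad], collapse = ", "), " of ", path, call. = FALSE)
  key <- paste(df$experiment, df$treatment, df$replicate, df$variable,
               df$time_h)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (series, time) rows at line(s) ",
         paste(line[dup], collapse = ", "), " of ", path, call. = FALSE)
  df
}

#' Read dilution assays from a long-format CSV
#'
#' Columns: `experiment`, `treatment`, `replicate`, `day`, `time_h`,
#' `viral_count`, `b`, `B` (`b`, `B` constant within an assay).
#'
#' @param path Path to a CSV file.
#' @return Named list of [dilution_assay()] objects.
#' @export
read_dilution <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("experiment", "treatment", "replicate", "day", "time_h",
            "viral_count", "b", "B")
  if (!all(want %in% names(df)))
    stop("malformed dilution file ", path, call. = FALSE)
  keys <- unique(df[c("experiment", "treatment", "replicate", "day")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    g <- df[df$experiment == k$experiment & df$treatment == k$treatment &
              df$replicate == k$replicate & df$day == k$day, ]
    g <- g[order(g$time_h), ]
    dilution_assay(times = g$time_h, viral_counts = g$viral_count,
                   b = g$b[1], B = g$B[1], experiment = k$experiment,
                   treatment = k$treatment, replicate = k$replicate)
  })
  names(out) <- paste(keys$treatment, keys$day, keys$replicate, sep = "_")
  out
}

#' Read a leucine assay file
#'
#' Columns: `experiment`, `treatment`, `replicate`, `time_h`, `role`
#' ("live"/"control"), `leucine_pmol`.
#'
#' @param path Path to a CSV file.
#' @return Data frame suitable for [bacterial_production_table()].
#' @export
read_leucine <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("experiment", "treatment", "replicate", "time_h", "role",
            "leucine_pmol")
  if (!all(want %in% names(df)))
    stop("malformed leucine file ", path, call. = FALSE)
  if (!all(df$role %in% c("live", "control")))
    stop("role must be 'live' or 'control' in ", path, call. = FALSE)
  df
}

#' Read a raw band list
#'
#' Columns: `lane`, `position_px`, `surface`.
#'
#' @param path Path to a CSV file.
#' @return Data frame suitable for [match_bands()].
#' @export
read_bands <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lane", "position_px", "surface") %in% names(df)))
    stop("malformed band file ", path, call. = FALSE)
  df
}

#' Write an experiment bundle to a directory
#'
#' Writes `counts.csv` (long format), `dilution.csv`, `leucine.csv`,
#' `bands.csv` (if present) and `truth.yaml` (ground-truth simulation
#' parameters, simulated bundles only).
#'
#' @param bundle An `experiment_bundle`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$counts, file.path(dir, "counts.csv"),
                   row.names = FALSE)
  dil <- do.call(rbind, lapply(names(bundle$dilution_assays), function(nm) {
    a <- bundle$dilution_assays[[nm]]
    day <- as.numeric(strsplit(nm, "_")[[1]][2])
    data.frame(experiment = a$experiment, treatment = a$treatment,
               replicate = a$replicate, day = day, time_h = a$times,
               viral_count = a$viral_counts, b = a$b, B = a$B,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(dil, file.path(dir, "dilution.csv"), row.names = FALSE)
  utils::write.csv(bundle$leucine, file.path(dir, "leucine.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$bands))
    utils::write.csv(bundle$bands, file.path(dir, "bands.csv"),
                     row.names = FALSE)
  if (!is.null(bundle$truth)) {
    tr <- unclass(bundle$truth)
    tr$init <- as.list(tr$init)
    yaml::write_yaml(tr, file.path(dir, "truth.yaml"))
  }
  invisible(dir)
}

#' Read an experiment bundle from a directory written by [write_bundle()]
#'
#' @param dir Directory containing `counts.csv` (and optionally
#'   `dilution.csv`, `leucine.csv`, `bands.csv`, `truth.yaml`).
#' @return An `experiment_bundle` (with `truth` restored when present).
#' @export
read_bundle <- function(dir) {
  counts <- read_counts(file.path(dir, "counts.csv"))
  p <- function(f) file.path(dir, f)
  assays <- if (file.exists(p("dilution.csv"))) read_dilution(p("dilution.csv"))
            else list()
  leucine <- if (file.exists(p("leucine.csv"))) read_leucine(p("leucine.csv"))
             else NULL
  bands <- if (file.exists(p("bands.csv"))) read_bands(p("bands.csv"))
           else NULL
  truth <- NULL
  if (file.exists(p("truth.yaml"))) {
    tr <- yaml::read_yaml(p("truth.yaml"))
    tr$init <- unlist(tr$init)
    truth <- structure(tr, class = "sim_params")
  }
  structure(list(label = counts$experiment[1], counts = counts,
                 dilution_assays = assays, leucine = leucine,
                 bands = bands, truth = truth),
            class = "experiment_bundle")
}
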