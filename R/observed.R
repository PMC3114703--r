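#' Published summary tables from the four lake experiments
#'
#' Accessors for the small reference tables shipped with the package:
#' treatment-level net growth rates (mean and sd per horizon), in situ
#' starting abundances, treatment starting/final abundances of the
#' filtration-sensitive populations, and the DGGE band-partition tallies.
#' The band partition's split of the "shared with V by exactly two
#' treatments" remainder into V+VF and V+VFA pairs is a synthetic choice
#' (only the published totals constrain it); all other numbers are
#' published measurements.
#'
#' @return A data frame.
#' @name observed_tables
NULL

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "microloop")
  if (path == "") stop("missing extdata file ", file, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname observed_tables
#' @export
observed_growth_rates <- function() .extdata("observed_growth_rates.csv")

#' @rdname observed_tables
#' @export
observed_insitu_abundances <- function() .extdata("observed_insitu_abundances.csv")

#' @rdname observed_tables
#' @export
observed_treatment_initials <- function() .extdata("observed_treatment_initials.csv")

#' @rdname observed_tables
#' @export
observed_band_partitions <- function() .extdata("observed_band_partition.csv")

#' Loss-rate table from published growth rates
#'
#' Applies the g = r - rb identity to a treatment-level growth-rate
#' table: for each experiment and horizon, the loss rate of a predator
#' treatment is the V treatment's mean net growth rate minus its own.
#'
#' @param rates Data frame as returned by [observed_growth_rates()]
#'   (columns `experiment`, `treatment`, `horizon_h`, `growth_rate`).
#' @return The input with a `loss_rate` column added (NA for V rows).
#' @export
loss_rates_from_growth <- function(rates = observed_growth_rates()) {
  key <- paste(rates$experiment, rates$horizon_h)
  v_rate <- rates$growth_rate[rates$treatment == "V"]
  names(v_rate) <- key[rates$treatment == "V"]
  rates$loss_rate <- ifelse(rates$treatment == "V", NA_real_,
                            loss_rate(v_rate[key], rates$growth_rate))
  rates
}

#' Filtration bookkeeping from the published abundance tables
#'
#' Quantifies what the size fractionation removed: the fraction of the
#' in situ nanoflagellate populations (HNF, PNF) lost to the < 5-um
#' prefiltration in the VF/VFA treatments, and the residual fraction of
#' the picocyanobacterial community passing the < 1.6-um filter into the
#' V treatment.
#'
#' @param insitu In situ abundances ([observed_insitu_abundances()]).
#' @param initials Treatment t0/tfinal abundances
#'   ([observed_treatment_initials()]).
#' @return List with `removal` (per experiment x treatment x variable:
#'   `removal_frac` = 1 - t0/in situ for HNF and PNF in VF/VFA),
#'   `mean_removal` (per variable), and `pcy_residual_pct` (per
#'   experiment: 100 * t0_V / in situ for picocyanobacteria).
#' @export
filtration_summary <- function(insitu = observed_insitu_abundances(),
                               initials = observed_treatment_initials()) {
  ref <- stats::setNames(insitu$value, paste(insitu$experiment, insitu$variable))
  flag <- initials[initials$variable %in% c("hnf", "pnf") &
                     initials$treatment %in% c("VF", "VFA"), ]
  flag$removal_frac <- 1 - flag$t0 / ref[paste(flag$experiment, flag$variable)]
  mean_removal <- stats::aggregate(removal_frac ~ variable, data = flag,
                                   FUN = mean)
  pcy <- initials[initials$variable == "picocyano" &
                    initials$treatment == "V", ]
  pcy_residual <- 100 * pcy$t0 / ref[paste(pcy$experiment, "picocyano")]
  names(pcy_residual) <- pcy$experiment
  list(removal = flag[c("experiment", "treatment", "variable", "t0",
                        "removal_frac")],
       mean_removal = mean_removal,
       pcy_residual_pct = pcy_residual)
}

#' Band matrices encoding the published band partitions
#'
#' Builds one synthetic [band_partition_fixture()] per experiment from
#' the published band tallies, so the commonality computation can be run
#' end to end against the printed percentages.
#'
#' @param partitions Data frame as [observed_band_partitions()].
#' @return Named list of `band_matrix` objects.
#' @export
band_fixtures_from_partitions <- function(partitions = observed_band_partitions()) {
  out <- lapply(seq_len(nrow(partitions)), function(i) {
    p <- partitions[i, ]
    band_partition_fixture(common_all = p$common_all,
                           specific_v = p$specific_v,
                           specific_vf = p$specific_vf,
                           specific_vfa = p$specific_vfa,
                           pair_vfa_vf = p$pair_vfa_vf,
                           pair_v_vf = p$pair_v_vf,
                           pair_v_vfa = p$pair_v_vfa)
  })
  names(out) <- partitions$experiment
  out
}
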