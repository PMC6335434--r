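#' Simulate a complement-dependent cytotoxicity decoy experiment
#'
#' Emulates the exosome "decoy" assay: target cells exposed to cytotoxic
#' patient serum plus complement in the presence of increasing amounts of
#' exosomes, which sequester the cytotoxic antibodies. Cytotoxicity
#' follows a saturating inhibition model,
#' `cytotoxicity(dose) = c0 / (1 + decoy_strength * dose)`,
#' read out both as plate-reader viability absorbance and as live-imaging
#' dead-cell counts. Every experimental condition has a replicate-matched
#' spontaneous-lysis well (complement without serum) at the same dose, and
#' the plate assay includes total-lysis wells.
#'
#' @param config A [sim_config()]; uses `decoy_strength`, `cdc_doses`,
#'   `cdc_replicates`, `cdc_noise`, `cdc_baseline` and the master seed.
#' @return A data.frame of class `cdc_experiment` with columns
#'   `serum_group, dose_ug, replicate, time_h, readout_type, value,
#'   well_role` (`readout_type` is `absorbance` or `dead_count`;
#'   `well_role` is `experimental`, `spontaneous` or `total_lysis`).
#' @export
simulate_cdc <- function(config) {
  config <- validate_sim_config(config)
  set.seed(child_seed(config$seed, "cdc"))
  doses <- sort(config$cdc_doses)
  reps <- config$cdc_replicates
  cv <- config$cdc_noise
  noise <- function(k) if (cv <= 0) rep(1, k) else
    stats::rlnorm(k, -cv^2 / 2, cv)
  cyto <- config$cdc_baseline / (1 + config$decoy_strength * doses)
  s0 <- 1.0       # spontaneous-well absorbance scale
  dead_base <- 50 # spontaneous dead-cell count scale
  dead_gain <- 300

  rows <- list()
  add <- function(group, dose, rep_, type, value, role)
    rows[[length(rows) + 1L]] <<- data.frame(
      serum_group = group, dose_ug = dose, replicate = rep_, time_h = 2,
      readout_type = type, value = value, well_role = role,
      stringsAsFactors = FALSE)
  for (i in seq_along(doses)) {
    for (r in seq_len(reps)) {
      add("pdac", doses[i], r, "absorbance",
          s0 * (1 - cyto[i]) * noise(1), "experimental")
      add("pdac", doses[i], r, "absorbance", s0 * noise(1), "spontaneous")
      add("pdac", doses[i], r, "dead_count",
          round((dead_base + dead_gain * cyto[i]) * noise(1)), "experimental")
      add("pdac", doses[i], r, "dead_count",
          round(dead_base * noise(1)), "spontaneous")
    }
  }
  for (r in seq_len(reps))
    add("pdac", 0, r, "absorbance", 0.05 * s0 * noise(1), "total_lysis")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cdc_experiment", "data.frame")
  out
}
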