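#' Simulate multi-set autoantibody microarray data
#'
#' Emulates a recombinant-protein-array serology study run in several
#' independent sample sets, each with its own location and scale (different
#' array batches, scanners and cohorts), merged later by standardizing to
#' the healthy controls of each set. Antigens are the planted tumor
#' antigens of the study (which carry a `serology_effect`-SD case effect on
#' the standardized scale) plus `n_null_antigens` null antigens with no
#' case effect. The planted antigen identifiers are identical to those in
#' [simulate_proteomics()] under the same config, so the serology readout
#' can be joined to the proteomic cascade.
#'
#' @param config A [sim_config()]; uses `serology_sets`, `serology_effect`,
#'   `n_null_antigens` and the master seed.
#' @return Long-form data.frame `antigen_id, sample_id, intensity, set,
#'   group` of background-subtracted array intensities (arbitrary units).
#' @export
simulate_serology <- function(config) {
  config <- validate_sim_config(config)
  antigens <- c(planted_antigen_ids(config),
                sprintf("NULL%03d", seq_len(config$n_null_antigens)))
  set.seed(child_seed(config$seed, "serology"))
  sets <- config$serology_sets
  out <- vector("list", length(sets))
  for (s in seq_along(sets)) {
    set_name <- names(sets)[s]
    counts <- sets[[s]]
    groups <- rep(names(counts), counts)
    sample_ids <- sprintf("%s_%s_%02d", set_name, groups,
                          unlist(lapply(counts, seq_len)))
    loc <- 100 * s^2                  # set-specific location shift
    scl <- 40 * 1.7^(s - 1)           # set-specific scale
    z <- matrix(stats::rnorm(length(antigens) * length(sample_ids)),
                length(antigens), length(sample_ids),
                dimnames = list(antigens, sample_ids))
    is_case <- groups == "case"
    is_planted <- !startsWith(antigens, "NULL")
    z[is_planted, is_case] <- z[is_planted, is_case] + config$serology_effect
    raw <- loc + scl * z
    out[[s]] <- data.frame(
      antigen_id = rep(antigens, times = length(sample_ids)),
      sample_id = rep(sample_ids, each = length(antigens)),
      intensity = as.vector(raw),
      set = set_name,
      group = rep(groups, each = length(antigens)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Planted antigen ids consistent with simulate_proteomics: the planted
# draw is the first RNG use of the proteomics stage stream.
planted_antigen_ids <- function(config) {
  ids <- sprintf("GENE%04d", seq_len(config$n_proteins))
  set.seed(child_seed(config$seed, "proteomics"))
  sample(ids, config$n_planted_antigens)
}
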