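#' Configuration for the synthetic antigen-discovery study
#'
#' Defines the size, structure and noise of the simulated study that the
#' generator functions ([simulate_proteomics()], [simulate_serology()],
#' [simulate_cdc()]) produce. Defaults emulate the design of a
#' multi-compartment exosome proteomics study of pancreatic cancer:
#' six cancer cell lines fractionated into five compartments, pooled
#' case/control plasma immunoglobulin-bound fractions (pools of ~10
#' subjects each), six case and six control plasma exosome preparations
#' sized by nanoparticle tracking, three independent serology sample sets,
#' and a three-dose complement-dependent cytotoxicity (CDC) decoy assay.
#'
#' The negative-binomial count model uses the mean/dispersion
#' parameterization (variance = mu + dispersion * mu^2), the standard for
#' spectral counts. `nb_dispersion = 0` is the noise-free limit: counts are
#' then exactly the (integer) planted means, which makes every realized
#' fold change equal its planted value.
#'
#' @param n_proteins Number of simulated proteins (>= 1).
#' @param n_planted_antigens Number of planted exosome-surface tumor
#'   antigens carrying all planted effects.
#' @param n_unique_case Number of proteins unique to cases (control means
#'   zero in the Ig-bound and plasma experiments) exercising the infinite
#'   fold-change path. Not counted as antigens.
#' @param n_cell_lines Number of cell lines (default 6).
#' @param compartments Compartment labels; the default five-compartment
#'   layout is total cell extract (TCE), cell surface, total exosome
#'   extract (TEE), exosome surfaceome and exosome cargo.
#' @param n_case_pools,n_control_pools Ig-bound case/control plasma pools.
#' @param n_case_plasma,n_control_plasma Plasma exosome samples per group.
#' @param surface_fold Planted exosome-surface enrichment (> 1), applied to
#'   the exosome surfaceome compartment relative to cargo and TEE.
#' @param case_ratio Planted case/control ratio (> 1) for planted antigens
#'   in the Ig-bound counts and plasma MS1 intensities.
#' @param nb_dispersion Negative-binomial dispersion (>= 0) of counts.
#' @param baseline_mean_counts Mean of the log-normal distribution from
#'   which integer per-protein baseline spectral counts are drawn.
#' @param intensity_sigma Log-normal scale (natural-log sd) of technical
#'   MS1 intensity noise (default 0.1, i.e. ~10% CV).
#' @param particle_mean_nm,particle_sd_nm Normal diameter distribution of
#'   plasma exosomes (default 110 / 16 nm).
#' @param particle_mean_nm_cell,particle_sd_nm_cell Diameter distribution
#'   of cell-line exosomes (default 82 / 3 nm).
#' @param n_tracks_per_sample Expected nanoparticle-tracking counts per
#'   plasma sample before the per-sample yield factor.
#' @param serology_sets Named list of per-set sample counts; each entry is
#'   a named integer vector over groups `case`, `healthy`, `pancreatitis`.
#'   Defaults emulate three sets of 10/10/10, 13/13 and 42/50/50 samples.
#' @param serology_effect Planted case effect for planted antigens on the
#'   control-standardized scale (in healthy-control SD units).
#' @param n_null_antigens Antigens carrying no effect on the array.
#' @param decoy_strength Saturating inhibition coefficient of the exosome
#'   decoy model: cytotoxicity(dose) = c0 / (1 + decoy_strength * dose).
#' @param cdc_doses Exosome doses (micrograms), must include 0.
#' @param cdc_replicates Replicate wells per condition.
#' @param cdc_noise Multiplicative noise CV of CDC readouts.
#' @param cdc_baseline Baseline cytotoxic fraction c0 at dose 0 (0-1).
#' @param seed Master seed; each generator stage derives its own child seed
#'   from it by stage name, so adding a stage never perturbs earlier ones.
#'
#' @return A validated list of class `exo_sim_config`.
#' @export
sim_config <- function(n_proteins = 2000,
                       n_planted_antigens = 25,
                       n_unique_case = 3,
                       n_cell_lines = 6,
                       compartments = c("TCE", "cell_surface", "TEE",
                                        "exo_surface", "exo_cargo"),
                       n_case_pools = 6, n_control_pools = 6,
                       n_case_plasma = 6, n_control_plasma = 6,
                       surface_fold = 2.0, case_ratio = 3.0,
                       nb_dispersion = 0.2,
                       baseline_mean_counts = 50,
                       intensity_sigma = 0.1,
                       particle_mean_nm = 110, particle_sd_nm = 16,
                       particle_mean_nm_cell = 82, particle_sd_nm_cell = 3,
                       n_tracks_per_sample = 300,
                       serology_sets = list(
                         set1 = c(case = 10, healthy = 10, pancreatitis = 10),
                         set2 = c(case = 13, healthy = 13),
                         set3 = c(case = 42, healthy = 50, pancreatitis = 50)),
                       serology_effect = 2.0,
                       n_null_antigens = 25,
                       decoy_strength = 1.0,
                       cdc_doses = c(0, 1, 2.5),
                       cdc_replicates = 3,
                       cdc_noise = 0.05,
                       cdc_baseline = 0.6,
                       seed = 1) {
  cfg <- list(n_proteins = n_proteins,
              n_planted_antigens = n_planted_antigens,
              n_unique_case = n_unique_case,
              n_cell_lines = n_cell_lines,
              compartments = compartments,
              n_case_pools = n_case_pools,
              n_control_pools = n_control_pools,
              n_case_plasma = n_case_plasma,
              n_control_plasma = n_control_plasma,
              surface_fold = surface_fold, case_ratio = case_ratio,
              nb_dispersion = nb_dispersion,
              baseline_mean_counts = baseline_mean_counts,
              intensity_sigma = intensity_sigma,
              particle_mean_nm = particle_mean_nm,
              particle_sd_nm = particle_sd_nm,
              particle_mean_nm_cell = particle_mean_nm_cell,
              particle_sd_nm_cell = particle_sd_nm_cell,
              n_tracks_per_sample = n_tracks_per_sample,
              serology_sets = serology_sets,
              serology_effect = serology_effect,
              n_null_antigens = n_null_antigens,
              decoy_strength = decoy_strength,
              cdc_doses = cdc_doses,
              cdc_replicates = cdc_replicates,
              cdc_noise = cdc_noise,
              cdc_baseline = cdc_baseline,
              seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  pos_int <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
    x >= 1 && x == round(x)
  for (f in c("n_proteins", "n_planted_antigens", "n_cell_lines",
              "n_case_pools", "n_control_pools",
              "n_case_plasma", "n_control_plasma", "cdc_replicates"))
    if (!pos_int(cfg[[f]]))
      stop("configuration error: `", f, "` must be a positive integer",
           call. = FALSE)
  if (!pos_int(cfg$n_unique_case + 1))  # allows 0
    stop("configuration error: `n_unique_case` must be a non-negative integer",
         call. = FALSE)
  if (cfg$n_planted_antigens + cfg$n_unique_case > cfg$n_proteins)
    stop("configuration error: planted proteins exceed n_proteins", call. = FALSE)
  if (anyDuplicated(cfg$compartments) || length(cfg$compartments) < 1L)
    stop("configuration error: compartment labels must be unique", call. = FALSE)
  if (!is.numeric(cfg$surface_fold) || cfg$surface_fold <= 1)
    stop("configuration error: `surface_fold` must exceed 1", call. = FALSE)
  if (!is.numeric(cfg$case_ratio) || cfg$case_ratio <= 1)
    stop("configuration error: `case_ratio` must exceed 1", call. = FALSE)
  if (!is.numeric(cfg$nb_dispersion) || cfg$nb_dispersion < 0)
    stop("configuration error: `nb_dispersion` must be >= 0", call. = FALSE)
  if (!is.numeric(cfg$baseline_mean_counts) || cfg$baseline_mean_counts <= 0)
    stop("configuration error: `baseline_mean_counts` must be > 0", call. = FALSE)
  if (!is.numeric(cfg$intensity_sigma) || cfg$intensity_sigma <= 0)
    stop("configuration error: `intensity_sigma` must be > 0", call. = FALSE)
  if (!is.list(cfg$serology_sets) || length(cfg$serology_sets) < 2L)
    stop("configuration error: need at least 2 serology sets", call. = FALSE)
  for (s in names(cfg$serology_sets)) {
    n <- cfg$serology_sets[[s]]
    if (is.na(n["healthy"]) || n[["healthy"]] < 2L)
      stop("configuration error: serology set `", s,
           "` needs at least 2 healthy controls", call. = FALSE)
  }
  if (!is.numeric(cfg$decoy_strength) || cfg$decoy_strength < 0)
    stop("configuration error: `decoy_strength` must be >= 0", call. = FALSE)
  if (any(cfg$cdc_doses < 0))
    stop("configuration error: negative exosome dose", call. = FALSE)
  if (length(cfg$cdc_doses) < 2L || !any(cfg$cdc_doses == 0))
    stop("configuration error: need >= 2 CDC doses including 0", call. = FALSE)
  if (cfg$cdc_baseline <= 0 || cfg$cdc_baseline >= 1)
    stop("configuration error: `cdc_baseline` must be in (0, 1)", call. = FALSE)
  if (!pos_int(abs(cfg$seed) + 1))
    stop("configuration error: `seed` must be an integer", call. = FALSE)
  structure(cfg, class = "exo_sim_config")
}

#' @export
print.exo_sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "exo_sim_config: %d proteins (%d planted antigens, %d unique-to-case)\n",
    "  %d cell lines x %d compartments; Ig pools %d case / %d control\n",
    "  plasma %d case / %d control; surface_fold %.2f; case_ratio %.2f\n",
    "  nb_dispersion %.3g; seed %d\n"),
    x$n_proteins, x$n_planted_antigens, x$n_unique_case,
    x$n_cell_lines, length(x$compartments),
    x$n_case_pools, x$n_control_pools,
    x$n_case_plasma, x$n_control_plasma,
    x$surface_fold, x$case_ratio, x$nb_dispersion, x$seed))
  invisible(x)
}

# Deterministic child seed per generator stage: a stage's stream depends
# only on (master seed, stage name), never on which other stages ran.
child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 9349) %% 2147483629)
}

# Negative-binomial counts; dispersion 0 is the deterministic limit.
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(rep_len(round(mu), n))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}
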