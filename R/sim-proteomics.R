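#' Simulate the multi-compartment proteomic study with planted ground truth
#'
#' Generates the three proteomic data sets of the synthetic study, with a
#' recorded ground truth for recovery testing:
#'
#' * `cellline` — spectral counts for `n_cell_lines` cell lines x the five
#'   fractionation compartments. Planted antigens are enriched
#'   `surface_fold`-fold in the exosome surfaceome relative to every other
#'   compartment; exosome marker proteins (CD81, CD9, ...) are enriched in
#'   all exosome compartments and the depleted control set (CANX, ...) in
#'   the cellular compartments, so marker QC is exercised.
#' * `ig` — spectral counts for the immunoglobulin-bound fractions of
#'   pooled case and control plasma. Planted antigens (and planted
#'   contaminants: Ig chains, an acute-phase and an abundant plasma
#'   protein, which the exclusion stage must remove) have case means
#'   scaled by `case_ratio`; unique-to-case proteins have control mean 0.
#' * `plasma` — log-normal MS1 ion intensities for individual case and
#'   control plasma exosome preparations. Each sample has a latent exosome
#'   yield that scales both its intensities and its nanoparticle-tracking
#'   counts, which is what particle normalization is meant to divide out.
#' * `particles` — long-form nanoparticle diameter tables for the plasma
#'   samples (normal around 110 +/- 16 nm) and the cell lines (82 +/- 3 nm).
#' * `evidence` — gene-expression confirmation table (11 cell-line FPKM
#'   columns, a TCGA log2 expression summary, and a 0-8 count of external
#'   datasets reporting tumor overexpression).
#'
#' With `nb_dispersion = 0` the generator runs in its deterministic
#' (noise-free) limit: counts equal their integer planted means,
#' intensities equal their planted means, yields are 1 and diameters are
#' distribution quantiles, so every realized ratio equals its planted fold
#' exactly and cascade recovery is exact.
#'
#' @param config A [sim_config()].
#' @return A list of class `exo_proteomics_sim` with elements `cellline`,
#'   `ig` (both [spectral_counts()]), `plasma` ([ion_intensities()]),
#'   `particles`, `particles_cell` (data.frames `sample_id, diameter_nm`),
#'   `evidence` (data.frame) and `truth` (planted ground truth).
#' @export
simulate_proteomics <- function(config) {
  config <- validate_sim_config(config)
  noise_free <- config$nb_dispersion <= 0
  set.seed(child_seed(config$seed, "proteomics"))

  ids <- sprintf("GENE%04d", seq_len(config$n_proteins))
  markers <- exosome_markers()
  depleted <- depleted_markers()
  contaminants <- c("IGKC", "IGHG1", "CRP", "ALB")
  all_ids <- c(ids, markers, depleted, contaminants)
  n <- length(all_ids)

  planted <- sample(ids, config$n_planted_antigens)
  pool_uc <- setdiff(ids, planted)
  unique_case <- if (config$n_unique_case > 0)
    sample(pool_uc, config$n_unique_case) else character(0)

  # integer baselines so the noise-free ratios are exact
  base <- pmax(1L, as.integer(round(stats::rlnorm(
    n, meanlog = log(config$baseline_mean_counts) - 0.5, sdlog = 1))))
  names(base) <- all_ids
  special <- c(planted, unique_case, markers, depleted, contaminants)
  base[special] <- pmax(base[special], 10L)

  truth <- list(
    antigen_ids = planted,
    unique_case_ids = unique_case,
    marker_ids = markers, depleted_ids = depleted,
    contaminant_ids = contaminants,
    surface_fold = stats::setNames(rep(config$surface_fold,
                                       length(planted)), planted),
    case_ratio = stats::setNames(rep(config$case_ratio,
                                     length(planted)), planted),
    serology_effect = config$serology_effect,
    decoy_strength = config$decoy_strength)

  ## --- cell line x compartment counts -------------------------------------
  lines <- sprintf("CL%d", seq_len(config$n_cell_lines))
  comp <- config$compartments
  cell_samples <- expand.grid(line = lines, compartment = comp,
                              KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE)
  cell_samples$sample_id <- paste(cell_samples$line, cell_samples$compartment,
                                  sep = ".")
  exo_comp <- intersect(c("TEE", "exo_surface", "exo_cargo"), comp)
  cell_comp <- intersect(c("TCE", "cell_surface"), comp)
  cell_counts <- matrix(0, n, nrow(cell_samples),
                        dimnames = list(all_ids, cell_samples$sample_id))
  for (j in seq_len(nrow(cell_samples))) {
    cc <- cell_samples$compartment[j]
    mu <- base
    if (cc == "exo_surface") mu[planted] <- config$surface_fold * base[planted]
    if (cc %in% exo_comp) mu[markers] <- 3 * base[markers]
    if (cc %in% cell_comp) mu[depleted] <- 3 * base[depleted]
    cell_counts[, j] <- rcounts(n, mu, config$nb_dispersion)
  }
  cellline <- spectral_counts(cell_counts, cell_samples)

  ## --- Ig-bound case/control pool counts ----------------------------------
  pools <- data.frame(
    sample_id = c(sprintf("case_pool_%d", seq_len(config$n_case_pools)),
                  sprintf("control_pool_%d", seq_len(config$n_control_pools))),
    group = rep(c("case", "control"),
                c(config$n_case_pools, config$n_control_pools)),
    stringsAsFactors = FALSE)
  ig_counts <- matrix(0, n, nrow(pools),
                      dimnames = list(all_ids, pools$sample_id))
  elevated <- c(planted, contaminants)
  for (j in seq_len(nrow(pools))) {
    mu <- base
    if (pools$group[j] == "case") {
      mu[elevated] <- config$case_ratio * base[elevated]
      mu[unique_case] <- base[unique_case]
    } else {
      mu[unique_case] <- 0
    }
    ig_counts[, j] <- rcounts(n, mu, config$nb_dispersion)
  }
  ig <- spectral_counts(ig_counts, pools)

  ## --- plasma exosome MS1 intensities + particle tables -------------------
  plasma_ids <- c(sprintf("case_ex_%d", seq_len(config$n_case_plasma)),
                  sprintf("control_ex_%d", seq_len(config$n_control_plasma)))
  plasma_groups <- rep(c("case", "control"),
                       c(config$n_case_plasma, config$n_control_plasma))
  base_int <- base * 2000  # MS1 intensity scale tied to abundance
  yields <- if (noise_free) rep(1, length(plasma_ids)) else
    stats::rlnorm(length(plasma_ids), meanlog = 0, sdlog = 0.2)
  intens <- matrix(0, n, length(plasma_ids),
                   dimnames = list(all_ids, plasma_ids))
  for (j in seq_along(plasma_ids)) {
    mu <- base_int
    if (plasma_groups[j] == "case") {
      mu[elevated] <- config$case_ratio * base_int[elevated]
    } else {
      mu[unique_case] <- 0
    }
    mu <- mu * yields[j]
    intens[, j] <- if (noise_free) mu else
      mu * stats::rlnorm(n, -config$intensity_sigma^2 / 2,
                         config$intensity_sigma)
  }
  plasma <- ion_intensities(intens, stats::setNames(plasma_groups, plasma_ids))

  particles <- sim_particles(plasma_ids, yields, config$n_tracks_per_sample,
                             config$particle_mean_nm, config$particle_sd_nm,
                             noise_free)
  particles_cell <- sim_particles(lines, rep(1, length(lines)),
                                  config$n_tracks_per_sample,
                                  config$particle_mean_nm_cell,
                                  config$particle_sd_nm_cell, noise_free)

  ## --- gene-expression evidence -------------------------------------------
  expressed <- rep(TRUE, n)
  if (!noise_free) {
    idx_other <- which(!(all_ids %in% special))
    expressed[sample(idx_other, round(0.1 * length(idx_other)))] <- FALSE
  }
  fpkm <- matrix(0, n, 11, dimnames = list(all_ids, sprintf("fpkm_%d", 1:11)))
  fpkm[expressed, ] <- if (noise_free) 10 else
    stats::rlnorm(sum(expressed) * 11, log(10), 1)
  tcga <- ifelse(expressed,
                 if (noise_free) 8 else stats::runif(n, 4, 12), 0)
  onco <- integer(n)
  is_planted <- all_ids %in% planted
  onco[is_planted] <- if (noise_free) 4L else
    stats::rbinom(sum(is_planted), 8, 0.5)
  onco[!is_planted] <- if (noise_free) 0L else
    stats::rbinom(sum(!is_planted), 8, 0.08)
  evidence <- data.frame(gene_id = all_ids, fpkm, tcga_log2 = tcga,
                         oncomine_hits = onco,
                         row.names = NULL, stringsAsFactors = FALSE)

  structure(list(cellline = cellline, ig = ig, plasma = plasma,
                 particles = particles, particles_cell = particles_cell,
                 evidence = evidence, truth = truth,
                 config = config),
            class = "exo_proteomics_sim")
}

# Nanoparticle-tracking diameter table; track counts scale with the
# per-sample yield. In the deterministic limit diameters are distribution
# quantiles so the 30-200 nm window count is identical across samples.
sim_particles <- function(sample_ids, yields, n_tracks, mean_nm, sd_nm,
                          noise_free) {
  out <- lapply(seq_along(sample_ids), function(j) {
    k <- max(1L, round(n_tracks * yields[j]))
    d <- if (noise_free)
      stats::qnorm((seq_len(k) - 0.5) / k, mean_nm, sd_nm)
    else stats::rnorm(k, mean_nm, sd_nm)
    data.frame(sample_id = sample_ids[j], diameter_nm = pmax(d, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.exo_proteomics_sim <- function(x, ...) {
  cat("Synthetic multi-compartment proteomic study\n")
  cat(sprintf("  planted antigens: %d; unique-to-case: %d; dispersion %.3g\n",
              length(x$truth$antigen_ids), length(x$truth$unique_case_ids),
              x$config$nb_dispersion))
  print(x$cellline); print(x$ig); print(x$plasma)
  invisible(x)
}
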