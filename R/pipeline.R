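#' Default analysis thresholds
#'
#' All thresholds of the antigen-prioritization pipeline, at the values
#' used throughout the candidate-selection literature this package
#' implements: detection at 5 normalized MS2 counts, case/control ratio
#' 1.5, surface enrichment 1.25-fold, plasma elevation 2.5-fold, Ig-chain
#' plasma elevation 3.5-fold, HLA-II peptide length 12-34 residues with
#' predicted IC50 below 500 nM, particle window 30-200 nm, and a
#' 17,611-gene universe for overlap testing. Every report echoes the
#' thresholds it ran with, so deviations are always visible.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(min_ms2 = 5, detect_min_samples = 1, strict_detection = FALSE,
       ig_ratio = 1.5,
       surface_fold = 1.25, surface_min_samples = 2,
       plasma_fold = 2.5, plasma_min_samples = 2,
       ig_chain_fold = 3.5,
       ic50 = 500, pep_min_len = 12, pep_max_len = 34,
       particle_low = 30, particle_high = 200,
       universe = 17611, alpha = 0.05)
}

#' Run the antigen-prioritization pipeline end to end
#'
#' Orchestrates normalization, the Ig-bound selection cascade, compartment
#' enrichment, marker QC, particle-normalized plasma elevation, overlap
#' statistics, the final candidate intersection cascade, and — when the
#' corresponding inputs are present — HLA-II epitope filtering/mapping,
#' serology standardization and testing, and the CDC decoy analysis.
#' Stages whose inputs are missing are skipped and logged. Deterministic
#' under a fixed seed.
#'
#' @param study A list as produced by [simulate_study()] or
#'   [read_study_dir()]: elements `cellline`, `ig`, `plasma`, `particles`,
#'   `evidence` are required; `serology`, `cdc`, `peptides`, `proteins`
#'   and `truth` are optional.
#' @param thresholds See [default_thresholds()]; partial lists are merged
#'   over the defaults.
#' @param seed Seed for the pipeline's stochastic components (permutation
#'   tests).
#' @return A provenance report of class `exo_report`.
#' @export
run_pipeline <- function(study, thresholds = list(), seed = 1) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  for (required in c("cellline", "ig", "plasma", "particles", "evidence"))
    if (is.null(study[[required]]))
      stop("data error: study lacks required input `", required, "`",
           call. = FALSE)
  if (nrow(study$ig$counts) == 0L || nrow(study$cellline$counts) == 0L)
    stop("data error: empty protein matrix", call. = FALSE)

  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  skipped <- character(0)
  report <- list(tool = "exoprio", version = as.character(
    utils::packageVersion("exoprio")),
    seed = seed, thresholds = th)

  ## Ig-bound cascade (quantile normalization inside, recorded)
  ig_rep <- ig_bound_cascade(study$ig, study$evidence,
                             min_count = th$min_ms2,
                             min_samples = th$detect_min_samples,
                             strict_detection = th$strict_detection,
                             ratio_fold = th$ig_ratio)
  ig_surv <- cascade_survivors(ig_rep)
  report$ig_cascade <- ig_rep

  ## cell-line compartments: normalize once, then enrichment + QC
  cl <- quantile_normalize(study$cellline)
  exo_enr <- compartment_enrichment(cl, "exo_surface",
                                    c("exo_cargo", "TEE"),
                                    fold = th$surface_fold,
                                    min_count = th$min_ms2,
                                    min_samples = th$surface_min_samples)
  report$exo_surface_enrichment <- exo_enr$report
  cell_enr <- compartment_enrichment(cl, "cell_surface", "TCE",
                                     fold = th$surface_fold,
                                     min_count = th$min_ms2,
                                     min_samples = th$surface_min_samples)
  report$cell_surface_enrichment <- cell_enr$report
  report$marker_qc <- marker_qc(cl, alpha = th$alpha)

  ## plasma exosomes: particle-normalize, then elevation
  pw <- count_particles_in_window(study$particles,
                                  th$particle_low, th$particle_high)
  plasma_norm <- normalize_by_particles(study$plasma, pw)
  plasma <- plasma_exosome_elevation(plasma_norm,
                                     min_samples = th$plasma_min_samples,
                                     fold = th$plasma_fold)
  report$plasma_elevation <- plasma$report
  plasma_detected <- cascade_survivors(plasma$report, "detection")

  ## Ig chains in plasma exosomes at the higher fold threshold
  ig_rows <- grep("^IG(H|K|L|J)", rownames(plasma_norm$intensity),
                  value = TRUE)
  if (length(ig_rows)) {
    fc <- plasma$fold_changes
    fc <- fc[fc$protein_id %in% ig_rows, , drop = FALSE]
    report$ig_chain_elevation <- list(
      fold = th$ig_chain_fold,
      elevated = fc$protein_id[ratio_passes(fc$ratio, th$ig_chain_fold)],
      fold_changes = fc)
  }

  ## overlap statistics
  report$overlaps <- list(
    ig_vs_plasma = hypergeometric_overlap(
      length(intersect(ig_surv, plasma_detected)),
      length(ig_surv), length(plasma_detected), th$universe),
    ig_vs_exo_surface = hypergeometric_overlap(
      length(intersect(ig_surv, exo_enr$ids)),
      length(ig_surv), length(exo_enr$ids), th$universe))

  ## final candidate intersection cascade
  cand <- cascade_report("candidate antigens", universe = ig_surv)
  cand <- add_cascade_stage(cand, "ig_bound", "Ig-bound cascade survivors",
                            NA_real_, ig_surv, ig_surv)
  s2 <- intersect(ig_surv, exo_enr$ids)
  cand <- add_cascade_stage(cand, "exo_surface_enriched",
                            sprintf("surface > %g x cargo and TEE",
                                    th$surface_fold),
                            th$surface_fold, ig_surv, s2)
  s3 <- intersect(s2, plasma$ids)
  cand <- add_cascade_stage(cand, "plasma_elevated",
                            sprintf("plasma ratio > %g", th$plasma_fold),
                            th$plasma_fold, s2, s3)
  report$candidates <- cand

  ## recovery against planted truth, when available
  if (!is.null(study$truth)) {
    truth <- study$truth$antigen_ids
    tp <- length(intersect(s3, truth))
    report$recovery <- list(
      n_truth = length(truth), n_called = length(s3), true_positives = tp,
      precision = if (length(s3)) tp / length(s3) else NA_real_,
      recall = if (length(truth)) tp / length(truth) else NA_real_)
  }

  ## epitope evidence
  if (!is.null(study$peptides) && !is.null(study$proteins)) {
    filt <- filter_hla2_peptides(study$peptides,
                                 min_len = th$pep_min_len,
                                 max_len = th$pep_max_len,
                                 ic50_threshold = th$ic50)
    mapped <- map_peptides_to_sources(filt$kept, study$proteins)
    report$epitopes <- list(
      n_input = nrow(study$peptides), n_kept = nrow(filt$kept),
      evidence = epitope_evidence_summary(mapped$evidence, filt$kept),
      unmapped = mapped$unmapped)
  } else skipped <- c(skipped, "epitopes")

  ## serology
  if (!is.null(study$serology)) {
    merged <- standardize_and_merge_sets(study$serology)
    report$serology <- serology_antigen_tests(merged)
  } else skipped <- c(skipped, "serology")

  ## CDC decoy analysis
  if (!is.null(study$cdc)) {
    report$cdc <- decoy_dose_response(study$cdc, "absorbance", seed = seed)
  } else skipped <- c(skipped, "cdc")

  report$skipped <- skipped
  report$timestamps <- list(started = started,
                            finished = format(Sys.time(),
                                              "%Y-%m-%dT%H:%M:%S%z"))
  structure(report, class = "exo_report")
}

#' @export
print.exo_report <- function(x, ...) {
  cat(sprintf("exoprio run (seed %d)\n", x$seed))
  print(x$ig_cascade)
  print(x$candidates)
  cat(sprintf("overlap Ig-bound vs plasma: p = %.3g (RF %.2f)\n",
              x$overlaps$ig_vs_plasma$p_upper,
              x$overlaps$ig_vs_plasma$representation_factor))
  if (!is.null(x$recovery))
    cat(sprintf("recovery: precision %.3f, recall %.3f\n",
                x$recovery$precision, x$recovery$recall))
  if (length(x$skipped))
    cat("skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

report_to_list <- function(report) {
  simplify <- function(x) {
    if (inherits(x, "cascade_report")) {
      out <- list(name = x$name,
                  stages = lapply(unname(x$stages), function(s)
                    s[c("stage", "rule", "threshold", "n_input",
                        "n_surviving", "surviving_ids")]))
      if (!is.null(x$annotations)) out$annotations <- x$annotations
      return(out)
    }
    if (inherits(x, "marker_qc"))
      return(list(pass = x$pass,
                  marker_p = x$markers$test$p_value,
                  depleted_p = if (!is.null(x$depleted$test))
                    x$depleted$test$p_value else NULL,
                  missing = x$markers$missing))
    if (inherits(x, c("overlap_result", "rank_test", "decoy_result",
                      "roc_result")))
      return(lapply(unclass(x), simplify))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, simplify))
    x
  }
  simplify(unclass(report))
}

#' Write a pipeline report to disk
#'
#' Renders the provenance report as machine-readable JSON
#' (`report.json`), a human-readable Markdown summary (`report.md`), and
#' one TSV per filter cascade.
#'
#' @param report An `exo_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "exo_report"))
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir))
    stop("cannot create output directory: ", dir, call. = FALSE)
  paths <- character(0)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report_to_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(paths, json_path)

  md <- c(sprintf("# exoprio report (seed %d)", report$seed), "")
  for (nm in names(report)) {
    x <- report[[nm]]
    if (inherits(x, "cascade_report")) {
      md <- c(md, sprintf("## %s", nm), "",
              "| stage | rule | in | out |", "|---|---|---|---|",
              vapply(x$stages, function(s)
                sprintf("| %s | %s | %d | %d |", s$stage, s$rule,
                        s$n_input, s$n_surviving), ""), "")
      tsv <- file.path(dir, sprintf("cascade_%s.tsv", nm))
      write_tsv(as.data.frame(x), tsv)
      paths <- c(paths, tsv)
    } else if (inherits(x, "overlap_result")) {
      md <- c(md, sprintf("## %s", nm), "",
              sprintf("overlap %d / (%d, %d), universe %d: p = %.3g, RF = %.2f",
                      x$k, x$K, x$n, x$N, x$p_upper,
                      x$representation_factor), "")
    }
  }
  if (!is.null(report$overlaps)) {
    md <- c(md, "## overlaps", "",
            vapply(names(report$overlaps), function(nm) {
              x <- report$overlaps[[nm]]
              sprintf("- %s: k=%d K=%d n=%d N=%d p=%.3g RF=%.2f", nm,
                      x$k, x$K, x$n, x$N, x$p_upper,
                      x$representation_factor)
            }, ""), "")
  }
  if (!is.null(report$recovery))
    md <- c(md, "## recovery", "",
            sprintf("precision %.3f, recall %.3f (%d called, %d planted)",
                    report$recovery$precision, report$recovery$recall,
                    report$recovery$n_called, report$recovery$n_truth), "")
  if (!is.null(report$marker_qc))
    md <- c(md, "## marker_qc", "",
            sprintf("pass: %s (marker p %.3g)", report$marker_qc$pass,
                    report$marker_qc$markers$test$p_value), "")
  if (!is.null(report$cdc))
    md <- c(md, "## cdc", "",
            sprintf("trend p = %.4g, monotone decreasing: %s",
                    report$cdc$trend_p, report$cdc$monotone_decreasing), "")
  if (length(report$skipped))
    md <- c(md, "## skipped stages", "",
            paste("-", report$skipped), "")
  md_path <- file.path(dir, "report.md")
  writeLines(md, md_path)
  invisible(c(paths, md_path))
}
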