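#' Detection filter on a spectral-count matrix
#'
#' Selects proteins whose count reaches `min_count` (inclusively by
#' default; strictly with `strict = TRUE`) in at least `min_samples` of
#' the considered columns. This is the "at least five normalized MS2
#' counts" rule and, in its strict two-of-six form, the cell-line
#' detection rule.
#'
#' @param x [spectral_counts()] object or numeric matrix.
#' @param min_count Count threshold (default 5).
#' @param min_samples Minimum number of qualifying columns (default 1).
#' @param strict If `TRUE` the count must exceed `min_count` (`>`),
#'   otherwise reach it (`>=`).
#' @param columns Optional character/integer subset of columns to consider.
#' @return List with `ids` (surviving protein identifiers) and `stage`
#'   (rule metadata for a [cascade_report()]).
#' @export
select_detected <- function(x, min_count = 5, min_samples = 1,
                            strict = FALSE, columns = NULL) {
  mat <- if (inherits(x, "spectral_counts")) x$counts else as.matrix(x)
  if (!is.null(columns)) mat <- mat[, columns, drop = FALSE]
  if (min_samples < 1)
    stop("`min_samples` must be at least 1", call. = FALSE)
  if (min_samples > ncol(mat))
    stop("`min_samples` exceeds the number of columns considered",
         call. = FALSE)
  hits <- if (strict) mat > min_count else mat >= min_count
  ids <- rownames(mat)[rowSums(hits) >= min_samples]
  rule <- sprintf("%s%g counts in >=%d of %d samples",
                  if (strict) ">" else ">=", min_count, min_samples,
                  ncol(mat))
  list(ids = ids, stage = list(rule = rule, threshold = min_count))
}

#' Ig-bound antigen prioritization cascade
#'
#' The candidate-selection cascade for proteins identified in the
#' immunoglobulin-bound fraction of pooled case and control plasma:
#'
#' 1. detection — at least `min_count` normalized MS2 counts in at least
#'    `min_samples` pools (any pool);
#' 2. ratio — case-to-control average MS2 count ratio of at least
#'    `ratio_fold` (proteins unique to cases, with an infinite ratio,
#'    pass; proteins absent from both groups are dropped);
#' 3. expression — confirmed expression of the corresponding gene: FPKM of
#'    at least `fpkm_min` in at least `fpkm_lines_min` of the cell-line
#'    FPKM columns AND a TCGA log2 expression summary of at least
#'    `tcga_min` (genes missing from `evidence` fail);
#' 4. exclusion — removal of immunoglobulin chains (by gene-symbol
#'    prefix), acute-phase response proteins and high-abundance plasma
#'    proteins.
#'
#' Survivors are annotated with a non-filtering overexpression flag: the
#' count of external expression datasets reporting tumor overexpression
#' (`oncomine_hits`), flagged when at least `oncomine_min`.
#'
#' @param ig [spectral_counts()] with a `group` column (`case`/`control`)
#'   in its sample annotation.
#' @param evidence data.frame with `gene_id`, `fpkm_*` columns,
#'   `tcga_log2` and `oncomine_hits`.
#' @param exclusions List as returned by [default_exclusions()].
#' @param min_count,min_samples,strict_detection Detection rule.
#' @param ratio_fold Ratio threshold (inclusive; default 1.5).
#' @param fpkm_min,fpkm_lines_min,tcga_min Expression-confirmation rule.
#' @param oncomine_min Overexpression-flag threshold (default 2).
#' @param normalize If `TRUE` (default) quantile-normalize the counts
#'   before filtering; recorded in the report.
#' @return A [cascade_report()] with an `annotations` data.frame attached
#'   (per-survivor ratio, `oncomine_hits`, `oncomine_flag`).
#' @export
ig_bound_cascade <- function(ig, evidence, exclusions = default_exclusions(),
                             min_count = 5, min_samples = 1,
                             strict_detection = FALSE,
                             ratio_fold = 1.5,
                             fpkm_min = 1, fpkm_lines_min = 1, tcga_min = 1,
                             oncomine_min = 2, normalize = TRUE) {
  stopifnot(inherits(ig, "spectral_counts"))
  grp <- ig$samples$group
  if (is.null(grp) || !any(grp == "case") || !any(grp == "control"))
    stop("Ig-bound matrix needs both case and control pools", call. = FALSE)
  if (normalize) ig <- quantile_normalize(ig)
  mat <- ig$counts
  rep_ <- cascade_report(
    if (normalize) "ig_bound (quantile-normalized counts)" else "ig_bound",
    universe = rownames(mat))

  det <- select_detected(ig, min_count, min_samples, strict_detection)
  rep_ <- add_cascade_stage(rep_, "detection", det$stage$rule, min_count,
                            rownames(mat), det$ids)

  fc <- row_fold_changes(mat[det$ids, , drop = FALSE], grp == "case")
  keep_ratio <- fc$protein_id[ratio_passes(fc$ratio, ratio_fold,
                                           inclusive = TRUE)]
  rep_ <- add_cascade_stage(rep_, "case_control_ratio",
                            sprintf("case/control mean ratio >= %g (Inf passes)",
                                    ratio_fold),
                            ratio_fold, det$ids, keep_ratio)

  expressed <- confirmed_expression(evidence, fpkm_min, fpkm_lines_min,
                                    tcga_min)
  keep_expr <- intersect(keep_ratio, expressed)
  rep_ <- add_cascade_stage(rep_, "expression_confirmed",
                            sprintf("FPKM >= %g in >= %d lines and TCGA log2 >= %g",
                                    fpkm_min, fpkm_lines_min, tcga_min),
                            fpkm_min, keep_ratio, keep_expr)

  excluded <- is_excluded(keep_expr, exclusions)
  keep_final <- keep_expr[!excluded]
  rep_ <- add_cascade_stage(rep_, "exclusion_lists",
                            "remove Ig chains, acute-phase and abundant plasma proteins",
                            NA_real_, keep_expr, keep_final)

  ann <- fc[match(keep_final, fc$protein_id),
            c("protein_id", "case_mean", "control_mean", "ratio", "status")]
  m <- match(keep_final, evidence$gene_id)
  ann$oncomine_hits <- evidence$oncomine_hits[m]
  ann$oncomine_flag <- !is.na(ann$oncomine_hits) &
    ann$oncomine_hits >= oncomine_min
  rownames(ann) <- NULL
  rep_$annotations <- ann
  rep_
}

confirmed_expression <- function(evidence, fpkm_min, fpkm_lines_min,
                                 tcga_min) {
  fpkm_cols <- grep("^fpkm", names(evidence), value = TRUE)
  if (!length(fpkm_cols) || !"tcga_log2" %in% names(evidence))
    stop("`evidence` needs fpkm_* columns and tcga_log2", call. = FALSE)
  fp <- as.matrix(evidence[, fpkm_cols, drop = FALSE])
  ok <- rowSums(fp >= fpkm_min) >= fpkm_lines_min &
    evidence$tcga_log2 >= tcga_min
  evidence$gene_id[ok]
}

is_excluded <- function(ids, exclusions) {
  pref <- exclusions$ig_chain_prefixes
  by_prefix <- Reduce(`|`, lapply(pref, function(p) startsWith(ids, p)),
                      rep(FALSE, length(ids)))
  by_prefix | ids %in% exclusions$acute_phase_proteins |
    ids %in% exclusions$abundant_plasma_proteins
}

#' Compartment enrichment filter
#'
#' Selects proteins enriched in a target compartment relative to every
#' reference compartment: the per-protein mean count across cell lines in
#' the target must exceed `fold` times the mean in each reference
#' (conjunction over references), intersected with the strict detection
#' rule (counts above `min_count` in at least `min_samples` cell lines of
#' the target compartment). The default reproduces the exosome-surfaceome
#' rule: surface vs both cargo and total exosome extract at >1.25-fold,
#' with >5 counts in at least 2 of the cell lines.
#'
#' @param x [spectral_counts()] whose sample annotation has `compartment`
#'   and `line` columns; counts are assumed already normalized.
#' @param target Target compartment label.
#' @param references Character vector of reference compartment labels
#'   (must not contain `target`).
#' @param fold Enrichment fold threshold (> 1; strict comparison).
#' @param min_count,min_samples Detection rule on the target compartment
#'   (strict `>`).
#' @return List with `ids`, `report` (a [cascade_report()]) and `means`
#'   (per-protein per-compartment mean counts).
#' @export
compartment_enrichment <- function(x, target = "exo_surface",
                                   references = c("exo_cargo", "TEE"),
                                   fold = 1.25,
                                   min_count = 5, min_samples = 2) {
  stopifnot(inherits(x, "spectral_counts"))
  comp <- x$samples$compartment
  if (is.null(comp)) stop("sample annotation lacks `compartment`", call. = FALSE)
  known <- unique(comp)
  bad <- setdiff(c(target, references), known)
  if (length(bad))
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (target %in% references)
    stop("`target` must not be one of `references`", call. = FALSE)
  if (fold <= 1) stop("`fold` must exceed 1", call. = FALSE)

  mat <- x$counts
  means <- sapply(c(target, references), function(cc)
    rowMeans(mat[, comp == cc, drop = FALSE]))
  rep_ <- cascade_report(sprintf("%s enrichment", target),
                         universe = rownames(mat))
  det <- select_detected(x, min_count, min_samples, strict = TRUE,
                         columns = which(comp == target))
  rep_ <- add_cascade_stage(rep_, "detection", det$stage$rule, min_count,
                            rownames(mat), det$ids)
  enough <- Reduce(`&`, lapply(references, function(r)
    means[, target] > fold * means[, r]))
  keep <- intersect(det$ids, rownames(mat)[enough])
  rep_ <- add_cascade_stage(
    rep_, "enrichment",
    sprintf("mean %s > %g x mean of every reference (%s)", target, fold,
            paste(references, collapse = ", ")),
    fold, det$ids, keep)
  list(ids = keep, report = rep_, means = as.data.frame(means))
}

#' Plasma-exosome elevation filter
#'
#' Selects proteins detected in at least `min_samples` plasma exosome
#' samples whose particle-normalized case/control mean MS1 intensity ratio
#' strictly exceeds `fold`. Proteins unique to cases (infinite ratio)
#' qualify. Requires particle-normalized intensities (see
#' [normalize_by_particles()]).
#'
#' @param intensities [ion_intensities()] normalized by particle counts.
#' @param min_samples Detection rule: observed (> 0) in at least this many
#'   samples (default 2).
#' @param fold Elevation threshold (strict; default 2.5).
#' @return List with `ids`, `report` (a [cascade_report()]) and
#'   `fold_changes` (per-protein data.frame).
#' @export
plasma_exosome_elevation <- function(intensities, min_samples = 2,
                                     fold = 2.5) {
  stopifnot(inherits(intensities, "ion_intensities"))
  if (!isTRUE(intensities$normalized))
    stop("intensities are not particle-normalized; ",
         "run normalize_by_particles() first", call. = FALSE)
  grp <- intensities$groups
  if (sum(grp == "case") < 2 || sum(grp == "control") < 2)
    stop("need at least two case and two control samples", call. = FALSE)
  mat <- intensities$intensity
  rep_ <- cascade_report("plasma exosome elevation",
                         universe = rownames(mat))
  detected <- rownames(mat)[rowSums(mat > 0) >= min_samples]
  rep_ <- add_cascade_stage(rep_, "detection",
                            sprintf("observed in >= %d samples", min_samples),
                            min_samples, rownames(mat), detected)
  fc <- row_fold_changes(mat[detected, , drop = FALSE], grp == "case")
  keep <- fc$protein_id[ratio_passes(fc$ratio, fold, inclusive = FALSE)]
  rep_ <- add_cascade_stage(rep_, "elevation",
                            sprintf("case/control mean ratio > %g (Inf passes)",
                                    fold),
                            fold, detected, keep)
  list(ids = keep, report = rep_, fold_changes = fc)
}

#' Marker-panel quality control for exosome preparations
#'
#' Compares the per-marker average counts between exosome compartments and
#' cellular compartments with a one-sided rank test. QC passes when the
#' exosome marker panel is significantly enriched in the exosome
#' compartments while the depleted panel is not.
#'
#' @param x [spectral_counts()] with `compartment` annotation.
#' @param markers Exosome marker symbols (default packaged panel).
#' @param depleted Depleted-control symbols (default packaged panel).
#' @param exosome_compartments,cell_compartments Compartment groupings.
#' @param alpha Significance level (default 0.05).
#' @return List of class `marker_qc` with per-panel test results, missing
#'   symbols, and a logical `pass`.
#' @export
marker_qc <- function(x, markers = exosome_markers(),
                      depleted = depleted_markers(),
                      exosome_compartments = c("TEE", "exo_surface",
                                               "exo_cargo"),
                      cell_compartments = c("TCE", "cell_surface"),
                      alpha = 0.05) {
  stopifnot(inherits(x, "spectral_counts"))
  if (!length(markers)) stop("marker set is empty", call. = FALSE)
  comp <- x$samples$compartment
  mat <- x$counts
  exo_cols <- comp %in% exosome_compartments
  cell_cols <- comp %in% cell_compartments
  if (!any(exo_cols) || !any(cell_cols))
    stop("compartment groupings not found in the data", call. = FALSE)

  panel <- function(symbols) {
    present <- intersect(symbols, rownames(mat))
    missing <- setdiff(symbols, rownames(mat))
    if (!length(present))
      return(list(present = present, missing = missing, test = NULL))
    exo_means <- rowMeans(mat[present, exo_cols, drop = FALSE])
    cell_means <- rowMeans(mat[present, cell_cols, drop = FALSE])
    test <- mann_whitney(exo_means, cell_means, alternative = "greater")
    list(present = present, missing = missing,
         exo_means = exo_means, cell_means = cell_means, test = test)
  }
  mk <- panel(markers)
  dp <- panel(depleted)
  if (is.null(mk$test))
    stop("QC failure: no marker found in data (missing: ",
         paste(mk$missing, collapse = ", "), ")", call. = FALSE)
  pass <- mk$test$p_value < alpha &&
    (is.null(dp$test) || dp$test$p_value >= alpha)
  structure(list(markers = mk, depleted = dp, alpha = alpha, pass = pass),
            class = "marker_qc")
}

#' @export
print.marker_qc <- function(x, ...) {
  cat(sprintf("marker QC: %s\n", if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  exosome markers (n=%d): one-sided p = %.3g\n",
              length(x$markers$present), x$markers$test$p_value))
  if (!is.null(x$depleted$test))
    cat(sprintf("  depleted panel (n=%d): one-sided p = %.3g\n",
                length(x$depleted$present), x$depleted$test$p_value))
  if (length(x$markers$missing))
    cat("  missing markers:", paste(x$markers$missing, collapse = ", "), "\n")
  invisible(x)
}
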