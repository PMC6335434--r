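#' Standardize and merge multi-set serology data
#'
#' Array sets run in different batches/cohorts have arbitrary location and
#' scale. For each set and antigen, intensities are standardized to the
#' healthy controls of that set (subtract their mean, divide by their
#' sample standard deviation), after which the sets are merged on a common
#' scale where healthy controls have mean 0 and SD 1.
#'
#' @param data Long-form data.frame with columns `antigen_id, sample_id,
#'   intensity, set, group`. Group labels must include the control group.
#' @param control_group Group defining the standardization reference
#'   (default `"healthy"`).
#' @return The merged data.frame with an additional `standardized` column
#'   (labels preserved).
#' @export
standardize_and_merge_sets <- function(data, control_group = "healthy") {
  need <- c("antigen_id", "sample_id", "intensity", "set", "group")
  if (!all(need %in% names(data)))
    stop("`data` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(data$intensity)))
    stop("intensities must be finite", call. = FALSE)
  data$standardized <- NA_real_
  for (s in unique(data$set)) {
    in_set <- data$set == s
    ctrl <- in_set & data$group == control_group
    if (!any(ctrl))
      stop("set `", s, "` has no ", control_group, " controls", call. = FALSE)
    for (a in unique(data$antigen_id[in_set])) {
      sel <- in_set & data$antigen_id == a
      v <- data$intensity[sel & data$group == control_group]
      if (length(v) < 2L)
        stop("antigen `", a, "` in set `", s,
             "` has fewer than 2 controls", call. = FALSE)
      sdv <- stats::sd(v)
      if (sdv == 0)
        stop("zero control variance for antigen `", a, "` in set `", s, "`",
             call. = FALSE)
      data$standardized[sel] <- (data$intensity[sel] - mean(v)) / sdv
    }
  }
  data
}

#' ROC analysis of an antigen score
#'
#' Area under the ROC curve with cases-higher orientation (AUC < 0.5
#' means controls score higher), computed as the Mann-Whitney
#' probabilistic index U / (n1 * n2) — identical to trapezoidal
#' integration of the empirical ROC curve. The 95% confidence interval is
#' DeLong's by default (seeded stratified bootstrap optional); the
#' p-value against AUC = 0.5 comes from the Mann-Whitney test.
#'
#' @param scores Numeric vector.
#' @param labels Vector of class labels.
#' @param positive Label of the case class (default `"case"`).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_n Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap CI.
#' @param alternative Sidedness of the Mann-Whitney p (default
#'   two-sided).
#' @return List of class `roc_result`: `auc`, `ci` (length-2), `p_value`,
#'   `n_case`, `n_control`.
#' @export
roc_analysis <- function(scores, labels, positive = "case",
                         ci_method = c("delong", "bootstrap"),
                         boot_n = 2000, seed = 1,
                         alternative = "two.sided") {
  ci_method <- match.arg(ci_method)
  labels <- as.character(labels)
  if (!positive %in% labels || all(labels == positive))
    stop("both classes must be present", call. = FALSE)
  cases <- scores[labels == positive]
  controls <- scores[labels != positive]
  mw <- mann_whitney(cases, controls, alternative = alternative)
  roc <- suppressMessages(pROC::roc(
    response = factor(labels == positive, levels = c(FALSE, TRUE)),
    predictor = scores, direction = "<", quiet = TRUE))
  ci <- if (ci_method == "delong") {
    as.numeric(pROC::ci.auc(roc, method = "delong"))[c(1, 3)]
  } else {
    set.seed(seed)
    as.numeric(pROC::ci.auc(roc, method = "bootstrap",
                            boot.n = boot_n, progress = "none"))[c(1, 3)]
  }
  ci <- pmin(pmax(ci, 0), 1)
  auc <- as.numeric(pROC::auc(roc))  # trapezoidal; equals U/(n1*n2)
  structure(list(auc = auc, ci = ci, p_value = mw$p_value,
                 n_case = length(cases), n_control = length(controls)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), p = %.3g (%d cases, %d controls)\n",
              x$auc, x$ci[1], x$ci[2], x$p_value, x$n_case, x$n_control))
  invisible(x)
}

#' Per-antigen group testing on merged serology data
#'
#' Mann-Whitney comparison of standardized case versus control scores per
#' antigen, with AUC and Benjamini-Hochberg FDR across antigens.
#'
#' @param merged Output of [standardize_and_merge_sets()].
#' @param case_group,control_group Group labels to compare.
#' @param alternative Sidedness (default two-sided).
#' @return data.frame `antigen_id, auc, p, fdr`, ordered by p.
#' @export
serology_antigen_tests <- function(merged, case_group = "case",
                                   control_group = "healthy",
                                   alternative = "two.sided") {
  if (!"standardized" %in% names(merged))
    stop("run standardize_and_merge_sets() first", call. = FALSE)
  antigens <- unique(merged$antigen_id)
  rows <- lapply(antigens, function(a) {
    d <- merged[merged$antigen_id == a, ]
    mw <- mann_whitney(d$standardized[d$group == case_group],
                       d$standardized[d$group == control_group],
                       alternative = alternative)
    data.frame(antigen_id = a, auc = mw$auc, p = mw$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out[order(out$p), ]
}

#' Bead-based (Luminex) autoantibody score
#'
#' Computes the exosome-bead reactivity score
#' `log2(MFI_exosome / MFI_uncoated)` together with the anti-Ig-normalized
#' intermediates. Normalizing both the exosome-coupled and the uncoated
#' bead MFI to the anti-human-Ig bead MFI cancels algebraically in the
#' ratio, so the anti-Ig channel is retained as a QC column rather than
#' affecting the score.
#'
#' @param panel data.frame with columns `sample_id`, `mfi_exosome`,
#'   `mfi_uncoated`, `mfi_anti_ig` (and optionally `group`).
#' @return data.frame with `exo_over_ig`, `uncoated_over_ig` (QC
#'   intermediates) and `score` = log2(mfi_exosome / mfi_uncoated).
#' @export
luminex_score <- function(panel) {
  need <- c("sample_id", "mfi_exosome", "mfi_uncoated", "mfi_anti_ig")
  if (!all(need %in% names(panel)))
    stop("`panel` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(panel$mfi_uncoated <= 0) || any(panel$mfi_anti_ig <= 0))
    stop("uncoated and anti-Ig MFIs must be positive", call. = FALSE)
  if (any(panel$mfi_exosome < 0))
    stop("MFIs must be non-negative", call. = FALSE)
  out <- panel
  out$exo_over_ig <- panel$mfi_exosome / panel$mfi_anti_ig
  out$uncoated_over_ig <- panel$mfi_uncoated / panel$mfi_anti_ig
  out$score <- log2(out$exo_over_ig / out$uncoated_over_ig)
  out
}
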