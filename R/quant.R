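#' Quantile normalization of a count or intensity matrix
#'
#' Forces every column to share the same distribution: the reference
#' distribution is the vector of row-wise means of the column-sorted
#' input, and each column's values are replaced by the reference value at
#' their rank. With `ties = "average"` (the default, matching the usual
#' behavior of quantile normalization in expression analysis), tied values
#' within a column all receive the mean of the reference values their rank
#' positions span; with `ties = "first"` ties are broken by position so
#' that every column's multiset of values equals the reference exactly.
#'
#' The operation preserves within-column rank order and is idempotent.
#'
#' @param x Numeric matrix (proteins x samples) or a [spectral_counts()]
#'   object, in which case the counts slot is normalized in place.
#' @param ties `"average"` or `"first"` (see above).
#' @return Object of the same type as `x` with normalized values; row and
#'   column order unchanged.
#' @export
quantile_normalize <- function(x, ties = c("average", "first")) {
  ties <- match.arg(ties)
  if (inherits(x, "spectral_counts")) {
    x$counts <- quantile_normalize(x$counts, ties = ties)
    return(x)
  }
  x <- as.matrix(x)
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("cannot quantile-normalize an empty matrix", call. = FALSE)
  if (ncol(x) == 1L) {
    warning("single-column matrix returned unchanged", call. = FALSE)
    return(x)
  }
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- ref[rank(x[, j], ties.method = "first")]
    if (ties == "average") v <- stats::ave(v, x[, j], FUN = mean)
    out[, j] <- v
  }
  out
}

#' Count nanoparticles in a diameter window
#'
#' Counts, per sample, the tracked particle diameters falling inside the
#' closed window `[low_nm, high_nm]` — by default the 30-200 nm window
#' used to quantify exosome-sized vesicles from nanoparticle tracking.
#'
#' @param particles data.frame with columns `sample_id` and `diameter_nm`
#'   (one row per tracked particle).
#' @param low_nm,high_nm Window bounds in nm; `0 < low_nm < high_nm`;
#'   boundary diameters are counted (closed interval).
#' @return Named integer vector of per-sample window counts; samples with
#'   no in-window particles report 0.
#' @export
count_particles_in_window <- function(particles, low_nm = 30, high_nm = 200) {
  if (!all(c("sample_id", "diameter_nm") %in% names(particles)))
    stop("`particles` needs columns sample_id and diameter_nm", call. = FALSE)
  if (!(low_nm > 0 && high_nm > low_nm))
    stop("invalid window: need 0 < low_nm < high_nm", call. = FALSE)
  ids <- unique(as.character(particles$sample_id))
  inside <- particles$diameter_nm >= low_nm & particles$diameter_nm <= high_nm
  counts <- table(factor(particles$sample_id[inside], levels = ids))
  stats::setNames(as.integer(counts), ids)
}

#' Normalize MS1 intensities by per-sample particle counts
#'
#' Divides each sample's intensities by that sample's particle count
#' (typically the 30-200 nm window count from
#' [count_particles_in_window()]), putting samples on a per-exosome scale.
#' Within-sample ratios are unchanged.
#'
#' @param intensities An [ion_intensities()] object or numeric matrix.
#' @param counts Named numeric vector of positive per-sample particle
#'   counts covering every intensity sample.
#' @return Object of the same type with normalized intensities.
#' @export
normalize_by_particles <- function(intensities, counts) {
  mat <- if (inherits(intensities, "ion_intensities"))
    intensities$intensity else as.matrix(intensities)
  missing <- setdiff(colnames(mat), names(counts))
  if (length(missing))
    stop("no particle count for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  cc <- counts[colnames(mat)]
  bad <- names(cc)[!is.finite(cc) | cc <= 0]
  if (length(bad))
    stop("non-positive particle count for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  mat <- sweep(mat, 2L, cc, "/")
  if (inherits(intensities, "ion_intensities")) {
    intensities$intensity <- mat
    intensities$normalized <- TRUE
    intensities
  } else mat
}

#' Case/control fold change with explicit infinite and undefined sentinels
#'
#' Compares arithmetic group means. A protein observed in cases but absent
#' from all controls has an infinite ratio (reported as `Inf`, the
#' "unique to cases" convention: such a protein is maximally elevated and
#' passes any fold threshold); a protein absent from both groups is
#' undefined (`NaN`) and is excluded from ranking. No pseudocount is
#' applied unless requested.
#'
#' @param case,control Numeric vectors of non-negative values; both
#'   non-empty.
#' @param pseudocount Optional constant added to both means before the
#'   ratio (default 0, i.e. off).
#' @return List with `case_mean`, `control_mean`, `ratio` and `status`
#'   (`"finite"`, `"inf"` or `"undefined"`).
#' @export
fold_change <- function(case, control, pseudocount = 0) {
  if (length(case) < 1L || length(control) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  cm <- mean(case) + pseudocount
  km <- mean(control) + pseudocount
  ratio <- if (km > 0) cm / km else if (cm > 0) Inf else NaN
  status <- if (is.nan(ratio)) "undefined" else
    if (is.infinite(ratio)) "inf" else "finite"
  list(case_mean = cm, control_mean = km, ratio = ratio, status = status)
}

# Row-wise fold changes for a matrix split into case/control columns.
# Returns a data.frame (protein_id, case_mean, control_mean, ratio, status).
row_fold_changes <- function(mat, is_case) {
  cm <- rowMeans(mat[, is_case, drop = FALSE])
  km <- rowMeans(mat[, !is_case, drop = FALSE])
  ratio <- ifelse(km > 0, cm / km, ifelse(cm > 0, Inf, NaN))
  status <- ifelse(is.nan(ratio), "undefined",
                   ifelse(is.infinite(ratio), "inf", "finite"))
  data.frame(protein_id = rownames(mat), case_mean = cm, control_mean = km,
             ratio = ratio, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

# A fold-threshold test where Inf always qualifies and NaN never does.
ratio_passes <- function(ratio, fold, inclusive = FALSE) {
  ok <- if (inclusive) ratio >= fold else ratio > fold
  ok & !is.nan(ratio)
}
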