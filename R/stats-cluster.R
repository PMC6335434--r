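#' Correlation-based complete-linkage hierarchical clustering
#'
#' Clusters the rows of a matrix with distance `1 - Pearson correlation`
#' and complete linkage, the standard layout for proteomic heatmaps.
#' Identical rows merge at height 0; perfectly anti-correlated rows are at
#' distance 2. Ties are broken deterministically by input order (the
#' agglomeration of [stats::hclust()]).
#'
#' @param x Numeric matrix with at least 2 rows; every row must have
#'   positive variance (a constant row has no defined correlation).
#' @return An object of class `hclust` (merge history, heights, leaf
#'   order).
#' @export
correlation_cluster <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    stop("need at least two rows to cluster", call. = FALSE)
  vars <- apply(x, 1L, stats::var)
  if (any(vars == 0)) {
    bad <- rownames(x)[vars == 0]
    if (is.null(bad)) bad <- which(vars == 0)
    stop("constant row(s) cannot be correlated: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(t(x)))
  stats::hclust(d, method = "complete")
}
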