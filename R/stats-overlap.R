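#' Hypergeometric significance of a gene-set overlap
#'
#' Upper-tail (inclusive) hypergeometric test for the overlap of two gene
#' sets drawn from a common universe: the probability of observing an
#' overlap at least as large as `k` between a set of size `K` and a set of
#' size `n` in a universe of `N` genes, plus the representation factor
#' (observed / expected overlap, `k * N / (K * n)`). The default universe
#' of 17,611 genes is the genome-wide protein-coding background commonly
#' used by overlap calculators.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K,n The two set sizes (both <= N).
#' @param N Universe size (default 17611).
#' @return List of class `overlap_result`: `k, K, n, N, p_upper,
#'   representation_factor, expected`.
#' @export
hypergeometric_overlap <- function(k, K, n, N = 17611) {
  for (v in list(k, K, n, N))
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v))
      stop("k, K, n, N must be non-negative integers", call. = FALSE)
  if (K > N || n > N)
    stop("set sizes cannot exceed the universe", call. = FALSE)
  if (k > min(K, n))
    stop("overlap cannot exceed the smaller set", call. = FALSE)
  p <- if (k == 0) 1 else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(k = k, K = K, n = n, N = N,
                 p_upper = p,
                 representation_factor = ifelse(K * n > 0, k * N / (K * n),
                                                NaN),
                 expected = K * n / N),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap %d of sets %d and %d (universe %d): p = %.3g, RF = %.2f (expected %.1f)\n",
    x$k, x$K, x$n, x$N, x$p_upper, x$representation_factor, x$expected))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-values use the point-probability criterion (summing all
#' tables with the same margins whose probability does not exceed the
#' observed table's), the most common convention.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `p_value`, `odds_ratio` (conditional MLE) and
#'   `alternative`.
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == 2L) || any(table < 0) ||
      any(table != round(table)))
    stop("`table` must be a 2x2 matrix of non-negative integers",
         call. = FALSE)
  if (sum(table) == 0)
    stop("all-zero table has no defined test", call. = FALSE)
  ft <- stats::fisher.test(table, alternative = alternative)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       alternative = alternative)
}

#' Annotation-set enrichment by hypergeometric overlap
#'
#' Tests a query gene set against each annotation term (for example GMT
#' localization or pathway sets) with [hypergeometric_overlap()] and
#' adjusts across terms by Benjamini-Hochberg.
#'
#' @param query Character vector of gene identifiers.
#' @param sets Named list of character vectors (annotation terms). Genes
#'   outside the universe are dropped with a warning.
#' @param universe Either an integer universe size `N` (query and term
#'   sizes are used as given) or a character vector enumerating the
#'   universe (sets and query are intersected with it).
#' @return data.frame with columns `term, k, K, n, p, fdr,
#'   representation_factor`, ordered by p.
#' @export
annotation_set_enrichment <- function(query, sets, universe = 17611) {
  if (!length(query)) stop("empty query set", call. = FALSE)
  if (!is.list(sets) || is.null(names(sets)))
    stop("`sets` must be a named list of gene vectors", call. = FALSE)
  query <- unique(as.character(query))
  if (is.character(universe)) {
    N <- length(unique(universe))
    drop <- setdiff(query, universe)
    if (length(drop))
      warning(length(drop), " query gene(s) outside the universe dropped",
              call. = FALSE)
    query <- intersect(query, universe)
    sets <- lapply(sets, intersect, y = universe)
  } else {
    N <- as.integer(universe)
  }
  rows <- lapply(names(sets), function(tm) {
    term_genes <- unique(sets[[tm]])
    ov <- hypergeometric_overlap(length(intersect(query, term_genes)),
                                 length(query), length(term_genes), N)
    data.frame(term = tm, k = ov$k, K = ov$K, n = ov$n, p = ov$p_upper,
               representation_factor = ov$representation_factor,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out[order(out$p), c("term", "k", "K", "n", "p", "fdr",
                      "representation_factor")]
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (term, description,
#'   genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
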