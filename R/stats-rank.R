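#' Mann-Whitney rank test with AUC
#'
#' Rank-sum comparison of two groups reporting the U statistic, the
#' probabilistic index AUC = U / (n1 * n2) (the probability that a random
#' group-1 value exceeds a random group-2 value, ties counting half — the
#' ROC area when group 1 are cases), and a p-value. For small samples
#' (both groups of at most `exact_max` values) the p-value is exact, by
#' enumeration of all group assignments of the pooled values, which is
#' correct in the presence of ties; otherwise the normal approximation
#' with tie and continuity correction is used.
#'
#' @param x,y Numeric vectors (group 1, group 2); both non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` (group 1
#'   stochastically larger) or `"less"`.
#' @param exact_max Largest per-group size for exact enumeration
#'   (default 8).
#' @return List of class `rank_test`: `U`, `auc`, `p_value`, `n1`, `n2`,
#'   `method` (`"exact"` or `"normal"`), `alternative`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater",
                                               "less"),
                         exact_max = 8) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  U <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n2)

  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n1 + n2, n1)
    r <- rank(pooled)
    us <- apply(combs, 2L, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- switch(alternative,
                two.sided = mean(abs(us - mu) >= abs(U - mu) - 1e-12),
                greater = mean(us >= U - 1e-12),
                less = mean(us <= U + 1e-12))
    method <- "exact"
  } else {
    N <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      mu <- n1 * n2 / 2
      cc <- 0.5  # continuity correction
      z <- switch(alternative,
                  two.sided = (abs(U - mu) - cc) / sqrt(sigma2),
                  greater = (U - mu - cc) / sqrt(sigma2),
                  less = -(U - mu + cc) / sqrt(sigma2))
      p <- if (alternative == "two.sided")
        2 * stats::pnorm(max(z, 0), lower.tail = FALSE)
      else stats::pnorm(z, lower.tail = FALSE)
      p <- min(p, 1)
    }
    method <- "normal"
  }
  structure(list(U = U, auc = auc, p_value = p, n1 = n1, n2 = n2,
                 method = method, alternative = alternative),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s, %s): U = %g, AUC = %.3f, p = %.4g\n",
              x$method, x$alternative, x$U, x$auc, x$p_value))
  invisible(x)
}

#' Unpaired t-test (Welch by default)
#'
#' Thin wrapper around the two-sample t-test with the degenerate-input
#' convention used throughout the pipeline: when both groups have zero
#' variance and equal means the p-value is 1 (no evidence of a
#' difference) instead of an error.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (direction of
#'   group 1 relative to group 2).
#' @param var_equal Pooled-variance form if `TRUE`; Welch otherwise.
#' @return List with `p_value`, `statistic`, `estimate` (mean difference),
#'   `alternative`.
#' @export
t_test_unpaired <- function(x, y, alternative = c("two.sided", "greater",
                                                  "less"),
                            var_equal = FALSE) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(p_value = 1, statistic = 0,
                  estimate = 0, alternative = alternative))
    # constant groups with different means: difference is exact
    return(list(p_value = 0, statistic = sign(mean(x) - mean(y)) * Inf,
                estimate = mean(x) - mean(y), alternative = alternative))
  }
  tt <- stats::t.test(x, y, alternative = alternative,
                      var.equal = var_equal)
  list(p_value = tt$p.value, statistic = unname(tt$statistic),
       estimate = unname(diff(rev(tt$estimate))),
       alternative = alternative)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control; monotone in the input and capped
#' at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
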