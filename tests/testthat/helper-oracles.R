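# Independent oracles used across tests. These deliberately use brute-force
# enumeration / direct geometry, never the package's own code paths.

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# C(N, n) draws of n items from a universe with K marked items.
enum_hypergeom_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Two-sided Fisher p by enumeration over all tables with the observed
# margins, summing probabilities <= the observed table's (point-probability
# criterion).
enum_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a)
    stats::dhyper(a, r1, r2, c1), 0)
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs + 1e-12])
}

# ROC area by explicit trapezoidal integration over score thresholds.
trapezoid_auc <- function(scores, labels, positive = "case") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(pos >= t), 0))
  fpr <- c(0, vapply(th, function(t) mean(neg >= t), 0))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Brute-force Mann-Whitney U by pair counting (ties count half).
pair_count_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# A small, fast simulation configuration for structural tests.
quick_config <- function(...) {
  sim_config(n_proteins = 60, n_planted_antigens = 5, n_unique_case = 2,
             n_case_pools = 3, n_control_pools = 3,
             n_tracks_per_sample = 100,
             serology_sets = list(set1 = c(case = 5, healthy = 5),
                                  set2 = c(case = 6, healthy = 6),
                                  set3 = c(case = 4, healthy = 4,
                                           pancreatitis = 3)),
             n_null_antigens = 5, ...)
}
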