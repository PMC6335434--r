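test_that("hypergeometric overlap matches exhaustive enumeration", {
  # hand-checkable case: (k=3, K=4, n=5, N=10) -> 66/252
  ov <- hypergeometric_overlap(3, 4, 5, 10)
  expect_equal(ov$p_upper, enum_hypergeom_upper(3, 4, 5, 10),
               tolerance = 1e-12)
  expect_equal(ov$p_upper, 66 / 252, tolerance = 1e-12)
  # sweep all configurations in small universes
  for (N in c(6, 9, 12)) {
    for (n in 1:N) {
      draws <- utils::combn(N, n)
      for (K in 1:N) {
        hits <- apply(draws, 2L, function(d) sum(d <= K))
        for (k in 0:min(K, n))
          expect_equal(hypergeometric_overlap(k, K, n, N)$p_upper,
                       mean(hits >= k), tolerance = 1e-12)
      }
    }
  }
})

test_that("hypergeometric overlap handles tails, errors and the RF formula", {
  expect_equal(hypergeometric_overlap(0, 50, 80, 1000)$p_upper, 1)
  expect_error(hypergeometric_overlap(6, 5, 10, 20), "smaller set")
  expect_error(hypergeometric_overlap(1, 30, 10, 20), "universe")
  ov <- hypergeometric_overlap(19, 92, 1097, 17611)
  expect_equal(ov$representation_factor, 19 * 17611 / (92 * 1097))
  # deep upper tail does not underflow
  deep <- hypergeometric_overlap(80, 100, 100, 17611)
  expect_gt(deep$p_upper, 0)
  expect_lt(deep$p_upper, 1e-100)
})

test_that("Fisher's exact test matches the margin-conditional enumeration", {
  tab <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact(tab)$p_value, enum_fisher_two_sided(tab),
               tolerance = 1e-12)
  expect_equal(fisher_exact(tab)$p_value, 34 / 70, tolerance = 1e-12)
  # maximally unbalanced table attains the minimal two-sided p = 2/C(2n, n)
  for (n in c(3, 5)) {
    tab2 <- matrix(c(0, n, n, 0), 2, byrow = TRUE)
    expect_equal(fisher_exact(tab2)$p_value, 2 / choose(2 * n, n),
                 tolerance = 1e-12)
  }
  # identical rows carry no association
  expect_equal(fisher_exact(matrix(c(4, 6, 4, 6), 2, byrow = TRUE))$p_value, 1)
  expect_error(fisher_exact(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("Mann-Whitney U, AUC and exact p match brute-force oracles", {
  x <- c(2, 4); y <- c(1, 3)
  mw <- mann_whitney(x, y)
  expect_equal(mw$U, pair_count_u(x, y))
  expect_equal(mw$U, 3)
  expect_equal(mw$auc, 0.75)
  expect_equal(mw$method, "exact")
  # perfect separation
  expect_equal(mann_whitney(c(0.9, 0.8, 0.7), c(0.6, 0.5))$auc, 1.0)
  # complete separation at n = 7 vs 7 attains the minimal one-sided p
  mw7 <- mann_whitney(8:14, 1:7, alternative = "greater")
  expect_equal(mw7$p_value, 1 / choose(14, 7), tolerance = 1e-12)
  # identical groups: AUC 1/2, two-sided p 1 (exact even with ties)
  mwt <- mann_whitney(c(1, 1, 2), c(1, 1, 2))
  expect_equal(mwt$auc, 0.5)
  expect_equal(mwt$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney symmetry and agreement with wilcox.test", {
  set.seed(5)
  for (i in 1:20) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    x <- round(rnorm(n1), 1); y <- round(rnorm(n2), 1)  # ties likely
    a <- mann_whitney(x, y); b <- mann_whitney(y, x)
    expect_equal(a$auc, 1 - b$auc, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(a$U, pair_count_u(x, y))
    if (a$method == "normal") {
      ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                 correct = TRUE))
      expect_equal(a$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
  # tie-free exact case agrees with wilcox.test's exact distribution
  x <- c(1.1, 2.3, 5.7, 0.2); y <- c(3.1, 4.4, 0.9)
  expect_equal(mann_whitney(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("unpaired t-test conventions and calibration hold", {
  expect_equal(t_test_unpaired(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_equal(t_test_unpaired(c(3, 3), c(2, 2))$p_value, 0)
  # one-sided p is half the two-sided p in the stated direction
  x <- c(5, 6, 7, 8); y <- c(1, 2, 3, 4)
  expect_equal(t_test_unpaired(x, y, "greater", var_equal = TRUE)$p_value,
               t_test_unpaired(x, y, var_equal = TRUE)$p_value / 2,
               tolerance = 1e-12)
  expect_error(t_test_unpaired(1, c(1, 2)), "at least 2")
  # null calibration: rejection rate at alpha = 0.05 inside binomial 99% CI
  set.seed(42)
  rej <- mean(replicate(400, {
    t_test_unpaired(rnorm(6), rnorm(6))$p_value < 0.05
  }))
  ci <- qbinom(c(0.005, 0.995), 400, 0.05) / 400
  expect_gte(rej, ci[1]); expect_lte(rej, ci[2])
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(3)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("correlation clustering uses 1 - r with complete linkage", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  hc <- correlation_cluster(m)
  # identical-profile rows merge first at height 0
  expect_equal(hc$merge[1, ], c(-1, -2))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  # anti-correlated rows sit at distance 2 (complete linkage keeps the max)
  expect_equal(hc$height[2], 2, tolerance = 1e-12)
  # column permutation leaves merge heights unchanged
  hc2 <- correlation_cluster(m[, c(3, 1, 4, 2)])
  expect_equal(hc2$height, hc$height, tolerance = 1e-12)
  expect_error(correlation_cluster(rbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "a")
  expect_error(correlation_cluster(m[1, , drop = FALSE]), "two rows")
})

test_that("annotation-set enrichment matches the per-term oracle", {
  universe <- letters[1:10]
  sets <- list(T1 = c("a", "b", "c", "d"), T2 = c("h", "i", "j"))
  query <- c("a", "b", "c", "e", "f")
  res <- annotation_set_enrichment(query, sets, universe)
  expect_equal(res$p[res$term == "T1"],
               enum_hypergeom_upper(3, 5, 4, 10), tolerance = 1e-12)
  expect_equal(res$p[res$term == "T2"],
               enum_hypergeom_upper(0, 5, 3, 10), tolerance = 1e-12)
  expect_equal(res$p[res$term == "T2"], 1)   # disjoint term
  expect_equal(res$fdr, bh_fdr(res$p))
  # query equal to a term makes that term most significant
  res2 <- annotation_set_enrichment(sets$T1, sets, universe)
  expect_equal(res2$term[1], "T1")
  expect_error(annotation_set_enrichment(character(0), sets, universe),
               "empty")
})

test_that("GMT round trip preserves gene sets", {
  tmp <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tA\tB\tC", "T2\tdesc\tX\tY"), tmp)
  sets <- read_gmt(tmp)
  expect_equal(sets$T1, c("A", "B", "C"))
  expect_equal(sets$T2, c("X", "Y"))
})
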