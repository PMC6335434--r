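long_set <- function(antigen, values, groups, set = "set1") {
  data.frame(antigen_id = antigen,
             sample_id = sprintf("%s_%02d", set, seq_along(values)),
             intensity = values, set = set, group = groups)
}

test_that("control standardization matches the hand-computed example", {
  d <- long_set("AG1", c(8, 10, 12, 14),
                c("healthy", "healthy", "healthy", "case"))
  out <- standardize_and_merge_sets(d)
  # controls: mean 10, sample SD 2 -> case value 14 standardizes to 2.0
  expect_equal(out$standardized[out$group == "case"], 2.0)
  expect_equal(mean(out$standardized[out$group == "healthy"]), 0,
               tolerance = 1e-12)
  # already standardized controls pass through unchanged
  d2 <- long_set("AG1", c(-1, 0, 1, 2.5),
                 c("healthy", "healthy", "healthy", "case"))
  out2 <- standardize_and_merge_sets(d2)
  expect_equal(out2$standardized, d2$intensity, tolerance = 1e-12)
})

test_that("standardization errors are specific", {
  d <- long_set("AG1", c(5, 5, 9), c("healthy", "healthy", "case"))
  expect_error(standardize_and_merge_sets(d), "zero control variance")
  d1 <- long_set("AG1", c(5, 9), c("healthy", "case"))
  expect_error(standardize_and_merge_sets(d1), "fewer than 2 controls")
  d3 <- long_set("AG1", c(5, 6, 9), c("sick", "sick", "case"))
  expect_error(standardize_and_merge_sets(d3), "no healthy controls")
})

test_that("merged sets leave per-set controls at mean 0 and SD 1", {
  merged <- standardize_and_merge_sets(
    simulate_serology(quick_config(seed = 51)))
  for (s in unique(merged$set)) {
    for (a in unique(merged$antigen_id)) {
      v <- merged$standardized[merged$set == s & merged$antigen_id == a &
                                 merged$group == "healthy"]
      expect_equal(mean(v), 0, tolerance = 1e-12)
      expect_equal(sd(v), 1, tolerance = 1e-12)
    }
  }
})

test_that("standardization is affine-invariant per set", {
  d <- simulate_serology(quick_config(seed = 52))
  out1 <- standardize_and_merge_sets(d)
  d2 <- d
  d2$intensity[d2$set == "set2"] <- -3 * d2$intensity[d2$set == "set2"] + 40
  out2 <- standardize_and_merge_sets(d2)
  keep <- out1$set != "set2"
  expect_equal(out1$standardized[keep], out2$standardized[keep],
               tolerance = 1e-10)
  # a negative scale flips the sign but keeps the magnitude
  expect_equal(abs(out1$standardized[!keep]), abs(out2$standardized[!keep]),
               tolerance = 1e-10)
})

test_that("ROC AUC equals the rank-based probabilistic index", {
  scores <- c(2, 4, 1, 3)
  labels <- c("case", "case", "control", "control")
  roc <- roc_analysis(scores, labels)
  expect_equal(roc$auc, 0.75)
  expect_equal(roc$auc, mann_whitney(c(2, 4), c(1, 3))$auc,
               tolerance = 1e-12)
  expect_equal(roc$auc, trapezoid_auc(scores, labels), tolerance = 1e-12)
  # perfect separation; label inversion maps AUC to 1 - AUC
  expect_equal(suppressWarnings(roc_analysis(c(5, 6, 1, 2), labels))$auc,
               1.0)  # pROC flags the degenerate CI at AUC == 1
  flipped <- ifelse(labels == "case", "control", "case")
  expect_equal(roc_analysis(scores, flipped)$auc, 0.25, tolerance = 1e-12)
  expect_error(roc_analysis(scores, rep("case", 4)), "both classes")
  # CI brackets the AUC
  set.seed(14)
  sc <- c(rnorm(20, 1), rnorm(20))
  lb <- rep(c("case", "control"), each = 20)
  r <- roc_analysis(sc, lb)
  expect_lte(r$ci[1], r$auc); expect_gte(r$ci[2], r$auc)
})

test_that("AUC equals U/(n1 n2) on random tied score sets", {
  set.seed(6)
  for (i in 1:30) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    scores <- round(c(rnorm(n1, 0.5), rnorm(n2)), 1)
    labels <- rep(c("case", "control"), c(n1, n2))
    mw <- mann_whitney(scores[labels == "case"],
                       scores[labels == "control"])
    expect_equal(trapezoid_auc(scores, labels), mw$U / (n1 * n2),
                 tolerance = 1e-12)
    expect_equal(roc_analysis(scores, labels)$auc, mw$auc,
                 tolerance = 1e-12)
  }
})

test_that("planted serology effects yield high AUCs after merging", {
  tests <- serology_antigen_tests(standardize_and_merge_sets(
    simulate_serology(quick_config(seed = 53, serology_effect = 2))))
  planted <- !startsWith(tests$antigen_id, "NULL")
  expect_gte(mean(tests$auc[planted]), 0.85)
  expect_lt(mean(tests$auc[!planted]), 0.75)
})

test_that("Luminex scoring cancels the anti-Ig factor", {
  panel <- data.frame(sample_id = c("s1", "s2"),
                      mfi_exosome = c(3200, 3200),
                      mfi_uncoated = c(100, 100),
                      mfi_anti_ig = c(500, 1000))
  out <- luminex_score(panel)
  expect_equal(out$score, c(5, 5))           # log2(32), anti-Ig cancels
  expect_equal(out$exo_over_ig, c(6.4, 3.2)) # QC intermediate retained
  expect_error(luminex_score(transform(panel, mfi_uncoated = 0)), "positive")
  expect_error(luminex_score(transform(panel, mfi_anti_ig = 0)), "positive")
})
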