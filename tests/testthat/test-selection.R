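make_counts <- function(mat, compartment = NULL, group = NULL, line = NULL) {
  ann <- data.frame(sample_id = colnames(mat))
  if (!is.null(compartment)) ann$compartment <- compartment
  if (!is.null(group)) ann$group <- group
  if (!is.null(line)) ann$line <- line
  spectral_counts(mat, ann)
}

test_that("detection thresholds are applied with exact boundary semantics", {
  m <- rbind(a = 5, b = 4.99)
  colnames(m) <- "s1"
  sel <- select_detected(m, min_count = 5, min_samples = 1)
  expect_equal(sel$ids, "a")  # "at least five" keeps the boundary value
  m2 <- rbind(a = c(6, 6, 0, 0, 0, 0), b = c(6, 5, 5, 5, 5, 5))
  colnames(m2) <- paste0("s", 1:6)
  sel2 <- select_detected(m2, min_count = 5, min_samples = 2, strict = TRUE)
  expect_equal(sel2$ids, "a")  # b has only one strict exceedance
  expect_error(select_detected(m2, min_samples = 0), "at least 1")
  expect_error(select_detected(m2, min_samples = 7), "exceeds")
})

test_that("the Ig-bound cascade filters by ratio, expression and exclusion", {
  ids <- c("KEEP1", "LOWRATIO", "NOEXPR", "IGKC", "CRP", "ALB", "UNDETECTED")
  case <- rbind(c(30, 30), c(6, 6), c(30, 30), c(30, 30), c(30, 30),
                c(30, 30), c(1, 1))
  ctrl <- rbind(c(10, 10), c(4.5, 4.5), c(10, 10), c(10, 10), c(10, 10),
                c(10, 10), c(1, 1))
  m <- cbind(case, ctrl)
  dimnames(m) <- list(ids, c("c1", "c2", "k1", "k2"))
  sc <- make_counts(m, group = c("case", "case", "control", "control"))
  ev <- data.frame(gene_id = ids,
                   fpkm_1 = c(5, 5, 0, 5, 5, 5, 5),
                   fpkm_2 = 0,
                   tcga_log2 = c(8, 8, 0, 8, 8, 8, 8),
                   oncomine_hits = c(3, 0, 0, 0, 0, 0, 0))
  rep_ <- ig_bound_cascade(sc, ev, normalize = FALSE)
  df <- as.data.frame(rep_)
  expect_equal(df$n_surviving,
               c(6,  # UNDETECTED out (<5 everywhere)
                 5,  # LOWRATIO out (6/4.5 = 1.333 < 1.5)
                 4,  # NOEXPR out
                 1)) # IGKC (prefix), CRP, ALB (lists) out
  expect_equal(cascade_survivors(rep_), "KEEP1")
  expect_true(rep_$annotations$oncomine_flag)
  expect_error(ig_bound_cascade(make_counts(m, group = rep("case", 4)), ev),
               "case and control")
})

test_that("the ratio rule keeps the exact 1.5 boundary value", {
  m <- rbind(BOUNDARY = c(30, 30, 20, 20), BELOW = c(29.9, 29.9, 20, 20))
  colnames(m) <- paste0("s", 1:4)
  sc <- make_counts(m, group = c("case", "case", "control", "control"))
  ev <- data.frame(gene_id = rownames(m), fpkm_1 = 5, tcga_log2 = 8,
                   oncomine_hits = 0)
  rep_ <- ig_bound_cascade(sc, ev, normalize = FALSE)
  expect_equal(cascade_survivors(rep_), "BOUNDARY")
})

test_that("cascade reports enforce nested, monotone survivor sets", {
  rep_ <- cascade_report("toy", universe = letters[1:5])
  rep_ <- add_cascade_stage(rep_, "s1", "r", 1, letters[1:5], letters[1:4])
  expect_error(add_cascade_stage(rep_, "s2", "r", 1, letters[1:5],
                                 letters[4:5]), "nested")
  rep_ <- add_cascade_stage(rep_, "s2", "r", 1, letters[1:4], letters[2:3])
  df <- as.data.frame(rep_)
  expect_true(all(diff(df$n_surviving) <= 0))
})

test_that("compartment enrichment requires exceeding every reference", {
  comp <- rep(c("exo_surface", "exo_cargo", "TEE"), each = 2)
  m <- rbind(enriched = c(13, 13, 10, 10, 10, 10),
             weak     = c(12, 12, 10, 10, 10, 10),
             one_ref  = c(13, 13, 10, 10, 11, 11))
  colnames(m) <- paste0("s", 1:6)
  sc <- make_counts(m, compartment = comp)
  res <- compartment_enrichment(sc, "exo_surface", c("exo_cargo", "TEE"),
                                fold = 1.25, min_count = 5, min_samples = 2)
  expect_equal(res$ids, "enriched")            # 1.3 > 1.25 vs both
  # weak: 1.2 < 1.25; one_ref: 13/11 = 1.18 vs TEE fails the conjunction
  expect_error(compartment_enrichment(sc, "nucleus", "TEE"), "unknown")
  expect_error(compartment_enrichment(sc, "TEE", "TEE"), "references")
  # detection intersects: a high-ratio protein below counts is dropped
  m2 <- m / 10
  res2 <- compartment_enrichment(make_counts(m2, compartment = comp),
                                 "exo_surface", c("exo_cargo", "TEE"))
  expect_length(res2$ids, 0)
})

test_that("plasma elevation demands particle normalization and strict fold", {
  m <- rbind(elev = c(5.1, 5.1, 2, 2), not = c(4.8, 4.8, 2, 2),
             uniq = c(3, 3, 0, 0), rare = c(9, 0, 0, 0))
  colnames(m) <- paste0("s", 1:4)
  ii <- ion_intensities(m, c(s1 = "case", s2 = "case",
                             s3 = "control", s4 = "control"))
  expect_error(plasma_exosome_elevation(ii), "particle-normalized")
  ii <- normalize_by_particles(ii, c(s1 = 1, s2 = 1, s3 = 1, s4 = 1))
  res <- plasma_exosome_elevation(ii, min_samples = 2, fold = 2.5)
  expect_setequal(res$ids, c("elev", "uniq"))  # 2.55 > 2.5; Inf qualifies
  # "not": 2.4 < 2.5; "rare": detected in only one sample
  expect_equal(cascade_survivors(res$report, "detection"),
               c("elev", "not", "uniq"))
})

test_that("marker QC reaches the minimal exact p under complete separation", {
  comp <- rep(c("TEE", "exo_surface", "exo_cargo", "TCE", "cell_surface"),
              each = 2)
  mk <- exosome_markers()
  dp <- depleted_markers()
  m <- matrix(10, length(mk) + length(dp), 10,
              dimnames = list(c(mk, dp), paste0("s", 1:10)))
  exo_cols <- comp %in% c("TEE", "exo_surface", "exo_cargo")
  m[mk, exo_cols] <- 100 + seq_along(mk)          # strict separation
  sc <- make_counts(m, compartment = comp)
  qc <- marker_qc(sc)
  expect_true(qc$pass)
  expect_equal(qc$markers$test$p_value, 1 / choose(14, 7), tolerance = 1e-12)
  expect_equal(qc$markers$test$method, "exact")
  # all markers absent is a QC failure naming them
  m2 <- m[dp, , drop = FALSE]
  expect_error(marker_qc(make_counts(m2, compartment = comp)), "CD81")
  # identical distributions: p ~ 1, QC fails
  m3 <- matrix(10, length(mk), 10, dimnames = list(mk, paste0("s", 1:10)))
  qc3 <- marker_qc(make_counts(m3, compartment = comp), depleted = "NONE")
  expect_false(qc3$pass)
  expect_equal(qc3$markers$test$p_value, 1)
})

test_that("packaged marker panels carry the canonical symbols", {
  expect_setequal(exosome_markers(),
                  c("CD81", "CD9", "FLOT1", "FLOT2", "PDCD6IP", "SDCBP",
                    "TSG101"))
  expect_setequal(depleted_markers(), c("CANX", "CYC1", "GOLGA2", "HSP90B1"))
  ex <- default_exclusions()
  expect_true(all(c("CRP", "SAA1") %in% ex$acute_phase_proteins))
  expect_true(all(c("ALB", "TF") %in% ex$abundant_plasma_proteins))
})

test_that("cascade selection is invariant to row and column permutation", {
  set.seed(99)
  cfg <- quick_config(seed = 15)
  sim <- simulate_proteomics(cfg)
  rep1 <- ig_bound_cascade(sim$ig, sim$evidence)
  ig2 <- sim$ig
  pr <- sample(nrow(ig2$counts)); pc <- sample(ncol(ig2$counts))
  ig2$counts <- ig2$counts[pr, pc]
  ig2$samples <- ig2$samples[pc, ]
  rep2 <- ig_bound_cascade(ig2, sim$evidence[sample(nrow(sim$evidence)), ])
  expect_setequal(cascade_survivors(rep1), cascade_survivors(rep2))
  expect_equal(as.data.frame(rep1)$n_surviving,
               as.data.frame(rep2)$n_surviving)
})

test_that("noise-free planted simulations are recovered exactly", {
  cfg <- quick_config(seed = 31, nb_dispersion = 0)
  sim <- simulate_proteomics(cfg)
  report <- run_pipeline(unclass(sim), seed = 1)
  expect_setequal(cascade_survivors(report$candidates),
                  sim$truth$antigen_ids)
  expect_equal(report$recovery$precision, 1.0)
  expect_equal(report$recovery$recall, 1.0)
})
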