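test_that("configuration validation rejects invalid studies", {
  expect_error(sim_config(n_proteins = 0), "configuration error")
  expect_error(sim_config(nb_dispersion = -0.1), "configuration error")
  expect_error(sim_config(surface_fold = 1), "configuration error")
  expect_error(sim_config(compartments = c("TEE", "TEE")), "unique")
  expect_error(sim_config(serology_sets = list(s1 = c(case = 3, healthy = 1),
                                               s2 = c(case = 3, healthy = 3))),
               "healthy controls")
  expect_error(sim_config(cdc_doses = c(1, 2.5)), "including 0")
  expect_error(sim_config(cdc_doses = c(0, -1)), "negative")
})

test_that("the proteomics generator is deterministic and seed-sensitive", {
  cfg <- quick_config(seed = 4)
  a <- simulate_proteomics(cfg)
  b <- simulate_proteomics(cfg)
  expect_identical(a, b)
  for (s in c(5, 6, 7)) {
    d <- simulate_proteomics(quick_config(seed = s))
    expect_false(identical(a$ig$counts, d$ig$counts))
  }
  # counts are non-negative integers; intensities positive where observed
  expect_true(all(a$cellline$counts >= 0))
  expect_true(all(a$cellline$counts == round(a$cellline$counts)))
  expect_true(all(a$ig$counts == round(a$ig$counts)))
  expect_true(all(a$plasma$intensity >= 0))
  # planted truth is consistent with the protein universe
  expect_true(all(a$truth$antigen_ids %in% rownames(a$ig$counts)))
  expect_length(a$truth$antigen_ids, cfg$n_planted_antigens)
})

test_that("the noise-free limit realizes planted folds exactly", {
  sim <- simulate_proteomics(quick_config(seed = 2, nb_dispersion = 0,
                                          surface_fold = 2.0))
  comp <- sim$cellline$samples$compartment
  surf <- rowMeans(sim$cellline$counts[, comp == "exo_surface"])
  cargo <- rowMeans(sim$cellline$counts[, comp == "exo_cargo"])
  planted <- sim$truth$antigen_ids
  expect_equal(unname(surf[planted] / cargo[planted]),
               rep(2.0, length(planted)), tolerance = 1e-9)
  # non-planted proteins sit at ratio exactly 1
  others <- setdiff(sprintf("GENE%04d", 1:60), planted)
  expect_equal(unname(surf[others] / cargo[others]),
               rep(1, length(others)), tolerance = 1e-12)
  # Ig-bound case/control ratios realize case_ratio for planted antigens
  grp <- sim$ig$samples$group
  cm <- rowMeans(sim$ig$counts[planted, grp == "case", drop = FALSE])
  km <- rowMeans(sim$ig$counts[planted, grp == "control", drop = FALSE])
  expect_equal(unname(cm / km), rep(3.0, length(planted)), tolerance = 1e-9)
})

test_that("non-planted case/control log-ratios are centered at zero", {
  logs <- unlist(lapply(1:10, function(s) {
    sim <- simulate_proteomics(sim_config(n_proteins = 400,
                                          n_planted_antigens = 5,
                                          seed = 100 + s))
    grp <- sim$ig$samples$group
    keep <- setdiff(sprintf("GENE%04d", 1:400),
                    c(sim$truth$antigen_ids, sim$truth$unique_case_ids))
    cm <- rowMeans(sim$ig$counts[keep, grp == "case"])
    km <- rowMeans(sim$ig$counts[keep, grp == "control"])
    log(cm / km)
  }))
  se <- sd(logs) / sqrt(length(logs))
  expect_lt(abs(mean(logs)), 3 * se)
})

test_that("unique-to-case proteins exercise the infinite fold-change path", {
  sim <- simulate_proteomics(quick_config(seed = 9))
  grp <- sim$ig$samples$group
  uc <- sim$truth$unique_case_ids
  expect_true(all(sim$ig$counts[uc, grp == "control"] == 0))
  fc <- fold_change(sim$ig$counts[uc[1], grp == "case"],
                    sim$ig$counts[uc[1], grp == "control"])
  expect_equal(fc$status, "inf")
})

test_that("particle tables carry plausible diameters scaled by yield", {
  sim <- simulate_proteomics(quick_config(seed = 3))
  expect_true(all(sim$particles$diameter_nm > 0))
  expect_setequal(unique(sim$particles$sample_id),
                  colnames(sim$plasma$intensity))
  m <- mean(sim$particles$diameter_nm)
  expect_gt(m, 90); expect_lt(m, 130)       # plasma vesicles ~110 nm
  mc <- mean(sim$particles_cell$diameter_nm)
  expect_gt(mc, 75); expect_lt(mc, 89)      # cell-line vesicles ~82 nm
})

test_that("serology generator is deterministic with set-specific scales", {
  cfg <- quick_config(seed = 8)
  a <- simulate_serology(cfg)
  expect_identical(a, simulate_serology(cfg))
  expect_setequal(unique(a$set), c("set1", "set2", "set3"))
  # location/scale differ across sets for healthy controls
  ctrl <- a[a$group == "healthy", ]
  mus <- tapply(ctrl$intensity, ctrl$set, mean)
  sds <- tapply(ctrl$intensity, ctrl$set, sd)
  expect_gt(diff(range(mus)), 100)
  expect_gt(max(sds) / min(sds), 1.5)
  # planted antigens shared with the proteomics generator
  sim <- simulate_proteomics(cfg)
  expect_true(all(sim$truth$antigen_ids %in% a$antigen_id))
})

test_that("null-effect serology antigens have AUC centered at 0.5", {
  aucs <- unlist(lapply(1:25, function(s) {
    d <- simulate_serology(quick_config(seed = 300 + s, serology_effect = 2))
    merged <- standardize_and_merge_sets(d)
    nulls <- grep("^NULL", unique(d$antigen_id), value = TRUE)
    vapply(nulls, function(a) {
      x <- merged[merged$antigen_id == a, ]
      mann_whitney(x$standardized[x$group == "case"],
                   x$standardized[x$group == "healthy"])$auc
    }, 0)
  }))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se)
})

test_that("set shifts do not leak through standardization into AUC", {
  # the same seed with rescaled set locations/scales gives identical
  # standardized AUCs, because standardization is affine-invariant per set
  d <- simulate_serology(quick_config(seed = 77, serology_effect = 2))
  d2 <- d
  for (s in unique(d2$set)) {
    sel <- d2$set == s
    shift <- which(unique(d$set) == s) * 1000
    d2$intensity[sel] <- 13 * d2$intensity[sel] + shift
  }
  t1 <- serology_antigen_tests(standardize_and_merge_sets(d))
  t2 <- serology_antigen_tests(standardize_and_merge_sets(d2))
  expect_equal(t1$auc[order(t1$antigen_id)], t2$auc[order(t2$antigen_id)],
               tolerance = 1e-10)
})

test_that("the CDC generator is deterministic, monotone when noise-free", {
  cfg <- quick_config(seed = 21)
  a <- simulate_cdc(cfg)
  expect_identical(a, simulate_cdc(cfg))
  expect_setequal(unique(a$well_role),
                  c("experimental", "spontaneous", "total_lysis"))
  # every experimental condition has a matched spontaneous well
  exps <- a[a$well_role == "experimental", ]
  spont <- a[a$well_role == "spontaneous", ]
  expect_true(all(paste(exps$dose_ug, exps$replicate, exps$readout_type) %in%
                    paste(spont$dose_ug, spont$replicate,
                          spont$readout_type)))
  # noise-free cytotoxicity strictly decreases with dose
  b <- simulate_cdc(quick_config(seed = 21, cdc_noise = 0,
                                 decoy_strength = 1.5))
  res <- decoy_dose_response(b, "absorbance")
  expect_true(all(diff(res$per_dose$mean) < 0))
  expect_true(res$monotone_decreasing)
})
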