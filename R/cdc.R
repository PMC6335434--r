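#' Percent viability from plate-reader absorbances
#'
#' `100 * experimental / spontaneous`: the viability of cells exposed to
#' serum plus complement relative to the replicate-matched
#' antibody-independent (spontaneous) lysis well. Values may exceed 100.
#'
#' @param experimental,spontaneous Absorbances (spontaneous must be > 0).
#' @return Percentage(s); vectorized.
#' @export
percent_viability <- function(experimental, spontaneous) {
  if (any(spontaneous <= 0))
    stop("spontaneous absorbance must be positive", call. = FALSE)
  100 * experimental / spontaneous
}

#' Live-imaging cytotoxicity fold change
#'
#' Background-subtracted dead-cell counts relative to the control
#' condition (serum plus complement without exosomes):
#' `max(dead_exp - dead_spont, 0) / max(dead_ctrl - dead_ctrl_spont, eps)`.
#' Negative background-subtracted counts are floored at 0; a floored
#' denominator (guarded by `eps`) raises a warning. The control condition
#' itself evaluates to 1.
#'
#' @param dead_exp,dead_spont Dead-cell counts of the experimental
#'   condition and its spontaneous (complement-only) well.
#' @param dead_ctrl,dead_ctrl_spont Same for the no-exosome control
#'   condition.
#' @param eps Guard against a zero denominator (default 1e-9).
#' @return Fold change(s); vectorized. Units cancel provided all four
#'   inputs share them.
#' @export
live_imaging_cytotoxicity <- function(dead_exp, dead_spont,
                                      dead_ctrl, dead_ctrl_spont,
                                      eps = 1e-9) {
  num <- pmax(dead_exp - dead_spont, 0)
  den <- dead_ctrl - dead_ctrl_spont
  if (any(den <= 0))
    warning("control background-subtracted count <= 0; denominator guarded",
            call. = FALSE)
  num / pmax(den, eps)
}

#' Exosome decoy dose-response analysis
#'
#' Quantifies the dose-dependent inhibition of complement-dependent
#' cytotoxicity by exosomes. Per dose and replicate, cytotoxicity is
#' `100 - percent_viability` for plate-reader data or the
#' background-subtracted dead-cell fold change for imaging data. The
#' dose-response is assessed two ways: pairwise unpaired t-tests of each
#' dose against dose 0 (the classical readout), and a seeded permutation
#' trend test (Spearman correlation of dose with the replicate-level
#' response, one-sided for inhibition), since pairwise tests alone do not
#' establish dose-dependence. A monotonicity flag records whether the
#' per-dose point estimates are non-increasing.
#'
#' @param experiment A [simulate_cdc()]-style data.frame (`serum_group,
#'   dose_ug, replicate, time_h, readout_type, value, well_role`).
#' @param readout `"absorbance"` (plate) or `"dead_count"` (imaging).
#' @param n_perm Permutation count (default 999).
#' @param seed Seed for the permutation test.
#' @return List of class `decoy_result`: `per_dose` (dose, mean, sd, n),
#'   `pairwise` (dose vs 0 t-test p-values), `trend_p`, `trend_rho`,
#'   `monotone_decreasing`, `readout`.
#' @export
decoy_dose_response <- function(experiment,
                                readout = c("absorbance", "dead_count"),
                                n_perm = 999, seed = 1) {
  readout <- match.arg(readout)
  need <- c("dose_ug", "replicate", "readout_type", "value", "well_role")
  if (!all(need %in% names(experiment)))
    stop("`experiment` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- experiment[experiment$readout_type == readout, ]
  doses <- sort(unique(d$dose_ug[d$well_role == "experimental"]))
  if (length(doses) < 2L)
    stop("need at least two exosome doses", call. = FALSE)

  # replicate-level cytotoxicity per dose
  resp <- list()
  for (dose in doses) {
    ex <- d[d$dose_ug == dose & d$well_role == "experimental", ]
    sp <- d[d$dose_ug == dose & d$well_role == "spontaneous", ]
    if (!nrow(sp))
      stop("missing spontaneous wells at dose ", dose, call. = FALSE)
    sp_val <- sp$value[match(ex$replicate, sp$replicate)]
    sp_val[is.na(sp_val)] <- mean(sp$value)
    if (readout == "absorbance") {
      cyto <- 100 - percent_viability(ex$value, sp_val)
    } else {
      ctrl <- d[d$dose_ug == 0 & d$well_role == "experimental", ]
      ctrl_sp <- d[d$dose_ug == 0 & d$well_role == "spontaneous", ]
      ctrl_sp_val <- ctrl_sp$value[match(ctrl$replicate, ctrl_sp$replicate)]
      cyto <- live_imaging_cytotoxicity(
        ex$value, sp_val,
        mean(ctrl$value), mean(ctrl_sp_val, na.rm = TRUE))
    }
    resp[[as.character(dose)]] <- data.frame(dose_ug = dose,
                                             replicate = ex$replicate,
                                             cytotoxicity = cyto)
  }
  resp <- do.call(rbind, resp)
  if (min(table(resp$dose_ug)) < 2L)
    stop("need at least two replicates per dose", call. = FALSE)

  per_dose <- do.call(rbind, lapply(split(resp, resp$dose_ug), function(g)
    data.frame(dose_ug = g$dose_ug[1], mean = mean(g$cytotoxicity),
               sd = stats::sd(g$cytotoxicity), n = nrow(g))))
  rownames(per_dose) <- NULL

  pairwise <- do.call(rbind, lapply(doses[doses > 0], function(dose) {
    p <- t_test_unpaired(resp$cytotoxicity[resp$dose_ug == dose],
                         resp$cytotoxicity[resp$dose_ug == 0])$p_value
    data.frame(dose_ug = dose, p_vs_dose0 = p)
  }))

  # permutation trend test: Spearman(dose, response), one-sided for a
  # decreasing trend (decoy inhibition)
  obs_rho <- stats::cor(resp$dose_ug, resp$cytotoxicity, method = "spearman")
  set.seed(seed)
  perm_rho <- replicate(n_perm, stats::cor(
    resp$dose_ug, sample(resp$cytotoxicity), method = "spearman"))
  trend_p <- (1 + sum(perm_rho <= obs_rho)) / (n_perm + 1)

  structure(list(per_dose = per_dose, pairwise = pairwise,
                 trend_p = trend_p, trend_rho = obs_rho,
                 monotone_decreasing = !is.unsorted(-per_dose$mean),
                 readout = readout),
            class = "decoy_result")
}

#' @export
print.decoy_result <- function(x, ...) {
  cat(sprintf("decoy dose-response (%s readout)\n", x$readout))
  print(x$per_dose, row.names = FALSE)
  cat(sprintf("  trend: rho = %.3f, permutation p = %.4g; monotone decreasing: %s\n",
              x$trend_rho, x$trend_p, x$monotone_decreasing))
  if (!is.null(x$pairwise))
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  dose %g vs 0: t-test p = %.4g\n",
                  x$pairwise$dose_ug[i], x$pairwise$p_vs_dose0[i]))
  invisible(x)
}
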