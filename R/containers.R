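#' Spectral-count matrix with sample annotation
#'
#' Container for protein-level MS2 spectral counts. Rows are proteins,
#' columns are samples (a cell line x compartment combination, or a
#' case/control plasma pool). Sample annotation travels with the counts so
#' that downstream filters can address columns by compartment or group.
#'
#' @param counts Numeric matrix, proteins x samples; non-negative; rownames
#'   are unique protein identifiers (gene symbols in the default simulation).
#' @param samples data.frame with one row per column of `counts`; must
#'   contain a `sample_id` column matching `colnames(counts)` and at least
#'   one of `compartment` (for fractionation experiments) or `group`
#'   (`case`/`control`, for pooled plasma experiments). A `line` column
#'   identifies the cell line or pool.
#'
#' @return An object of class `spectral_counts`: a list with elements
#'   `counts` and `samples`.
#' @export
spectral_counts <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || nrow(counts) < 1L || ncol(counts) < 1L)
    stop("`counts` must be a non-empty numeric matrix", call. = FALSE)
  if (any(counts < 0))
    stop("spectral counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("`counts` needs unique protein identifiers as rownames", call. = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples))
    stop("`samples` must contain a `sample_id` column", call. = FALSE)
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (!identical(colnames(counts), as.character(samples$sample_id)))
    stop("colnames(counts) must match samples$sample_id in order", call. = FALSE)
  if (!any(c("compartment", "group") %in% names(samples)))
    stop("`samples` must carry a `compartment` and/or `group` column", call. = FALSE)
  structure(list(counts = counts, samples = samples), class = "spectral_counts")
}

#' @export
print.spectral_counts <- function(x, ...) {
  cat(sprintf("spectral_counts: %d proteins x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  for (col in intersect(c("compartment", "group", "line"), names(x$samples))) {
    tb <- table(x$samples[[col]])
    cat(sprintf("  %s: %s\n", col,
                paste(sprintf("%s(%d)", names(tb), tb), collapse = ", ")))
  }
  invisible(x)
}

#' MS1 ion-intensity table
#'
#' Protein x sample matrix of MS1 precursor ion intensities for plasma
#' exosome preparations, with per-sample case/control labels. Intensities
#' are arbitrary units, non-negative; a zero means the protein was not
#' observed in that sample.
#'
#' @param intensity Non-negative numeric matrix with protein rownames and
#'   sample colnames.
#' @param groups Character vector (`"case"`/`"control"`), one per column,
#'   or a named vector keyed by sample id.
#' @return An object of class `ion_intensities`.
#' @export
ion_intensities <- function(intensity, groups) {
  intensity <- as.matrix(intensity)
  if (!is.numeric(intensity) || any(intensity < 0) || any(!is.finite(intensity)))
    stop("intensities must be finite and non-negative", call. = FALSE)
  if (is.null(rownames(intensity)) || anyDuplicated(rownames(intensity)))
    stop("`intensity` needs unique protein identifiers as rownames", call. = FALSE)
  if (is.null(colnames(intensity)) || anyDuplicated(colnames(intensity)))
    stop("`intensity` needs unique sample identifiers as colnames", call. = FALSE)
  if (!is.null(names(groups))) groups <- groups[colnames(intensity)]
  groups <- as.character(groups)
  if (length(groups) != ncol(intensity) || anyNA(groups))
    stop("`groups` must provide one label per sample", call. = FALSE)
  structure(list(intensity = intensity,
                 groups = stats::setNames(groups, colnames(intensity))),
            class = "ion_intensities")
}

#' @export
print.ion_intensities <- function(x, ...) {
  tb <- table(x$groups)
  cat(sprintf("ion_intensities: %d proteins x %d samples (%s)\n",
              nrow(x$intensity), ncol(x$intensity),
              paste(sprintf("%s(%d)", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Filter-cascade report
#'
#' Ordered provenance record of a candidate-selection cascade: each stage
#' stores the rule applied, its threshold, the number of identifiers
#' entering and surviving, and the surviving identifiers themselves.
#' Survivor sets are nested: stage k is a subset of stage k - 1.
#'
#' @param name Character scalar naming the cascade.
#' @param universe Optional character vector of identifiers entering stage 1.
#' @return An empty `cascade_report` to be grown with [add_cascade_stage()].
#' @export
cascade_report <- function(name, universe = NULL) {
  structure(list(name = name, universe = universe, stages = list()),
            class = "cascade_report")
}

#' Append a selection stage to a cascade report
#'
#' @param report A [cascade_report()].
#' @param stage Character scalar, stage name.
#' @param rule Human-readable rule text.
#' @param threshold Numeric threshold the rule applied (NA if none).
#' @param input_ids Identifiers entering the stage.
#' @param surviving_ids Identifiers surviving the stage; must be a subset of
#'   `input_ids` and of the previous stage's survivors.
#' @return The updated report.
#' @export
add_cascade_stage <- function(report, stage, rule, threshold, input_ids,
                              surviving_ids) {
  stopifnot(inherits(report, "cascade_report"))
  surviving_ids <- as.character(surviving_ids)
  input_ids <- as.character(input_ids)
  if (!all(surviving_ids %in% input_ids))
    stop("surviving identifiers must be a subset of the stage input", call. = FALSE)
  k <- length(report$stages)
  if (k > 0L) {
    prev <- report$stages[[k]]$surviving_ids
    if (!all(surviving_ids %in% prev))
      stop("cascade stages must be nested: survivors at stage ", k + 1L,
           " are not a subset of stage ", k, call. = FALSE)
  }
  report$stages[[stage]] <- list(
    stage = stage, rule = rule, threshold = threshold,
    n_input = length(input_ids), n_surviving = length(surviving_ids),
    surviving_ids = surviving_ids)
  report
}

#' Survivors of a cascade (optionally at a named stage)
#' @param report A `cascade_report`.
#' @param stage Stage name; default the last stage.
#' @return Character vector of surviving identifiers.
#' @export
cascade_survivors <- function(report, stage = NULL) {
  stopifnot(inherits(report, "cascade_report"))
  if (length(report$stages) == 0L) return(character(0))
  if (is.null(stage)) stage <- length(report$stages)
  report$stages[[stage]]$surviving_ids
}

#' @export
as.data.frame.cascade_report <- function(x, ...) {
  if (length(x$stages) == 0L)
    return(data.frame(stage = character(), rule = character(),
                      threshold = numeric(), n_input = integer(),
                      n_surviving = integer()))
  do.call(rbind, lapply(x$stages, function(s)
    data.frame(stage = s$stage, rule = s$rule, threshold = s$threshold,
               n_input = s$n_input, n_surviving = s$n_surviving,
               row.names = NULL, stringsAsFactors = FALSE)))
}

#' @export
print.cascade_report <- function(x, ...) {
  cat(sprintf("cascade_report: %s\n", x$name))
  df <- as.data.frame(x)
  if (nrow(df)) print(df, row.names = FALSE) else cat("  (no stages)\n")
  invisible(x)
}
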