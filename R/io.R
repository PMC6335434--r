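#' Read a protein count/intensity matrix with its sample annotation
#'
#' Matrices are TSV with a `protein_id` first column and one column per
#' sample; the sidecar annotation TSV maps `sample_id` to its labels
#' (`line`, `compartment`, `group` as applicable).
#'
#' @param path Matrix TSV path.
#' @param samples_path Sidecar annotation TSV path.
#' @return A [spectral_counts()] object.
#' @export
read_count_matrix <- function(path, samples_path) {
  mat <- read_tsv_strict(path)
  if (names(mat)[1] != "protein_id")
    stop("data error in ", path, ": first column must be `protein_id`",
         call. = FALSE)
  m <- as.matrix(mat[, -1, drop = FALSE])
  rownames(m) <- mat$protein_id
  spectral_counts(m, read_tsv_strict(samples_path))
}

#' Read an MS1 intensity matrix with group labels
#' @param path Matrix TSV (`protein_id` + sample columns).
#' @param samples_path Annotation TSV with `sample_id` and `group`.
#' @return An [ion_intensities()] object.
#' @export
read_intensity_matrix <- function(path, samples_path) {
  mat <- read_tsv_strict(path)
  ann <- read_tsv_strict(samples_path)
  m <- as.matrix(mat[, -1, drop = FALSE])
  rownames(m) <- mat[[1]]
  ion_intensities(m, stats::setNames(ann$group, ann$sample_id))
}

read_tsv_strict <- function(path) {
  if (!file.exists(path))
    stop("data error: file not found: ", path, call. = FALSE)
  out <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("data error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  out
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

matrix_to_df <- function(m) {
  data.frame(protein_id = rownames(m), as.data.frame(m, check.names = FALSE),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Generate the complete synthetic study
#'
#' Convenience wrapper running all three generators
#' ([simulate_proteomics()], [simulate_serology()], [simulate_cdc()])
#' under one configuration.
#'
#' @param config A [sim_config()].
#' @return List of class `exo_study` with the proteomics components
#'   (`cellline`, `ig`, `plasma`, `particles`, `particles_cell`,
#'   `evidence`, `truth`), plus `serology`, `cdc` and the `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  prot <- simulate_proteomics(config)
  out <- unclass(prot)
  out$serology <- simulate_serology(config)
  out$cdc <- simulate_cdc(config)
  epi <- simulate_epitopes(config)
  out$peptides <- epi$peptides
  out$proteins <- epi$proteins
  structure(out, class = "exo_study")
}

#' Write a simulated study to a directory of TSV files
#'
#' Writes the count matrices with sample sidecars, the intensity matrix,
#' particle tables, evidence, serology and CDC tables, plus the planted
#' truth as `truth.json`.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv(matrix_to_df(study$cellline$counts), p("cellline_counts.tsv"))
  write_tsv(study$cellline$samples, p("cellline_samples.tsv"))
  write_tsv(matrix_to_df(study$ig$counts), p("ig_counts.tsv"))
  write_tsv(study$ig$samples, p("ig_samples.tsv"))
  write_tsv(matrix_to_df(study$plasma$intensity), p("plasma_intensity.tsv"))
  write_tsv(data.frame(sample_id = names(study$plasma$groups),
                       group = unname(study$plasma$groups)),
            p("plasma_samples.tsv"))
  write_tsv(study$particles, p("particles_plasma.tsv"))
  write_tsv(study$particles_cell, p("particles_cellline.tsv"))
  write_tsv(study$evidence, p("expression_evidence.tsv"))
  if (!is.null(study$serology)) write_tsv(study$serology, p("serology.tsv"))
  if (!is.null(study$cdc)) write_tsv(study$cdc, p("cdc.tsv"))
  if (!is.null(study$peptides)) write_tsv(study$peptides, p("peptides.tsv"))
  if (!is.null(study$proteins))
    Biostrings::writeXStringSet(study$proteins, p("proteins.fasta"))
  jsonlite::write_json(study$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#' @param dir Directory path.
#' @return List of class `exo_study` (without a config).
#' @export
read_study_dir <- function(dir) {
  p <- function(f) file.path(dir, f)
  out <- list(
    cellline = read_count_matrix(p("cellline_counts.tsv"),
                                 p("cellline_samples.tsv")),
    ig = read_count_matrix(p("ig_counts.tsv"), p("ig_samples.tsv")),
    plasma = read_intensity_matrix(p("plasma_intensity.tsv"),
                                   p("plasma_samples.tsv")),
    particles = read_tsv_strict(p("particles_plasma.tsv")),
    evidence = read_tsv_strict(p("expression_evidence.tsv")))
  if (file.exists(p("particles_cellline.tsv")))
    out$particles_cell <- read_tsv_strict(p("particles_cellline.tsv"))
  if (file.exists(p("serology.tsv")))
    out$serology <- read_tsv_strict(p("serology.tsv"))
  if (file.exists(p("cdc.tsv")))
    out$cdc <- read_tsv_strict(p("cdc.tsv"))
  if (file.exists(p("peptides.tsv")))
    out$peptides <- read_tsv_strict(p("peptides.tsv"))
  if (file.exists(p("proteins.fasta")))
    out$proteins <- Biostrings::readAAStringSet(p("proteins.fasta"))
  if (file.exists(p("truth.json")))
    out$truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  structure(out, class = "exo_study")
}

#' Read a simulation configuration from YAML
#'
#' YAML keys mirror the arguments of [sim_config()]; absent keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path, seed = NULL) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stop("configuration error: unknown field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) vals$seed <- seed
  do.call(sim_config, vals)
}
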