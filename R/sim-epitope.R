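#' Simulate eluted HLA class II peptides with predicted affinities
#'
#' Generates synthetic protein sequences for a subset of the planted
#' antigens (plus a few background proteins) and an eluted-peptide table
#' with predicted IC50 values per allele. The table deliberately contains
#' records exercising every filter path: in-window peptides with strong
#' predicted binding, too-short and too-long peptides, weak binders at or
#' above the affinity threshold, and peptides not present in any source
#' protein.
#'
#' @param config A [sim_config()].
#' @param n_source Number of planted antigens given a sequence (default
#'   10, capped at the number planted).
#' @param n_background Additional non-antigen proteins with sequences.
#' @param seq_length Protein sequence length in residues (default 200).
#' @return List with `peptides` (data.frame `sequence, allele, ic50_nM,
#'   cell_line`) and `proteins` (named `Biostrings::AAStringSet`).
#' @export
simulate_epitopes <- function(config, n_source = 10, n_background = 5,
                              seq_length = 200) {
  config <- validate_sim_config(config)
  planted <- planted_antigen_ids(config)
  set.seed(child_seed(config$seed, "epitope"))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_source <- min(n_source, length(planted))
  src_ids <- planted[seq_len(n_source)]
  bg_ids <- sprintf("BG%03d", seq_len(n_background))
  ids <- c(src_ids, bg_ids)
  seqs <- vapply(ids, function(i)
    paste(sample(aa, seq_length, replace = TRUE), collapse = ""), "")
  proteins <- Biostrings::AAStringSet(seqs)
  names(proteins) <- ids

  alleles <- c("DRB1*01:01", "DRB1*04:01", "DRB1*07:01")
  lines <- sprintf("CL%d", seq_len(config$n_cell_lines))
  take <- function(id, len) {
    s <- seqs[[id]]
    start <- sample(nchar(s) - len + 1L, 1L)
    substr(s, start, start + len - 1L)
  }
  rows <- list()
  add <- function(seq, ic50) rows[[length(rows) + 1L]] <<- data.frame(
    sequence = seq, allele = sample(alleles, 1L),
    ic50_nM = ic50, cell_line = sample(lines, 1L),
    stringsAsFactors = FALSE)
  for (id in src_ids) {
    for (k in seq_len(3)) {                      # strong binders in window
      add(take(id, sample(12:34, 1L)), stats::rlnorm(1, log(100), 0.5))
    }
    add(take(id, sample(8:11, 1L)), 100)         # too short
    add(take(id, 40), 100)                       # too long
    add(take(id, sample(12:34, 1L)),             # weak binder
        500 + stats::rlnorm(1, log(500), 0.3))
  }
  for (k in seq_len(3))                          # unmapped decoys
    add(paste(sample(aa, 15, replace = TRUE), collapse = ""),
        stats::rlnorm(1, log(100), 0.5))
  peptides <- do.call(rbind, rows)
  rownames(peptides) <- NULL
  list(peptides = peptides, proteins = proteins)
}
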