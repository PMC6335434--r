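#' Filter eluted HLA class II peptides by length and predicted affinity
#'
#' Retains peptides of `min_len` to `max_len` residues (inclusive) whose
#' predicted binding affinity is strictly below `ic50_threshold` nM.
#' Affinity predictions are inputs (one row per peptide-allele pair); by
#' default a peptide qualifies if its best (minimum) IC50 over the
#' provided alleles passes, or per allele with `per_allele = TRUE`.
#' Sequences containing characters outside the 20-letter amino-acid
#' alphabet are rejected with a named reason rather than silently dropped.
#'
#' @param peptides data.frame with columns `sequence`, `allele`,
#'   `ic50_nM` and optionally `cell_line`.
#' @param min_len,max_len Length window in residues (default 12-34,
#'   inclusive).
#' @param ic50_threshold Affinity threshold in nM (strict `<`; default
#'   500).
#' @param per_allele If `TRUE`, keep peptide-allele rows individually;
#'   if `FALSE` (default) a peptide passes on its best allele.
#' @return List with `kept` (filtered peptide data.frame, one row per
#'   retained peptide-allele record, plus `length` and `best_ic50`
#'   columns) and `rejected` (data.frame of rejected records with a
#'   `reason` column).
#' @export
filter_hla2_peptides <- function(peptides, min_len = 12, max_len = 34,
                                 ic50_threshold = 500, per_allele = FALSE) {
  need <- c("sequence", "allele", "ic50_nM")
  if (!all(need %in% names(peptides)))
    stop("`peptides` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (min_len > max_len || min_len < 1 || ic50_threshold <= 0)
    stop("invalid thresholds", call. = FALSE)
  pep <- peptides
  pep$sequence <- toupper(as.character(pep$sequence))
  pep$length <- nchar(pep$sequence)
  valid <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", pep$sequence)
  reasons <- character(nrow(pep))
  reasons[!valid] <- "invalid residues"
  len_ok <- pep$length >= min_len & pep$length <= max_len
  reasons[valid & !len_ok] <- sprintf("length outside %d-%d", min_len, max_len)
  best <- stats::ave(pep$ic50_nM, pep$sequence, FUN = min)
  pep$best_ic50 <- best
  ic50_ok <- if (per_allele) pep$ic50_nM < ic50_threshold else
    best < ic50_threshold
  reasons[valid & len_ok & !ic50_ok] <-
    sprintf("IC50 >= %g nM", ic50_threshold)
  keep <- valid & len_ok & ic50_ok
  rejected <- pep[!keep, , drop = FALSE]
  rejected$reason <- reasons[!keep]
  rownames(rejected) <- NULL
  kept <- pep[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Map peptides to their source proteins by exact substring match
#'
#' Locates every occurrence of each peptide in a protein sequence
#' collection. Peptides matching several proteins yield one evidence
#' record per protein occurrence; unmapped peptides are listed
#' separately. Reported positions are 1-based inclusive.
#'
#' @param peptides Character vector of peptide sequences, or the `kept`
#'   data.frame from [filter_hla2_peptides()] (its `sequence` column is
#'   used; duplicates are collapsed).
#' @param proteins Named character vector of protein sequences, a
#'   `Biostrings::AAStringSet`, or a path to a FASTA file.
#' @param collapse_il If `TRUE`, leucine and isoleucine are treated as
#'   equivalent during matching (reported sequences keep the original
#'   residues). Default `FALSE` (exact matching).
#' @return List with `evidence` (data.frame `protein_id, peptide, start,
#'   end`, 1-based inclusive) and `unmapped` (character vector).
#' @export
map_peptides_to_sources <- function(peptides, proteins,
                                    collapse_il = FALSE) {
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  peptides <- unique(toupper(as.character(peptides)))
  if (!length(peptides)) {
    warning("empty peptide set: no evidence produced", call. = FALSE)
    return(list(evidence = data.frame(protein_id = character(),
                                      peptide = character(),
                                      start = integer(), end = integer()),
                unmapped = character(0)))
  }
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins))
    proteins <- Biostrings::readAAStringSet(proteins)
  if (!methods::is(proteins, "AAStringSet"))
    proteins <- Biostrings::AAStringSet(proteins)
  if (length(proteins) == 0L || any(Biostrings::width(proteins) == 0))
    stop("protein sequences must be non-empty", call. = FALSE)
  if (is.null(names(proteins)))
    stop("protein sequences must be named", call. = FALSE)
  subj <- proteins
  if (collapse_il)
    subj <- Biostrings::AAStringSet(chartr("I", "L", as.character(proteins)))
  rows <- list()
  unmapped <- character(0)
  for (pep in peptides) {
    pat <- if (collapse_il) chartr("I", "L", pep) else pep
    hits <- Biostrings::vmatchPattern(pat, subj)
    found <- FALSE
    for (i in seq_along(hits)) {
      ir <- hits[[i]]
      if (length(ir)) {
        found <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = names(proteins)[i], peptide = pep,
          start = BiocGenerics::start(ir), end = BiocGenerics::end(ir),
          stringsAsFactors = FALSE)
      }
    }
    if (!found) unmapped <- c(unmapped, pep)
  }
  evidence <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), peptide = character(),
               start = integer(), end = integer())
  rownames(evidence) <- NULL
  list(evidence = evidence, unmapped = unmapped)
}

#' Summarize epitope evidence per source protein
#'
#' @param evidence The `evidence` data.frame from
#'   [map_peptides_to_sources()].
#' @param peptides Optional `kept` data.frame from
#'   [filter_hla2_peptides()] providing per-peptide `best_ic50`.
#' @return data.frame `protein_id, n_peptides, n_occurrences, best_ic50`.
#' @export
epitope_evidence_summary <- function(evidence, peptides = NULL) {
  if (!nrow(evidence))
    return(data.frame(protein_id = character(), n_peptides = integer(),
                      n_occurrences = integer(), best_ic50 = numeric()))
  sp <- split(evidence, evidence$protein_id)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    protein_id = d$protein_id[1],
    n_peptides = length(unique(d$peptide)),
    n_occurrences = nrow(d),
    best_ic50 = if (!is.null(peptides))
      min(peptides$best_ic50[match(unique(d$peptide), peptides$sequence)],
          na.rm = TRUE) else NA_real_,
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
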