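#' Packaged marker and exclusion lists
#'
#' Small editable text fixtures shipped with the package: the canonical
#' exosome marker panel (CD81, CD9, FLOT1, FLOT2, PDCD6IP, SDCBP, TSG101),
#' the endosomal/organelle proteins expected to be depleted from exosomes
#' (CANX, CYC1, GOLGA2, HSP90B1), and the acute-phase and abundant plasma
#' protein exclusion lists used by the Ig-bound selection cascade.
#'
#' @return Character vector of gene symbols.
#' @name marker_lists
NULL

read_symbol_list <- function(file) {
  path <- system.file("extdata", file, package = "exoprio", mustWork = TRUE)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @rdname marker_lists
#' @export
exosome_markers <- function() read_symbol_list("markers_exosome.txt")

#' @rdname marker_lists
#' @export
depleted_markers <- function() read_symbol_list("markers_depleted.txt")

#' Default exclusion lists for the Ig-bound cascade
#'
#' Immunoglobulin chains are excluded by gene-symbol prefix; acute-phase
#' response and high-abundance plasma proteins by packaged symbol lists
#' (editable text under `inst/extdata/`).
#'
#' @return A list with `ig_chain_prefixes`, `acute_phase_proteins` and
#'   `abundant_plasma_proteins`.
#' @export
default_exclusions <- function() {
  list(ig_chain_prefixes = c("IGH", "IGK", "IGL", "IGJ"),
       acute_phase_proteins = read_symbol_list("exclusion_acute_phase.txt"),
       abundant_plasma_proteins = read_symbol_list("exclusion_abundant_plasma.txt"))
}
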