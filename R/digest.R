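# In-silico tryptic digestion and candidate biomarker peptide selection.

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R except when the next residue is proline
#' (canonical trypsin rule) and emits all products with 0..`max_missed` missed
#' cleavages, with 1-based inclusive coordinates in the parent sequence.
#'
#' @param protein single protein sequence (standard residue letters).
#' @param max_missed maximum number of missed cleavages (>= 0).
#' @return A tibble ordered by `start` then peptide length, with columns
#'   `sequence`, `start`, `end`, `missed_cleavages` and the flags `c_term_k`,
#'   `c_term_r`, `contains_m`, `contains_c`, `taggable`. `taggable` is true iff
#'   the peptide ends in lysine (the TPP tag targets the C-terminal lysine
#'   epsilon-amine).
#' @examples
#' digest("AAKRPMIAAEAEKGGR")
#' @export
digest <- function(protein, max_missed = 0L) {
  residues <- .check_sequence(protein)
  n <- length(residues)
  max_missed <- as.integer(max_missed)
  stopifnot(max_missed >= 0L)

  # cleavage happens after position i when residue i is K/R and i+1 is not P
  cut_after <- which(residues %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | residues[pmin(cut_after + 1L, n)] != "P"]
  bounds <- unique(c(0L, cut_after, n)) # segment boundaries
  starts <- utils::head(bounds, -1) + 1L
  ends <- bounds[-1]
  n_seg <- length(starts)

  out <- list()
  for (i in seq_len(n_seg)) {
    for (m in 0:min(max_missed, n_seg - i)) {
      s <- starts[i]
      e <- ends[i + m]
      out[[length(out) + 1L]] <- list(
        sequence = paste(residues[s:e], collapse = ""),
        start = s, end = e, missed_cleavages = m
      )
    }
  }
  pep <- dplyr::bind_rows(out)
  pep <- dplyr::arrange(pep, .data$start, .data$end - .data$start)
  .flag_peptides(pep)
}

.flag_peptides <- function(pep) {
  dplyr::mutate(
    pep,
    c_term_k = grepl("K$", .data$sequence),
    c_term_r = grepl("R$", .data$sequence),
    contains_m = grepl("M", .data$sequence, fixed = TRUE),
    contains_c = grepl("C", .data$sequence, fixed = TRUE),
    taggable = .data$c_term_k
  )
}

#' Select candidate biomarker peptides
#'
#' Filters digestion products by length and (optionally) C-terminal lysine —
#' the residue the fixed-charge TPP tag derivatizes — and annotates warnings
#' and uniqueness. Methionine content is a flag, not an exclusion: an
#' oxidation-prone residue is a caveat, but a Met peptide shown stable during
#' sample preparation can still be a good candidate.
#'
#' @param peptides tibble from [digest()] (or any tibble with a `sequence`
#'   column; missing flag columns are derived).
#' @param min_len,max_len inclusive length bounds (defaults 6 and 25, the
#'   usual tryptic-peptide working range for triple-quadrupole assays).
#' @param require_c_term_k keep only peptides ending in lysine (TPP-taggable).
#' @param proteome optional character vector (or tibble with `sequence`) of
#'   protein sequences; when supplied, each candidate gets `n_matches`
#'   (exact substring occurrences, counted with overlap) and `unique_in_proteome`.
#' @return The filtered, annotated tibble.
#' @export
select_candidates <- function(peptides, min_len = 6L, max_len = 25L,
                              require_c_term_k = TRUE, proteome = NULL) {
  stopifnot(min_len <= max_len)
  pep <- tibble::as_tibble(peptides)
  if (nrow(pep) == 0) return(pep)
  if (!"c_term_k" %in% names(pep)) pep <- .flag_peptides(pep)
  len <- nchar(pep$sequence)
  keep <- len >= min_len & len <= max_len
  if (require_c_term_k) keep <- keep & pep$c_term_k
  pep <- pep[keep, , drop = FALSE]
  if (!is.null(proteome)) {
    if (is.data.frame(proteome)) proteome <- proteome$sequence
    pep$n_matches <- vapply(
      pep$sequence,
      function(s) sum(vapply(proteome, .count_overlapping, 0L, pattern = s)),
      0L, USE.NAMES = FALSE
    )
    pep$unique_in_proteome <- pep$n_matches == 1L
  }
  pep
}

.count_overlapping <- function(subject, pattern) {
  hits <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

#' Read a protein FASTA file
#'
#' Multi-record, wrapped lines; trailing stop characters (`*`) are stripped.
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `name` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    name = names(set),
    sequence = unname(gsub("*", "", as.character(set), fixed = TRUE))
  )
}
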