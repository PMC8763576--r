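codons_for <- function(aa3, code = Biostrings::GENETIC_CODE) {
  one <- aa_three_to_one(aa3)
  names(code)[code == one]
}

#' Single-nucleotide reachability between amino acids
#'
#' Two amino acids (or an amino acid and stop) are single-nucleotide
#' reachable when some codon of the first differs from some codon of the
#' second at exactly one position under the standard nuclear genetic
#' code. An identical pair is reachable through synonymous identity.
#'
#' @param ref_aa,alt_aa amino acids (one- or three-letter code, or `*`).
#' @return logical vector.
#' @export
#' @examples
#' single_nt_reachable("Trp", "Cys")  # TRUE  (TGG -> TGT)
#' single_nt_reachable("Trp", "Phe")  # FALSE (two changes needed)
single_nt_reachable <- function(ref_aa, alt_aa) {
  ref <- aa_normalize(ref_aa)
  alt <- aa_normalize(alt_aa)
  M <- reachability_matrix()
  unname(M[cbind(ref, alt)])
}

reach_env <- new.env(parent = emptyenv())

#' Reachability mask over the 21 residues (20 amino acids + stop)
#'
#' @return 21x21 logical matrix, dimnames in three-letter code with
#'   `"*"` for stop.
#' @export
reachability_matrix <- function() {
  if (!is.null(reach_env$M)) return(reach_env$M)
  code <- Biostrings::GENETIC_CODE
  aas <- c(AA3, "*")
  n <- length(aas)
  M <- matrix(FALSE, n, n, dimnames = list(aas, aas))
  codon_sets <- lapply(aas, codons_for, code = code)
  hamming1 <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) == 1L
  }
  for (i in seq_len(n)) {
    M[i, i] <- TRUE  # synonymous identity
    for (j in seq_len(n)) {
      if (i == j) next
      for (a in codon_sets[[i]]) {
        if (any(vapply(codon_sets[[j]], hamming1, logical(1), a = a))) {
          M[i, j] <- TRUE
          break
        }
      }
    }
  }
  reach_env$M <- M
  M
}

#' Build the 20x20 substitution grid from missense records
#'
#' Each distinct missense variant increments one cell of the reference
#' by alternate amino acid grid; per-reference-residue row totals are
#' attached, along with the single-nucleotide reachability mask. Records
#' falling in an unreachable cell are flagged as suspect (with a
#' warning) but retained, since a curated census should contain none.
#'
#' @param census a `fxi_census`, or a data.frame with `ref_aa`,
#'   `alt_aa`, `effect` columns; only missense rows with a parsed
#'   protein change are counted.
#' @return a `substitution_grid` list: `counts` (20x20 integer matrix,
#'   ref x alt), `row_totals`, `reachable` (logical mask), `suspect`
#'   (data.frame of offending records), `n_missense`.
#' @export
build_grid <- function(census) {
  keep <- !is.na(census$ref_aa) & !is.na(census$alt_aa) &
    census$effect == "missense"
  rec <- census[keep, , drop = FALSE]
  counts <- matrix(0L, 20L, 20L, dimnames = list(AA3, AA3))
  if (nrow(rec)) {
    t <- table(factor(rec$ref_aa, AA3), factor(rec$alt_aa, AA3))
    counts[] <- as.integer(t)
  }
  mask <- reachability_matrix()[AA3, AA3]
  suspect_cells <- counts > 0L & !mask
  suspect <- rec[paste(rec$ref_aa, rec$alt_aa) %in%
                   apply(which(suspect_cells, arr.ind = TRUE), 1L,
                         function(ij) paste(AA3[ij[1]], AA3[ij[2]])), ,
                 drop = FALSE]
  if (nrow(suspect))
    warning("substitutions not reachable by a single nucleotide change: ",
            paste(suspect$protein_change, collapse = ", "))
  out <- list(counts = counts, row_totals = rowSums(counts),
              reachable = mask, suspect = suspect,
              n_missense = nrow(rec))
  class(out) <- "substitution_grid"
  out
}

#' Write a substitution grid as a 21x21 TSV
#'
#' Header row and column hold the amino acids; cells hold counts.
#' @param grid a `substitution_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  utils::write.table(grid$counts, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
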