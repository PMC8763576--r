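#' Convert HGVS residue numbering to legacy (mature-protein) numbering
#'
#' FXI is synthesised with an 18-residue signal peptide. HGVS protein
#' numbering counts from the initiator Met (codon 1), whereas the older
#' literature counts from Glu19, the first residue of the mature protein.
#' The two schemes differ by a fixed offset of 18 (e.g. Ser575 is legacy
#' Ser557, Glu135* is legacy Glu117*).
#'
#' @param residue_hgvs integer vector of HGVS residue numbers (19..625).
#' @return integer vector of legacy residue numbers.
#' @seealso [legacy_to_hgvs()]
#' @export
#' @examples
#' hgvs_to_legacy(575) # 557
#' legacy_to_hgvs(117) # 135
hgvs_to_legacy <- function(residue_hgvs) {
  residue_hgvs <- as.integer(residue_hgvs)
  if (any(is.na(residue_hgvs)))
    stop("residue numbers must be integers")
  if (any(residue_hgvs < 19L))
    stop("residues 1-18 lie in the signal peptide and have no legacy number")
  residue_hgvs - 18L
}

#' Convert legacy (mature-protein) numbering to HGVS numbering
#'
#' @param residue_legacy integer vector of legacy residue numbers (>= 1).
#' @return integer vector of HGVS residue numbers.
#' @seealso [hgvs_to_legacy()]
#' @export
legacy_to_hgvs <- function(residue_legacy) {
  residue_legacy <- as.integer(residue_legacy)
  if (any(is.na(residue_legacy)))
    stop("residue numbers must be integers")
  if (any(residue_legacy < 1L))
    stop("legacy residue numbers start at 1 (Glu19 in HGVS numbering)")
  residue_legacy + 18L
}
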