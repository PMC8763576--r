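#' Bundled FXI variant census fixture
#'
#' A census table transcribed from the printed variant lists and
#' tallies of the FXI deficiency database survey: all individually
#' named variants (the cysteine-loss and cysteine-gain lists, founder
#' and recurrent variants, interface polymorphisms, accessibility
#' hotspots) as per-variant rows, with aggregate rows (`aggregate =
#' TRUE`) filling in the published marginal counts where per-variant
#' identities are not printed. Hotspot substitution identities at Thr51
#' and Gly97 are plausible single-nucleotide changes chosen here (the
#' source tallies the residues, not the substitutions) -- see the
#' package vignette.
#'
#' @return a `fxi_census` (272 variants in total).
#' @export
fxi_census <- function() {
  read_census(system.file("extdata", "fxi_census.csv", package = "fxivar",
                          mustWork = TRUE))
}

#' Bundled FXI disulfide-bridge table
#'
#' The curated monomer bridge list: three intradomain bridges per Apple
#' domain, five SP-domain bridges, the free Cys29, and the interchain
#' Cys339-Cys339 bridge of the dimer.
#'
#' @return data.frame with columns `kind`, `cys1`, `cys2`.
#' @export
fxi_disulfides <- function() {
  utils::read.csv(system.file("extdata", "fxi_disulfides.csv",
                              package = "fxivar", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Bundled FXI-like precursor sequence (synthetic)
#'
#' A 625-residue stand-in for the FXI precursor in which every residue
#' identity printed in the source material (the conserved and free
#' cysteines, catalytic triad, activation site, dimer-interface
#' residues, and all residues named by a variant) is placed at its HGVS
#' position; the remaining positions are deterministic filler. It is
#' NOT the true F11 reference translation -- suitable for exercising
#' numbering, domain and alignment machinery, not for sequence-level
#' biology. See the FASTA header.
#'
#' @return `AAStringSet` of length one.
#' @export
fxi_sequence <- function() {
  read_fasta(system.file("extdata", "fxi_sequence_synthetic.fasta",
                         package = "fxivar", mustWork = TRUE))
}
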