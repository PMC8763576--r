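#' Theoretical maximum sidechain accessible surface areas
#'
#' Per-residue maxima (square Angstrom) for the sidechain in an
#' extended Gly-X-Gly tripeptide, used as the denominator when
#' converting sidechain SASA into percent accessibility. Glycine is
#' assigned a small Calpha-based reference, matching the convention that
#' its Calpha stands in for the missing sidechain. The table is
#' configurable: only the bin boundaries derived from the percentages
#' drive the downstream classification, not the absolute areas.
#'
#' @return named numeric vector over three-letter residue codes.
#' @export
max_asa_sidechain <- function() {
  c(ALA = 67, ARG = 196, ASN = 113, ASP = 106, CYS = 104, GLN = 144,
    GLU = 138, GLY = 25, HIS = 151, ILE = 140, LEU = 137, LYS = 167,
    MET = 160, PHE = 175, PRO = 105, SER = 80, THR = 102, TRP = 217,
    TYR = 187, VAL = 117)
}

#' Maximum accessible area of the toy pseudo-sidechain
#'
#' For synthetic structures built by [make_helix()], every non-Gly
#' sidechain is a single 1.9-Angstrom pseudo-sphere, so its theoretical
#' maximum accessible area is the isolated-sphere area
#' 4 pi (1.9 + probe)^2 regardless of residue type. Use this table in
#' place of [max_asa_sidechain()] when classifying burial on toys, so
#' that percentages are on the 0-100 scale the bins assume.
#'
#' @param probe_radius solvent probe radius in Angstrom.
#' @return named numeric vector over the 20 residue types.
#' @export
max_asa_pseudo_sidechain <- function(probe_radius = 1.4) {
  a <- 4 * pi * (1.9 + probe_radius)^2
  vals <- stats::setNames(rep(a, length(max_asa_sidechain())),
                          names(max_asa_sidechain()))
  # Gly toy "sidechain" is its CA (a carbon sphere)
  vals["GLY"] <- 4 * pi * (1.7 + probe_radius)^2
  vals
}

#' Percent accessibility, binning and burial classification
#'
#' Converts per-residue sidechain SASA into percent accessibility by
#' dividing by the theoretical maximum for the residue type, then bins
#' the percentage in tens: 0-9% is bin 0, 10-19% bin 1, and so on, with
#' everything from 90% up (including over 100%, possible in extended
#' conformations) capped at bin 9. Residues in bins 0 or 1 are
#' classified as buried, bins 2-9 as solvent-exposed.
#'
#' @param atoms an `atomset`, or a data.frame from [residue_sasa()] with
#'   columns chain/resno/resid/sasa.
#' @param max_asa named vector of per-residue-type maxima; see
#'   [max_asa_sidechain()].
#' @param state label recorded on the profile (e.g. `"intact"`,
#'   `"isolated_domain"`, `"monomer"`, `"dimer"`).
#' @param ... passed to [compute_sasa()] when `atoms` is an `atomset`.
#' @return an `accessibility_profile` data.frame: chain, resno, resid,
#'   sasa_sidechain, percent, bin, buried, state.
#' @export
relative_accessibility <- function(atoms, max_asa = max_asa_sidechain(),
                                   state = "intact", ...) {
  prof <- if (inherits(atoms, "atomset"))
    residue_sasa(atoms, which = "sidechain", ...) else atoms
  if (!all(c("chain", "resno", "resid", "sasa") %in% names(prof)))
    stop("need chain/resno/resid/sasa columns")
  unknown <- setdiff(unique(prof$resid), names(max_asa))
  if (length(unknown))
    stop("residue type(s) missing from the max-ASA table: ",
         paste(unknown, collapse = ", "))
  percent <- 100 * prof$sasa / unname(max_asa[prof$resid])
  out <- data.frame(chain = prof$chain, resno = prof$resno,
                    resid = prof$resid, sasa_sidechain = prof$sasa,
                    percent = percent,
                    bin = accessibility_bin(percent),
                    stringsAsFactors = FALSE)
  out$buried <- out$bin <= 1L
  out$state <- state
  class(out) <- c("accessibility_profile", "data.frame")
  out
}

#' Percent accessibility to decile bin
#' @param percent numeric percentages (may exceed 100).
#' @return integer bins 0..9.
#' @export
accessibility_bin <- function(percent) {
  as.integer(floor(pmin(percent, 99.9) / 10))
}

#' Burial classification of census variants on a structure
#'
#' Joins variant residues onto a per-residue accessibility profile and
#' cross-tabulates phenotype against burial class. Variants at residues
#' absent from the structure are reported as `"not classified"`.
#'
#' @param census a `fxi_census`; rows without a residue position are
#'   skipped, and by default only substitution records (missense,
#'   including missense polymorphisms) are classified.
#' @param profile an `accessibility_profile` of the intact structure.
#' @param effects effects to include.
#' @return list: `variants` (per-variant classification), `cross_tab`
#'   (phenotype x class contingency table), `n_not_classified`.
#' @export
annotate_variants <- function(census, profile,
                              effects = c("missense")) {
  keep <- !is.na(census$residue) & census$effect %in% effects
  v <- as.data.frame(census[keep, c("protein_change", "residue",
                                    "phenotype")])
  idx <- match(v$residue, profile$resno)
  v$percent <- profile$percent[idx]
  v$bin <- profile$bin[idx]
  v$class <- ifelse(is.na(v$bin), "not classified",
                    ifelse(v$bin <= 1L, "buried", "exposed"))
  ct <- table(phenotype = factor(v$phenotype, PHENOTYPES),
              class = factor(v$class,
                             c("buried", "exposed", "not classified")))
  list(variants = v, cross_tab = ct,
       n_not_classified = sum(v$class == "not classified"))
}

#' Read per-residue accessibilities from a classic DSSP output file
#'
#' A minimal reader for the fixed-column dialect of DSSP text output:
#' returns residue number, chain, amino acid (one-letter), the
#' eight-state secondary structure code and the accessibility in square
#' Angstrom. Secondary structure is ingested only, never computed here.
#'
#' @param path path to a DSSP output file.
#' @return data.frame resno/chain/aa/ss/acc.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) != 1L) stop("not a classic DSSP output file: ", path)
  body <- lines[(start + 1L):length(lines)]
  body <- body[nchar(body) >= 38]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"  # chain breaks
  body <- body[keep]
  data.frame(resno = as.integer(substr(body, 6, 10)),
             chain = trimws(substr(body, 12, 12)),
             aa = substr(body, 14, 14),
             ss = trimws(substr(body, 17, 17)),
             acc = as.numeric(substr(body, 35, 38)),
             stringsAsFactors = FALSE)
}

#' Write an accessibility profile as TSV
#' @param profile an `accessibility_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  out <- as.data.frame(profile)
  out$sasa_sidechain <- sprintf("%.3f", out$sasa_sidechain)
  out$percent <- sprintf("%.2f", out$percent)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
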