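VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Construct an atom set
#'
#' The atom-level container used throughout the structural analyses: one
#' row per heavy atom with chain, author residue number (HGVS-aligned
#' for FXI structures), residue type, atom name, element, coordinates in
#' Angstrom, van der Waals radius, and a backbone/sidechain partition.
#' Glycine has no sidechain atoms; for accessibility its Calpha stands
#' in (see [relative_accessibility()]).
#'
#' @param chain,resno,resid,elety,x,y,z per-atom vectors: chain id,
#'   residue number, residue type (three-letter, upper case), atom name,
#'   coordinates.
#' @param element optional element symbols; inferred from the atom name
#'   when omitted.
#' @return an `atomset` data.frame.
#' @export
atomset <- function(chain, resno, resid, elety, x, y, z, element = NULL) {
  if (is.null(element)) element <- substr(gsub("^[0-9]", "", elety), 1, 1)
  element <- toupper(element)
  bad <- !element %in% names(VDW_RADII)
  if (any(bad))
    stop("unknown element(s): ", paste(unique(element[bad]), collapse = ", "))
  a <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                  resid = toupper(as.character(resid)),
                  elety = as.character(elety),
                  element = element,
                  x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                  stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(a[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  a$radius <- unname(VDW_RADII[a$element])
  a$region <- ifelse(a$elety %in% BACKBONE_ATOMS, "backbone", "sidechain")
  class(a) <- c("atomset", "data.frame")
  a
}

#' Read a structure from a PDB or mmCIF file
#'
#' The first model is used; among alternate locations only blank or "A"
#' altloc atoms are kept; hydrogens, waters and hetero ligands are
#' dropped. Residues with missing atoms are retained (and can be listed
#' via `incomplete_residues()` on the result's attributes).
#'
#' @param path path to the coordinate file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return an `atomset` data.frame of heavy protein atoms.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty coordinate file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  pdb <- if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
         else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  ele <- toupper(at$elesy)
  ele[is.na(ele) | ele == ""] <- substr(gsub("^[0-9]", "", at$elety), 1, 1)[
    is.na(ele) | ele == ""]
  keep <- !ele %in% c("H", "D")
  at <- at[keep, , drop = FALSE]
  ele <- ele[keep]
  if (nrow(at) == 0L) stop("no protein atoms found in ", path)
  out <- atomset(chain = at$chain, resno = at$resno, resid = at$resid,
                 elety = at$elety, x = at$x, y = at$y, z = at$z,
                 element = ele)
  # flag residues missing any canonical backbone atom
  key <- paste(out$chain, out$resno)
  has_bb <- tapply(out$elety, key,
                   function(e) all(c("N", "CA", "C") %in% e))
  attr(out, "incomplete_residues") <- names(has_bb)[!has_bb]
  out
}

#' Write an atom set as a PDB file
#'
#' @param atoms an `atomset`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  pdb <- bio3d::write.pdb(
    file = path, xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    type = rep("ATOM", nrow(atoms)), resno = atoms$resno,
    resid = atoms$resid, chain = atoms$chain, elety = atoms$elety,
    elesy = atoms$element)
  invisible(path)
}

#' Per-residue table of an atom set
#' @param atoms an `atomset`.
#' @return data.frame chain/resno/resid, one row per residue, in file
#'   order.
#' @export
residues_of <- function(atoms) {
  key <- !duplicated(paste(atoms$chain, atoms$resno))
  out <- as.data.frame(atoms[key, c("chain", "resno", "resid")])
  rownames(out) <- NULL
  out
}
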