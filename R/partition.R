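#' Split a structure into isolated domain substructures
#'
#' @param atoms an `atomset`.
#' @param map a [domain_map()] covering every residue present (the
#'   signal peptide is absent from crystal structures and simply
#'   matches no atoms).
#' @return named list of `atomset`s, one per domain with atoms present,
#'   atoms unchanged.
#' @export
split_domains <- function(atoms, map = default_domain_map()) {
  dom <- assign_domain(atoms$resno, map)
  if (any(is.na(dom)))
    stop("residue(s) outside the domain map: ",
         paste(unique(atoms$resno[is.na(dom)]), collapse = ", "))
  out <- lapply(split(seq_len(nrow(atoms)), factor(dom, map$name)),
                function(i) atoms[i, , drop = FALSE])
  out[vapply(out, nrow, integer(1)) > 0L]
}

#' Accessibility change upon domain separation
#'
#' Computes per-residue accessibility bins for the intact structure and
#' for each domain in isolation, and their difference. Isolation can
#' only uncover surface, so the delta is non-negative for every residue;
#' residues with `delta >= contact_threshold` are reported as
#' interdomain-contact residues.
#'
#' @param atoms an `atomset` (single chain or assembly).
#' @param map a [domain_map()].
#' @param contact_threshold minimum bin increase (default 1, i.e. ten
#'   percentage points) that marks an interdomain contact.
#' @param max_asa per-residue-type maxima for the percent conversion;
#'   see [max_asa_sidechain()] (or [max_asa_pseudo_sidechain()] for
#'   toys).
#' @param ... passed to [compute_sasa()].
#' @return data.frame: chain, resno, resid, domain, bin_intact,
#'   bin_isolated, delta, contact.
#' @export
separation_delta <- function(atoms, map = default_domain_map(),
                             contact_threshold = 1L,
                             max_asa = max_asa_sidechain(), ...) {
  intact <- relative_accessibility(atoms, max_asa = max_asa,
                                   state = "intact", ...)
  parts <- split_domains(atoms, map)
  iso <- do.call(rbind, lapply(names(parts), function(nm) {
    p <- relative_accessibility(parts[[nm]], max_asa = max_asa,
                                state = "isolated_domain", ...)
    p$domain <- nm
    p
  }))
  key_i <- paste(intact$chain, intact$resno)
  key_s <- paste(iso$chain, iso$resno)
  idx <- match(key_i, key_s)
  out <- data.frame(chain = intact$chain, resno = intact$resno,
                    resid = intact$resid, domain = iso$domain[idx],
                    bin_intact = intact$bin,
                    bin_isolated = iso$bin[idx],
                    stringsAsFactors = FALSE)
  out$delta <- out$bin_isolated - out$bin_intact
  out$contact <- out$delta >= contact_threshold
  out
}

#' Interface residues of an assembly by buried surface area
#'
#' Per-residue buried surface area (BSA) is the all-atom SASA of the
#' residue in its own monomer alone minus its SASA in the assembly.
#' Residues losing more than `bsa_cutoff` square Angstrom belong to the
#' interface.
#'
#' @param assembly an `atomset` with at least two chains (a single
#'   chain yields an empty interface).
#' @param bsa_cutoff BSA cut-off in square Angstrom (default 5).
#' @param ... passed to [compute_sasa()].
#' @return data.frame chain/resno/resid/sasa_monomer/sasa_assembly/bsa
#'   with attribute `interface` (logical) exposed as column
#'   `interface`.
#' @export
interface_residues <- function(assembly, bsa_cutoff = 5, ...) {
  chains <- unique(assembly$chain)
  sasa_asm <- residue_sasa(assembly, which = "all", ...)
  mono <- do.call(rbind, lapply(chains, function(ch) {
    m <- assembly[assembly$chain == ch, , drop = FALSE]
    residue_sasa(m, which = "all", ...)
  }))
  key_a <- paste(sasa_asm$chain, sasa_asm$resno)
  key_m <- paste(mono$chain, mono$resno)
  idx <- match(key_a, key_m)
  out <- data.frame(chain = sasa_asm$chain, resno = sasa_asm$resno,
                    resid = sasa_asm$resid,
                    sasa_monomer = mono$sasa[idx],
                    sasa_assembly = sasa_asm$sasa,
                    stringsAsFactors = FALSE)
  out$bsa <- out$sasa_monomer - out$sasa_assembly
  out$interface <- length(chains) > 1L & out$bsa > bsa_cutoff
  out
}

#' Detect disulfide bridges geometrically
#'
#' Cysteine pairs whose Sgamma-Sgamma distance is at most `sg_cutoff`
#' (covalent bonds refine near 2.05 Angstrom; the default 2.3 tolerates
#' refinement noise while excluding van der Waals contacts). Each Cys
#' joins at most one bridge: candidate pairs are accepted nearest
#' first. Bridges between different chains are flagged interchain.
#'
#' @param atoms an `atomset` containing Cys SG atoms.
#' @param sg_cutoff maximum Sgamma-Sgamma distance in Angstrom.
#' @return list: `bridges` (data.frame chain1/resno1/chain2/resno2/
#'   distance/interchain) and `free_cys` (data.frame chain/resno of
#'   unpaired cysteines).
#' @export
find_disulfides <- function(atoms, sg_cutoff = 2.3) {
  sg <- atoms[atoms$resid == "CYS" & atoms$elety == "SG", , drop = FALSE]
  n <- nrow(sg)
  bridges <- data.frame(chain1 = character(0), resno1 = integer(0),
                        chain2 = character(0), resno2 = integer(0),
                        distance = numeric(0), interchain = logical(0))
  if (n >= 2L) {
    xyz <- as.matrix(sg[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    cand <- which(upper.tri(d) & d <= sg_cutoff, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used <- logical(n)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used[i] || used[j]) next
        used[i] <- used[j] <- TRUE
        bridges <- rbind(bridges, data.frame(
          chain1 = sg$chain[i], resno1 = sg$resno[i],
          chain2 = sg$chain[j], resno2 = sg$resno[j],
          distance = d[i, j],
          interchain = sg$chain[i] != sg$chain[j]))
      }
    }
  }
  paired <- c(paste(bridges$chain1, bridges$resno1),
              paste(bridges$chain2, bridges$resno2))
  free <- sg[!paste(sg$chain, sg$resno) %in% paired,
             c("chain", "resno"), drop = FALSE]
  rownames(free) <- NULL
  list(bridges = bridges, free_cys = as.data.frame(free))
}

#' Assemble a two-chain dimer from a monomer and a rigid-body transform
#'
#' The second chain is the monomer under `x -> R x + t`. A transform
#' that collapses the chains onto each other (minimum interatomic
#' distance below 1 Angstrom) triggers a warning, as with the identity
#' transform.
#'
#' @param monomer an `atomset` (single chain).
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector in Angstrom.
#' @param chains length-2 chain labels for the output.
#' @return an `atomset` with two chains.
#' @export
build_dimer <- function(monomer, rotation = diag(3),
                        translation = c(0, 0, 0),
                        chains = c("A", "B")) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  xyz <- as.matrix(monomer[, c("x", "y", "z")])
  xyz2 <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3,
                                       byrow = TRUE)
  partner <- monomer
  partner$x <- xyz2[, 1]; partner$y <- xyz2[, 2]; partner$z <- xyz2[, 3]
  monomer$chain <- chains[1]
  partner$chain <- chains[2]
  mind <- min(sqrt(pmax(0, outer(rowSums(xyz^2), rep(1, nrow(xyz2))) +
                     outer(rep(1, nrow(xyz)), rowSums(xyz2^2)) -
                     2 * xyz %*% t(xyz2))))
  if (mind < 1)
    warning("chains collide: minimum interatomic distance ",
            sprintf("%.2f", mind), " Angstrom")
  out <- rbind(monomer, partner)
  class(out) <- c("atomset", "data.frame")
  out
}

#' Distance check for named salt bridges
#'
#' Reports, for each (acidic residue, basic residue) pair, the minimum
#' sidechain N-O distance across chains and whether it satisfies the
#' salt-bridge criterion (<= 4 Angstrom). Intended as a demonstration
#' report for the dimer-interface bridges Glu305-Lys349 and
#' Asp307-Arg363.
#'
#' @param assembly an `atomset`.
#' @param pairs data.frame with columns `res_acid`, `res_base` (HGVS
#'   residue numbers).
#' @param cutoff distance criterion in Angstrom.
#' @return data.frame res_acid/res_base/min_distance/salt_bridge.
#' @export
salt_bridges <- function(assembly,
                         pairs = data.frame(res_acid = c(305, 307),
                                            res_base = c(349, 363)),
                         cutoff = 4) {
  out <- pairs
  out$min_distance <- NA_real_
  for (k in seq_len(nrow(pairs))) {
    o <- assembly[assembly$resno == pairs$res_acid[k] &
                    assembly$element == "O" &
                    assembly$region == "sidechain", , drop = FALSE]
    nn <- assembly[assembly$resno == pairs$res_base[k] &
                     assembly$element == "N" &
                     assembly$region == "sidechain", , drop = FALSE]
    if (nrow(o) && nrow(nn)) {
      d <- sqrt(outer(rowSums(as.matrix(o[, c("x", "y", "z")])^2),
                      rep(1, nrow(nn))) +
                  outer(rep(1, nrow(o)),
                        rowSums(as.matrix(nn[, c("x", "y", "z")])^2)) -
                  2 * as.matrix(o[, c("x", "y", "z")]) %*%
                    t(as.matrix(nn[, c("x", "y", "z")])))
      out$min_distance[k] <- min(d)
    }
  }
  out$salt_bridge <- !is.na(out$min_distance) & out$min_distance <= cutoff
  out
}

#' Tabulate a curated disulfide-bridge list
#'
#' Summarises a bridge table (as shipped in `inst/extdata`): intrachain
#' bridge count per monomer, split into Apple-domain and SP-domain
#' bridges, plus interchain bridges and free cysteines.
#'
#' @param bridges data.frame with columns `kind` (`"bridge"`,
#'   `"interchain"` or `"free"`), `cys1`, `cys2` (HGVS residue numbers;
#'   `cys2` empty for free cysteines).
#' @param map a [domain_map()].
#' @return list with `n_bridges`, `n_apple`, `n_sp`, `interchain`
#'   (data.frame), `free_cys` (integer vector).
#' @export
disulfide_census <- function(bridges, map = default_domain_map()) {
  intra <- bridges[bridges$kind == "bridge", , drop = FALSE]
  dom1 <- assign_domain(intra$cys1, map)
  dom2 <- assign_domain(intra$cys2, map)
  apple <- apple_domains(map)
  list(n_bridges = nrow(intra),
       n_apple = sum(dom1 %in% apple & dom2 %in% apple),
       n_sp = sum(dom1 == "SP" & dom2 == "SP"),
       interchain = bridges[bridges$kind == "interchain", , drop = FALSE],
       free_cys = bridges$cys1[bridges$kind == "free"])
}
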