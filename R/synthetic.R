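#' Build an idealized alpha-helix with pseudo-sidechains
#'
#' A deterministic toy structure for testing the accessibility and
#' interface machinery: backbone atoms (N, CA, C, O) on an ideal helix
#' (rise 1.5 Angstrom, 100 degrees per residue) plus one outward-facing
#' pseudo-sidechain sphere (CB, radius 1.9 Angstrom) per non-Gly
#' residue; cysteines additionally carry an SG atom further out so that
#' disulfide geometry can be engineered. The sidechain model is a
#' single-sphere caricature, not a biophysical rotamer.
#'
#' @param n_res number of residues (>= 3).
#' @param residue_types three-letter residue codes, recycled to
#'   `n_res`.
#' @param chain chain identifier.
#' @param resno_start first residue number.
#' @param phase rotation of the first residue about the helix axis
#'   (radians).
#' @param origin length-3 offset added to all coordinates.
#' @return an `atomset`.
#' @export
#' @examples
#' h <- make_helix(10)
#' diff(h$z[h$elety == "CA"])  # 1.5 Angstrom axial rise
make_helix <- function(n_res, residue_types = "ALA", chain = "A",
                       resno_start = 1L, phase = 0,
                       origin = c(0, 0, 0)) {
  stopifnot(n_res >= 3)
  types <- toupper(rep_len(residue_types, n_res))
  bad <- !types %in% names(max_asa_sidechain())
  if (any(bad))
    stop("unknown residue type(s): ", paste(unique(types[bad]),
                                            collapse = ", "))
  rows <- list()
  for (i in seq_len(n_res)) {
    th <- phase + (i - 1) * 100 * pi / 180
    z0 <- (i - 1) * 1.5
    at <- function(elety, r, dth, dz, element)
      data.frame(elety = elety, x = r * cos(th + dth),
                 y = r * sin(th + dth), z = z0 + dz, element = element,
                 stringsAsFactors = FALSE)
    a <- rbind(at("N", 1.6, -0.45, -0.50, "N"),
               at("CA", 2.3, 0.00, 0.00, "C"),
               at("C", 2.0, 0.45, 0.50, "C"),
               at("O", 2.0, 0.75, 1.25, "O"))
    if (types[i] != "GLY")
      a <- rbind(a, at("CB", 3.4, 0, 0, "C"))
    if (types[i] == "CYS")
      a <- rbind(a, at("SG", 4.4, 0, 0.30, "S"))
    a$resno <- resno_start + i - 1L
    a$resid <- types[i]
    rows[[i]] <- a
  }
  a <- do.call(rbind, rows)
  out <- atomset(chain = chain, resno = a$resno, resid = a$resid,
                 elety = a$elety, x = a$x + origin[1], y = a$y + origin[2],
                 z = a$z + origin[3], element = a$element)
  out$radius[out$elety == "CB"] <- 1.9  # pseudo-sidechain sphere
  out
}

#' Pack two helices against each other with a controlled gap
#'
#' The second helix is rotated 180 degrees about the helix axis (so its
#' sidechains face the first) and translated along x until the minimum
#' surface-to-surface separation between the two atom sets equals
#' `gap`. The designed contact residues -- those whose pseudo-sidechain
#' sphere lies within `gap + contact_margin` of the partner's surface --
#' are returned as ground truth for interface recovery tests.
#'
#' @param helixA,helixB `atomset`s from [make_helix()].
#' @param gap target minimum surface separation in Angstrom (>= 0).
#' @param axial_offset z-shift applied to the second helix.
#' @param contact_margin extra surface separation (Angstrom) allowed for
#'   a residue to count as a designed contact (default 2).
#' @param arrangement `"chains"` (two chains A/B) or `"domains"` (one
#'   chain, second helix renumbered to follow the first; a matching
#'   two-domain [domain_map()] is returned).
#' @return list: `assembly` (`atomset`), `contacts` (data.frame
#'   chain/resno of designed contact residues), `map` (domain map, for
#'   the `"domains"` arrangement), `offset` (the x translation used).
#' @export
make_packed_pair <- function(helixA, helixB, gap, axial_offset = 0,
                             contact_margin = 2,
                             arrangement = c("chains", "domains")) {
  stopifnot(gap >= 0)
  arrangement <- match.arg(arrangement)
  B <- helixB
  B$x <- -helixB$x
  B$y <- -helixB$y
  B$z <- helixB$z + axial_offset
  A_xyz <- as.matrix(helixA[, c("x", "y", "z")])
  B_xyz <- as.matrix(B[, c("x", "y", "z")])
  rsum <- outer(helixA$radius, B$radius, "+")
  mingap_at <- function(D) {
    Bx <- B_xyz; Bx[, 1] <- Bx[, 1] + D
    d <- sqrt(outer(rowSums(A_xyz^2), rep(1, nrow(Bx))) +
                outer(rep(1, nrow(A_xyz)), rowSums(Bx^2)) -
                2 * A_xyz %*% t(Bx))
    min(d - rsum)
  }
  D <- stats::uniroot(function(D) mingap_at(D) - gap,
                      lower = 0, upper = 200, tol = 1e-8)$root
  B$x <- B$x + D
  if (arrangement == "domains") {
    shift <- max(helixA$resno) - min(B$resno) + 1L
    B$resno <- B$resno + shift
    B$chain <- helixA$chain[1]
  } else {
    helixA$chain <- "A"
    B$chain <- "B"
  }
  assembly <- rbind(helixA, B)
  class(assembly) <- c("atomset", "data.frame")
  # ground truth: pseudo-sidechain within gap + margin of the partner
  # surface. Once the gap exceeds the solvent-probe diameter (2.8 A for
  # water) a probe fits between the surfaces, nothing can be buried,
  # and the designed contact set is empty by construction.
  contact_of <- function(side, other) {
    sc <- side[side$elety %in% c("CB", "SG"), , drop = FALSE]
    o_xyz <- as.matrix(other[, c("x", "y", "z")])
    hits <- logical(nrow(sc))
    if (gap < 2 * 1.4) {
      for (k in seq_len(nrow(sc))) {
        d <- sqrt(colSums((t(o_xyz) - c(sc$x[k], sc$y[k], sc$z[k]))^2))
        hits[k] <- any(d - sc$radius[k] - other$radius <=
                         gap + contact_margin)
      }
    }
    unique(sc[hits, c("chain", "resno"), drop = FALSE])
  }
  nA <- nrow(helixA)
  sideA <- assembly[seq_len(nA), , drop = FALSE]
  sideB <- assembly[-seq_len(nA), , drop = FALSE]
  contacts <- rbind(contact_of(sideA, sideB), contact_of(sideB, sideA))
  rownames(contacts) <- NULL
  map <- NULL
  if (arrangement == "domains")
    map <- domain_map(c("D1", "D2"),
                      c(min(sideA$resno), min(sideB$resno)),
                      c(max(sideA$resno), max(sideB$resno)))
  list(assembly = assembly, contacts = as.data.frame(contacts),
       map = map, offset = D)
}

#' Generate a synthetic variant census with exact marginals
#'
#' Produces a per-variant census whose [tabulate_census()] output
#' reproduces the requested marginal counts exactly: genetic events over
#' all variants, effects over point variants, phenotypes over
#' disease-associated variants, and optional allele-frequency strata.
#' Substitutions are drawn (reproducibly under `seed`) from the bundled
#' FXI-like sequence, restricted to single-nucleotide-reachable changes.
#'
#' @param events named integer vector of event-type counts (names among
#'   point/deletion/insertion/duplication/polymorphism).
#' @param effects named integer vector over
#'   missense/nonsense/silent/undefined; must sum to `events["point"]`.
#' @param phenotypes named integer vector over type_I/type_II/unknown;
#'   must sum to the disease-associated total (all events except
#'   polymorphism).
#' @param af_strata optional data.frame with columns `n` and `af`:
#'   assigns allele frequency `af` to `n` variants each; total `n` must
#'   not exceed the census size.
#' @param seed integer seed for reproducibility.
#' @return a `fxi_census` of per-variant rows.
#' @export
make_census <- function(events, effects = NULL, phenotypes = NULL,
                        af_strata = NULL, seed = 1L) {
  bad <- setdiff(names(events), setdiff(EVENT_TYPES, "undefined"))
  if (length(bad)) stop("unknown event type(s): ", paste(bad, collapse = ", "))
  events <- events[events > 0]
  n_point <- if ("point" %in% names(events)) events[["point"]] else 0L
  if (is.null(effects)) effects <- c(missense = n_point)
  effects <- effects[effects > 0]
  if (sum(effects) != n_point)
    stop("effect counts must sum to the point-variant count")
  n_disease <- sum(events[setdiff(names(events), "polymorphism")])
  if (is.null(phenotypes)) phenotypes <- c(unknown = n_disease)
  phenotypes <- phenotypes[phenotypes > 0]
  if (sum(phenotypes) != n_disease)
    stop("phenotype counts must sum to the disease-associated total")
  total <- sum(events)
  if (!is.null(af_strata) && sum(af_strata$n) > total)
    stop("allele-frequency strata exceed the census size")
  if (total == 0L)
    return(as_census(empty_census_frame()))

  set.seed(seed)
  seq1 <- strsplit(as.character(fxi_sequence()[[1]]), "")[[1]]
  M <- reachability_matrix()
  rows <- empty_census_frame()
  used <- character(0)
  draw_change <- function(kind) {
    # kind: missense / nonsense / silent
    repeat {
      res <- sample(19:625, 1L)
      ref <- aa_one_to_three(seq1[res])
      alt <- switch(kind,
        silent = ref,
        nonsense = if (M[ref, "*"]) "*" else NA_character_,
        missense = {
          ok <- AA3[M[ref, AA3] & AA3 != ref]
          if (length(ok)) sample(ok, 1L) else NA_character_
        })
      if (is.na(alt)) next
      pc <- paste0(ref, res, alt)
      if (!pc %in% used) { used <<- c(used, pc); return(pc) }
    }
  }
  add_row <- function(pc, event, effect, phenotype) {
    rows[nrow(rows) + 1L, ] <<- list(pc, NA_character_, event, effect,
                                     phenotype, NA_real_, NA_real_,
                                     NA_real_, 1L, FALSE, 1L)
  }
  for (ef in names(effects)) {
    for (k in seq_len(effects[[ef]])) {
      pc <- if (ef == "undefined") NA_character_ else draw_change(ef)
      add_row(pc, "point", ef, "unknown")
    }
  }
  for (ev in setdiff(names(events), c("point", "polymorphism")))
    for (k in seq_len(events[[ev]]))
      add_row(NA_character_, ev, "undefined", "unknown")
  if ("polymorphism" %in% names(events))
    for (k in seq_len(events[["polymorphism"]]))
      add_row(NA_character_, "polymorphism", "undefined", "polymorphism")
  # spread phenotypes over the disease-associated rows, reproducibly
  disease_idx <- which(rows$phenotype == "unknown")
  assign <- sample(rep(names(phenotypes), phenotypes))
  rows$phenotype[disease_idx] <- assign
  if (!is.null(af_strata)) {
    idx <- sample(seq_len(nrow(rows)), sum(af_strata$n))
    rows$allele_frequency[idx] <- rep(af_strata$af, af_strata$n)
  }
  as_census(rows)
}

empty_census_frame <- function() {
  data.frame(protein_change = character(0), cdna_change = character(0),
             event_type = character(0), effect = character(0),
             phenotype = character(0), fxi_c = numeric(0),
             fxi_ag = numeric(0), allele_frequency = numeric(0),
             n_patients = integer(0), aggregate = logical(0),
             count = integer(0), stringsAsFactors = FALSE)
}
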