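#' Conserved cysteine anchor positions of the FXI Apple domains
#'
#' The six conserved cysteines of each Apple domain (C1..C6 in sequence
#' order), in HGVS numbering: the C1-C6, C2-C5 and C3-C4 pairs form the
#' three intradomain disulfide bridges. Cys339 of Ap4, the interchain
#' half-cystine, is not one of the six conserved anchors.
#'
#' @return named list of length-6 integer vectors (Ap1..Ap4).
#' @export
apple_cys_anchors <- function() {
  list(Ap1 = c(20, 46, 50, 56, 76, 103),
       Ap2 = c(110, 136, 140, 146, 165, 193),
       Ap3 = c(200, 226, 230, 236, 255, 283),
       Ap4 = c(291, 317, 321, 327, 346, 374))
}

#' Extract the Apple-domain sequences from a full FXI sequence
#'
#' @param sequence full precursor sequence: a single character string
#'   (one-letter codes, HGVS position = string index) or an
#'   `AAString`/`AAStringSet` of length one.
#' @param map a [domain_map()].
#' @return named character vector of the Ap1..Ap4 sequences, with
#'   attribute `starts` giving the HGVS number of each first residue.
#' @export
apple_sequences <- function(sequence, map = default_domain_map()) {
  if (inherits(sequence, "AAStringSet")) sequence <- sequence[[1]]
  sequence <- as.character(sequence)
  ap <- map[grepl("^Ap", map$name), , drop = FALSE]
  out <- vapply(seq_len(nrow(ap)),
                function(i) substr(sequence, ap$start[i], ap$end[i]),
                character(1))
  names(out) <- ap$name
  attr(out, "starts") <- stats::setNames(ap$start, ap$name)
  out
}

# Align one segment of each domain to the reference segment and lay the
# residues out on reference-anchored columns (insertions left-aligned
# after their preceding reference position). Returns, per domain, the
# 0-based column offsets of its residues, plus the segment width.
align_segment <- function(segs, reference, submat, gap_opening,
                          gap_extension) {
  ref_seq <- segs[[reference]]
  nref <- nchar(ref_seq)
  ins_after <- integer(nref + 1L)  # index r+1 = insertions after ref pos r
  placed <- list()
  for (nm in names(segs)) {
    s <- segs[[nm]]
    if (nm == reference) { placed[[nm]] <- list(ref = seq_len(nref)); next }
    if (nchar(s) == 0L) { placed[[nm]] <- list(ref = integer(0)); next }
    if (nref == 0L) {
      placed[[nm]] <- list(ins = list(r = 0L, k = seq_len(nchar(s))))
      ins_after[1L] <- max(ins_after[1L], nchar(s))
      next
    }
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s), Biostrings::AAString(ref_seq),
      type = "global", substitutionMatrix = submat,
      gapOpening = gap_opening, gapExtension = gap_extension)
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    q <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    r <- 0L; slot <- 0L
    pos <- vector("list", nchar(s)); k <- 0L
    for (t in seq_along(p)) {
      if (q[t] != "-") { r <- r + 1L; slot <- 0L }
      if (p[t] != "-") {
        k <- k + 1L
        if (q[t] != "-") pos[[k]] <- list(type = "ref", at = r)
        else {
          slot <- slot + 1L
          pos[[k]] <- list(type = "ins", at = r, slot = slot)
          ins_after[r + 1L] <- max(ins_after[r + 1L], slot)
        }
      }
    }
    placed[[nm]] <- list(detail = pos)
  }
  # column offset of ref position r and of insertion slot s after r
  ref_col <- cumsum(ins_after[seq_len(nref)] + 1L)
  ins_base <- c(0L, ref_col)[seq_len(nref + 1L)]
  width <- if (nref) ref_col[nref] + ins_after[nref + 1L] else ins_after[1L]
  cols <- list()
  for (nm in names(segs)) {
    pl <- placed[[nm]]
    if (!is.null(pl$ref)) {
      cols[[nm]] <- ref_col[pl$ref]
    } else if (!is.null(pl$ins)) {
      cols[[nm]] <- ins_base[pl$ins$r + 1L] + pl$ins$k
    } else {
      cols[[nm]] <- vapply(pl$detail, function(e) {
        if (e$type == "ref") ref_col[e$at]
        else ins_base[e$at + 1L] + e$slot
      }, integer(1))
    }
  }
  list(cols = cols, width = width)
}

#' Align the four Apple-domain sequences into a consensus frame
#'
#' Builds a consensus alignment of the four Apple domains in which the
#' six conserved cysteines are forced into common anchor columns
#' (labelled C1..C6) and the inter-anchor segments are aligned to the
#' reference domain (Ap2, the domain conventionally taken to represent
#' the consensus) by standard global alignment with a substitution
#' matrix and affine gaps. With `anchors = NULL` no constraint is
#' applied and the whole sequence is aligned as one segment.
#'
#' @param sequences named character vector of domain sequences
#'   (one-letter codes).
#' @param anchors named list of anchor positions (HGVS numbering, equal
#'   length across domains), as [apple_cys_anchors()]; or `NULL`.
#' @param starts named integer vector, HGVS number of the first residue
#'   of each sequence (defaults to the `starts` attribute, else 1).
#' @param reference name of the reference domain; default `"Ap2"` when
#'   present.
#' @param substitution_matrix name of a substitution matrix shipped
#'   with Biostrings (default `"BLOSUM62"`).
#' @param gap_opening,gap_extension affine gap penalties.
#' @return a `consensus_map` list: `length` (number of columns),
#'   `mapping` (per domain, named integer vector residue -> column),
#'   `cys_columns` (named C1..C6), `residues` (per-column character
#'   matrix, domains x columns).
#' @export
align_apples <- function(sequences, anchors = apple_cys_anchors(),
                         starts = NULL,
                         reference = if ("Ap2" %in% names(sequences))
                           "Ap2" else names(sequences)[1],
                         substitution_matrix = "BLOSUM62",
                         gap_opening = 10, gap_extension = 0.5) {
  doms <- names(sequences)
  if (is.null(doms)) stop("sequences must be named")
  if (is.null(starts)) {
    starts <- attr(sequences, "starts")
    if (is.null(starts)) starts <- stats::setNames(rep(1L, length(sequences)),
                                                   doms)
  }
  submat <- substitution_matrix
  n_anchor <- if (is.null(anchors)) 0L else length(anchors[[1]])
  if (n_anchor > 0L) {
    for (nm in doms) {
      if (length(anchors[[nm]]) != n_anchor)
        stop("all domains need the same number of anchors")
      rel <- anchors[[nm]] - starts[[nm]] + 1L
      aa <- substring(sequences[[nm]], rel, rel)
      if (any(aa != "C"))
        stop("domain ", nm, " lacks Cys at anchor position(s) ",
             paste(anchors[[nm]][aa != "C"], collapse = ", "))
    }
  }
  # cut each domain into alternating segments and anchor singletons
  seg_bounds <- function(nm) {
    s <- starts[[nm]]; e <- s + nchar(sequences[[nm]]) - 1L
    a <- if (n_anchor) anchors[[nm]] else integer(0)
    lo <- c(s, a + 1L)
    hi <- c(a - 1L, e)
    cbind(lo, hi)
  }
  col_cursor <- 0L
  mapping <- lapply(doms, function(nm) integer(0))
  names(mapping) <- doms
  cys_columns <- integer(0)
  for (k in seq_len(n_anchor + 1L)) {
    segs <- lapply(doms, function(nm) {
      b <- seg_bounds(nm)[k, ]
      if (b[2] < b[1]) "" else
        substring(sequences[[nm]],
                  b[1] - starts[[nm]] + 1L, b[2] - starts[[nm]] + 1L)
    })
    names(segs) <- doms
    al <- align_segment(segs, reference, submat, gap_opening,
                        gap_extension)
    for (nm in doms) {
      b <- seg_bounds(nm)[k, ]
      if (b[2] >= b[1]) {
        resn <- seq.int(b[1], b[2])
        mapping[[nm]] <- c(mapping[[nm]],
                           stats::setNames(col_cursor + al$cols[[nm]], resn))
      }
    }
    col_cursor <- col_cursor + al$width
    if (k <= n_anchor) {
      col_cursor <- col_cursor + 1L
      cys_columns <- c(cys_columns, col_cursor)
      for (nm in doms)
        mapping[[nm]] <- c(mapping[[nm]],
                           stats::setNames(col_cursor, anchors[[nm]][k]))
    }
  }
  mapping <- lapply(mapping, function(m) m[order(as.integer(names(m)))])
  if (any(vapply(mapping, function(m) any(diff(m) <= 0), logical(1))))
    stop("internal error: non-increasing column mapping")
  if (n_anchor)
    names(cys_columns) <- paste0("C", seq_len(n_anchor))
  L <- col_cursor
  residues <- matrix("-", length(doms), L,
                     dimnames = list(doms, NULL))
  for (nm in doms) {
    rel <- as.integer(names(mapping[[nm]])) - starts[[nm]] + 1L
    residues[nm, mapping[[nm]]] <-
      strsplit(sequences[[nm]], "")[[1]][rel]
  }
  out <- list(length = L, mapping = mapping, cys_columns = cys_columns,
              residues = residues, starts = starts)
  class(out) <- "consensus_map"
  out
}

#' Project census variants onto consensus Apple-domain columns
#'
#' Each qualifying variant (by default substitutions: missense records,
#' including missense polymorphisms) residing in an Apple domain
#' increments the tally of its consensus column. The dominant phenotype
#' per column is the modal phenotype of its variants, with ties
#' reported as `"unknown"`. Variants outside the Apple domains are
#' excluded and counted in the `n_excluded` attribute (with a message).
#'
#' @param census a `fxi_census`.
#' @param cmap a `consensus_map` from [align_apples()].
#' @param effects effects to project.
#' @return data.frame, one row per consensus column: `column`,
#'   `cys_index` (`""` for non-anchor columns), per-domain residue
#'   letters, `tally`, `dominant_phenotype`.
#' @export
project_variants <- function(census, cmap, effects = c("missense")) {
  keep <- !is.na(census$residue) & census$effect %in% effects
  v <- census[keep, , drop = FALSE]
  col_of <- rep(NA_integer_, nrow(v))
  for (nm in names(cmap$mapping)) {
    idx <- match(v$residue, as.integer(names(cmap$mapping[[nm]])))
    hit <- !is.na(idx)
    col_of[hit] <- cmap$mapping[[nm]][idx[hit]]
  }
  excluded <- sum(is.na(col_of))
  if (excluded)
    message(excluded, " variant(s) outside the Apple domains excluded")
  v <- v[!is.na(col_of), , drop = FALSE]
  col_of <- col_of[!is.na(col_of)]
  tally <- tabulate(col_of, nbins = cmap$length)
  dominant <- rep("", cmap$length)
  for (cl in unique(col_of)) {
    ph <- v$phenotype[col_of == cl]
    tt <- sort(table(ph), decreasing = TRUE)
    dominant[cl] <- if (length(tt) > 1L && tt[1] == tt[2]) "unknown"
                    else names(tt)[1]
  }
  cys_index <- rep("", cmap$length)
  cys_index[cmap$cys_columns] <- names(cmap$cys_columns)
  out <- data.frame(column = seq_len(cmap$length), cys_index = cys_index,
                    t(cmap$residues), tally = tally,
                    dominant_phenotype = dominant,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- excluded
  out
}

#' Read a protein sequence from a FASTA file
#' @param path path to a FASTA file.
#' @return `AAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readAAStringSet(path)
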