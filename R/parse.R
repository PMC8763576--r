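#' Parse an HGVS-style protein change
#'
#' Accepts changes written with one- or three-letter amino acid codes,
#' e.g. `"Cys56Arg"`, `"Glu135*"`, `"Ala100Ala"`, `"C56R"`. The effect is
#' derived from the parsed residues: stop replacement is nonsense,
#' identical reference and alternate is silent, anything else missense.
#'
#' @param text character vector of protein-change strings.
#' @return a data.frame with columns `protein_change` (normalised
#'   three-letter form), `ref_aa`, `residue`, `alt_aa` and `effect`.
#' @export
#' @examples
#' parse_protein_change(c("Phe301Leu", "Glu135*", "Ala100Ala"))
parse_protein_change <- function(text) {
  re3 <- "^([A-Za-z]{3})([0-9]+)([A-Za-z]{3}|\\*)$"
  re1 <- "^([A-Za-z])([0-9]+)([A-Za-z]|\\*)$"
  n <- length(text)
  ref <- alt <- chg <- character(n)
  res <- integer(n)
  for (i in seq_len(n)) {
    x <- trimws(text[[i]])
    m <- regmatches(x, regexec(re3, x))[[1]]
    if (length(m) == 0L) m <- regmatches(x, regexec(re1, x))[[1]]
    if (length(m) == 0L)
      stop("cannot parse protein change: '", x, "'")
    ref[i] <- aa_normalize(m[2], allow_stop = FALSE)
    res[i] <- as.integer(m[3])
    alt[i] <- aa_normalize(m[4])
    chg[i] <- paste0(ref[i], res[i], alt[i])
  }
  effect <- ifelse(alt == "*", "nonsense",
                   ifelse(ref == alt, "silent", "missense"))
  data.frame(protein_change = chg, ref_aa = ref, residue = res,
             alt_aa = alt, effect = effect, stringsAsFactors = FALSE)
}

#' Expand slashed multi-substitution shorthand
#'
#' The literature often lists several substitutions at one residue as
#' e.g. `"Cys56Arg/Trp"`, meaning Cys56Arg and Cys56Trp. This expands
#' such shorthand into one protein-change string per alternate residue,
#' preserving order. Strings without a slash pass through unchanged
#' (after normalisation by [parse_protein_change()] syntax rules).
#'
#' @param text a single protein-change string, possibly slashed.
#' @return character vector of individual protein-change strings.
#' @export
#' @examples
#' expand_shorthand("Cys56Arg/Trp")
expand_shorthand <- function(text) {
  stopifnot(length(text) == 1L)
  parts <- strsplit(trimws(text), "/", fixed = TRUE)[[1]]
  if (length(parts) == 0L) stop("empty protein change")
  head_parsed <- parse_protein_change(parts[1])
  out <- head_parsed$protein_change
  if (length(parts) > 1L) {
    extra <- vapply(parts[-1], function(a) {
      paste0(head_parsed$ref_aa, head_parsed$residue, aa_normalize(a))
    }, character(1))
    out <- c(out, unname(extra))
  }
  out
}
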