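#' Amino acid code tables
#'
#' Conversion between one-letter and three-letter amino acid codes. The
#' stop codon is written `*` in both conventions.
#'
#' @name aa-codes
#' @keywords internal
NULL

AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3

#' Normalize an amino acid token to the three-letter code
#'
#' Accepts one-letter codes, three-letter codes (any case for the first
#' letter), or the stop symbol `*` / `Ter` / `X`. Vectorised.
#'
#' @param aa character vector of amino acid tokens.
#' @param allow_stop logical; accept the stop symbol.
#' @return character vector of three-letter codes (`"*"` for stop).
#' @export
#' @examples
#' aa_normalize(c("C", "cys", "Trp", "*"))
aa_normalize <- function(aa, allow_stop = TRUE) {
  out <- character(length(aa))
  for (i in seq_along(aa)) {
    x <- aa[[i]]
    if (is.na(x)) { out[i] <- NA_character_; next }
    x <- trimws(x)
    if (x %in% c("*", "Ter", "ter", "X", "x", "stop", "Stop")) {
      if (!allow_stop) stop("stop symbol not allowed here: ", aa[[i]])
      out[i] <- "*"
    } else if (nchar(x) == 1L) {
      hit <- match(toupper(x), AA1)
      if (is.na(hit)) stop("unknown amino acid code: ", x)
      out[i] <- AA3[hit]
    } else if (nchar(x) == 3L) {
      x3 <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))
      if (!x3 %in% AA3) stop("unknown amino acid code: ", x)
      out[i] <- x3
    } else {
      stop("unknown amino acid code: ", x)
    }
  }
  out
}

#' Three-letter to one-letter conversion
#' @param aa3 character vector of three-letter codes (or `"*"`).
#' @return one-letter codes.
#' @export
aa_three_to_one <- function(aa3) {
  ifelse(aa3 == "*", "*", unname(AA1[aa3]))
}

#' One-letter to three-letter conversion
#' @param aa1 character vector of one-letter codes (or `"*"`).
#' @return three-letter codes.
#' @export
aa_one_to_three <- function(aa1) {
  ifelse(aa1 == "*", "*", AA3[match(toupper(aa1), AA1)])
}
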