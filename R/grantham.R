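#' Amino acid physicochemical properties for the Grantham distance
#'
#' Composition (c, atomic weight ratio of non-carbon elements in side
#' groups), polarity (p) and molecular volume (v) for the 20 standard
#' amino acids, as tabulated in 1974.
#'
#' @return data.frame with columns `aa` (three-letter code), `c`, `p`,
#'   `v`.
#' @export
grantham_properties <- function() {
  data.frame(
    aa = c("Ser", "Arg", "Leu", "Pro", "Thr", "Ala", "Val", "Gly", "Ile",
           "Phe", "Tyr", "Cys", "His", "Gln", "Asn", "Lys", "Asp", "Glu",
           "Met", "Trp"),
    c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0, 0.20, 2.75, 0.58,
          0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
    p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2, 6.2, 5.5,
          10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
    v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132, 136, 55, 96, 85,
          56, 119, 54, 83, 105, 170),
    stringsAsFactors = FALSE)
}

#' Build the Grantham distance matrix
#'
#' The chemical distance between amino acids i and j is
#' \deqn{D_{ij} = \rho \sqrt{\alpha (c_i-c_j)^2 + \beta (p_i-p_j)^2 +
#'   \gamma (v_i-v_j)^2}}
#' with composition c, polarity p and molecular volume v. The
#' normalisation constant \eqn{\rho} is fixed so that the mean over the
#' 190 unordered pairs of distinct amino acids equals `mean_distance`
#' (100 by convention), and scores are rounded to integers, giving the
#' familiar range of 5 (Leu-Ile) to 215 (Cys-Trp) with zero diagonal.
#'
#' @param props property table as from [grantham_properties()].
#' @param alpha,beta,gamma weighting coefficients for the squared
#'   property differences.
#' @param mean_distance target mean over unordered non-identical pairs.
#' @param round_scores logical; round to integers (the published form).
#' @return 20x20 symmetric numeric matrix with three-letter dimnames.
#' @export
#' @examples
#' G <- grantham_matrix()
#' G["Leu", "Ile"]  # 5, the smallest non-identical distance
#' max(G)           # 215 (Cys-Trp)
grantham_matrix <- function(props = grantham_properties(), alpha = 1.833,
                            beta = 0.1018, gamma = 0.000399,
                            mean_distance = 100, round_scores = TRUE) {
  stopifnot(nrow(props) == 20L, !anyDuplicated(props$aa))
  d2 <- function(x) outer(x, x, "-")^2
  raw <- sqrt(alpha * d2(props$c) + beta * d2(props$p) + gamma * d2(props$v))
  rho <- mean_distance / mean(raw[upper.tri(raw)])
  D <- rho * raw
  if (round_scores) D <- round_half_up(D, 0)
  dimnames(D) <- list(props$aa, props$aa)
  D
}

#' Grantham distance between two amino acids
#'
#' @param ref_aa,alt_aa amino acids (one- or three-letter code). Stop
#'   codons have no defined Grantham score and are rejected.
#' @param matrix a matrix from [grantham_matrix()].
#' @return numeric vector of scores (0 for identical residues).
#' @export
#' @examples
#' grantham_distance("Phe", "Leu")  # 22
grantham_distance <- function(ref_aa, alt_aa, matrix = grantham_matrix()) {
  ref <- aa_normalize(ref_aa, allow_stop = TRUE)
  alt <- aa_normalize(alt_aa, allow_stop = TRUE)
  if (any(ref == "*" | alt == "*"))
    stop("Grantham distance is undefined for stop codons")
  matrix[cbind(ref, alt)]
}

#' Write the amino acid property table as CSV
#' @param props table from [grantham_properties()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grantham_properties <- function(props = grantham_properties(), path) {
  utils::write.csv(props, path, row.names = FALSE)
  invisible(path)
}
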