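#' Construct a domain map over HGVS residue numbering
#'
#' A domain map is an ordered set of contiguous, non-overlapping residue
#' intervals covering the full FXI precursor (1..625 by default): the
#' signal peptide, the four Apple domains and the serine protease (SP)
#' domain.
#'
#' @param name character vector of domain names.
#' @param start,end integer vectors of first/last HGVS residue per domain.
#' @return a `domain_map` data.frame with columns `name`, `start`, `end`.
#' @export
#' @examples
#' default_domain_map()
domain_map <- function(name, start, end) {
  map <- data.frame(name = as.character(name), start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  if (any(map$end < map$start)) stop("domain end before start")
  o <- order(map$start)
  map <- map[o, , drop = FALSE]
  if (nrow(map) > 1L) {
    gaps <- map$start[-1L] - map$end[-nrow(map)]
    if (any(gaps != 1L))
      stop("domain intervals must be contiguous and non-overlapping")
  }
  if (anyDuplicated(map$name)) stop("duplicate domain names")
  rownames(map) <- NULL
  class(map) <- c("domain_map", "data.frame")
  map
}

#' Default FXI domain map
#'
#' Signal peptide 1-18, Apple domains Ap1 19-108, Ap2 109-198, Ap3
#' 199-288, Ap4 289-379, and the serine protease domain 380-625. The
#' Apple intervals bracket the conserved disulfide spans of each domain
#' (Ap1 Cys20-Cys103 through Ap4 Cys291-Cys374) and the SP interval
#' starts at the first SP-domain half-cystine (Cys380), upstream of the
#' Arg387-Ile388 activation site.
#'
#' @return a [domain_map()].
#' @export
default_domain_map <- function() {
  domain_map(name  = c("signal", "Ap1", "Ap2", "Ap3", "Ap4", "SP"),
             start = c(1, 19, 109, 199, 289, 380),
             end   = c(18, 108, 198, 288, 379, 625))
}

#' Assign residues to domains
#'
#' @param residue_hgvs integer vector of HGVS residue numbers.
#' @param map a [domain_map()]; defaults to [default_domain_map()].
#' @return character vector of domain names; `NA` for residues outside
#'   the map (with `strict = TRUE` an error instead).
#' @param strict logical; error on residues outside the map.
#' @export
#' @examples
#' assign_domain(c(301, 575, 135))
assign_domain <- function(residue_hgvs, map = default_domain_map(),
                          strict = FALSE) {
  residue_hgvs <- as.integer(residue_hgvs)
  idx <- findInterval(residue_hgvs, map$start)
  out <- rep(NA_character_, length(residue_hgvs))
  ok <- !is.na(residue_hgvs) & idx >= 1L & idx <= nrow(map)
  ok[ok] <- residue_hgvs[ok] <= map$end[idx[ok]]
  out[ok] <- map$name[idx[ok]]
  if (strict && any(!ok & !is.na(residue_hgvs)))
    stop("residue outside the domain map: ",
         paste(residue_hgvs[!ok & !is.na(residue_hgvs)], collapse = ", "))
  out
}

#' Names of the Apple domains in a map
#' @param map a [domain_map()].
#' @return character vector of domain names starting with "Ap".
#' @keywords internal
apple_domains <- function(map = default_domain_map()) {
  map$name[grepl("^Ap", map$name)]
}
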