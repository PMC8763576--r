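EVENT_TYPES <- c("point", "deletion", "insertion", "duplication",
                 "polymorphism", "undefined")
EFFECTS <- c("missense", "nonsense", "silent", "undefined")
PHENOTYPES <- c("type_I", "type_II", "unknown", "polymorphism")

#' Round half away from zero
#'
#' Printed percentages in the census tables are rounded half-up (73.53
#' style), which differs from R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read a variant census table
#'
#' Reads the census CSV schema: columns `protein_change`, `cdna_change`,
#' `event_type`, `effect`, `phenotype`, `fxi_c`, `fxi_ag`,
#' `allele_frequency`, `n_patients`, `aggregate`, `count`. Per-variant
#' rows (`aggregate = FALSE`, `count = 1`) carry a parseable protein
#' change where one is known; aggregate rows (`aggregate = TRUE`)
#' represent `count` distinct variants whose individual identities are
#' not recorded, and enter tabulations with that weight.
#'
#' Protein changes are parsed on read; parsed fields (`ref_aa`,
#' `residue`, `alt_aa`) are appended, and a stated `effect` that
#' contradicts the parsed change is an error.
#'
#' @param path path to the CSV file.
#' @return a `fxi_census` data.frame.
#' @export
read_census <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  as_census(raw)
}

#' Validate and annotate a raw census data.frame
#'
#' @param raw data.frame in the census CSV schema (see [read_census()]).
#' @return a `fxi_census` data.frame with parsed residue fields.
#' @export
as_census <- function(raw) {
  needed <- c("protein_change", "cdna_change", "event_type", "effect",
              "phenotype", "fxi_c", "fxi_ag", "allele_frequency",
              "n_patients", "aggregate", "count")
  miss <- setdiff(needed, names(raw))
  if (length(miss))
    stop("census table is missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(raw)
  if (n == 0L) {
    out <- raw
    out$ref_aa <- character(0); out$residue <- integer(0)
    out$alt_aa <- character(0)
    class(out) <- c("fxi_census", "data.frame")
    return(out)
  }
  raw$aggregate <- as.logical(raw$aggregate)
  raw$count <- as.integer(raw$count)
  raw$n_patients <- as.integer(raw$n_patients)
  for (i in seq_len(n)) {
    if (!raw$event_type[i] %in% EVENT_TYPES)
      stop("row ", i, ": unknown event_type '", raw$event_type[i], "'")
    if (!raw$effect[i] %in% EFFECTS)
      stop("row ", i, ": unknown effect '", raw$effect[i], "'")
    if (!raw$phenotype[i] %in% PHENOTYPES)
      stop("row ", i, ": unknown phenotype '", raw$phenotype[i], "'")
    if (is.na(raw$count[i]) || raw$count[i] < 1L)
      stop("row ", i, ": count must be a positive integer")
    if (!raw$aggregate[i] && raw$count[i] != 1L)
      stop("row ", i, ": per-variant rows must have count = 1")
  }
  # polymorphism labelling is two-way: event type and phenotype agree
  bad <- xor(raw$event_type == "polymorphism", raw$phenotype == "polymorphism")
  if (any(bad))
    stop("row ", which(bad)[1],
         ": polymorphism event type and phenotype must agree")
  af <- raw$allele_frequency
  if (any(!is.na(af) & (af < 0 | af > 1)))
    stop("allele_frequency must lie in [0, 1]")

  ref <- alt <- rep(NA_character_, n)
  res <- rep(NA_integer_, n)
  has_pc <- !is.na(raw$protein_change)
  if (any(has_pc)) {
    parsed <- parse_protein_change(raw$protein_change[has_pc])
    ref[has_pc] <- parsed$ref_aa
    res[has_pc] <- parsed$residue
    alt[has_pc] <- parsed$alt_aa
    raw$protein_change[has_pc] <- parsed$protein_change
    stated <- raw$effect[has_pc]
    derived <- parsed$effect
    clash <- stated != "undefined" & stated != derived
    if (any(clash))
      stop("row ", which(has_pc)[clash][1], ": stated effect '",
           stated[clash][1], "' contradicts protein change '",
           parsed$protein_change[clash][1], "'")
    raw$effect[has_pc] <- derived
    if (any(res[has_pc] < 1L | res[has_pc] > 625L))
      stop("protein residue numbers must lie in 1..625")
  }
  raw$ref_aa <- ref
  raw$residue <- res
  raw$alt_aa <- alt
  dup <- has_pc & duplicated(raw$protein_change) & !raw$aggregate
  if (any(dup))
    stop("duplicate variant: ", raw$protein_change[which(dup)[1]])
  class(raw) <- c("fxi_census", "data.frame")
  raw
}

#' Write a census table in the standard CSV schema
#' @param census a `fxi_census` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  cols <- c("protein_change", "cdna_change", "event_type", "effect",
            "phenotype", "fxi_c", "fxi_ag", "allele_frequency",
            "n_patients", "aggregate", "count")
  utils::write.csv(as.data.frame(census)[, cols], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Classify a variant phenotype from activity and antigen levels
#'
#' FXI coagulant activity (FXI:C) within the normal range marks an
#' unaffected measurement. Below it, a FXI:C to FXI:Ag ratio < 0.7
#' indicates a dysfunctional but normally secreted protein (Type II,
#' CRM+); otherwise activity and antigen fall together (Type I, CRM-).
#' A missing antigen measurement leaves the phenotype unknown.
#'
#' @param fxi_c FXI coagulant activity, IU/dL.
#' @param fxi_ag FXI antigen level, IU/dL.
#' @param normal_range length-2 numeric, normal FXI:C range in IU/dL.
#' @param ratio_cutoff FXI:C / FXI:Ag ratio below which a deficient
#'   measurement is called Type II.
#' @return character vector: `"type_I"`, `"type_II"`, `"unaffected"` or
#'   `"unknown"`.
#' @export
#' @examples
#' classify_phenotype(30, 100)  # type_II
#' classify_phenotype(30, 35)   # type_I
classify_phenotype <- function(fxi_c, fxi_ag, normal_range = c(70, 150),
                               ratio_cutoff = 0.7) {
  n <- max(length(fxi_c), length(fxi_ag))
  fxi_c <- rep_len(fxi_c, n); fxi_ag <- rep_len(fxi_ag, n)
  if (any(stats::na.omit(c(fxi_c, fxi_ag)) <= 0))
    stop("activity and antigen measurements must be positive")
  out <- rep("unknown", n)
  normal <- !is.na(fxi_c) & fxi_c >= normal_range[1] & fxi_c <= normal_range[2]
  out[normal] <- "unaffected"
  low <- !is.na(fxi_c) & !normal
  known <- low & !is.na(fxi_ag)
  out[known & fxi_c / fxi_ag < ratio_cutoff] <- "type_II"
  out[known & fxi_c / fxi_ag >= ratio_cutoff] <- "type_I"
  out
}

#' Split a census by allele-frequency rarity
#'
#' Commonly-occurring variants have an allele frequency above the
#' cut-off; records without an allele frequency are counted separately.
#' Aggregate rows contribute their `count`.
#'
#' @param census a `fxi_census`.
#' @param af_cutoff allele-frequency cut-off in (0, 1); default 0.01.
#' @return named list: `n_common` (AF > cutoff), `n_rare` (AF <= cutoff),
#'   `n_no_af` (no frequency recorded).
#' @export
rarity_filter <- function(census, af_cutoff = 0.01) {
  stopifnot(af_cutoff > 0, af_cutoff < 1)
  if (nrow(census) == 0L)
    return(list(n_common = 0L, n_rare = 0L, n_no_af = 0L))
  w <- census$count
  af <- census$allele_frequency
  list(n_common = sum(w[!is.na(af) & af > af_cutoff]),
       n_rare   = sum(w[!is.na(af) & af <= af_cutoff]),
       n_no_af  = sum(w[is.na(af)]))
}

pct_table <- function(counts, denom, digits = 2) {
  data.frame(category = names(counts), count = as.integer(counts),
             percent = round_half_up(100 * as.integer(counts) / denom,
                                     digits),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tabulate a variant census
#'
#' Counts and percentages (two decimal places, rounded half-up) of
#' unique variants: by genetic event type over all variants; by effect
#' over point variants; by phenotype over disease-associated variants
#' (everything that is not a polymorphism); and by domain over all
#' variants. Aggregate rows contribute their `count`; rows without a
#' residue position fall in domain `unassigned`.
#'
#' @param census a `fxi_census`.
#' @param map a [domain_map()].
#' @return a `census_summary` list with elements `by_event`, `by_effect`,
#'   `by_phenotype`, `by_domain` (data.frames category/count/percent) and
#'   `denominators`.
#' @export
tabulate_census <- function(census, map = default_domain_map()) {
  w <- census$count
  total <- sum(w)
  ev <- tapply(w, factor(census$event_type, EVENT_TYPES), sum,
               default = 0L)
  point <- census$event_type == "point"
  ef <- tapply(w[point], factor(census$effect[point], EFFECTS), sum,
               default = 0L)
  disease <- census$phenotype != "polymorphism"
  ph <- tapply(w[disease],
               factor(census$phenotype[disease],
                      setdiff(PHENOTYPES, "polymorphism")),
               sum, default = 0L)
  dom <- assign_domain(census$residue, map)
  dom[is.na(dom)] <- "unassigned"
  dm <- tapply(w, factor(dom, c(map$name, "unassigned")), sum,
               default = 0L)
  out <- list(
    by_event     = pct_table(ev, total),
    by_effect    = pct_table(ef, sum(w[point])),
    by_phenotype = pct_table(ph, sum(w[disease])),
    by_domain    = pct_table(dm, total),
    denominators = list(total = total, point = sum(w[point]),
                        disease_associated = sum(w[disease]),
                        polymorphisms = sum(w[!disease])))
  class(out) <- "census_summary"
  out
}

#' @export
print.census_summary <- function(x, ...) {
  cat("FXI variant census:", x$denominators$total, "variants (",
      x$denominators$disease_associated, "disease-associated,",
      x$denominators$polymorphisms, "polymorphisms )\n")
  for (nm in c("by_event", "by_effect", "by_phenotype", "by_domain")) {
    cat("\n", sub("by_", "By ", nm), ":\n", sep = "")
    print(x[[nm]], row.names = FALSE)
  }
  invisible(x)
}

#' Census of cysteine variants
#'
#' Cys-loss variants substitute or truncate a native cysteine (missense
#' or nonsense at a Cys codon); Cys-gain variants introduce a new
#' cysteine. Distinct variants are counted once; aggregate rows carry no
#' residue identity and are excluded.
#'
#' @param census a `fxi_census`.
#' @param map a [domain_map()].
#' @return list with `n_cys_loss`, `n_cys_loss_apple`, `n_cys_loss_sp`,
#'   `n_cys_gain`, and per-phenotype breakdowns `loss_by_phenotype`,
#'   `gain_by_phenotype`, plus the underlying row subsets `loss`, `gain`.
#' @export
cys_census <- function(census, map = default_domain_map()) {
  pc <- !is.na(census$protein_change)
  loss <- census[pc & census$ref_aa == "Cys" &
                   census$effect %in% c("missense", "nonsense"), ,
                 drop = FALSE]
  gain <- census[pc & !is.na(census$alt_aa) & census$alt_aa == "Cys" &
                   census$effect == "missense", , drop = FALSE]
  dom <- assign_domain(loss$residue, map)
  list(n_cys_loss = nrow(loss),
       n_cys_loss_apple = sum(dom %in% apple_domains(map)),
       n_cys_loss_sp = sum(dom == "SP"),
       n_cys_gain = nrow(gain),
       loss_by_phenotype = table(factor(loss$phenotype, PHENOTYPES)),
       gain_by_phenotype = table(factor(gain$phenotype, PHENOTYPES)),
       loss = loss, gain = gain)
}
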