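report_header <- function(inputs) {
  ver <- as.character(utils::packageVersion("fxivar"))
  hashes <- vapply(inputs, function(p) unname(tools::md5sum(p)),
                   character(1))
  c(paste0("# fxivar ", ver),
    paste0("# input ", names(inputs), " md5=", hashes))
}

write_report <- function(df, path, inputs, row_names = FALSE,
                         col_names = TRUE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(report_header(inputs), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = row_names,
                     col.names = if (row_names) NA else col_names)
  invisible(path)
}

#' Run the full FXI variant analysis and write a report bundle
#'
#' Drives every stage of the analysis from a configuration (a named
#' list or the path of a YAML file) and writes tab-separated reports to
#' `out_dir`. Census-level reports (census summary, rarity split,
#' cysteine census, substitution grid, Grantham scores, disulfide
#' census, consensus Apple projection) are always produced; structural
#' reports (accessibility profile, variant burial cross-tabulation,
#' domain-separation deltas, interface and disulfide geometry) are added
#' when a structure file is configured. Every report opens with comment
#' lines carrying the tool version and the MD5 hash of each input, and
#' identical configuration plus inputs yields byte-identical reports
#' (the SASA sampling is deterministic).
#'
#' Configuration fields: `census` (CSV path; required), `structure`
#' (PDB/mmCIF path; optional), `sequence` (FASTA; defaults to the
#' bundled one), `disulfides` (CSV; defaults to the bundled table),
#' `out_dir` (required), and optional numeric parameters `probe_radius`
#' (1.4), `n_points` (960), `bsa_cutoff` (5), `af_cutoff` (0.01), and
#' `domain_map` (data.frame-coercible with name/start/end).
#'
#' @param config named list, or path to a YAML file with the same
#'   fields.
#' @return invisibly, the character vector of files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$census)) stop("config must name a census file")
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  probe <- config$probe_radius %||% 1.4
  npts <- config$n_points %||% 960
  bsa_cut <- config$bsa_cutoff %||% 5
  af_cut <- config$af_cutoff %||% 0.01
  map <- if (is.null(config$domain_map)) default_domain_map()
         else do.call(domain_map, as.list(as.data.frame(config$domain_map)))
  seq_path <- config$sequence %||%
    system.file("extdata", "fxi_sequence_synthetic.fasta",
                package = "fxivar", mustWork = TRUE)
  ss_path <- config$disulfides %||%
    system.file("extdata", "fxi_disulfides.csv", package = "fxivar",
                mustWork = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(census = config$census, sequence = seq_path,
              disulfides = ss_path)
  if (!is.null(config$structure))
    inputs <- c(inputs, structure = config$structure)
  out <- function(name) file.path(config$out_dir, name)
  written <- character(0)
  emit <- function(df, name, ...) {
    write_report(df, out(name), inputs, ...)
    written <<- c(written, out(name))
  }

  census <- read_census(config$census)
  summ <- tabulate_census(census, map)
  stacked <- do.call(rbind, lapply(
    c("by_event", "by_effect", "by_phenotype", "by_domain"),
    function(g) cbind(grouping = sub("by_", "", g), summ[[g]])))
  emit(stacked, "census_summary.tsv")
  rar <- rarity_filter(census, af_cut)
  emit(data.frame(af_cutoff = af_cut, n_common = rar$n_common,
                  n_rare = rar$n_rare, n_no_af = rar$n_no_af),
       "rarity.tsv")
  cys <- cys_census(census, map)
  emit(data.frame(
    metric = c("cys_loss", "cys_loss_apple", "cys_loss_sp", "cys_gain"),
    count = c(cys$n_cys_loss, cys$n_cys_loss_apple, cys$n_cys_loss_sp,
              cys$n_cys_gain)), "cys_census.tsv")
  grid <- build_grid(census)
  emit(grid$counts, "substitution_grid.tsv", row_names = TRUE)
  G <- grantham_matrix()
  mis <- census[census$effect == "missense" & !is.na(census$ref_aa), ,
                drop = FALSE]
  emit(data.frame(protein_change = mis$protein_change,
                  grantham = grantham_distance(mis$ref_aa, mis$alt_aa, G)),
       "grantham_scores.tsv")
  ss <- disulfide_census(fxi_disulfides_from(ss_path), map)
  emit(data.frame(metric = c("bridges_per_monomer", "apple_bridges",
                             "sp_bridges", "interchain", "free_cys"),
                  value = c(ss$n_bridges, ss$n_apple, ss$n_sp,
                            nrow(ss$interchain),
                            paste(ss$free_cys, collapse = ";"))),
       "disulfide_census.tsv")
  seqs <- apple_sequences(read_fasta(seq_path), map)
  cmap <- align_apples(seqs)
  proj <- suppressMessages(project_variants(census, cmap))
  emit(proj, "consensus_report.tsv")

  if (!is.null(config$structure)) {
    structure <- read_structure(config$structure)
    prof <- relative_accessibility(structure, state = "intact",
                                   probe_radius = probe, n_points = npts)
    emit(as.data.frame(prof), "accessibility_profile.tsv")
    ann <- annotate_variants(census, prof)
    emit(as.data.frame.matrix(ann$cross_tab), "variant_accessibility.tsv",
         row_names = TRUE)
    sep <- separation_delta(structure, map, probe_radius = probe,
                            n_points = npts)
    emit(sep, "separation_delta.tsv")
    iface <- interface_residues(structure, bsa_cutoff = bsa_cut,
                                probe_radius = probe, n_points = npts)
    iface$sasa_monomer <- sprintf("%.3f", iface$sasa_monomer)
    iface$sasa_assembly <- sprintf("%.3f", iface$sasa_assembly)
    iface$bsa <- sprintf("%.3f", iface$bsa)
    emit(iface, "interface_report.tsv")
    geom <- find_disulfides(structure)
    if (nrow(geom$bridges))
      geom$bridges$distance <- sprintf("%.3f", geom$bridges$distance)
    emit(geom$bridges, "disulfide_geometry.tsv")
  }
  invisible(written)
}

fxi_disulfides_from <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
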