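test_that("identical sequences align to the identity mapping", {
  seqs <- c(D1 = "AVLSGTEKIR", D2 = "AVLSGTEKIR", D3 = "AVLSGTEKIR",
            D4 = "AVLSGTEKIR")
  cm <- align_apples(seqs, anchors = NULL)
  expect_equal(cm$length, 10L)
  for (nm in names(seqs))
    expect_equal(unname(cm$mapping[[nm]]), 1:10)
})

test_that("a single insertion opens one gap column between anchors", {
  seqs <- c(D1 = "CAVLSGC", D2 = "CAVLSGC", D3 = "CAVLSGC",
            D4 = "CAVRLSGC")
  anchors <- list(D1 = c(1, 7), D2 = c(1, 7), D3 = c(1, 7),
                  D4 = c(1, 8))
  cm <- align_apples(seqs, anchors = anchors, reference = "D1")
  expect_equal(cm$length, 8L)
  expect_equal(sum(cm$residues["D1", ] == "-"), 1L)
  expect_equal(sum(cm$residues["D4", ] == "-"), 0L)
  # flanking anchors stay in common columns
  expect_equal(unname(cm$mapping$D4[c("1", "8")]),
               unname(cm$mapping$D1[c("1", "7")]))
})

test_that("missing anchor cysteines are rejected", {
  seqs <- c(D1 = "CAVLSGC", D2 = "CAVLSGC", D3 = "CAVLSGC",
            D4 = "AAVLSGC")
  anchors <- list(D1 = c(1, 7), D2 = c(1, 7), D3 = c(1, 7),
                  D4 = c(1, 7))
  expect_error(align_apples(seqs, anchors = anchors), "lacks Cys")
})

test_that("the FXI Apple domains align with six anchored Cys columns", {
  cm <- align_apples(apple_sequences(fxi_sequence()))
  expect_equal(names(cm$cys_columns), paste0("C", 1:6))
  for (k in 1:6)
    expect_true(all(cm$residues[, cm$cys_columns[k]] == "C"))
  # mappings strictly increasing, no crossing
  for (nm in names(cm$mapping))
    expect_true(all(diff(cm$mapping[[nm]]) > 0))
  # consensus length near the ~87-residue Apple domain
  expect_gt(cm$length, 80L)
  expect_lt(cm$length, 110L)
})

test_that("variant projection tallies hit all six conserved Cys columns", {
  cm <- align_apples(apple_sequences(fxi_sequence()))
  proj <- suppressMessages(project_variants(fxi_census(), cm))
  expect_true(all(proj$tally[cm$cys_columns] >= 1L))
})

test_that("Thr51 and Gly97 are hotspot columns among non-Cys positions", {
  cm <- align_apples(apple_sequences(fxi_sequence()))
  proj <- suppressMessages(project_variants(fxi_census(), cm))
  non_cys_neighbours <- function(col) {
    setdiff(c(col - 1L, col + 1L), cm$cys_columns)
  }
  for (res in c(51, 97)) {
    col <- unname(cm$mapping$Ap1[as.character(res)])
    for (nb in non_cys_neighbours(col))
      expect_gt(proj$tally[col], proj$tally[nb])
  }
})

test_that("projected tallies sum to the number of Apple-domain variants", {
  cm <- align_apples(apple_sequences(fxi_sequence()))
  cen <- fxi_census()
  expect_message(proj <- project_variants(cen, cm), "excluded")
  in_ap <- !is.na(cen$residue) & cen$effect == "missense" &
    assign_domain(cen$residue) %in% c("Ap1", "Ap2", "Ap3", "Ap4")
  expect_equal(sum(proj$tally), sum(in_ap))
  expect_equal(attr(proj, "n_excluded"),
               sum(!is.na(cen$residue) & cen$effect == "missense") -
                 sum(in_ap))
})

test_that("empty census projects to all-zero tallies", {
  cm <- align_apples(apple_sequences(fxi_sequence()))
  proj <- project_variants(fxi_census()[0, ], cm)
  expect_true(all(proj$tally == 0L))
  expect_true(all(proj$dominant_phenotype == ""))
})

test_that("dominant phenotype is modal with ties reported unknown", {
  cm <- align_apples(apple_sequences(fxi_sequence()))
  cen <- as_census(data.frame(
    protein_change = c("Val38Ala", "Val38Leu", "Pro41Leu", "Pro41Thr"),
    cdna_change = NA, event_type = "point", effect = "missense",
    phenotype = c("type_I", "type_I", "type_I", "type_II"),
    fxi_c = NA, fxi_ag = NA, allele_frequency = NA, n_patients = 1,
    aggregate = FALSE, count = 1))
  proj <- project_variants(cen, cm)
  c38 <- unname(cm$mapping$Ap1["38"])
  c41 <- unname(cm$mapping$Ap1["41"])
  expect_equal(proj$dominant_phenotype[c38], "type_I")
  expect_equal(proj$dominant_phenotype[c41], "unknown")  # tie
})
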