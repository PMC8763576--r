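test_that("phenotype classification follows the activity/antigen rule", {
  expect_equal(classify_phenotype(30, 100), "type_II")  # ratio 0.30
  expect_equal(classify_phenotype(30, 35), "type_I")    # ratio ~0.86
  expect_equal(classify_phenotype(100, 100), "unaffected")
  expect_equal(classify_phenotype(30, NA), "unknown")
  expect_error(classify_phenotype(-5, 100), "positive")
})

test_that("rarity filter splits on the allele-frequency cut-off", {
  cen <- as_census(data.frame(
    protein_change = NA, cdna_change = NA, event_type = "point",
    effect = "undefined", phenotype = "unknown", fxi_c = NA, fxi_ag = NA,
    allele_frequency = c(0.02, 0.005, 0.0001, NA), n_patients = 1,
    aggregate = FALSE, count = 1))
  r <- rarity_filter(cen, 0.01)
  expect_equal(r, list(n_common = 1L, n_rare = 2L, n_no_af = 1L))
  r0 <- rarity_filter(cen[0, ], 0.01)
  expect_equal(r0, list(n_common = 0L, n_rare = 0L, n_no_af = 0L))
})

test_that("bundled census reproduces the published rarity counts", {
  cen <- fxi_census()
  r <- rarity_filter(cen, 0.01)
  expect_equal(r$n_common, 9L)   # all commonly-occurring = polymorphisms
  expect_equal(r$n_rare, 108L)
  expect_equal(rarity_filter(cen, 0.001)$n_rare, 104L)
})

test_that("tabulation covers a degenerate one-variant census", {
  cen <- as_census(data.frame(
    protein_change = NA, cdna_change = NA, event_type = "deletion",
    effect = "undefined", phenotype = "unknown", fxi_c = NA, fxi_ag = NA,
    allele_frequency = NA, n_patients = 1, aggregate = FALSE, count = 1))
  s <- tabulate_census(cen)
  expect_equal(s$by_event$percent[s$by_event$category == "deletion"], 100)
})

test_that("percentages within each grouping sum to 100", {
  s <- tabulate_census(fxi_census())
  for (g in c("by_event", "by_effect", "by_phenotype", "by_domain"))
    expect_lt(abs(sum(s[[g]]$percent) - 100), 0.011)
})

test_that("disease-associated and polymorphism counts partition the census", {
  s <- tabulate_census(fxi_census())
  expect_equal(s$denominators$disease_associated +
                 s$denominators$polymorphisms, s$denominators$total)
  expect_equal(s$denominators$total, 272L)
})

test_that("census validation catches schema and consistency errors", {
  row <- data.frame(protein_change = "Cys56Arg", cdna_change = NA,
                    event_type = "point", effect = "nonsense",
                    phenotype = "type_I", fxi_c = NA, fxi_ag = NA,
                    allele_frequency = NA, n_patients = 1,
                    aggregate = FALSE, count = 1)
  expect_error(as_census(row), "contradicts")
  row$effect <- "missense"; row$phenotype <- "polymorphism"
  expect_error(as_census(row), "polymorphism")
  row$phenotype <- "type_I"; row$allele_frequency <- 2
  expect_error(as_census(row), "allele_frequency")
  expect_error(as_census(row[, -1]), "missing columns")
})

test_that("cysteine census matches the printed variant lists", {
  cc <- cys_census(fxi_census())
  expect_equal(cc$n_cys_loss, 28L)
  expect_equal(cc$n_cys_loss_apple, 20L)
  expect_equal(cc$n_cys_loss_sp, 8L)
  expect_equal(cc$n_cys_gain, 13L)
  expect_equal(as.integer(cc$loss_by_phenotype[c("type_I", "type_II",
                                                 "polymorphism",
                                                 "unknown")]),
               c(12L, 1L, 1L, 14L))
  expect_equal(as.integer(cc$gain_by_phenotype[c("type_I", "type_II",
                                                 "unknown")]),
               c(8L, 1L, 4L))
})

test_that("a census without cysteine positions yields a zero Cys census", {
  cen <- as_census(data.frame(
    protein_change = "Phe301Leu", cdna_change = NA, event_type = "point",
    effect = "missense", phenotype = "unknown", fxi_c = NA, fxi_ag = NA,
    allele_frequency = NA, n_patients = 1, aggregate = FALSE, count = 1))
  cc <- cys_census(cen)
  expect_equal(c(cc$n_cys_loss, cc$n_cys_loss_apple, cc$n_cys_loss_sp,
                 cc$n_cys_gain), rep(0L, 4))
})

test_that("half-up rounding matches printed percentage style", {
  expect_equal(round_half_up(6.985, 2), 6.99)
  expect_equal(round_half_up(c(73.529, 16.544), 2), c(73.53, 16.54))
  expect_equal(round_half_up(0.5, 0), 1)
})
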