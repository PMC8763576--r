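test_that("helix generator is deterministic with ideal geometry", {
  h1 <- make_helix(10)
  h2 <- make_helix(10)
  expect_identical(h1, h2)
  ca_z <- h1$z[h1$elety == "CA"]
  expect_equal(diff(ca_z), rep(1.5, 9))      # 1.5 A rise per residue
  expect_equal(nrow(h1[h1$elety == "CB", ]), 10L)
  expect_equal(unique(h1$radius[h1$elety == "CB"]), 1.9)
  g <- make_helix(5, c("ALA", "GLY"))
  expect_false(any(g$elety == "CB" & g$resid == "GLY"))
  expect_error(make_helix(2), "n_res")
  expect_error(make_helix(5, "ZZZ"), "ZZZ")
})

test_that("every residue of an isolated helix is solvent-exposed", {
  p <- relative_accessibility(make_helix(12, c("LEU", "SER", "LYS")))
  expect_true(all(p$percent > 20))
  o <- residue_sasa(make_helix(12, c("LEU", "SER", "LYS")),
                    sasa = oracle_sasa(make_helix(12, c("LEU", "SER",
                                                        "LYS"))))
  po <- relative_accessibility(o)
  expect_true(all(po$percent > 20))
})

test_that("packed pairs honour the requested gap and symmetry", {
  pair <- make_packed_pair(make_helix(9), make_helix(9), gap = 0.5)
  A <- pair$assembly[pair$assembly$chain == "A", ]
  B <- pair$assembly[pair$assembly$chain == "B", ]
  d <- as.matrix(stats::dist(as.matrix(
    pair$assembly[, c("x", "y", "z")])))[seq_len(nrow(A)),
                                         nrow(A) + seq_len(nrow(B))]
  gaps <- d - outer(A$radius, B$radius, "+")
  expect_equal(min(gaps), 0.5, tolerance = 1e-6)
  expect_equal(sort(pair$contacts$resno[pair$contacts$chain == "A"]),
               sort(pair$contacts$resno[pair$contacts$chain == "B"]))
  far <- make_packed_pair(make_helix(9), make_helix(9), gap = 30)
  expect_equal(nrow(far$contacts), 0L)
})

test_that("synthetic census reproduces requested marginals exactly", {
  cen <- make_census(
    events = c(point = 200, polymorphism = 45, deletion = 19,
               duplication = 4, insertion = 4),
    effects = c(missense = 154, nonsense = 27, silent = 2,
                undefined = 17),
    phenotypes = c(type_I = 96, type_II = 12, unknown = 119),
    seed = 7)
  s <- tabulate_census(cen)
  expect_equal(s$denominators$total, 272L)
  ev <- stats::setNames(s$by_event$percent, s$by_event$category)
  expect_equal(unname(ev[c("point", "polymorphism", "deletion",
                           "duplication", "insertion")]),
               c(73.53, 16.54, 6.99, 1.47, 1.47))
  ef <- stats::setNames(s$by_effect$percent, s$by_effect$category)
  expect_equal(unname(ef[c("missense", "nonsense", "silent",
                           "undefined")]),
               c(77.00, 13.50, 1.00, 8.50))
  ph <- stats::setNames(s$by_phenotype$count, s$by_phenotype$category)
  expect_equal(unname(ph[c("type_I", "type_II", "unknown")]),
               c(96L, 12L, 119L))
  # all generated substitutions are single-nucleotide reachable
  mis <- cen[!is.na(cen$ref_aa) & cen$effect == "missense", ]
  expect_true(all(single_nt_reachable(mis$ref_aa, mis$alt_aa)))
})

test_that("synthetic census is reproducible under a fixed seed", {
  a <- make_census(events = c(point = 20), seed = 11)
  b <- make_census(events = c(point = 20), seed = 11)
  expect_identical(a, b)
  c2 <- make_census(events = c(point = 20), seed = 12)
  expect_false(identical(a, c2))
})

test_that("infeasible marginals and empty requests are handled", {
  expect_error(make_census(events = c(point = 10),
                           effects = c(missense = 5)), "sum")
  expect_error(make_census(events = c(point = 5, deletion = 5),
                           effects = c(missense = 5),
                           phenotypes = c(type_I = 3)), "sum")
  empty <- make_census(events = c(point = 0))
  expect_equal(nrow(empty), 0L)
  strata <- data.frame(n = c(2, 3), af = c(0.05, 1e-4))
  cen <- make_census(events = c(point = 10), af_strata = strata,
                     seed = 3)
  r <- rarity_filter(cen, 0.01)
  expect_equal(r$n_common, 2L)
  expect_equal(r$n_rare, 3L)
  expect_equal(r$n_no_af, 5L)
})
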