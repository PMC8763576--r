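test_that("isolated sphere SASA matches the analytic area", {
  a <- atomset("A", 1, "ALA", "C", 0, 0, 0)
  expect_equal(compute_sasa(a), 4 * pi * (1.7 + 1.4)^2,
               tolerance = 0.005)
  s <- atomset("A", 1, "CYS", "SG", 0, 0, 0)
  expect_equal(compute_sasa(s), 4 * pi * (1.8 + 1.4)^2,
               tolerance = 0.005)
})

test_that("well-separated atoms each keep their isolated-sphere area", {
  a <- atomset("A", 1:2, "ALA", c("C", "C"), x = c(0, 10), y = 0, z = 0)
  expect_equal(compute_sasa(a), rep(4 * pi * 3.1^2, 2), tolerance = 1e-9)
})

test_that("an atom enclosed in a tight 12-neighbour cage is occluded", {
  cage <- make_caged_atom(shell = 3.4)
  s <- compute_sasa(cage, n_points = 10000)
  expect_lt(s[1], 1)
  oracle <- oracle_sasa(cage[1:13, ], n_points = 10000)
  expect_lt(oracle[1], 1)
})

test_that("coincident atom centres are rejected", {
  a <- atomset("A", 1:2, "ALA", c("C", "C"), x = c(0, 0), y = 0, z = 0)
  expect_error(compute_sasa(a), "coincident")
})

test_that("SASA is invariant under rigid-body motion", {
  h <- make_helix(8, c("ALA", "LEU", "SER"))
  s0 <- compute_sasa(h)
  R <- rotation_z(1.1) %*%
    matrix(c(1, 0, 0, 0, cos(0.6), sin(0.6), 0, -sin(0.6), cos(0.6)), 3)
  xyz <- as.matrix(h[, c("x", "y", "z")]) %*% t(R)
  h2 <- h
  h2$x <- xyz[, 1] + 7.3; h2$y <- xyz[, 2] - 2.1; h2$z <- xyz[, 3] + 11
  s1 <- compute_sasa(h2)
  expect_equal(sum(s1), sum(s0), tolerance = 0.01)
  expect_equal(s1, s0, tolerance = 0.02)
})

test_that("adding atoms never increases existing atoms' SASA", {
  h <- make_helix(6)
  extra <- atomset("A", 99, "ALA", "C", 3.5, 0.5, 4)
  grown <- rbind(h, extra)
  class(grown) <- c("atomset", "data.frame")
  s_before <- compute_sasa(h)
  s_after <- compute_sasa(grown)[seq_len(nrow(h))]
  expect_true(all(s_after <= s_before + 1e-9))
  expect_lt(sum(s_after), sum(s_before))
})

test_that("spiral-lattice SASA agrees with a dense random-point oracle", {
  pair <- make_packed_pair(make_helix(7, c("LEU", "SER", "THR")),
                           make_helix(7, c("VAL", "ASN", "LYS")),
                           gap = 0.8)
  atoms <- pair$assembly
  s <- residue_sasa(atoms, sasa = compute_sasa(atoms, n_points = 960),
                    which = "all")
  o <- residue_sasa(atoms, sasa = oracle_sasa(atoms, n_points = 10000),
                    which = "all")
  rel <- abs(s$sasa - o$sasa) / pmax(o$sasa, 1)
  expect_true(all(rel < 0.02))
})

test_that("percent accessibility bins and burial follow the decile rule", {
  prof <- data.frame(chain = "A", resno = 1:4, resid = "ALA",
                     sasa = c(0.05, 0.15, 0.25, 1.08) * 67)
  p <- relative_accessibility(prof)
  expect_equal(p$bin, c(0L, 1L, 2L, 9L))
  expect_equal(p$buried, c(TRUE, TRUE, FALSE, FALSE))
  expect_gt(p$percent[4], 100)  # extended conformations allowed
  expect_equal(accessibility_bin(c(9.9, 10, 19.9, 20, 99.9, 250)),
               c(0L, 1L, 1L, 2L, 9L, 9L))
})

test_that("unknown residue types are rejected against the max-ASA table", {
  prof <- data.frame(chain = "A", resno = 1, resid = "XYZ", sasa = 10)
  expect_error(relative_accessibility(prof), "XYZ")
})

test_that("variant burial classification builds the phenotype cross-tab", {
  h <- make_helix(12, "ALA", resno_start = 19)
  pair <- make_packed_pair(h, make_helix(12, "ALA", resno_start = 19),
                           gap = 0.5)
  prof <- relative_accessibility(
    pair$assembly[pair$assembly$chain == "A", ])
  cen <- as_census(data.frame(
    protein_change = c("Ala19Val", "Ala20Val", "Ala27Val", "Ala99Val"),
    cdna_change = NA, event_type = "point", effect = "missense",
    phenotype = c("type_I", "type_I", "type_II", "unknown"),
    fxi_c = NA, fxi_ag = NA, allele_frequency = NA, n_patients = 1,
    aggregate = FALSE, count = 1))
  ann <- annotate_variants(cen, prof)
  expect_equal(ann$n_not_classified, 1L)  # residue 99 absent
  expect_equal(sum(ann$cross_tab), 4L)
  expect_equal(ann$variants$class[ann$variants$residue == 99],
               "not classified")
  by_class <- table(ann$variants$class)
  truth <- table(ifelse(prof$resno %in% c(19, 20, 27) & prof$buried,
                        "buried", "exposed")[prof$resno %in% c(19, 20, 27)])
  expect_equal(unname(by_class["buried"]), unname(truth["buried"]))
})

test_that("empty census gives an empty burial table", {
  prof <- relative_accessibility(make_helix(4))
  ann <- annotate_variants(fxi_census()[0, ], prof)
  expect_equal(sum(ann$cross_tab), 0L)
  expect_equal(nrow(ann$variants), 0L)
})
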