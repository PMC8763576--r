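test_that("domain splitting preserves atoms and partitions residues", {
  pair <- make_packed_pair(make_helix(10), make_helix(10), gap = 0.5,
                           arrangement = "domains")
  parts <- split_domains(pair$assembly, pair$map)
  expect_equal(length(parts), 2L)
  expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(pair$assembly))
  expect_equal(sort(unname(unlist(lapply(parts,
                                         function(p) unique(p$resno))))),
               sort(unique(pair$assembly$resno)))
  one <- domain_map("all", 1, 20)
  expect_equal(nrow(split_domains(pair$assembly, one)$all),
               nrow(pair$assembly))
  expect_error(split_domains(pair$assembly, domain_map("d", 1, 5)),
               "outside")
})

test_that("separation deltas are non-negative and find the interface", {
  pair <- make_packed_pair(make_helix(12), make_helix(12), gap = 0.5,
                           arrangement = "domains")
  sep <- separation_delta(pair$assembly, pair$map)
  expect_true(all(sep$delta >= 0L))
  contact_resnos <- sort(pair$contacts$resno)
  deep <- sep[sep$resno %in% contact_resnos, ]
  expect_true(any(deep$delta >= 2L))       # burial-to-exposure transition
  far <- sep[!sep$resno %in% contact_resnos, ]
  expect_true(all(far$delta == 0L))
  expect_equal(sort(sep$resno[sep$contact]), contact_resnos)
})

test_that("widely separated domains show zero delta everywhere", {
  pair <- make_packed_pair(make_helix(8), make_helix(8), gap = 30,
                           arrangement = "domains")
  expect_equal(nrow(pair$contacts), 0L)
  sep <- separation_delta(pair$assembly, pair$map)
  expect_true(all(sep$delta == 0L))
})

test_that("interface residues recover the designed contact set exactly", {
  pair <- make_packed_pair(make_helix(19), make_helix(19), gap = 0.5)
  iface <- interface_residues(pair$assembly, bsa_cutoff = 5)
  got <- iface[iface$interface, c("chain", "resno")]
  truth <- pair$contacts[order(pair$contacts$chain, pair$contacts$resno), ]
  got <- got[order(got$chain, got$resno), ]
  rownames(got) <- rownames(truth) <- NULL
  expect_equal(got, truth)
  # symmetric homodimer: same residue set on both chains
  expect_equal(sort(got$resno[got$chain == "A"]),
               sort(got$resno[got$chain == "B"]))
})

test_that("an isolated monomer has an empty interface", {
  h <- make_helix(10)
  iface <- interface_residues(h, bsa_cutoff = 5)
  expect_false(any(iface$interface))
})

test_that("summed per-residue BSA accounts for the assembly's buried area", {
  pair <- make_packed_pair(make_helix(10), make_helix(10), gap = 0.5)
  iface <- interface_residues(pair$assembly)
  total_mono <- sum(iface$sasa_monomer)
  asm <- sum(residue_sasa(pair$assembly, which = "all")$sasa)
  expect_equal(sum(iface$bsa), total_mono - asm, tolerance = 0.02)
})

test_that("disulfides pair by Sgamma distance with nearest-neighbour resolution", {
  # three Cys: 1-2 bonded at 2.05 A, 3 free at 4 A from 2
  sg <- atomset("A", 1:3, "CYS", "SG", x = c(0, 2.05, 6.05), y = 0, z = 0)
  ss <- find_disulfides(sg)
  expect_equal(nrow(ss$bridges), 1L)
  expect_equal(ss$bridges$resno1, 1L)
  expect_equal(ss$bridges$resno2, 2L)
  expect_equal(ss$bridges$distance, 2.05)
  expect_false(ss$bridges$interchain)
  expect_equal(ss$free_cys$resno, 3L)
  # each Cys joins at most one bridge even in a close triplet
  tri <- atomset("A", 1:3, "CYS", "SG", x = c(0, 2.0, 4.2), y = 0, z = 0)
  ss2 <- find_disulfides(tri)
  expect_equal(nrow(ss2$bridges), 1L)
  expect_equal(ss2$bridges$distance, 2.0)
})

test_that("interchain bridges are flagged on assemblies", {
  sg <- atomset(c("A", "B"), c(339, 339), "CYS", "SG",
                x = c(0, 2.05), y = 0, z = 0)
  ss <- find_disulfides(sg)
  expect_true(ss$bridges$interchain)
})

test_that("dimer assembly transforms a chain and warns on collision", {
  h <- make_helix(8)
  d <- build_dimer(h, rotation_z(pi), translation = c(25, 0, 0))
  expect_equal(nrow(d), 2L * nrow(h))
  expect_equal(sort(unique(d$chain)), c("A", "B"))
  expect_warning(build_dimer(h), "collide")  # identity transform
})

test_that("curated disulfide table reproduces the printed monomer census", {
  ss <- disulfide_census(fxi_disulfides())
  expect_equal(ss$n_bridges, 17L)
  expect_equal(ss$n_apple, 12L)
  expect_equal(ss$n_sp, 5L)
  expect_equal(ss$free_cys, 29)
  expect_equal(ss$interchain$cys1, 339)
  expect_equal(ss$interchain$cys2, 339)
})

test_that("salt-bridge distance check reports the dimer pairs", {
  # two pseudo-residues: Glu-like sidechain O and Lys-like sidechain N
  a <- atomset(c("A", "B"), c(305, 349), c("GLU", "LYS"),
               c("OE1", "NZ"), x = c(0, 3.2), y = 0, z = 0)
  sb <- salt_bridges(a, pairs = data.frame(res_acid = 305,
                                           res_base = 349))
  expect_true(sb$salt_bridge)
  expect_equal(sb$min_distance, 3.2)
})
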