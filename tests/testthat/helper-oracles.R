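# Independent oracles used to cross-check the package implementations.

# Brute-force SASA with an independent dense point construction
# (equal-area latitude bands with sqrt(2)-rotation azimuths, a
# different low-discrepancy set from the package's golden spiral) and
# all-pairs neighbour checks instead of the package's cell list.
oracle_sasa <- function(atoms, probe = 1.4, n_points = 10000) {
  i_pt <- seq_len(n_points)
  zz <- 1 - 2 * (i_pt - 0.5) / n_points
  phi <- 2 * pi * ((i_pt * sqrt(2)) %% 1)
  rr <- sqrt(pmax(0, 1 - zz^2))
  base_pts <- cbind(rr * cos(phi), rr * sin(phi), zz)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ext <- atoms$radius + probe
  n <- nrow(atoms)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- base_pts
    pts <- sweep(pts * ext[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- colSums((t(pts) - xyz[j, ])^2)
      free <- free & d2 >= ext[j]^2
    }
    out[i] <- 4 * pi * ext[i]^2 * mean(free)
  }
  out
}

# Genetic-code reachability by direct enumeration over codon pairs,
# written against Biostrings' codon table with string comparison.
oracle_reachable <- function(aa1, aa2) {
  code <- Biostrings::GENETIC_CODE
  c1 <- names(code)[code == aa_three_to_one(aa1)]
  c2 <- names(code)[code == aa_three_to_one(aa2)]
  if (aa1 == aa2) return(TRUE)
  for (a in c1) for (b in c2) {
    if (sum(charToRaw(a) != charToRaw(b)) == 1L) return(TRUE)
  }
  FALSE
}

# A 12-neighbour icosahedral-like cage of carbon atoms around a centre
# atom, tight enough to occlude it almost completely.
make_caged_atom <- function(shell = 3.4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v <- v / sqrt(rowSums(v^2)) * shell
  atomset(chain = "A", resno = seq_len(13), resid = "ALA",
          elety = rep("C", 13),
          x = c(0, v[, 1]), y = c(0, v[, 2]), z = c(0, v[, 3]))
}

# Toy with preset accessibility classes: each "buried" residue's CB is
# enclosed in a 12-atom cage (carried by a wall pseudo-residue), each
# "exposed" residue stands free; residues are spaced far apart so the
# classes are exact by construction.
make_burial_toy <- function(buried_res, exposed_res, wall_resno = 999L) {
  phi <- (1 + sqrt(5)) / 2
  shell <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  shell <- shell / sqrt(rowSums(shell^2)) * 3.4
  rows <- list()
  all_res <- c(buried_res, exposed_res)
  for (k in seq_along(all_res)) {
    cx <- 25 * k
    res <- all_res[k]
    rows[[length(rows) + 1L]] <- data.frame(
      resno = res, elety = c("CA", "CB"), x = cx + c(-4, 0), y = 0, z = 0)
    if (res %in% buried_res)
      rows[[length(rows) + 1L]] <- data.frame(
        resno = wall_resno, elety = "CG", x = cx + shell[, 1],
        y = shell[, 2], z = shell[, 3])
  }
  a <- do.call(rbind, rows)
  atomset(chain = "A", resno = a$resno, resid = "ALA", elety = a$elety,
          x = a$x, y = a$y, z = a$z, element = "C")
}

rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}
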