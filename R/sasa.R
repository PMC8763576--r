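#' Deterministic unit-sphere sampling points
#'
#' Golden-section spiral lattice: `n` nearly uniformly spaced points on
#' the unit sphere, reproducible without a random seed.
#'
#' @param n number of points (>= 1).
#' @return n x 3 numeric matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Solvent-accessible surface area by sphere-point sampling
#'
#' For every atom, sample points are placed on the solvent-accessible
#' sphere of radius (vdW radius + probe radius) and tested against the
#' accessible spheres of all neighbouring atoms; the accessible fraction
#' times the sphere area gives the atom's SASA. This is the classic
#' rolling-probe sampling construction with a deterministic spiral
#' lattice in place of random points.
#'
#' @param atoms an `atomset` (see [atomset()]).
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points sample points per atom (>= 100; default 960).
#' @return numeric vector of per-atom areas in square Angstrom, in atom
#'   order.
#' @export
#' @examples
#' a <- atomset("A", 1, "ALA", "C", 0, 0, 0)
#' compute_sasa(a)  # isolated sphere: 4*pi*(1.7+1.4)^2
compute_sasa <- function(atoms, probe_radius = 1.4, n_points = 960) {
  stopifnot(n_points >= 100)
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  rad <- atoms$radius
  pts <- sphere_points(n_points)
  ext <- rad + probe_radius
  # cell-list neighbour search; cell edge = largest possible contact range
  cut <- 2 * max(ext)
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cut)
  key <- cell[, 1] + 4096 * (cell[, 2] + 4096 * cell[, 3])
  cell_index <- split(seq_len(n), key)
  neighbour_cells <- function(ci) {
    shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    keys <- (ci[1] + shifts[, 1]) + 4096 * ((ci[2] + shifts[, 2]) +
            4096 * (ci[3] + shifts[, 3]))
    unlist(cell_index[as.character(keys)], use.names = FALSE)
  }
  area <- numeric(n)
  sphere_area <- 4 * pi * ext^2
  for (i in seq_len(n)) {
    cand <- neighbour_cells(cell[i, ])
    cand <- cand[cand != i]
    if (length(cand)) {
      d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[i, ])^2))
      if (any(d < 1e-4))
        stop("coincident atom centers at rows ", i, " and ",
             cand[which(d < 1e-4)[1]])
      cand <- cand[d < ext[i] + ext[cand]]
    }
    if (!length(cand)) { area[i] <- sphere_area[i]; next }
    P <- sweep(pts * ext[i], 2, xyz[i, ], "+")
    C <- xyz[cand, , drop = FALSE]
    d2 <- outer(rowSums(P^2), rep(1, nrow(C))) +
      outer(rep(1, nrow(P)), rowSums(C^2)) - 2 * P %*% t(C)
    blocked <- d2 < matrix((ext[cand])^2, nrow(P), length(cand),
                           byrow = TRUE)
    frac <- sum(rowSums(blocked) == 0L) / n_points
    area[i] <- sphere_area[i] * frac
  }
  area
}

#' Per-residue SASA sums
#'
#' Sums per-atom SASA within each residue, over all atoms or the
#' sidechain only. Glycine's Calpha is counted as its sidechain, the
#' usual convention when relative sidechain accessibilities are wanted.
#'
#' @param atoms an `atomset`.
#' @param sasa per-atom areas from [compute_sasa()]; computed if `NULL`.
#' @param which `"sidechain"` or `"all"`.
#' @param ... passed to [compute_sasa()].
#' @return data.frame chain/resno/resid/sasa.
#' @export
residue_sasa <- function(atoms, sasa = NULL, which = c("sidechain", "all"),
                         ...) {
  which <- match.arg(which)
  if (is.null(sasa)) sasa <- compute_sasa(atoms, ...)
  use <- if (which == "all") rep(TRUE, nrow(atoms))
         else atoms$region == "sidechain" |
              (atoms$resid == "GLY" & atoms$elety == "CA")
  key <- paste(atoms$chain, atoms$resno)
  res <- residues_of(atoms)
  s <- tapply(sasa * use, factor(key, unique(key)), sum)
  res$sasa <- as.numeric(s)
  res
}
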