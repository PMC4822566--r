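# Shared fixture builders for the test suite. Everything is generated in
# code; no external files.

# Write a minimal one-atom P1 PDB file and return its path.
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb"),
                           occ = 1.0, b = 10.0) {
  writeLines(c(
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1           1",
    sprintf("ATOM      1  C1  LIG A   1       5.000   5.000   5.000%6.2f%6.2f           C",
            occ, b),
    "END"), path)
  path
}

# A small deterministic reflection set on a cubic P1 cell.
tiny_reflections <- function(cell = c(10, 10, 10, 90, 90, 90), d_min = 2,
                             seed = 42) {
  set.seed(seed)
  hkl <- hemisphere_hkl(cell, d_min)
  n <- nrow(hkl)
  rec <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    f_obs = runif(n, 1, 10), sig_f_obs = 0.1,
                    f_calc = runif(n, 1, 10),
                    phase = runif(n, -180, 180), fom = 1, d_factor = 1)
  reflection_set(cell, "P 1", rec)
}

# Assemble score_modes() input from a make_toy_crystal() result.
toy_modes <- function(toy) {
  Map(function(st, rf) list(structure = st, reflections = rf),
      toy$structures, toy$reflections)
}

# Harmonic parameters whose minimum is the default toy moiety's geometry:
# bonds along the S-C-N-O chain at their truth distances.
toy_ff <- function(atoms = default_toy_atoms(), k_bond = 300) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pairs <- rbind(c(1, 2), c(2, 3), c(2, 4))
  data.frame(i = pairs[, 1], j = pairs[, 2], k_bond = k_bond,
             r0 = sqrt(rowSums((xyz[pairs[, 1], ] - xyz[pairs[, 2], ])^2)))
}

# Independent brute-force footprint membership: scan every grid point with a
# triple loop, periodic minimum-image distance, same dominance rule as the
# hard partition (largest density wins, earlier atom keeps ties).
brute_membership <- function(zmap, atoms, rmaxs, dens_funs) {
  grid <- zmap$grid
  m <- modescore::orth_matrix(grid$unit_cell)
  fm <- solve(m)
  dims <- grid$dims
  owner <- integer(prod(dims))
  best <- rep(-Inf, prod(dims))
  for (kz in 0:(dims[3] - 1)) for (ky in 0:(dims[2] - 1)) {
    for (kx in 0:(dims[1] - 1)) {
      # linear index in R array order (first index fastest)
      lin <- 1L + kx + dims[1] * (ky + dims[2] * kz)
      fp <- c(kx / dims[1], ky / dims[2], kz / dims[3])
      for (a in seq_len(nrow(atoms))) {
        fa <- as.numeric(fm %*% c(atoms$x[a], atoms$y[a], atoms$z[a]))
        dd <- fp - fa
        dd <- dd - round(dd)
        r <- sqrt(sum((m %*% dd)^2))
        if (r <= rmaxs[a]) {
          dens <- dens_funs[[a]](r)
          if (dens > best[lin]) {
            best[lin] <- dens
            owner[lin] <- a
          }
        }
      }
    }
  }
  owner
}

# Per-mode strain energies of a toy ensemble under the reference backend.
toy_strain <- function(toy, bonds = toy_ff(toy$spec$atoms)) {
  be <- reference_backend(bonds)
  vapply(toy$structures, function(st) {
    mol <- molecule(st$atoms$element, as.matrix(st$atoms[, c("x", "y", "z")]))
    strain_energy(mol, be)$strain
  }, numeric(1))
}
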