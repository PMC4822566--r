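## Self-contained synthetic fixtures: toy P1 crystals with Gaussian-scattering
## atoms, planted proton-dependent heavy-atom displacements, additive
## amplitude noise, and the published worked-example scoring tables.

#' Enumerate the unique hemisphere of Miller indices
#'
#' One representative per Friedel pair (l > 0, or l = 0 and k > 0, or
#' k = l = 0 and h > 0) with d-spacing in \[d_min, d_max\].
#'
#' @param cell Length-6 cell.
#' @param d_min,d_max Resolution limits, Angstrom.
#' @return Integer matrix (n x 3).
#' @export
hemisphere_hkl <- function(cell, d_min, d_max = Inf) {
  hmax <- ceiling(cell[1:3] / d_min)
  g <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                             l = 0:hmax[3]))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g <- g[keep, , drop = FALSE]
  d <- d_spacing(g, cell)
  g[d >= d_min & d <= d_max, , drop = FALSE]
}

#' Structure factors by direct summation
#'
#' F(h) = sum_j n_j f_j(s) exp(-B_j s^2/4) exp(2 pi i h . x_j), with s = 1/d
#' and fractional coordinates x_j.
#'
#' @param s An [xtal_structure()].
#' @param hkl Integer matrix of Miller indices.
#' @return Complex vector of structure factors.
#' @export
structure_factors <- function(s, hkl) {
  stopifnot(inherits(s, "xtal_structure"))
  a <- s$atoms
  fmat <- frac_matrix(s$unit_cell)
  frac <- t(fmat %*% t(as.matrix(a[, c("x", "y", "z")])))
  sv <- 1 / d_spacing(hkl, s$unit_cell)
  f <- complex(length.out = nrow(hkl))
  for (j in seq_len(nrow(a))) {
    fj <- xray_form_factor(a$element[j], sv) * a$occ[j] *
      exp(-a$b[j] * sv^2 / 4)
    ph <- 2 * pi * as.numeric(hkl %*% frac[j, ])
    f <- f + fj * complex(real = cos(ph), imaginary = sin(ph))
  }
  f
}

# Default toy moiety: a 4-atom S-C-N-O fragment near the cell center.
default_toy_atoms <- function() {
  data.frame(
    element = c("S", "C", "N", "O"),
    x = c(3.2, 4.9, 5.6, 5.4),
    y = c(4.0, 4.3, 5.5, 3.3),
    z = c(4.0, 4.1, 4.3, 3.4),
    occ = 1, b = c(8, 10, 12, 15),
    chain = "A", resid = "LIG", resno = 1L,
    elety = c("S1", "C1", "N1", "O1"),
    stringsAsFactors = FALSE
  )
}

#' Specify a toy crystal
#'
#' A P1 cell with Gaussian-scattering atoms, per-mode heavy-atom
#' displacements standing in for proton-dependent geometry changes, and
#' additive Gaussian amplitude noise. Deterministic given the seed.
#'
#' @param cell Length-6 P1 cell (default 8 A cube).
#' @param atoms Atom table (see [xtal_structure()]); default 4-atom S-C-N-O
#'   moiety.
#' @param d_min,d_max Resolution limits; d_max defaults to the longest cell
#'   edge. d_min must be below a quarter of the shortest cell edge.
#' @param noise_frac Amplitude noise s.d. as a fraction of the mean true
#'   amplitude (default 0.02).
#' @param modes Named list of per-mode displacements; each element is either
#'   NULL (candidate identical to the truth), list(atom = index,
#'   shift = c(dx, dy, dz)), or an n x 3 displacement matrix for all atoms,
#'   in Angstrom. The truth is the undisplaced atom table.
#' @param seed RNG seed.
#' @return An object of class \code{toy_crystal_spec}.
#' @export
toy_crystal_spec <- function(cell = c(8, 8, 8, 90, 90, 90),
                             atoms = default_toy_atoms(),
                             d_min = 1.2, d_max = NULL, noise_frac = 0.02,
                             modes = list(true = NULL),
                             seed = 1L) {
  validate_cell(cell)
  if (is.null(d_max)) d_max <- max(cell[1:3])
  if (d_min >= min(cell[1:3]) / 4) {
    stop("d_min must be below a quarter of the shortest cell edge")
  }
  if (is.null(names(modes)) || any(!nzchar(names(modes)))) {
    stop("modes must be a named list")
  }
  structure(list(cell = cell, atoms = atoms, d_min = d_min, d_max = d_max,
                 noise_frac = noise_frac, modes = modes, seed = seed),
            class = "toy_crystal_spec")
}

# Wrap atoms into the cell (warn when any move).
wrap_atoms <- function(atoms, cell) {
  fmat <- frac_matrix(cell)
  m <- orth_matrix(cell)
  frac <- t(fmat %*% t(as.matrix(atoms[, c("x", "y", "z")])))
  wrapped <- frac - floor(frac)
  if (any(abs(wrapped - frac) > 1e-12)) {
    warning("atom(s) outside the cell were wrapped back in")
    cart <- t(m %*% t(wrapped))
    atoms$x <- cart[, 1]; atoms$y <- cart[, 2]; atoms$z <- cart[, 3]
  }
  atoms
}

#' Generate a toy crystal and its candidate-mode ensemble
#'
#' True amplitudes come from direct summation over the undisplaced atoms;
#' F_obs adds seeded Gaussian noise to |F_true| (clipped at zero). Each
#' candidate mode contributes its own F_calc and phases from its displaced
#' coordinates; m = D = 1 throughout.
#'
#' @param spec A [toy_crystal_spec()].
#' @return List with \code{structures} (named list of [xtal_structure()] per
#'   mode), \code{reflections} (named list of [reflection_set()] per mode,
#'   sharing F_obs), and \code{spec}.
#' @export
make_toy_crystal <- function(spec) {
  stopifnot(inherits(spec, "toy_crystal_spec"))
  set.seed(spec$seed)
  truth_atoms <- wrap_atoms(spec$atoms, spec$cell)
  truth <- xtal_structure(spec$cell, "P 1", truth_atoms)
  hkl <- hemisphere_hkl(spec$cell, spec$d_min, spec$d_max)
  f_true <- structure_factors(truth, hkl)
  amp_true <- Mod(f_true)
  noise_sd <- spec$noise_frac * mean(amp_true)
  f_obs <- pmax(0, amp_true + stats::rnorm(length(amp_true), sd = noise_sd))
  structures <- list()
  reflections <- list()
  for (id in names(spec$modes)) {
    a <- truth_atoms
    mv <- spec$modes[[id]]
    if (!is.null(mv)) {
      if (is.matrix(mv)) {
        a[, c("x", "y", "z")] <- a[, c("x", "y", "z")] + mv
      } else {
        a[mv$atom, c("x", "y", "z")] <- a[mv$atom, c("x", "y", "z")] + mv$shift
      }
      a <- wrap_atoms(a, spec$cell)
    }
    st <- xtal_structure(spec$cell, "P 1", a)
    fc <- structure_factors(st, hkl)
    rec <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                      f_obs = f_obs, sig_f_obs = noise_sd,
                      f_calc = Mod(fc),
                      phase = Arg(fc) * 180 / pi,
                      fom = 1, d_factor = 1)
    structures[[id]] <- st
    reflections[[id]] <- reflection_set(spec$cell, "P 1", rec)
  }
  list(structures = structures, reflections = reflections, spec = spec)
}

#' Suite of noise-only Z maps
#'
#' Replicated toy crystals whose candidate model equals the truth, so the
#' difference coefficients are pure amplitude noise: the resulting Z values
#' approach a standard normal population.
#'
#' @param n_replicates Number of maps (>= 1).
#' @param seed Base RNG seed; replicate r uses seed + r - 1.
#' @param spec Optional [toy_crystal_spec()] template (its seed is ignored).
#' @return List of \code{z_map} objects.
#' @export
null_map_suite <- function(n_replicates, seed = 1L, spec = NULL) {
  if (n_replicates < 1L) stop("need at least one replicate")
  if (is.null(spec)) spec <- toy_crystal_spec()
  lapply(seq_len(n_replicates), function(r) {
    spec$seed <- seed + r - 1L
    spec$modes <- list(true = NULL)
    toy <- make_toy_crystal(spec)
    zscore_map(synthesize_difference_map(toy$reflections$true))
  })
}

#' Published worked-example scoring tables
#'
#' The per-mode strain-energy, RSCC and ZDD columns (and the printed scores)
#' from the original validation studies of this scoring method: the
#' acetazolamide (AZM) complex of human carbonic anhydrase II (PDB 3hs4,
#' full data and the 1.4 A truncation) and the Asp215 protonation states of
#' an aspartic proteinase (PDB 2jjj), plus the per-atom signed ZDD pairs for
#' the key atoms (AZM N1; Asp215 OD1/OD2).
#'
#' @return A list of data.frames: \code{azm_3hs4}, \code{azm_3hs4_1p4},
#'   \code{azm_n1_zdd}, \code{asp215_2jjj}, \code{asp215_atom_zdd}.
#' @export
worked_example_tables <- function() {
  list(
    azm_3hs4 = data.frame(
      mode_id = c("3", "2", "1"),
      se = c(5.55, 8.89, 10.8),
      rscc = c(0.989, 0.978, 0.975),
      zdd = c(12.8, 24.9, 27.2),
      score_printed = c(2.72, -0.74, -1.98),
      stringsAsFactors = FALSE),
    azm_3hs4_1p4 = data.frame(
      mode_id = c("3", "2", "1"),
      se = c(5.89, 9.31, 10.1),
      rscc = c(0.989, 0.981, 0.978),
      zdd = c(9.42, 18.1, 20.9),
      score_printed = c(2.77, -0.88, -1.88),
      stringsAsFactors = FALSE),
    azm_n1_zdd = data.frame(
      mode_id = c("1", "2", "3"),
      zdd_neg = c(14.27, 14.58, 4.35),
      zdd_pos = c(20.45, 21.64, 4.66),
      stringsAsFactors = FALSE),
    asp215_2jjj = data.frame(
      mode_id = c("1", "2", "3"),
      se = c(12.2, 9.08, 17.3),
      rscc = c(0.987, 0.977, 0.979),
      zdd = c(6.05, 12.3, 11.3),
      score_printed = c(1.59, 0.24, -1.83),
      stringsAsFactors = FALSE),
    asp215_atom_zdd = data.frame(
      atom = c("OD1", "OD1", "OD1", "OD2", "OD2", "OD2"),
      mode_id = c("1", "2", "3", "1", "2", "3"),
      zdd_neg = c(5.98, 7.20, 7.78, 3.66, 10.96, 12.89),
      zdd_pos = c(3.76, 5.09, 5.35, 1.23, 7.79, 8.10),
      stringsAsFactors = FALSE)
  )
}
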