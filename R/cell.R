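## Unit-cell geometry helpers shared by all modules.
## Cells are length-6 numeric vectors: a, b, c in Angstrom, alpha, beta,
## gamma in degrees. Coordinates are Cartesian Angstrom everywhere except at
## the Fourier-synthesis boundary, where fractional coordinates are used.

#' Validate a unit cell
#'
#' @param cell Numeric vector of length 6: a, b, c (Angstrom), alpha, beta,
#'   gamma (degrees).
#' @return The cell, invisibly, after validation.
#' @keywords internal
validate_cell <- function(cell) {
  if (!is.numeric(cell) || length(cell) != 6L || anyNA(cell)) {
    stop("unit cell must be 6 finite numbers: a, b, c, alpha, beta, gamma")
  }
  if (any(cell[1:3] <= 0)) stop("cell lengths must be > 0")
  if (any(cell[4:6] <= 0) || any(cell[4:6] >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  invisible(cell)
}

#' Unit-cell volume
#'
#' @inheritParams validate_cell
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(cell) {
  validate_cell(cell)
  ca <- cos(cell[4] * pi / 180)
  cb <- cos(cell[5] * pi / 180)
  cg <- cos(cell[6] * pi / 180)
  cell[1] * cell[2] * cell[3] *
    sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
}

#' Fractional-to-Cartesian orthogonalization matrix
#'
#' Standard PDB convention: a along x, b in the xy plane.
#'
#' @inheritParams validate_cell
#' @return 3x3 matrix M such that cartesian = M %*% fractional.
#' @export
orth_matrix <- function(cell) {
  validate_cell(cell)
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- cell_volume(cell)
  matrix(c(
    a, b * cos(ga), cc * cos(be),
    0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
    0, 0,           v / (a * b * sin(ga))
  ), nrow = 3, byrow = TRUE)
}

#' Cartesian-to-fractional matrix
#' @inheritParams validate_cell
#' @return 3x3 matrix, inverse of [orth_matrix()].
#' @export
frac_matrix <- function(cell) solve(orth_matrix(cell))

#' d-spacings for Miller indices
#'
#' Computed from the reciprocal metric tensor, valid for any (triclinic)
#' cell: 1/d^2 = h' G* h with G* the inverse of the real-space metric tensor.
#'
#' @param hkl Integer matrix (n x 3) or length-3 vector of Miller indices.
#' @inheritParams validate_cell
#' @return Numeric vector of d-spacings in Angstrom.
#' @export
d_spacing <- function(hkl, cell) {
  if (is.vector(hkl)) hkl <- matrix(hkl, ncol = 3)
  m <- orth_matrix(cell)
  gstar <- solve(t(m) %*% m)              # reciprocal metric tensor
  inv_d2 <- rowSums((hkl %*% gstar) * hkl)
  if (any(inv_d2 <= 0)) stop("d-spacing undefined for the (0,0,0) index")
  1 / sqrt(inv_d2)
}

#' Minimum-image Cartesian distances in a periodic cell
#'
#' @param frac_points n x 3 matrix of fractional coordinates.
#' @param frac_center Length-3 fractional coordinate.
#' @inheritParams validate_cell
#' @return Numeric vector of distances (Angstrom) under the periodic
#'   minimum-image convention (nearest lattice translate).
#' @keywords internal
min_image_dist <- function(frac_points, frac_center, cell) {
  d <- sweep(frac_points, 2, frac_center)
  d <- d - round(d)                       # wrap into [-0.5, 0.5)
  m <- orth_matrix(cell)
  cart <- d %*% t(m)
  sqrt(rowSums(cart^2))
}
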