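## Real-space map synthesis and Z-score normalization.
##
## The difference density is the real Fourier transform
##   drho(x) = (1/V) * sum_h c(h) [m(h) Fobs(h) - D(h) Fcalc(h)]
##                      * cos(2 pi h.x - phi(h)),
## summed over the unique reflections of one hemisphere of reciprocal space
## with the centricity factor c = 1 (centric) or 2 (acentric) standing in for
## the Friedel mate; F(000) is excluded, so the synthesized grid has zero
## mean. Dividing by the map standard deviation gives the per-point Z score.

#' Construct a density grid
#'
#' @param unit_cell Length-6 cell.
#' @param space_group Hermann-Mauguin symbol.
#' @param values 3-d numeric array of grid values.
#' @param kind One of "difference_density", "z_score", "calc_density",
#'   "obs_density".
#' @return An object of class \code{density_grid}; \code{$spacing} is the
#'   maximum real-space grid interval along the three cell edges.
#' @export
density_grid <- function(unit_cell, space_group = "P 1", values,
                         kind = c("difference_density", "z_score",
                                  "calc_density", "obs_density")) {
  validate_cell(unit_cell)
  kind <- match.arg(kind)
  dims <- dim(values)
  if (is.null(dims) || length(dims) != 3L || any(dims < 2L)) {
    stop("grid values must be a 3-d array with >= 2 points per direction")
  }
  structure(list(unit_cell = as.numeric(unit_cell), space_group = space_group,
                 dims = dims, values = values,
                 spacing = max(unit_cell[1:3] / dims), kind = kind),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %s, %d x %d x %d, spacing %.3f A\n",
              x$kind, x$dims[1], x$dims[2], x$dims[3], x$spacing))
  invisible(x)
}

# Fractional coordinates of all grid points, in R array order
# (first index fastest).
grid_frac_coords <- function(dims) {
  cbind(rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3]),
        rep(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3]),
        rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2])) %*%
    diag(1 / dims)
}

# Map coefficients (amplitude, phase) for the supported synthesis types.
map_coefficients <- function(refl, type = c("difference", "two_fo_fc", "fc")) {
  type <- match.arg(type)
  r <- refl$records
  cfac <- ifelse(r$centric, 1, 2)
  amp <- switch(type,
    difference = cfac * (r$fom * r$f_obs - r$d_factor * r$f_calc),
    two_fo_fc  = cfac * (2 * r$fom * r$f_obs - r$d_factor * r$f_calc),
    fc         = cfac * r$d_factor * r$f_calc)
  list(hkl = as.matrix(r[, c("h", "k", "l")]), amp = amp,
       phase_rad = r$phase * pi / 180)
}

# Direct Fourier summation of a coefficient list onto a grid, chunked so the
# point-by-reflection phase matrix stays small.
fourier_synthesis <- function(unit_cell, space_group, coef, dims, kind) {
  v <- cell_volume(unit_cell)
  x <- grid_frac_coords(dims)
  n <- nrow(x)
  ca <- coef$amp * cos(coef$phase_rad) / v
  sa <- coef$amp * sin(coef$phase_rad) / v
  th <- t(coef$hkl)
  vals <- numeric(n)
  chunk <- max(1L, floor(4e6 / max(1L, nrow(coef$hkl))))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    p <- 2 * pi * (x[i:j, , drop = FALSE] %*% th)
    vals[i:j] <- cos(p) %*% ca + sin(p) %*% sa
    i <- j + 1L
  }
  density_grid(unit_cell, space_group, array(vals, dims), kind)
}

# Grid dimensions delivering at most the target spacing along each edge.
dims_for_spacing <- function(unit_cell, spacing) {
  pmax(2L, as.integer(ceiling(unit_cell[1:3] / spacing)))
}

#' Synthesize a difference-density map
#'
#' @param refl A [reflection_set()]. The stored m and D columns weight the
#'   coefficients c(h) \[m Fobs - D Fcalc\].
#' @param spacing Target maximum grid interval in Angstrom; must not exceed
#'   d_min/4 (the later order-statistic resampling assumes it). Default
#'   d_min/4.
#' @param dims Optional explicit grid counts (overrides \code{spacing}).
#' @return A [density_grid()] of kind "difference_density". Its mean is zero
#'   to numerical precision because F(000) is excluded from the synthesis.
#' @export
synthesize_difference_map <- function(refl, spacing = NULL, dims = NULL) {
  stopifnot(inherits(refl, "reflection_set"))
  if (is.null(dims)) {
    if (is.null(spacing)) spacing <- refl$d_min / 4
    dims <- dims_for_spacing(refl$unit_cell, spacing)
  }
  actual <- max(refl$unit_cell[1:3] / dims)
  if (actual > refl$d_min / 4 + 1e-9) {
    stop(sprintf("grid spacing %.3f A is coarser than d_min/4 = %.3f A",
                 actual, refl$d_min / 4))
  }
  fourier_synthesis(refl$unit_cell, refl$space_group,
                    map_coefficients(refl, "difference"), dims,
                    "difference_density")
}

#' Synthesize an observed-style or calculated map
#'
#' Coefficients are c(h)\[2 m Fobs - D Fcalc\] ("two_fo_fc") or
#' c(h) D Fcalc ("fc"). These maps feed the real-space correlation
#' coefficient, which is reported for comparison only and never enters the
#' mode score.
#'
#' @inheritParams synthesize_difference_map
#' @param type "two_fo_fc" or "fc".
#' @return A [density_grid()].
#' @export
synthesize_map <- function(refl, type = c("two_fo_fc", "fc"),
                           spacing = NULL, dims = NULL) {
  stopifnot(inherits(refl, "reflection_set"))
  type <- match.arg(type)
  if (is.null(dims)) {
    if (is.null(spacing)) spacing <- refl$d_min / 4
    dims <- dims_for_spacing(refl$unit_cell, spacing)
  }
  fourier_synthesis(refl$unit_cell, refl$space_group,
                    map_coefficients(refl, type), dims,
                    if (type == "fc") "calc_density" else "obs_density")
}

#' Standard deviation of a difference map
#'
#' Root-mean-square of the grid values about zero over the whole unit cell:
#' the standard measure of random error (a pure precision quantity).
#'
#' @param grid A [density_grid()] of kind "difference_density".
#' @return sigma, in the map's density units.
#' @export
map_sigma <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  if (grid$kind != "difference_density") {
    stop("map_sigma expects a difference-density grid")
  }
  s <- sqrt(mean(grid$values^2))
  if (s == 0) stop("degenerate map: all grid values are zero, Z undefined")
  s
}

#' Normalize a difference map to per-point Z scores
#'
#' @param grid A [density_grid()] of difference density.
#' @param sigma The map standard deviation (> 0), typically [map_sigma()].
#' @return An object of class \code{z_map}: \code{$grid} is a
#'   [density_grid()] of kind "z_score", \code{$sigma_delta_rho} the sigma
#'   used.
#' @export
zscore_map <- function(grid, sigma = map_sigma(grid)) {
  stopifnot(inherits(grid, "density_grid"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a single positive number")
  }
  zg <- density_grid(grid$unit_cell, grid$space_group, grid$values / sigma,
                     "z_score")
  structure(list(grid = zg, sigma_delta_rho = sigma), class = "z_map")
}

#' @export
print.z_map <- function(x, ...) {
  cat(sprintf("<z_map> %d x %d x %d, sigma[drho] = %.4g\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$sigma_delta_rho))
  invisible(x)
}

#' Real-space correlation coefficient
#'
#' Pearson correlation of observed-style and calculated density over a set of
#' grid points. A comparison metric only: it mixes model accuracy with data
#' precision, so it does not enter the mode score.
#'
#' @param obs_grid,calc_grid [density_grid()] objects sharing cell and dims.
#' @param points Integer vector of grid-point (linear array) indices.
#' @return Correlation in \[-1, 1\].
#' @export
rscc <- function(obs_grid, calc_grid, points) {
  stopifnot(inherits(obs_grid, "density_grid"),
            inherits(calc_grid, "density_grid"))
  if (!identical(obs_grid$dims, calc_grid$dims) ||
      any(abs(obs_grid$unit_cell - calc_grid$unit_cell) > 1e-9)) {
    stop("grids must share cell and dimensions")
  }
  if (length(points) == 0L) stop("empty point set")
  a <- obs_grid$values[points]
  b <- calc_grid$values[points]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance over the selected points: RSCC undefined")
  }
  stats::cor(a, b)
}

#' Export a density grid as a text table
#'
#' Plain-text stand-in for binary map formats: a header describing the cell
#' and dimensions followed by one value per line in array order (first index
#' fastest).
#'
#' @param grid A [density_grid()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_density_grid <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# CELL", paste(format(grid$unit_cell, digits = 10),
                                     collapse = " ")),
               paste("# SPACE_GROUP", grid$space_group),
               paste("# DIMS", paste(grid$dims, collapse = " ")),
               paste("# KIND", grid$kind)), con)
  writeLines(format(as.vector(grid$values), digits = 10), con)
  invisible(path)
}
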