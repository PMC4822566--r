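## Reflection data: Miller indices with observed/calculated amplitudes,
## model phases and optional sigma-A weights, plus resolution truncation.

# Symmetry rotation operators for the small set of space groups the toy
# fixtures use. Reflections are centric when some operator maps h to -h.
sym_rotations <- function(space_group) {
  sg <- gsub("\\s", "", toupper(space_group))
  id <- diag(3)
  switch(sg,
    "P1"  = list(id),
    "P-1" = list(id, -id),
    "P2"  = list(id, diag(c(-1, -1, 1))),  # synthetic twofold along c
    stop("unsupported space group: ", space_group,
         " (supported: P 1, P -1, P 2)")
  )
}

#' Centricity flags from space-group symmetry
#'
#' A reflection h is centric when a symmetry rotation maps h to -h.
#'
#' @param hkl n x 3 integer matrix of Miller indices.
#' @param space_group Hermann-Mauguin symbol.
#' @return Logical vector.
#' @export
centric_flags <- function(hkl, space_group) {
  if (is.vector(hkl)) hkl <- matrix(hkl, ncol = 3)
  rots <- sym_rotations(space_group)
  cen <- rep(FALSE, nrow(hkl))
  for (r in rots) {
    cen <- cen | apply(hkl %*% t(r) + hkl, 1, function(v) all(abs(v) < 1e-9))
  }
  cen
}

#' Construct a reflection set
#'
#' @param unit_cell Length-6 cell.
#' @param space_group Hermann-Mauguin symbol.
#' @param records data.frame with columns h, k, l, f_obs, sig_f_obs, f_calc,
#'   phase (degrees), and optionally fom (m), d_factor (D), centric,
#'   d_spacing. Missing m/D default to 1 (plain Fo-Fc coefficients) with a
#'   warning; centricity and d-spacings are computed when absent and
#'   cross-checked when present.
#' @return An object of class \code{reflection_set}. \code{d_min}/\code{d_max}
#'   attributes are the data's resolution limits.
#' @export
reflection_set <- function(unit_cell, space_group = "P 1", records) {
  validate_cell(unit_cell)
  need <- c("h", "k", "l", "f_obs", "sig_f_obs", "f_calc", "phase")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("reflection records missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stop("empty reflection set")
  if (any(records$f_obs < 0) || any(records$f_calc < 0)) {
    stop("negative structure-factor amplitude in reflection records")
  }
  hkl <- as.matrix(records[, c("h", "k", "l")])
  d <- d_spacing(hkl, unit_cell)
  if ("d_spacing" %in% names(records)) {
    rel <- abs(records$d_spacing - d) / d
    if (any(rel > 1e-6)) stop("stored d-spacings disagree with the cell")
  }
  records$d_spacing <- d
  cen <- centric_flags(hkl, space_group)
  if ("centric" %in% names(records)) {
    if (any(records$centric != cen)) {
      stop("centricity flags inconsistent with space-group symmetry")
    }
  }
  records$centric <- cen
  if (!"fom" %in% names(records)) {
    warning("no figure-of-merit column; taking m = 1 (plain Fo-Fc map)")
    records$fom <- 1
  }
  if (!"d_factor" %in% names(records)) {
    warning("no D column; taking D = 1 (plain Fo-Fc map)")
    records$d_factor <- 1
  }
  if (any(records$fom < 0 | records$fom > 1)) stop("m must lie in [0, 1]")
  rownames(records) <- NULL
  structure(list(unit_cell = as.numeric(unit_cell),
                 space_group = space_group,
                 records = records,
                 d_min = min(d), d_max = max(d)),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("<reflection_set> %d reflections, %s, %.2f - %.2f A\n",
              nrow(x$records), x$space_group, x$d_max, x$d_min))
  invisible(x)
}

#' Read reflections from a text table
#'
#' The supported format is a whitespace-delimited table with a header row,
#' preceded by two comment lines:
#' \preformatted{
#' # CELL a b c alpha beta gamma
#' # SPACE_GROUP P 1
#' H K L FP SIGFP FC PHIC [FOM] [D]
#' ...
#' }
#' Binary MTZ files are detected and rejected with a pointer to conversion
#' tooling (e.g. \code{gemmi mtz2csv}).
#'
#' @param path File path.
#' @param column_map Named list mapping record fields to column names.
#'   Defaults follow CCP4 conventions (FP/SIGFP/FC/PHIC, optional FOM/D).
#' @return A [reflection_set()].
#' @export
read_reflections <- function(path,
                             column_map = list(f_obs = "FP", sig_f_obs = "SIGFP",
                                               f_calc = "FC", phase = "PHIC",
                                               fom = "FOM", d_factor = "D")) {
  if (!file.exists(path)) stop("no such file: ", path)
  magic <- readBin(path, "raw", n = 4)
  if (identical(rawToChar(magic), "MTZ ")) {
    stop("binary MTZ input is not supported; convert to the documented ",
         "text table first (e.g. with 'gemmi mtz2csv')")
  }
  lines <- readLines(path, warn = FALSE)
  cell_ln <- grep("^#\\s*CELL", lines, value = TRUE)
  sg_ln <- grep("^#\\s*SPACE_GROUP", lines, value = TRUE)
  if (!length(cell_ln)) stop("reflection table lacks a '# CELL' header line")
  cell <- as.numeric(strsplit(trimws(sub("^#\\s*CELL", "", cell_ln[1])),
                              "\\s+")[[1]])
  sg <- if (length(sg_ln)) trimws(sub("^#\\s*SPACE_GROUP", "", sg_ln[1])) else "P 1"
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           stringsAsFactors = FALSE)
  mandatory <- c("H", "K", "L", column_map$f_obs, column_map$sig_f_obs,
                 column_map$f_calc, column_map$phase)
  miss <- setdiff(mandatory, names(tab))
  if (length(miss)) {
    stop("missing mandatory column(s) ", paste(miss, collapse = ", "),
         "; available: ", paste(names(tab), collapse = ", "))
  }
  rec <- data.frame(h = tab$H, k = tab$K, l = tab$L,
                    f_obs = tab[[column_map$f_obs]],
                    sig_f_obs = tab[[column_map$sig_f_obs]],
                    f_calc = tab[[column_map$f_calc]],
                    phase = tab[[column_map$phase]])
  if (!is.null(column_map$fom) && column_map$fom %in% names(tab)) {
    rec$fom <- tab[[column_map$fom]]
  }
  if (!is.null(column_map$d_factor) && column_map$d_factor %in% names(tab)) {
    rec$d_factor <- tab[[column_map$d_factor]]
  }
  reflection_set(cell, sg, rec)
}

#' Write reflections to the documented text table
#'
#' @param refl A [reflection_set()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_reflections <- function(refl, path) {
  stopifnot(inherits(refl, "reflection_set"))
  r <- refl$records
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# CELL", paste(format(refl$unit_cell, digits = 10),
                                     collapse = " ")),
               paste("# SPACE_GROUP", refl$space_group)), con)
  tab <- data.frame(H = r$h, K = r$k, L = r$l, FP = r$f_obs,
                    SIGFP = r$sig_f_obs, FC = r$f_calc, PHIC = r$phase,
                    FOM = r$fom, D = r$d_factor)
  utils::write.table(format(tab, digits = 12), con, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Truncate a reflection set at a high-resolution cutoff
#'
#' Keeps exactly the reflections with d-spacing >= \code{d_cut}. The input is
#' unmodified; truncating twice at the same cutoff is a no-op.
#'
#' @param refl A [reflection_set()].
#' @param d_cut High-resolution cutoff in Angstrom (> 0).
#' @return A new [reflection_set()].
#' @export
truncate_resolution <- function(refl, d_cut) {
  stopifnot(inherits(refl, "reflection_set"))
  if (!is.numeric(d_cut) || length(d_cut) != 1L || d_cut <= 0) {
    stop("d_cut must be a single positive number")
  }
  keep <- refl$records$d_spacing >= d_cut
  if (!any(keep)) {
    stop(sprintf("d_cut = %.3f A exceeds the data's d_max = %.3f A: no reflections survive",
                 d_cut, refl$d_max))
  }
  reflection_set(refl$unit_cell, refl$space_group,
                 refl$records[keep, , drop = FALSE])
}
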