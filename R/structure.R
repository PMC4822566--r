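## Model representation and coordinate-file I/O (PDB / mmCIF via bio3d).

#' Construct a crystal structure object
#'
#' @param unit_cell Numeric length-6 cell: a, b, c (Angstrom), angles (deg).
#' @param space_group Hermann-Mauguin symbol, e.g. "P 1".
#' @param atoms data.frame with columns element, x, y, z (Cartesian
#'   Angstrom), occ (fractional occupancy in \[0,1\]), b (isotropic B,
#'   Angstrom^2), chain, resid (residue name), resno, elety (atom name).
#' @return An object of class \code{xtal_structure}.
#' @export
xtal_structure <- function(unit_cell, space_group = "P 1", atoms) {
  validate_cell(unit_cell)
  need <- c("element", "x", "y", "z", "occ", "b",
            "chain", "resid", "resno", "elety")
  if (!is.data.frame(atoms) || nrow(atoms) == 0L) {
    stop("atom list must be a non-empty data.frame")
  }
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms missing columns: ", paste(miss, collapse = ", "))
  if (any(atoms$occ < 0 | atoms$occ > 1)) {
    stop("occupancy outside [0, 1] in atom record(s) ",
         paste(which(atoms$occ < 0 | atoms$occ > 1), collapse = ", "))
  }
  if (any(atoms$b < 0)) stop("negative B factor in atom record(s)")
  unknown <- setdiff(unique(toupper(atoms$element)),
                     scattering_factor_table()$element)
  if (length(unknown)) {
    stop("element(s) not in the scattering-factor table: ",
         paste(unknown, collapse = ", "))
  }
  atoms$element <- toupper(atoms$element)
  rownames(atoms) <- NULL
  structure(list(unit_cell = as.numeric(unit_cell),
                 space_group = space_group,
                 atoms = atoms),
            class = "xtal_structure")
}

#' @export
print.xtal_structure <- function(x, ...) {
  cat(sprintf("<xtal_structure> %d atoms, %s, cell %s\n",
              nrow(x$atoms), x$space_group,
              paste(signif(x$unit_cell, 5), collapse = " ")))
  invisible(x)
}

# Parse the CRYST1 record of a PDB file (bio3d's parsed object does not
# carry the cell, so this one fixed-format record is read directly).
parse_cryst1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(NULL)
  cl <- cl[1]
  cell <- as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24),
                       substr(cl, 25, 33), substr(cl, 34, 40),
                       substr(cl, 41, 47), substr(cl, 48, 54)))
  sg <- trimws(substr(cl, 56, 66))
  if (anyNA(cell)) stop("malformed CRYST1 record in ", path)
  list(cell = cell, space_group = if (nzchar(sg)) sg else "P 1")
}

# Cell from mmCIF _cell.* items (line-oriented; values are plain numbers).
parse_cif_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getv <- function(tag) {
    ln <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (!length(ln)) return(NA_real_)
    as.numeric(sub(".*?([-0-9.]+)\\s*$", "\\1", ln[1]))
  }
  cell <- c(getv("_cell\\.length_a"), getv("_cell\\.length_b"),
            getv("_cell\\.length_c"), getv("_cell\\.angle_alpha"),
            getv("_cell\\.angle_beta"), getv("_cell\\.angle_gamma"))
  if (anyNA(cell)) return(NULL)
  sgl <- grep("_symmetry\\.space_group_name_H-M", lines, value = TRUE)
  sg <- if (length(sgl)) gsub("['\"]", "", sub(".*H-M\\s+", "", sgl[1])) else "P 1"
  list(cell = cell, space_group = trimws(sg))
}

#' Read a model from a PDB or mmCIF file
#'
#' All ATOM/HETATM records are kept. Where alternate conformers are present,
#' the highest-occupancy conformer of each atom is retained (first on ties)
#' and the choice is reported via \code{message()}. The unit cell is required
#' because atomic footprints are computed in the periodic cell.
#'
#' @param path File path.
#' @param dialect "pdb" or "mmcif"; guessed from the extension by default.
#' @return An [xtal_structure()].
#' @export
read_model <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (dialect == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                    error = function(e) stop("PDB parse failure in ", path,
                                             ": ", conditionMessage(e)))
    cellinfo <- parse_cryst1(path)
  } else {
    pdb <- tryCatch(bio3d::read.cif(path, verbose = FALSE),
                    error = function(e) stop("mmCIF parse failure in ", path,
                                             ": ", conditionMessage(e)))
    cellinfo <- parse_cif_cell(path)
  }
  if (is.null(cellinfo)) {
    stop("no unit cell found in ", path,
         " (a cell is required to place atomic footprints)")
  }
  at <- pdb$atom
  atoms <- data.frame(
    element = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                             substr(trimws(at$elety), 1, 1), trimws(at$elesy))),
    x = at$x, y = at$y, z = at$z,
    occ = at$o, b = at$b,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resid = at$resid, resno = at$resno, elety = trimws(at$elety),
    alt = if ("alt" %in% names(at)) at$alt else NA_character_,
    stringsAsFactors = FALSE
  )
  # Collapse alternate conformers: highest occupancy per unique atom identity.
  if (any(!is.na(atoms$alt))) {
    key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(i) {
      i[which.max(atoms$occ[i])]
    }), use.names = FALSE)
    keep <- sort(keep)
    if (length(keep) < nrow(atoms)) {
      message(sprintf(
        "collapsed %d alternate-conformer records to highest occupancy",
        nrow(atoms) - length(keep)))
      atoms <- atoms[keep, , drop = FALSE]
    }
  }
  atoms$alt <- NULL
  xtal_structure(cellinfo$cell, cellinfo$space_group, atoms)
}

#' Write a model to PDB format
#'
#' @param s An [xtal_structure()].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(s, path) {
  stopifnot(inherits(s, "xtal_structure"))
  cr <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                s$unit_cell[1], s$unit_cell[2], s$unit_cell[3],
                s$unit_cell[4], s$unit_cell[5], s$unit_cell[6],
                s$space_group, 1L)
  writeLines(cr, path)
  a <- s$atoms
  bio3d::write.pdb(file = path, append = TRUE,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, o = a$occ, b = a$b, elesy = a$element)
  invisible(path)
}

#' Define an atom selection
#'
#' Predicates over atom identity fields. NULL fields match everything;
#' character fields are matched exactly after trimming.
#'
#' @param chain,resid,resno,elety Optional vectors of admissible values.
#' @param exclude_hydrogens Drop H atoms (default TRUE: the difference-density
#'   statistic is evaluated on heavy atoms, which carry the proton signal).
#' @return An object of class \code{atom_selection}.
#' @export
atom_selection <- function(chain = NULL, resid = NULL, resno = NULL,
                           elety = NULL, exclude_hydrogens = TRUE) {
  structure(list(chain = chain, resid = resid, resno = resno,
                 elety = elety, exclude_hydrogens = exclude_hydrogens),
            class = "atom_selection")
}

#' Apply an atom selection to a structure
#'
#' @param s An [xtal_structure()].
#' @param sel An [atom_selection()].
#' @return The selected atoms as a data.frame, in file order.
#' @export
select_atoms <- function(s, sel) {
  stopifnot(inherits(s, "xtal_structure"), inherits(sel, "atom_selection"))
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$resid)) keep <- keep & a$resid %in% sel$resid
  if (!is.null(sel$resno)) keep <- keep & a$resno %in% sel$resno
  if (!is.null(sel$elety)) keep <- keep & a$elety %in% sel$elety
  if (isTRUE(sel$exclude_hydrogens)) keep <- keep & a$element != "H"
  out <- a[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("selection matches no atoms")
  out
}
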