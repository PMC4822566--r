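## Ensemble mode scoring: combine strain energy and ZDD into XModeScore,
## rank the candidate modes, form delta metrics between a reference pair,
## and drive resolution-truncation sweeps.

#' XModeScore of an ensemble
#'
#' Score_i = -\[ (SE_i - mu_SE)/sigma_SE + (ZDD_i - mu_ZDD)/sigma_ZDD \],
#' with mu and sigma the mean and population (n-denominator) standard
#' deviation of each array over the candidate modes. Lower strain and lower
#' ZDD are better, so the highest score designates the best-supported mode.
#' A constant array (sigma = 0) contributes 0 to every mode and is reported
#' as degenerate via \code{message()}. Scores over a non-degenerate ensemble
#' sum to zero, and are invariant under affine rescaling of either input.
#'
#' @param se Per-mode strain energies, kcal/mol (length n >= 2).
#' @param zdd Per-mode combined ZDD values, aligned with \code{se}.
#' @param weights Length-2 weights for the (SE, ZDD) z-terms; default 1:1.
#' @return Numeric vector of scores.
#' @export
xmodescore <- function(se, zdd, weights = c(1, 1)) {
  if (length(se) != length(zdd)) stop("SE and ZDD arrays must be aligned")
  if (length(se) < 2L) stop("mode score undefined for fewer than 2 modes")
  zterm <- function(x, what) {
    s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))  # population sd
    if (s == 0) {
      message("degenerate ", what, " array (constant); its z-term is 0")
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  -(weights[1] * zterm(se, "SE") + weights[2] * zterm(zdd, "ZDD"))
}

#' Rank scored modes
#'
#' Descending by score; ties broken by lower ZDD, then lower SE, then
#' mode id. Adds/overwrites a \code{rank} column.
#'
#' @param rows data.frame with columns mode_id, se, zdd, xmodescore.
#' @return The rows, ordered best-first, with \code{rank} set to 1..n.
#' @export
rank_modes <- function(rows) {
  need <- c("mode_id", "se", "zdd", "xmodescore")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  o <- order(-rows$xmodescore, rows$zdd, rows$se, rows$mode_id)
  out <- rows[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Delta metrics between two modes
#'
#' Signed differences, second-listed minus first-listed mode (i.e. runner-up
#' minus winner when the pair is (winner, runner-up)), so a positive delta
#' on ZDD or SE means the first-listed mode is better on that metric.
#'
#' @param rows Scored rows (see [rank_modes()]); an \code{rscc} column is
#'   used when present.
#' @param reference_pair Length-2 vector of mode ids (first, second).
#' @return Named list: delta_zdd, delta_xmodescore, delta_rscc, delta_se.
#' @export
delta_metrics <- function(rows, reference_pair) {
  i1 <- match(reference_pair[1], rows$mode_id)
  i2 <- match(reference_pair[2], rows$mode_id)
  if (is.na(i1) || is.na(i2)) {
    stop("reference mode(s) absent: ",
         paste(reference_pair[c(is.na(i1), is.na(i2))], collapse = ", "))
  }
  list(delta_zdd = rows$zdd[i2] - rows$zdd[i1],
       delta_xmodescore = rows$xmodescore[i2] - rows$xmodescore[i1],
       delta_rscc = if ("rscc" %in% names(rows)) rows$rscc[i2] - rows$rscc[i1]
                    else NA_real_,
       delta_se = rows$se[i2] - rows$se[i1])
}

#' Score a candidate-mode ensemble at one resolution
#'
#' For each mode: truncate its reflections (optional), synthesize the
#' difference map, estimate sigma, normalize to Z, gather the selection's
#' atomic footprints with the mode's own coordinates, pool them, and compute
#' the combined ZDD; RSCC over the pooled points (2mFo-DFc vs DFc maps) is
#' reported for comparison. Strain energies are supplied per mode (they do
#' not depend on the resolution cutoff).
#'
#' @param modes Named list; each element is list(structure =
#'   \link{xtal_structure}, reflections = \link{reflection_set}).
#'   All modes must share F_obs indexing (same candidate data).
#' @param selection An [atom_selection()] defining the variable moiety.
#' @param se Named numeric vector of per-mode strain energies (kcal/mol),
#'   names matching \code{modes}.
#' @param d_cut Optional resolution cutoff (Angstrom) applied before scoring.
#' @param spacing_frac Grid spacing as a fraction of d_min (default 1/4).
#' @param combine ZDD combination rule, see [zdd_for_footprint()].
#' @param partition Footprint partition rule, see [gather_atom_points()].
#' @param min_reflections Guard: error when truncation leaves fewer.
#' @param compute_rscc Synthesize the observed/calculated map pair and report
#'   RSCC (default TRUE); disable to skip two map syntheses when only the
#'   score is needed.
#' @return data.frame of per-mode rows (mode_id, se, rscc, zdd_neg, zdd_pos,
#'   zdd, n_points, xmodescore, rank), ranked best-first.
#' @export
score_modes <- function(modes, selection, se, d_cut = NULL,
                        spacing_frac = 0.25, combine = "rss",
                        partition = "hard", min_reflections = 50L,
                        compute_rscc = TRUE) {
  if (length(modes) < 2L) stop("an ensemble needs at least 2 modes")
  ids <- names(modes)
  if (is.null(ids) || any(!nzchar(ids))) stop("modes must be named")
  if (!all(ids %in% names(se))) stop("strain energies missing for some modes")
  rows <- do.call(rbind, lapply(ids, function(id) {
    m <- modes[[id]]
    refl <- m$reflections
    if (!is.null(d_cut)) {
      if (d_cut < refl$d_min - 1e-9) {
        stop(sprintf("cutoff %.2f A is finer than the data's d_min %.2f A",
                     d_cut, refl$d_min))
      }
      refl <- truncate_resolution(refl, d_cut)
    }
    if (nrow(refl$records) < min_reflections) {
      stop(sprintf("only %d reflections at cutoff %s A (need >= %d)",
                   nrow(refl$records), format(d_cut), min_reflections))
    }
    spacing <- refl$d_min * spacing_frac
    dmap <- synthesize_difference_map(refl, spacing = spacing)
    zm <- zscore_map(dmap)
    sel_atoms <- select_atoms(m$structure, selection)
    fps <- gather_atom_points(zm, sel_atoms, d_min = refl$d_min,
                              d_max = refl$d_max, partition = partition)
    pooled <- pool_footprints(fps, zm)
    zr <- zdd_for_footprint(pooled, grid_spacing = zm$grid$spacing,
                            d_min = refl$d_min, combine = combine)
    cc <- NA_real_
    if (compute_rscc) {
      obs <- synthesize_map(refl, "two_fo_fc", dims = dmap$dims)
      calc <- synthesize_map(refl, "fc", dims = dmap$dims)
      cc <- rscc(obs, calc, pooled$point_idx)
    }
    data.frame(mode_id = id, se = unname(se[id]), rscc = cc,
               zdd_neg = zr$zdd_neg, zdd_pos = zr$zdd_pos, zdd = zr$zdd,
               n_points = pooled$n_points, stringsAsFactors = FALSE)
  }))
  rows$xmodescore <- xmodescore(rows$se, rows$zdd)
  rank_modes(rows)
}

#' Resolution-truncation sweep of an ensemble
#'
#' Rescores the fixed coordinates at a series of high-resolution cutoffs:
#' at each cutoff the reflections are truncated, the map resynthesized,
#' sigma, footprint radii (which depend on d_min) and ZDD recomputed, and
#' the ensemble rescored. Strain energy is cutoff-independent. Delta metrics
#' are tracked for a fixed reference pair: by default the top two modes at
#' the finest cutoff.
#'
#' @inheritParams score_modes
#' @param cutoffs Strictly increasing cutoffs, Angstrom, each >= the data's
#'   d_min.
#' @param reference_pair Optional length-2 mode ids for the deltas.
#' @return An object of class \code{sweep_result}: \code{$cutoffs},
#'   \code{$rows} (list of ranked data.frames), \code{$reference_pair},
#'   \code{$deltas} (data.frame per cutoff).
#' @export
resolution_sweep <- function(modes, selection, se, cutoffs,
                             reference_pair = NULL, ...) {
  if (is.unsorted(cutoffs, strictly = TRUE)) {
    stop("cutoffs must be strictly increasing")
  }
  rows <- lapply(cutoffs, function(dc) {
    score_modes(modes, selection, se, d_cut = dc, ...)
  })
  if (is.null(reference_pair)) {
    reference_pair <- rows[[1]]$mode_id[1:2]   # top two at finest cutoff
  }
  deltas <- do.call(rbind, lapply(seq_along(cutoffs), function(i) {
    d <- delta_metrics(rows[[i]], reference_pair)
    data.frame(d_cut = cutoffs[i], delta_zdd = d$delta_zdd,
               delta_xmodescore = d$delta_xmodescore,
               delta_rscc = d$delta_rscc, delta_se = d$delta_se)
  }))
  structure(list(cutoffs = cutoffs, rows = rows,
                 reference_pair = reference_pair, deltas = deltas),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d cutoffs (%.2f - %.2f A), reference pair %s vs %s\n",
              length(x$cutoffs), min(x$cutoffs), max(x$cutoffs),
              x$reference_pair[1], x$reference_pair[2]))
  print(x$deltas)
  invisible(x)
}
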