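## The difference-density Z-score statistic (ZDD).
##
## A footprint's Z values are thinned to the Shannon-Nyquist independent
## fraction, split by sign, and each sign set is summarized by maximizing,
## over the subset of largest magnitudes, the chi-square tail probability of
## the subset sum with a multiple-comparisons correction for having chosen
## the subset. The maximal probability converts to a two-tailed normal Z
## magnitude; the two signed metrics combine by root-sum-square.

#' Shannon-Nyquist resampling of sorted Z values
#'
#' Grid values sampled finer than d_min/2 are not statistically independent.
#' The values are sorted by increasing magnitude and thinned by stride
#' sampling anchored at the largest magnitude (so the extreme outlier is
#' always retained), keeping the fraction
#' f = min(1, (grid_spacing / (d_min/2))^3). At the conventional spacing of
#' d_min/4 this keeps 1/8 of the values.
#'
#' @param values Numeric vector of (signed) Z values.
#' @param grid_spacing Map grid interval, Angstrom (at most d_min/2, the
#'   independence spacing; maps are conventionally sampled at d_min/4).
#' @param d_min High-resolution limit of the data, Angstrom.
#' @return The retained values, sorted by increasing magnitude.
#' @export
resample_sorted <- function(values, grid_spacing, d_min) {
  if (length(values) == 0L) stop("empty value set")
  if (grid_spacing > d_min / 2 + 1e-9) {
    stop("grid spacing coarser than d_min/2: values cannot be thinned to independence")
  }
  f <- min(1, (grid_spacing / (d_min / 2))^3)
  stride <- max(1L, as.integer(round(1 / f)))
  srt <- values[order(abs(values))]
  n <- length(srt)
  keep <- sort(seq(n, 1L, by = -stride))
  srt[keep]
}

#' Order-statistic chi-square probability maximization
#'
#' For sorted magnitudes x_(1) <= ... <= x_(N) (null: |N(0,1)| order
#' statistics), each k = 1..N defines the tail subset {x_(k), ..., x_(N)}
#' with sum of squares S_k on N-k+1 degrees of freedom. The subset
#' probability is the chi-square CDF of S_k times a multiple-comparisons
#' correction I_k for having discarded the k-1 smallest values; the
#' statistic is the maximum over k. I_1 = 1 (no correction: plain chi-square
#' CDF of the full sum) and at k = N the product reduces to the Dunn-Sidak
#' corrected probability u^N of the single maximum, with
#' u = 2 Phi(x_(N)) - 1. The default correction, the unique simple form
#' matching both reductions, is I_k = u_(k)^(k-1) with
#' u_(k) = 2 Phi(x_(k)) - 1: the null probability that all excluded values
#' fall below the smallest included one. Both factors are computed through
#' their complements so probabilities near 1 keep full precision.
#'
#' @param x_sorted Nonnegative magnitudes sorted increasing.
#' @param correction A function(k, x_sorted) returning log(I_k); the default
#'   implements the form above.
#' @return List: \code{p_max}, \code{complement} (1 - p_max, computed
#'   directly), \code{k_star} (smallest argmax k), \code{n}.
#' @export
chi2_order_statistic_pmax <- function(x_sorted, correction = NULL) {
  n <- length(x_sorted)
  if (n == 0L) stop("empty input")
  if (is.unsorted(x_sorted)) stop("input must be sorted increasing")
  if (any(x_sorted < 0)) stop("magnitudes must be nonnegative")
  x2 <- x_sorted^2
  s_k <- rev(cumsum(rev(x2)))            # S_k = sum_{i=k}^{N} x_(i)^2
  nu <- n - seq_len(n) + 1
  qc <- stats::pchisq(s_k, nu, lower.tail = FALSE)   # 1 - chi^2 CDF
  if (is.null(correction)) {
    # log u_(k) via the chi-square(1) CDF: u = 2 Phi(x) - 1 = P(chi2_1 <= x^2)
    log_u <- stats::pchisq(x2, 1, log.p = TRUE)
    log_i <- (seq_len(n) - 1) * log_u
  } else {
    log_i <- vapply(seq_len(n), correction, numeric(1), x_sorted = x_sorted)
  }
  i_k <- exp(log_i)
  one_minus_i <- -expm1(log_i)
  comp <- one_minus_i + qc * i_k         # 1 - P(chi2) * I, stable near 0
  k_star <- which.min(comp)              # smallest k on ties
  list(p_max = 1 - comp[k_star], complement = comp[k_star],
       k_star = k_star, n = n)
}

#' Convert a maximal probability to a two-tailed Z magnitude
#'
#' Z = Phi^-1((1 + p_max)/2), evaluated through the upper-tail inverse of the
#' complement (1 - p_max) so extreme probabilities keep precision. p_max at
#' 1 within machine precision is capped at 1 - 1e-300 with a warning.
#'
#' @param p_max Probability in \[0, 1\].
#' @param complement Optional 1 - p_max computed directly upstream
#'   (preferred; see [chi2_order_statistic_pmax()]).
#' @return Nonnegative Z magnitude.
#' @export
zdd_from_pmax <- function(p_max = NULL, complement = NULL) {
  if (is.null(complement)) {
    if (is.null(p_max)) stop("supply p_max or its complement")
    if (p_max < 0 || p_max > 1) stop("p_max must lie in [0, 1]")
    complement <- 1 - p_max
  }
  if (complement <= 0) {
    warning("p_max at 1 within machine precision; capping Z")
    complement <- 1e-300
  }
  stats::qnorm(complement / 2, lower.tail = FALSE)
}

#' ZDD of a footprint
#'
#' Splits the (resampled) Z values by sign: magnitudes of the negative
#' values give ZDD- (misplaced atoms), positive values give ZDD+ (unmodelled
#' density); zeros are excluded. Each side runs through
#' [chi2_order_statistic_pmax()] and [zdd_from_pmax()]; the combined metric
#' is sqrt(ZDD-^2 + ZDD+^2) by default ("rss"), with "max" and "sidak"
#' (probability-level Sidak combination of the two sides) as alternatives.
#' An empty side contributes 0 with a warning; both sides empty is an error.
#'
#' @param fp An \code{atom_footprint} (see [gather_atom_points()]), or any
#'   list with a numeric \code{z} field.
#' @param grid_spacing,d_min Passed to [resample_sorted()]; set
#'   \code{resample = FALSE} if \code{fp$z} is already thinned.
#' @param resample Whether to apply Shannon-Nyquist thinning (default TRUE).
#' @param combine Combination rule for the two signed metrics.
#' @param correction Optional multiple-comparisons override, passed on.
#' @return An object of class \code{zdd_result}: zdd_neg, zdd_pos, zdd,
#'   p_max_neg, p_max_pos, k_star_neg, k_star_pos, n_neg, n_pos.
#' @export
zdd_for_footprint <- function(fp, grid_spacing = NULL, d_min = NULL,
                              resample = TRUE,
                              combine = c("rss", "max", "sidak"),
                              correction = NULL) {
  combine <- match.arg(combine)
  z <- fp$z
  if (resample) {
    if (is.null(grid_spacing) || is.null(d_min)) {
      stop("grid_spacing and d_min are required for resampling")
    }
    z <- resample_sorted(z, grid_spacing, d_min)
  }
  neg <- sort(abs(z[z < 0]))
  pos <- sort(z[z > 0])
  if (!length(neg) && !length(pos)) {
    stop("footprint has no nonzero Z values on either side")
  }
  side <- function(v, name) {
    if (!length(v)) {
      warning("no ", name, " Z values in footprint; that side's ZDD is 0")
      return(list(zdd = 0, p_max = 0, k_star = NA_integer_, n = 0L))
    }
    pm <- chi2_order_statistic_pmax(v, correction)
    list(zdd = zdd_from_pmax(complement = pm$complement),
         p_max = pm$p_max, k_star = pm$k_star, n = pm$n)
  }
  sn <- side(neg, "negative")
  sp <- side(pos, "positive")
  comb <- switch(combine,
    rss = sqrt(sn$zdd^2 + sp$zdd^2),
    max = max(sn$zdd, sp$zdd),
    sidak = {
      # combine at probability level: P(both sides below their max under null)
      cn <- 2 * stats::pnorm(sn$zdd, lower.tail = FALSE)
      cp <- 2 * stats::pnorm(sp$zdd, lower.tail = FALSE)
      comp <- cn + cp - cn * cp          # 1 - (1-cn)(1-cp), stably
      zdd_from_pmax(complement = comp)
    })
  structure(list(zdd_neg = sn$zdd, zdd_pos = sp$zdd, zdd = comb,
                 p_max_neg = sn$p_max, p_max_pos = sp$p_max,
                 k_star_neg = sn$k_star, k_star_pos = sp$k_star,
                 n_neg = sn$n, n_pos = sp$n, combine = combine),
            class = "zdd_result")
}

#' Combine signed ZDD metrics
#'
#' @param zdd_neg,zdd_pos Nonnegative Z magnitudes.
#' @param combine "rss" (default), "max" or "sidak".
#' @return Combined ZDD.
#' @export
combine_zdd <- function(zdd_neg, zdd_pos, combine = c("rss", "max", "sidak")) {
  combine <- match.arg(combine)
  switch(combine,
    rss = sqrt(zdd_neg^2 + zdd_pos^2),
    max = pmax(zdd_neg, zdd_pos),
    sidak = {
      cn <- 2 * stats::pnorm(zdd_neg, lower.tail = FALSE)
      cp <- 2 * stats::pnorm(zdd_pos, lower.tail = FALSE)
      mapply(function(a, b) zdd_from_pmax(complement = a + b - a * b), cn, cp)
    })
}

#' @export
print.zdd_result <- function(x, ...) {
  cat(sprintf("<zdd_result> ZDD- %.3f  ZDD+ %.3f  ZDD %.3f (%s; n- %d, n+ %d)\n",
              x$zdd_neg, x$zdd_pos, x$zdd, x$combine, x$n_neg, x$n_pos))
  invisible(x)
}
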