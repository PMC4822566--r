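# The ZDD statistic: resampling, order-statistic chi-square maximization,
# probability-to-Z conversion, and sign-split scoring.

# Straight-line reimplementation of the order-statistic maximization, with
# naive (non-complement) arithmetic. Used as the independent oracle.
brute_pmax <- function(x) {
  x <- sort(x)
  n <- length(x)
  p <- numeric(n)
  for (k in seq_len(n)) {
    s <- sum(x[k:n]^2)
    ck <- pchisq(s, n - k + 1)
    u <- 2 * pnorm(x[k]) - 1
    p[k] <- ck * u^(k - 1)
  }
  list(p_max = max(p), k_star = which.max(p))
}

test_that("resampling keeps the stated fraction anchored at the maximum", {
  # spacing d_min/2: fraction 1, pure sort
  v <- c(3, -1, 0.5, -2, 1.5)
  out <- resample_sorted(v, grid_spacing = 0.5, d_min = 1.0)
  expect_equal(out, v[order(abs(v))])

  # spacing d_min/4: fraction 1/8; 80 values -> 10 kept including the max
  set.seed(7)
  v80 <- rnorm(80)
  out80 <- resample_sorted(v80, grid_spacing = 0.25, d_min = 1.0)
  expect_length(out80, 10)
  expect_equal(max(abs(out80)), max(abs(v80)))

  expect_error(resample_sorted(numeric(0), 0.25, 1), "empty")
  expect_error(resample_sorted(v, grid_spacing = 0.8, d_min = 1), "coarser")
})

test_that("resampling equals brute-force stride enumeration", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(5:200, 1)
    v <- rnorm(n)
    spacing <- runif(1, 0.1, 0.5)
    f <- min(1, (spacing / 0.5)^3)          # d_min = 1
    stride <- max(1L, as.integer(round(1 / f)))
    srt <- v[order(abs(v))]
    keep <- sort(seq(n, 1L, by = -stride))
    expect_identical(resample_sorted(v, spacing, 1), srt[keep])
  }
})

test_that("k = 1 reduces to the plain chi-square CDF of the full sum", {
  set.seed(5)
  x <- sort(abs(rnorm(8)))
  # force k = 1 to win by making all values comparable and large
  xs <- sort(x + 3)
  res <- chi2_order_statistic_pmax(xs)
  brute <- brute_pmax(xs)
  expect_equal(res$p_max, brute$p_max, tolerance = 1e-12)
  # the k = 1 term itself is the chi^2_N CDF with no correction
  k1 <- pchisq(sum(xs^2), length(xs))
  expect_gte(res$p_max, k1 - 1e-12)
})

test_that("k = N reduces to the Dunn-Sidak corrected single maximum", {
  # one dominant outlier over near-zero companions: k = N wins
  x <- sort(c(rep(1e-3, 5), 5))
  res <- chi2_order_statistic_pmax(x)
  expect_equal(res$k_star, 6L)
  u <- 2 * pnorm(5) - 1
  expect_equal(res$p_max, u^6, tolerance = 1e-12)
})

test_that("the maximization matches the brute-force oracle draw-for-draw", {
  set.seed(99)
  for (rep in 1:2000) {
    n <- sample(1:6, 1)
    x <- sort(abs(rnorm(n)))
    res <- chi2_order_statistic_pmax(x)
    brute <- brute_pmax(x)
    expect_equal(res$p_max, brute$p_max, tolerance = 1e-12)
    expect_equal(res$k_star, brute$k_star)
  }
})

test_that("p_max is invariant under permutation of the footprint values", {
  set.seed(13)
  z <- rnorm(40)
  fp1 <- list(z = z)
  fp2 <- list(z = sample(z))
  r1 <- zdd_for_footprint(fp1, grid_spacing = 0.3, d_min = 1.2)
  r2 <- zdd_for_footprint(fp2, grid_spacing = 0.3, d_min = 1.2)
  expect_equal(r1$zdd, r2$zdd, tolerance = 1e-12)
  expect_equal(r1$k_star_neg, r2$k_star_neg)
})

test_that("Z conversion round-trips and the complement path is stable", {
  expect_equal(zdd_from_pmax(0), 0)
  # the complement path keeps precision into the far tail; the naive p_max
  # path saturates in double precision beyond z ~ 5-6, which is why the
  # engine propagates complements
  for (z in c(1, 3, 10)) {
    comp <- 2 * pnorm(z, lower.tail = FALSE)
    expect_equal(zdd_from_pmax(complement = comp), z, tolerance = 1e-12)
  }
  for (z in c(1, 3, 5)) {
    p <- 2 * pnorm(z) - 1
    expect_equal(zdd_from_pmax(p_max = p), z, tolerance = 1e-8)
  }
  # naive and complement paths agree away from saturation
  set.seed(2)
  for (p in runif(20, 0, 1 - 1e-8)) {
    expect_equal(zdd_from_pmax(p_max = p),
                 zdd_from_pmax(complement = 1 - p), tolerance = 1e-12)
  }
  expect_warning(zcap <- zdd_from_pmax(p_max = 1), "capping")
  expect_true(is.finite(zcap) && zcap > 30)
})

test_that("appending a larger maximum never decreases that side's ZDD", {
  set.seed(17)
  for (rep in 1:20) {
    z <- -abs(rnorm(30))                    # all negative side
    fp <- list(z = z)
    base <- suppressWarnings(zdd_for_footprint(fp, resample = FALSE))
    bigger <- list(z = c(z, -(max(abs(z)) + runif(1, 0.1, 2))))
    grown <- suppressWarnings(zdd_for_footprint(bigger, resample = FALSE))
    expect_gte(grown$zdd_neg + 1e-10, base$zdd_neg)
  }
})

test_that("sign sets are handled separately and degenerate inputs error", {
  expect_error(zdd_for_footprint(list(z = c(0, 0, 0)), resample = FALSE),
               "no nonzero")
  expect_warning(r <- zdd_for_footprint(list(z = c(0.5, 1.2, 2.0)),
                                        resample = FALSE), "negative")
  expect_equal(r$zdd_neg, 0)
  expect_gt(r$zdd_pos, 0)
  expect_equal(r$zdd, r$zdd_pos)            # rss with one side zero
  # combined metric dominates each side under the default combination
  set.seed(23)
  fp <- list(z = rnorm(50))
  res <- zdd_for_footprint(fp, resample = FALSE)
  expect_gte(res$zdd, max(res$zdd_neg, res$zdd_pos))
})

test_that("published atomic ZDD pairs reproduce the fourfold contrasts", {
  tabs <- worked_example_tables()
  n1 <- tabs$azm_n1_zdd
  cz <- combine_zdd(n1$zdd_neg, n1$zdd_pos)
  ratio13 <- cz[n1$mode_id == "1"] / cz[n1$mode_id == "3"]
  expect_gt(ratio13, 3.5)
  expect_lt(ratio13, 4.3)

  od2 <- subset(tabs$asp215_atom_zdd, atom == "OD2")
  cz2 <- combine_zdd(od2$zdd_neg, od2$zdd_pos)
  r21 <- cz2[od2$mode_id == "2"] / cz2[od2$mode_id == "1"]
  r31 <- cz2[od2$mode_id == "3"] / cz2[od2$mode_id == "1"]
  expect_true(r21 > 3.0 && r21 < 4.5)
  expect_true(r31 > 3.0 && r31 < 4.5)
})
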