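---
title: "Methods: difference-density mode scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: difference-density mode scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modescore)
```

## The model

A crystallographer has refined the same structure several times, once per
candidate protonation or tautomeric state of a moiety of interest (a ligand,
a catalytic aspartate, a histidine). Protons themselves are invisible at
typical resolutions, but each candidate state forces slightly different
heavy-atom geometry, and a *wrong* state leaves systematic residual features
in the mFo−DFc difference map around the moiety after refinement. The
package turns those residuals plus the model's internal strain into a single
ranking score per mode.

Assumptions: one refined model and one set of map coefficients
(Fobs, σFobs, Fcalc, φcalc, optionally m and D) per mode, all against the
same observed data; the moiety of interest is identifiable by an atom
selection; difference-map errors away from genuine signal behave like
Gaussian noise, which is what the Z-normalization and the χ² machinery
assume, and which holds increasingly well as the model improves.

## Difference density and its Z score

`synthesize_difference_map()` computes, over the Friedel-unique hemisphere,

Δρ(r) = (1/V) Σ_h c(h) [m·Fobs − D·Fcalc] cos(2π h·x − φ),

with c(h) = 1 for centric and 2 for acentric reflections. F(000) is not in
the sum, so Δρ has zero mean over the cell; its whole-cell RMS σ[Δρ]
(`map_sigma()`) is a pure precision measure, and `zscore_map()` divides by
it to give grid values z = Δρ/σ[Δρ] that are standard normal for a correct
model. The test suite verifies the synthesis against closed-form single
reflection maps, Parseval's theorem for σ, and Monte-Carlo null calibration
(pooled z mean within ±0.05, SD within 5% of 1).

Default grid spacing is d_min/4 (finer is accepted, coarser is an error):
fine enough that footprints are well sampled, and the independence
correction below accounts for the oversampling.

## Atomic footprints

Which grid points "belong" to an atom is decided by the band-limited atomic
density profile

ρ(r) = n ∫ 4π s² f(s) e^(−B s²/4) sinc(2π s r) ds,  s ∈ [0.5/d_max, 0.5/d_min],

with f(s) a packaged 4-Gaussian scattering-factor fit (H, C, N, O, F, P, S,
Cl, Zn; f(0) matches the electron count within 2%). Two numerical choices
deserve comment:

- **The s convention.** The band limits follow the method's printed
  definition (0.5/d). The alternative convention s = 1/d looks more natural
  next to the e^(−Bs²/4) damping factor, but it was tested and rejected: the
  sharper effective band edge makes the footprint radius (below)
  non-monotone in B and d_min, violating a property the method relies on.
  The profile only sets footprint radii and partition weights — map
  synthesis and the toy generator's structure factors use standard physical
  conventions — so the band convention is bookkeeping, frozen for
  stability.
- **The radius integral's plateau.** R_atom(r) = ∫₀^r 4π r'² ρ(r') dr'
  cannot be taken to r → ∞ literally: a band-limited density has no DC
  component, so the integral oscillates. The limiting value is estimated as
  the midline of the first ripple (mean of the first local maximum and the
  following local minimum of R_atom); when B-damping removes the ripple
  entirely, R_atom saturates and the saturation value is used. The two
  rules agree continuously as the ripple amplitude vanishes. The footprint
  radius r_max is where R_atom first reaches 95% of that value, located to
  1e−3 Å. First-crest and electron-count references were tested and
  rejected (parameter-sensitive, and unreachable at high B, respectively).

`rmax_95()` is monotone non-decreasing in both B and d_min; the acceptance
suite checks a 5×5 grid over B ∈ {5, 10, 20, 35, 50} Å² ×
d_min ∈ {1.5, 2.0, 2.5, 3.0, 3.5} Å, and the toy regime (B 8–15, d_min
1.0–1.4 Å) is verified separately. Extreme combinations — very large B at
substantially finer d_min than 1 Å — are outside the validated domain.

`gather_atom_points()` assigns every grid point within r_max of at least
one atom (periodic minimum-image) to exactly one footprint: the atom whose
ρ(distance) is largest, ties to the earlier atom. Hard assignment is the
default because fractionally splitting a point rescales Δρ and σ alike,
leaving z unchanged — fractional weights would either double-count the
point or break the independence assumptions downstream. `partition =
"shared"` provides the alternative bookkeeping. Membership is tested
against an independently coded brute-force periodic sphere scan.

## The ZDD statistic

For a footprint's z values:

1. **Independence thinning** (`resample_sorted()`): values sampled finer
   than d_min/2 are correlated; the sorted magnitudes are thinned by stride
   sampling, keeping the fraction f = min(1, (spacing/(d_min/2))³) anchored
   at the largest magnitude (at d_min/4 spacing, 1/8 of the values).
2. **Sign split**: negative values (misplaced atoms) and positive values
   (unmodelled density) are scored separately; zeros drop.
3. **Order-statistic maximization** (`chi2_order_statistic_pmax()`): for
   sorted magnitudes x₍₁₎ ≤ … ≤ x₍N₎, each k defines the tail subset with
   sum S_k on ν = N−k+1 degrees of freedom and probability
   p_k = P(χ²_ν ≤ S_k) · I_k, where I_k corrects for having discarded the
   k−1 smallest values. The correction used is I_k = u₍ₖ₎^(k−1) with
   u₍ₖ₎ = 2Φ(x₍ₖ₎) − 1 — the unique simple form matching both stated
   special cases: I₁ = 1 (plain χ²_N CDF of the full sum) and, at k = N,
   the Dunn–Šidák form u^N for the single maximum. It is replaceable via
   the `correction` argument. All factors are computed through their
   complements (`-expm1(log I)`, upper-tail `pchisq`), so probabilities
   within 1e−300 of 1 keep full precision.
4. **Conversion**: ZDD_side = Φ⁻¹((1 + p_max)/2), evaluated from the
   complement. The combined metric is √(ZDD₋² + ZDD₊²) by default
   ("rss"; the root-sum-square of two independent normal-equivalent
   magnitudes), with "max" and a probability-level "sidak" combination as
   alternatives. The rss default reproduces the two independent fourfold
   atomic-ZDD contrasts in the published validation tables, which is the
   evidence the package freezes it on.

The engine is verified against a naive independently written implementation
on thousands of random draws, and both special-case reductions are tested
exactly.

## Strain energy and the score

SE = E_singlepoint − E_optimized for the isolated moiety (hydrogens
included), both energies from the same backend; it is nonnegative by
construction and any backend violating that contract raises an error.
`reference_backend()` (harmonic bonds/angles, optional r⁻¹² repulsion,
analytic gradients, BFGS) makes synthetic work deterministic;
`external_backend()` wraps any command via `{input}`/`{output}` XYZ-file
placeholders.

`xmodescore()` combines the per-mode arrays:

Score_i = −[(SE_i − μ_SE)/σ_SE + (ZDD_i − μ_ZDD)/σ_ZDD],

with **population** (n-denominator) standard deviations — the sample SD
fails to reproduce the published scores (2.22 instead of 2.72 for the
best acetazolamide mode), the population SD reproduces every tested block
to two decimals, and an oracle test freezes the choice. A constant array
contributes zero with a message. Equal weights are the default; a
`weights` argument exists.

`resolution_sweep()` rescores fixed coordinates at increasing cutoffs and
tracks Δ-metrics for a fixed reference pair (default: top two modes at the
finest cutoff). Published sweeps re-refine at each truncation; this package
deliberately does not, so sweep outputs are qualitative contrast trends
(ΔZDD decaying with the cutoff), not reproduction targets.

## Synthetic fixtures and what the tests do and do not show

`toy_crystal_spec()`/`make_toy_crystal()` build P1 toy crystals:
direct-summation structure factors over Gaussian atoms, F_obs = |F_true|
plus seeded Gaussian amplitude noise, per-mode F_calc/φ with m = D = 1.
Defaults, chosen as ordinary small-molecule-in-P1 values and fixed before
any acceptance run: 8 Å cubic cell, a four-atom S–C–N–O moiety with B
8–15 Å², d_min 1.2 Å (1.0 Å and a 10 Å cell for sweep fixtures, so coarse
cutoffs keep ≥ 50 reflections), noise 2% of the mean amplitude, planted
heavy-atom displacements of 0.3 Å. These sizes keep every stochastic test
(20-seed recovery, 25-seed paired null/planted comparison, 10-replicate
null calibration) within a couple of minutes on one core.

Passing them demonstrates internal statistical correctness — calibration,
oracle equivalence, planted-truth recovery under the package's own noise
model — not performance on real crystals: there is no solvent, no
anisotropy, no refinement feedback, no phase error beyond the model
displacement, and only P1 data. The published-score reproductions
(`worked_example_tables()`) cover the score arithmetic on real published
inputs; the absolute published ZDD/SE values themselves require deposited
structure factors and a quantum-chemistry refinement engine, both outside
scope.

## Known limitations

- Space groups: P 1, P −1, P 2 only (centricity and hemisphere handling).
- Binary MTZ and CCP4 map formats are not read or written; text tables and
  a text grid export are provided, with pointers to converters.
- Altloc handling collapses to the highest-occupancy conformer.
- No automatic protomer enumeration: the user supplies the candidate modes.
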