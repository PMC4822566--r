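# modescore

Post-refinement scoring of protomer and tautomer modes from X-ray
difference density.

## The problem

Hydrogen atoms scatter X-rays too weakly to be seen directly in most
macromolecular electron-density maps, yet the protonation and tautomeric
state of a ligand or catalytic residue is often the chemically decisive
question. The positions of protons are nevertheless encoded indirectly: the
heavy atoms they bind to shift by tenths of an angstrom between protomers,
and those shifts leave systematic features in the mFo−DFc difference map
after refinement. `modescore` quantifies that evidence. Each candidate mode
(a protomer, tautomer, or flip state) is refined independently; the package
then scores how well each refined model silences the difference density
around the variable moiety, penalized by the internal strain its geometry
carries, and ranks the ensemble.

## The statistics

Three quantities are computed per mode:

- **ZDD**, the difference-density Z-score. The difference map Δρ is
  synthesized from the weighted coefficients c(h)[m·Fobs − D·Fcalc] over the
  Friedel-unique hemisphere (c = 1 centric, 2 acentric; F(000) excluded, so
  the map has zero mean) and normalized by its whole-cell RMS, σ[Δρ]. The
  grid points covering the moiety — every point within each atom's 95%
  footprint radius, assigned to the atom whose calculated band-limited
  density dominates there — are thinned to the Shannon–Nyquist independent
  fraction, split by sign, and each sign set's magnitudes are summarized by
  maximizing, over tail subsets of the order statistics, the χ² probability
  of the subset sum under a multiple-comparisons correction. The maximal
  probability converts to a normal-equivalent Z; the signed metrics combine
  as ZDD = √(ZDD₋² + ZDD₊²). Low ZDD means the model explains its density.
- **SE**, the strain energy: single-point energy minus locally optimized
  energy of the isolated moiety (kcal/mol), from a pluggable backend. A
  deterministic harmonic reference backend ships with the package; any
  external energy program can be wrapped through a two-line file protocol.
- **XModeScore**: for each mode *i* over the ensemble,
  Score_i = −[(SE_i − μ_SE)/σ_SE + (ZDD_i − μ_ZDD)/σ_ZDD], with population
  (n-denominator) standard deviations. The highest score designates the
  best-supported mode; scores of an ensemble sum to zero.

Resolution-truncation sweeps (`resolution_sweep()`) rescore the fixed
coordinates at a series of high-resolution cutoffs to show how the mode
contrast degrades as data are discarded.

## Worked example

A toy P1 crystal with a four-atom S–C–N–O moiety; the "data" are direct-sum
amplitudes with 2% Gaussian noise, and two decoy modes displace a heavy atom
by 0.3 Å (standing in for the geometry change a misassigned proton causes):

```r
library(modescore)

spec <- toy_crystal_spec(
  modes = list(neutral    = NULL,                                  # truth
               tautomer_a = list(atom = 3L, shift = c(0.3, 0, 0)),
               tautomer_b = list(atom = 1L, shift = c(0, -0.21, 0.21))),
  seed = 42)
toy <- make_toy_crystal(spec)

# strain energies from the built-in harmonic backend (bonds at the truth
# geometry, 300 kcal/mol/A^2)
xyz   <- as.matrix(spec$atoms[, c("x", "y", "z")])
pairs <- rbind(c(1, 2), c(2, 3), c(2, 4))
bonds <- data.frame(i = pairs[, 1], j = pairs[, 2], k_bond = 300,
                    r0 = sqrt(rowSums((xyz[pairs[, 1], ] - xyz[pairs[, 2], ])^2)))
backend <- reference_backend(bonds)
se <- vapply(toy$structures, function(st) {
  strain_energy(molecule(st$atoms$element,
                         as.matrix(st$atoms[, c("x", "y", "z")])),
                backend)$strain
}, numeric(1))

modes <- Map(function(st, rf) list(structure = st, reflections = rf),
             toy$structures, toy$reflections)
tab <- score_modes(modes, atom_selection(resid = "LIG"), se)
print(tab, digits = 3)
```

```
     mode_id    se  rscc zdd_neg zdd_pos  zdd n_points xmodescore rank
1    neutral 0.000 1.000    1.49   0.811  1.7     1211        2.2    1
2 tautomer_b 0.362 0.960   22.62  23.250 32.4     1221       -0.2    2
3 tautomer_a 4.398 0.989   22.96  18.352 29.4     1237       -2.0    3
```

The planted truth is nearly strain-free, silences its footprint (ZDD 1.7,
i.e. noise level), and ranks first; both decoys light up their footprints
with ZDD around 30 despite RSCC values that would look acceptable on their
own.

The score arithmetic on the published carbonic anhydrase II/acetazolamide
ensemble (packaged via `worked_example_tables()`):

```r
tabs <- worked_example_tables()
xmodescore(tabs$azm_3hs4$se, tabs$azm_3hs4$zdd)
```

```
  mode score
1    3  2.72
2    2 -0.74
3    1 -1.98
```

## Command-line tools

Two thin front-ends live in `inst/scripts/` (after installation, under
`system.file("scripts", package = "modescore")`):

```sh
Rscript make_fixtures.R --out demo --seed 7
Rscript score.R --models demo --reflections demo \
    --strain-from-file demo/strain.csv --selection LIG \
    --cutoffs 1.3,1.7 --out results.csv
```

`score.R` reads one PDB per mode, per-mode (or shared) text reflection
tables, and a strain CSV, writes the ranked table as CSV, and logs all
settings as JSON. Binary MTZ files are not read; `read_reflections()`
documents the expected text-table layout and suggests converters.

## Scope and limitations

- Space-group machinery covers P 1, P −1 and P 2 (the fixture groups);
  general symmetry is out of scope.
- The resolution sweep rescores fixed coordinates; it does not re-refine
  per truncation, so sweep values are qualitative contrast trends.
- Strain quality is bounded by the chosen energy backend; the built-in
  harmonic backend is for testing and synthetic work, not chemistry.
- See `vignette("modescore-methods")` for the model, parameter defaults,
  and the numerical design decisions.
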