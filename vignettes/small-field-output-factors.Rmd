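---
title: "Small-field output factor correction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-field output factor correction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfdose)
```

This vignette records how `sfdose` computes what it computes and why the
design is the way it is: the measurement model, the numerical choices, the
synthetic beam the tests run against, and the limits of what those tests
demonstrate.

## The measurement model

A commissioning dataset for a megavoltage photon beam consists of
depth-dose curves, lateral profiles, and field output factors (FOFs). For
fields below about 2 cm side, three effects make the raw measurements
detector-dependent: loss of lateral charged-particle equilibrium, partial
occlusion of the primary source by the collimators, and perturbation of
the measured signal by the detector itself. The package's analysis chain
follows current small-field practice:

1. **Scan metrics.** Profiles are normalised to 100 on the central axis
   and recentred on the midpoint of their 50% crossings; the dosimetric
   field width is the FWHM, the penumbra the 20–80% edge span. Depth doses
   are normalised to 100 at the maximum; `d_max` is refined parabolically.
2. **Equivalent square field size.** `S_clin = sqrt(A·B)` from the
   cross-plane and in-plane FWHM, *at the measurement plane* (SSD 100 cm,
   depth 10 cm, hence a 110 cm plane). No back-projection to the isocentre
   plane is applied: correction-factor tables are indexed by the
   dosimetric size where it was measured, and applying the geometric mean
   to widths expressed at the same plane keeps the arithmetic consistent
   with how such tables are published.
3. **Output factor correction.** The uncorrected FOF is the ratio of mean
   readings (ratio of means, not mean of ratios — the charge-collection
   convention; at 0.3% reading noise the difference is far below reporting
   precision). The corrected FOF multiplies it by `k(S_clin)`,
   interpolated linearly from a user-supplied table.
4. **Intermediate field method.** When a detector is only trusted up to an
   intermediate field (default 4 cm), the chain
   `clinical → intermediate (detector) → msr (reference chamber)` is used,
   with each leg carrying its own correction-factor ratio. With the
   intermediate field equal to the msr field the chain reduces to the
   direct method identically — this is enforced by test.
5. **Spread statistics.** Detector and dataset agreement is summarised per
   field size (or per treatment case) as mean, sample SD and
   `%SD = SD/mean × 100`. The SD divisor is `n − 1` throughout: with only
   three detectors pooled, the divisor visibly changes the printed value,
   and the sample convention is the one consistent with every printed
   summary in the bundled example dataset (encoded as a regression test).

## Numerical choices

- **Smoothing** is local polynomial least squares (Savitzky–Golay in
  spirit), default window 7 points, order 2. Unlike convolution-weight
  Savitzky–Golay it uses the actual sample positions, so unevenly spaced
  scans are handled; at the curve ends the window shrinks to the available
  points rather than padding. Polynomials up to the fit order are
  reproduced exactly, which protects peak positions — the reason this
  family is preferred over a moving average.
- **Level crossings** are located by linear interpolation between the
  bracketing samples and refined no further. On a ≤ 0.5 mm grid the
  residual error is orders of magnitude below the 0.01 cm at which field
  widths are reported; tests hold the extractors to ≤ 0.01 mm against
  dense-grid brute-force search on erf-edge profiles.
- **`d_max` ties** (a flat plateau of equal maxima) return the plateau
  midpoint — symmetric and deterministic. A maximum at the scan boundary
  is returned as-is with a warning rather than extrapolated.
- **k interpolation** is piecewise linear in `S_clin`, exact at knots, and
  *strict* about range: extrapolating a correction factor below the
  smallest tabulated field is precisely the failure mode the small-field
  protocols warn against, so out-of-range queries fail unless the caller
  opts into clamping (which warns).
- **Degenerate inputs** (all-zero curves, monotone "profiles" with no
  crossings, multi-crossing shapes) raise typed shape/degenerate errors
  naming the offending side rather than returning NaN.
- **Rounding for reports**: field widths at 0.01 cm, FOFs at 3 decimals,
  %SD at 1 decimal, round-half-even; everything is carried unrounded
  internally. Comparisons against previously printed values in the test
  suite allow one unit in the last printed digit, absorbing the source's
  own rounding.
- **Effective point of measurement**: no depth shift is ever applied
  implicitly. Whether a chamber depth-dose scan needs one depends on the
  acquisition setup and on whether the vendor software already shifted it,
  neither of which is recoverable from the scan file; `shift_curve()`
  exposes the offset as an explicit user decision, defaulting to none.

## The synthetic beam and detector models

No public small-field scan repository exists, so the package ships a
generator whose outputs have known truth. It emulates, with the simplest
smooth functional families that reproduce the qualitative phenomena:

- **Depth dose**: `PDD(d) ∝ (1 − e^(−a·d))·e^(−μ·d)` with μ = 0.0048/mm
  and `a` solved from `d_max` = 15 mm — PDD(10 cm) ≈ 67.7%, typical of a
  flattened 6 MV beam (TPR20,10 = 0.665).
- **Profiles**: sums of error functions with source-blur σ = 3 mm,
  sampled at 0.2 mm, spanning ±1.5 projected widths.
- **True FOF**: `Ω(S) = (1 − c1·e^(−S/λ))·O(S)` normalised to 1 at the
  10 cm msr field, with c1 = 0.42, λ = 5 cm; `O(S)` is a smooth occlusion
  drop below w0 = 1.2 cm (strength 0.5). This places Ω(1) ≈ 0.686 and
  Ω(6) ≈ 0.926, the regime observed for jaw-defined 6 MV fields.
- **Detector responses**: `r(S) = VA(S)·(1 + β·e^(−S/τ))`, normalised to
  1 at the msr field. `VA` is the mean of the closed-form profile over a
  1-D top-hat aperture — 3.6 mm for the micro-chamber (its cavity length)
  and 2.0 mm for the diodes (their sensitive diameter). β = +0.13 for the
  shielded diode, −0.034 for the unshielded one, 0 for chambers, with
  τ = 2 cm. These values were fixed once so that the uncorrected
  cross-detector %SD at a 1 cm field lands in the 4–6% band reported for
  real detector trios — a fixture calibration, not a physics claim.
- **Correction tables**: the implied `k = 1/r` is tabulated against the
  `S_clin` *measured from the generator's own emitted profiles*, exactly
  how protocol tables are indexed by dosimetric field size. Because the
  analysis pipeline recomputes the same `S_clin` from the same files, the
  zero-noise correction chain closes on the true FOF to floating-point
  precision — the closure test would instead inherit an interpolation
  error of order 10⁻⁶ if the tables were indexed by nominal side.
- **Noise**: i.i.d. Gaussian relative noise on readings only (default
  0.3%, 3 repeats), all under one integer seed; emitted files print
  numerics with round-trip-exact precision, so a rerun with the same seed
  is byte-identical.

What the generator does **not** emulate: head-scatter and MLC leaf-end
physics, spectral changes with field size and depth, angular/dose-rate
detector dependence, scan-arm positioning errors, and any treatment
planning system behaviour (dose calculation, MU computation, sub-2 cm
extrapolation). Passing the synthetic closure tests therefore demonstrates
that the *arithmetic and plumbing* of the correction chain are exact, and
that the statistical machinery behaves as designed under realistic noise —
not that any particular physical beam is modelled accurately. Conclusions
about real beams enter only through the bundled example commissioning
summaries, which the regression suite reproduces cell by cell.

One qualitative caveat found while validating the generator: the
penumbra-broadening margin of a chamber-sized aperture is essentially
constant (~0.3 mm) for fields with a flat top and *decreases* at 1 cm,
where the profile is all penumbra and CAX renormalisation damps the
apparent broadening. The suite therefore asserts strict positivity of the
margin (chamber scans always read a wider penumbra than point-detector
scans) rather than monotone growth toward small fields.

## Problem sizes

The shipped configuration — six fields (1, 2, 3, 4, 6, 10 cm), four
detectors, 0.2 mm profile grids, 0.5 mm depth grid, 200 Monte Carlo
replicates for the noise study — runs the full suite in well under a
minute and was chosen as the smallest scenario that exercises every code
path (occluded and unoccluded fields, both correction methods, both small-
field flag states) with comfortable statistical headroom.

## Known limitations

- Only the geometric-mean equivalent square is implemented; rectangular
  `2ab/(a+b)` and circular equivalences are out of scope.
- The daisy chain supports one intermediate field, not longer ladders.
- Correction-factor tables are user-supplied inputs; the package ships
  only the two EDGE values quoted for this beam quality plus
  generator-implied tables, and deliberately refuses to extrapolate below
  a table's smallest field.
- Scan input is the package's plain-text dialect; vendor binary formats
  and DICOM are not read.
- %SD is descriptive; no inferential statistics are attached to the
  comparisons.
```{r session}
sessionInfo()
```
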