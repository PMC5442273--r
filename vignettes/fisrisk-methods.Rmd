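---
title: "Methods: a Mamdani fuzzy system for oxidative-stress-based oral cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Mamdani fuzzy system for oxidative-stress-based oral cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fisrisk)
```

## The model

Oral potentially malignant disorders (OPMDs) progress to squamous cell
carcinoma at rates that are hard to predict from histopathology alone.
Oxidative stress is strongly associated with that progression: serum
malondialdehyde (MDA, a lipid-peroxidation end product, here in nmol/ml)
rises with oxidative load, while serum proton-donor capacity (total
antioxidant activity, expressed as an inhibition percentage) falls.
`fisrisk` turns these two biomarkers into a single malignization-risk score
on a 1–10 scale with a Mamdani fuzzy inference system:

1. Each variable carries a five-term linguistic partition
   `fm, m, Md, M, FM` (very small, small, medium, high, very high) made of
   piecewise-linear membership functions — shoulder trapezoids at the ends,
   half-overlapping triangles inside.
2. A crisp input pair is *fuzzified* into per-term membership degrees.
3. 25 IF–THEN rules — one per (MDA term, donors term) pair — fire with
   strength MIN over their antecedent degrees (the AND connective).
4. Each rule's consequent risk term is clipped (MIN implication) at the
   rule's strength; the clipped sets are aggregated pointwise by MAX.
5. The aggregate membership curve is defuzzified to the crisp risk.

The rule matrix (`oral_rule_matrix()`) encodes the clinical gradient "high
MDA with low antioxidant capacity is dangerous": its consequent index is
non-decreasing along MDA in every donors column and non-increasing along
donors in every MDA row. The extreme corners map (very high MDA, very low
donors) to very high risk and the mirror corner to very low risk.

The variation fields are those observed on the study cohort of 16 OPMD
patients: MDA on [1.1, 6.7] nmol/ml, proton donors on [38.5, 58.25]
inhibition %, risk on [1, 10]. We take 58.25 rather than the rounded
58.2 that appears alongside the field definition, because the final point
of the published 101-row sweep sits at 58.2500 and must lie inside the
universe; the 0.05 discrepancy is a typesetting-level inconsistency in the
source, documented here rather than hidden.

## Engine choices and their defaults

* **Defuzzifier.** The source names only the MIN-MAX composition; the
  defuzzifier is unstated. We adopt the **centroid** of the aggregated
  set — the Mamdani standard and the default of the Matlab-style toolboxes
  this kind of system is usually built in — computed as the discrete
  center of mass `sum(x*mu)/sum(mu)` over a uniform sample of the output
  universe. `bisector` and `mom` (mean of maximum) are available as
  sensitivity checks (`fis_options(defuzz = ...)`).
* **Resolution.** The output grid has 1001 points by default (both
  endpoints included; minimum 101). Doubling to 2001 moves crisp outputs
  by well under $10^{-3}$ risk units, so the discretization error is far
  below every tolerance used here.
* **Out-of-range inputs.** The variation fields come from the min/max of
  only 16 patients, so new patients may legitimately fall outside. Inputs
  are therefore clamped to the universe bounds with a warning;
  `strict = TRUE` (or `fis_options(clamp = FALSE)`) turns clamping into an
  error.
* **Degenerate knots.** A zero-width ramp is a step: the peak/plateau is a
  closed interval, so membership is exactly 1 at a coincident knot. This
  is what makes a zero-shoulder end trapezoid still reach full membership
  at the universe bound.
* **Rule weights** are all 1; product/sum composition variants and
  non-linear membership shapes are deliberately out of scope.

## The default partition and its calibration

The published figures show the membership layouts only graphically; knot
coordinates are not printed anywhere. We therefore (a) fix a reproducible
default and (b) recover the geometry from the published numbers.

**Default** (`standard_partition()`): breakpoints
$c_i = a + i\,(b-a)/4$, triangles `m, Md, M` peaked at $c_1, c_2, c_3$
with feet at their neighbours, and end trapezoids whose plateau covers a
`shoulder_fraction` (default 1/8, i.e. half the distance from the bound to
the nearest interior peak) of the universe. Memberships sum to one on
$[c_1, c_3]$.

**Calibration** (`calibrate()`): the published result table prints 15 of
the 101 rows of a diagonal sweep of both universes
($\mathrm{MDA}_i = 6.7 - 0.056\,(i-1)$,
$\mathrm{donors}_i = 38.5 + 0.1975\,(i-1)$), each with its crisp risk to
four decimals. These rows are bundled as a plain-text fixture
(`table2_printed()`) and treated as calibration evidence. Twelve free
parameters describe the geometry: per variable a shoulder fraction in
$[0, 0.25)$ and three interior-peak offsets, dimensionless in units of the
quarter width $h = (b-a)/4$ and bounded to $(-0.45, 0.45)$ so peak
ordering can never invert. Triangle feet stay tied to the neighbouring
peaks; that half-overlap constraint is what keeps a 12-parameter fit
identifiable from 12 points. The sum of squared risk residuals is
minimized by Nelder–Mead started deterministically at the default layout,
with a 2000-evaluation budget spent as three restarted rounds (each
restart re-inflates the simplex around the incumbent best, which rescues
the search when the simplex collapses early on this piecewise-smooth
objective). Infeasible proposals are projected back into the box before
evaluation. The whole procedure is deterministic: same rows, same fit.

```{r, eval = FALSE}
cal <- calibrate(table2_printed(), holdout = c(3L, 46L, 99L))
cal$holdout_errors   # |predicted - printed| on the three held-out rows
```

Holding out one printed row per block (rows 3, 46, 99) and fitting on the
other twelve reproduces the held-out risks to well within 0.2 risk units
(the tests compute the exact numbers); fitting on all 15 rows reproduces
the sweep extremes 9.3440 and 1.6560 comparably well. Exact four-decimal
agreement is not claimed: the source prints neither knots nor the
defuzzifier, so the recovered geometry is one member of the family of
layouts consistent with 15 printed points.

## The synthetic-recovery harness and the fixture generator

`synthetic_recovery_test(seed)` validates the calibration machinery
end-to-end where the ground truth *is* known: it draws a truth system with
seeded random knot perturbations — shoulder fractions uniform on
[0.05, 0.20] and peak offsets uniform within 15 % of the quarter width,
chosen as the range of layouts one could plausibly read off a published
membership figure — generates its full 101-row sweep, calibrates a fresh
default system on the 12 rows matching the printed fit pattern, and
reports holdout-risk and parameter recovery errors.

`generate_fixture(seed, n)` stands in for a patient cohort: `n` biomarker
pairs uniform over the two input universes (default `n = 16`, the study's
cohort size). It emulates only the support of the data, not its joint
distribution — real MDA and antioxidant capacity are negatively
correlated and not uniform — so passing tests demonstrate engine and
calibration correctness, not clinical performance on real patients.

## Numerical behaviour worth knowing

* **Centroid ripple.** With a monotone rule base, the crisp output of a
  clipped-centroid Mamdani engine is *almost* monotone in each input, but
  not exactly: as successive rules take over, the centroid of the
  aggregate wobbles by up to a couple of hundredths of a risk unit
  (stable under grid refinement, so intrinsic, not discretization). The
  tests therefore assert the bidirectional monotone trend within 0.2 risk
  units — the same tolerance used for reproducing printed risks — while
  the 101-row diagonal sweep of the default system is strictly decreasing
  and is asserted strictly.
* **Overfitted geometry.** A system calibrated to all 15 printed rows
  tracks them extremely closely but can acquire mild local
  non-monotonicities (~0.01 risk units) in unconstrained mid-sweep
  regions; monotonicity properties are therefore properties of the
  default layout, not of every fitted one.
* **Problem sizes.** The test suite evaluates the engine on a 200×200
  input grid, 10,000 random pairs for boundedness, 100 random pairs
  against an independent brute-force oracle (agreement within $10^{-6}$),
  and runs three full calibrations; this keeps the whole suite around a
  minute on one core while exercising every code path at the sizes the
  published analysis used (101-point sweeps, 1001-point output grid).

## Limitations

* Two inputs only; generalizing to *n* biomarkers, saliva-based variants
  and clinical validation are future work of the underlying study, not of
  this package.
* The recovered knot geometry is evidence-limited: 15 printed rows
  constrain 12 parameters, so the fit is a faithful reproduction of the
  published mapping, not a unique reconstruction of the original figures.
* The risk score is a decision-support quantity on an ordinal 1–10 scale,
  not a calibrated probability of malignant transformation.
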