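---
title: "Methods: Ellman-assay reduction, 4PL dose-response, and FIC synergy scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Ellman-assay reduction, 4PL dose-response, and FIC synergy scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ellmanfic)
```

This vignette is the package's own account of the models and numerical
choices behind each stage of the screening analysis: what is assumed, what
is a documented interpretation, and what a green test does and does not
establish.

## 1. From kinetic traces to percent inhibition

The Ellman assay couples acetylthiocholine hydrolysis to a chromophore, so
the absorbance increase after enzyme addition is proportional to residual
AChE activity. The assay design read here takes four pre-enzyme reads (0,
3, 6, 9 min) and a single post-enzyme read a few minutes later. The
pre-enzyme reads exist to capture spontaneous, non-enzymatic signal
(substrate autohydrolysis plus any extract colour drift).

The reduction contract is a documented interpretation, since assay
protocols of this family state the inputs but not the formula:

1. `spontaneous_drift()` — least-squares slope of the pre-enzyme reads
   versus time. Diagnostic: maximum absolute residual; above the
   `drift_threshold` (default 0.01 AU) the well is flagged
   `drift_nonlinear`. At least two pre-reads are required.
2. `enzymatic_signal()` — post-enzyme absorbance minus the
   drift-extrapolated baseline, `A_post − (A_last_pre + slope·Δt)`. The
   post-read time comes from the file, never hard-coded, so a plate with a
   longer post-enzyme incubation reduces correctly.
3. `percent_inhibition()` — `100·(1 − ΔA_sample/ΔA_control)` against the
   mean of all negative-control (solvent-only) wells on the plate. No
   per-column control structure is assumed. A non-positive control signal
   is a plate-level failure and errors out.

Values outside [0, 100] are reported and flagged, never clipped: clipping
would bias the tails of the downstream logistic fit. Clamping, if wanted,
is a presentation choice for report tables only.

The assay metadata records a 450 nm read wavelength although classical
Ellman chemistry is usually read near 412 nm; the pipeline treats
wavelength purely as metadata.

## 2. The four-parameter logistic and its inversion

Dose-response curves use the ascending 4PL in inhibition form,

$$ r(d) = b + (t - b)\,\frac{d^{h}}{d^{h} + \mathrm{IC}_{50}^{h}}, $$

with `bottom` \(b\) at dose 0, midpoint exactly at
\(r(\mathrm{IC}_{50}) = (b+t)/2\), and Hill slope \(h > 0\). For screen
samples the asymptotes default to fixed \(b = 0\), \(t = 100\): published
single-agent IC ladders of this assay family are exactly consistent with a
0–100 logistic, and freeing four parameters on 6–8-dose screens costs
precision for nothing. Both asymptotes can be freed (`bottom = NA`,
`top = NA`), and descending viability (MTT) curves reuse the identical
machinery through a sign flag (`decreasing = TRUE`) rather than duplicated
formulas.

Numerical choices in `fit_4pl()`:

* The optimizer works on \(\log \mathrm{IC}_{50}\) and \(\log h\), which
  enforces positivity without constraints and makes the midpoint error
  approximately scale-free.
* 4PL least squares is initialization-sensitive, so fits are multi-start:
  \(\mathrm{IC}_{50}\) seeded at the geometric mean of the doses
  bracketing the half response, \(h \in \{0.5, 1, 2, 4\}\); the smallest
  residual sum of squares wins and ties go to the smallest starting slope.
* A stalled optimizer reports `converged = FALSE` instead of raising; the
  fit object still carries the best parameters found.
* Standard errors come from the Gauss–Newton covariance at the optimum
  (numerical Jacobian), with the midpoint SE mapped off the log scale by
  the delta method. Replicate-level spread should be reported as mean ± SD
  across replicate-wise fits when triplicate plates are available.

Inversion is closed-form:
\(\mathrm{IC}_x = \mathrm{IC}_{50}\,[(x-b)/(t-x)]^{1/h}\), strictly
increasing in \(x\) on \((b, t)\); `build_ladder()` tabulates IC10…IC90.
Conversely, two ladder cells pin the curve:
\(h = \ln 81 / \ln(\mathrm{IC}_{90}/\mathrm{IC}_{10})\) for the canonical
pair, and the midpoint follows by inversion (`fourpl_from_ladder()`). On
the bundled reference ladders this reconstruction reproduces the printed
berberine and coptisine midpoints within 1%; the palmatine row implies
5.19 versus a printed 5.21 — a rounding-level inconsistency in the
reference values, which is why ladder-consistency tests carry a 1%
tolerance.

Activity calls use the screening rule "inactive if below 80% inhibition at
the 1250 µg/mL ceiling"; exactly 80.0 is called active (boundary decision,
documented here).

## 3. Combination scoring: two FIC conventions

The fixed-partner design dilutes one agent 1:1 from a start dose while
each partner is held at its own IC30 (`build_design()`). Scoring offers
two deliberately distinct summations:

**Fixed-dose CI (`compute_ci()`, the reporting default).** At effect level
x,
$$ \mathrm{CI}(x) = \frac{\mathrm{IC}_x(\text{combo})}{\mathrm{IC}_x(\text{varied alone})}
   + \sum_j \frac{\mathrm{IC}_x(\text{combo})}{d_j}, $$
with \(d_j\) the partner's fixed (IC30) dose. The textbook FE definition
is ambiguous about the partner denominator when the partner is held fixed;
checking candidate conventions against the 81 published CI cells of the
reference three-alkaloid dataset shows this fixed-dose denominator is the
one that reproduces the published table (the iso-effective alternative
does not: see the 0.70 vs 1.02 contrast below), so it is adopted as the
default. It is a potency-shift index for the varied agent, not a Loewe
statistic: a sham "combination" of an agent with itself at the same dose
gives CI = 1 only in the degenerate no-partner case.

**Classical Loewe FIC (`compute_classical_fic()`).** The iso-effective sum
\(\sum_i d_i / D_i(x)\) over all agents, where \(D_i(x)\) is agent i's
single-agent dose at the level. This is the statistic with the Loewe
guarantees — sham combinations score exactly 1, and on synthetic
checkerboards it recovers the generator's interaction index — and it is
what simulation validation uses. For the reference IC50-level cell of the
berberine+coptisine design the two conventions give 0.70 (fixed-dose)
versus 1.02 (classical), which is why the distinction is kept explicit
rather than collapsed.

One published row (palmatine varied + coptisine fixed) cannot be
reproduced by any single summation convention tested (its IC10 cell
computes to ≥ 0.60 against a printed 0.44); it is excluded from golden
comparisons as a probable transcription inconsistency in the source
values, not silently corrected. Reproduction tests use a tolerance of one
unit in the last printed digit: two cells (e.g. a printed 68.5 versus a
computed 68.42) miss the half-unit band, consistent with the printed
inputs themselves being rounded.

Classification schemes are total on \((0, \infty)\) with explicit
boundaries. Schelz: CI ≤ 0.5 synergy, (0.5, 1] additive, (1, 4)
indifferent, ≥ 4 antagonism. The published Berenbaum wording overlaps at
1.0 ("≤ 1 synergy, = 1 additive, ≥ 1 antagonism"); here 1.0 is assigned
to "additive" and the open intervals to synergy/antagonism. The bold-cell
convention (`table3_bold`) calls synergy iff CI < 1. Keeping all three
first-class matters because the same measured CI of 0.91 is "additive"
under Schelz and "synergy" under the bold-cell rule — both readings occur
in practice.

Isobologram coordinates (`isobologram_points()`) normalize iso-effective
dose pairs to FE axes; points below the unit line are exactly the
classical-FIC < 1 region. The partnerless case degenerates to a single
axis and is flagged rather than erroring.

## 4. The synthetic generator: a stated world

The generator exists so the whole pipeline can be tested against known
ground truth. Its defaults are fixed once and documented here; they are
fixture choices, not measured facts.

* **Agents** are 0–100 logistics. The default reference agents are
  reconstructed from the bundled single-agent ladders (berberine
  IC50 ≈ 1.48 µg/mL, h ≈ 1.29; coptisine 1.27, 2.94; palmatine 5.21,
  1.99).
* **Combinations** follow interaction-indexed Loewe additivity:
  the effect E of doses \(d_i\) solves
  \(\sum_i d_i / D_i(E) = \tau\). Each term is strictly decreasing in E,
  so the root is unique; it is found by bisection to an absolute effect
  tolerance of 1e-9 (hard-capped iteration count via interval halving
  from (0, 100)). \(\tau = 1\) reproduces Loewe additivity exactly and a
  single agent reduces to its own curve; \(\tau < 1\) generates synergy.
  A dose pool too dilute for the numerical floor returns 0% flagged
  `below_detection`. All agents must share 0/100 asymptotes in this
  version. Note the *existence constraint*: a fixed partner contributing
  \(d_j/D_j(x) \ge \tau\) means no varied dose attains level x — low-level
  ICs of strongly synergistic fixed-IC30 designs genuinely do not exist
  in this model, and checkerboard validation therefore picks per-level
  partner doses below the iso-effect contour.
* **Plates.** Pre-enzyme reads follow a linear drift (default 0.0015
  AU/min from a 0.08 AU baseline); the post-enzyme read adds
  `control_increment · (100 − inhibition)/100` (default 0.25 AU over the
  3-min incubation). Noise mimics the instrument, applied to absorbance
  reads and not to derived inhibition: additive Gaussian read noise
  (`sd_abs`, default 0.003 AU) and multiplicative rate noise (`sd_rel`,
  default 0.06). The source screens report only replicate SDs (roughly
  5–12% relative); the defaults are chosen to land summary SDs in that
  band and are fixture choices. Negative absorbances after noise are
  clipped to 0 and the rule is echoed in the plate metadata. Seeds are
  explicit arguments, echoed into metadata; the generator never touches
  global RNG state un-restored (identical seed ⇒ byte-identical CSV).
* **Not emulated:** Michaelis–Menten rate saturation, per-timepoint
  post-enzyme kinetics (the design has a single post read), plate-edge
  effects, carry-over, or compound-specific optical interference beyond
  linear drift. A green round-trip test therefore establishes the
  *analysis* is self-consistent, not that the instrument model is
  complete. Bliss-independence and median-effect generators are out of
  scope in this version.

## 5. I/O and reporting conventions

* Kinetic plates are long-form CSV (one row per well × timepoint), UTF-8,
  period decimals — long form keeps the parser agnostic to future read
  schedules. Concentrations are µg/mL throughout (one published summary
  header says mg/mL while its values are µg/mL; the package standardizes
  on µg/mL). Pre-reads must be exactly {0, 3, 6, 9} min in this version.
* Writers are byte-deterministic (fixed formats, fixed column order), so
  identical inputs give identical checksums and result tables round-trip.
* Display rounding, reverse-engineered from the reference tables and
  applied only at presentation: selectivity ratios to 2 significant
  figures (round half to even), CIs to 3, IC50s echo input precision.
  Unrounded values are always retained.
* YAML run configuration merges under explicit overrides
  (override-wins), and the effective parameter set is echoed for logging.
  There is no shell entry point: the exported functions and
  `scripts/acceptance.R` are the interface.

## 6. Known limitations

* The 4PL standard errors are asymptotic; with 6–8 doses the 3·SE
  midpoint interval is approximate (calibration is checked by simulation
  at 2%-of-scale read noise, covering ≥ 95% of 200 seeded runs).
* The fixed-dose CI is design-specific; comparisons across different
  partner dose choices need the classical FIC.
* Group-difference significance testing (t-tests between curves) is
  deliberately out of scope — the report carries means and SDs only.
* No 5PL/asymmetric curves, no Bayesian fits, no outlier rejection beyond
  QC flags.
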