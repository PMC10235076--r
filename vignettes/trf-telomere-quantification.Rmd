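---
title: "Quantifying telomere length from TRF Southern blots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying telomere length from TRF Southern blots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telogel)
```

## The measurement model

A terminal restriction fragment (TRF) assay leaves telomeric repeat
arrays intact while digesting the rest of the genome, so a probed
Southern blot shows each sample as a smear whose migration-axis position
encodes the distribution of telomere fragment sizes. `telogel` converts
scanned membranes into telomere-length (TL) statistics in four stages,
each of which is an explicit, testable function.

**Lane extraction.** A lane is a manually drawn column interval of the
gel image (`lane_roi`); its profile is the lateral *sum* of pixel
intensities at each row (`extract_profile`). Summation rather than
averaging follows densitometry convention; every downstream TL statistic
is invariant to positive rescaling, so the choice is inconsequential and
is verified as such by tests. Coordinates are 0-based and half-open
throughout, with row 0 at the top (gel-well side) of the image. Color
images are rejected outright: phosphorimager data is single-channel, and
a silent channel choice could corrupt quantification.

**Size calibration.** DNA migration is approximately linear in
log2(size), but the high-molecular-weight region of a gel is compressed,
so one straight line cannot fit the full 2–48.5 kb range. The scale is
therefore fitted as two segments, `log2(L) = a + b·row`: one on the
ladder's high-MW bands (48.5, 20, 15 kb for the QuickLoad 1 kb Extend
ladder) and one on its low-MW bands (10, 8, 6, 5, 4, 3, 2.5, 2 kb).
Manually seeded ladder peak positions are refined to the intensity
argmax within ±10 pixels of the seed (ties resolved toward the seed,
then toward the smaller row, so refinement is deterministic). The row at
which the scale switches from the high to the low segment is chosen for
*continuity*: among the rows where the low segment predicts a size
between 8 and 10 kb, the one minimizing the absolute log2 gap between
the two segments. This both reproduces the observed behaviour of such
calibrations — the switch always falls in the 8–10 kb range — and makes
the choice reproducible. A continuity gap above 0.15 log2 units (≈11% in
size) triggers a warning but keeps the scale, since a large gap signals
a mis-seeded or distorted ladder that the operator should inspect.
Sample lanes are assigned to the laterally nearest ladder (left, middle
or right of the membrane), ties toward the left. Sizes outside the
fitted band range are extrapolated rather than refused; sub-2 kb rows
are discarded later anyway, and the valid range is carried on the scale
object so callers can flag extrapolation.

**Distribution statistics.** Per sample lane, in order:

1. *Background*: subtract the lane's minimal intensity from every row.
   This makes all TL statistics exactly invariant to constant offsets.
2. *Pixel to size*: map each row through the piecewise scale. Per-pixel
   intensities are carried over without bin-width (Jacobian)
   reweighting, mirroring per-pixel practice; a `jacobian = TRUE` switch
   exists for sensitivity analysis and is off by default.
3. *Probe-bias correction*: longer telomeric fragments carry
   proportionally more repeats and bind proportionally more probe, so
   raw intensity overweights long fragments. Dividing each intensity by
   its fragment size, `wᵢ = Iᵢ/Lᵢ`, converts signal into relative
   fragment number. This I/L convention is the canonical TRF
   correction; the mean below is its fixed point.
4. *Truncation*: rows below 2 kb are discarded (genomic background,
   interstitial telomeric repeats, and the blow-up of 1/L). The
   boundary is kept: `size ≥ 2 kb` survives. A lane with no signal
   above the cutoff raises an error rather than returning a silent
   zero.
5. *Summary*: `mean = Σ Iᵢ / Σ (Iᵢ/Lᵢ)`, identically the w-weighted
   mean of size; med/Q1/Q3 are weighted quantiles of the normalized
   distribution under the **step convention** — the smallest size whose
   cumulative normalized weight reaches the probability — and
   IQ = Q3 − Q1. The step convention involves no interpolation, so
   results are exact and reproducible on the discrete pixel grid;
   whether an interpolating convention was ever intended in this
   assay's practice is not documented, so the deterministic choice is
   ours and is stated here.

**Cohort statistics.** The TL-size relationship is examined with three
nested-or-competing shapes — `ln(TL) ~ diameter`,
`ln(TL) ~ diameter + diameter²`, `ln(TL) ~ ln(diameter)` — and the
lowest-AIC fit is selected (ties to fewer parameters; fits on different
data subsets are refused as incomparable). The natural logarithm is
used for the response; AIC ranking is provably invariant to the
logarithm base, which the tests check. AIC carries the full Gaussian
log-likelihood constant so values are comparable with standard
statistical software. Commonality analysis decomposes the full model's
R² into one coefficient per non-empty subset of predictor blocks.
Rather than hard-coding inclusion–exclusion formulas, the coefficients
are obtained by solving the linear system
`R²(M) = Σ_{S ∩ M ≠ ∅} C(S)` over all non-empty models M — a
(2^p − 1)-square system with a unique solution — which makes
correctness checkable by construction for any number of blocks: the
coefficients must sum to the full-model R² and the unique coefficient
of X must equal `R²(full) − R²(full − X)`, identities the test suite
enforces at 1e-10. Categorical blocks enter subsets atomically (an
island factor's dummies are never split), percentages are relative to
the *non-adjusted* multiple R², and negative coefficients are reported
as-is — they indicate suppression, not error. Correlation matrices use
Spearman (rank) or Pearson coefficients with Benjamini–Hochberg
adjustment of the upper-triangle p-values; a constant column yields a
missing coefficient, never a zero.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `window` (peak refinement) | 10 | pixels | manual seeds are imprecise by a few pixels; ±10 recovers the local maximum without jumping to a neighbouring band |
| `min_kb` (truncation) | 2.0 | kb | below ~2 kb the signal is dominated by genomic and interstitial-repeat noise and the 1/L weight diverges |
| switch window | 8–10 | kb | the region where high- and low-MW calibrations meet on these ladders |
| `continuity_tol` | 0.15 | log2 units | ≈11% size discontinuity; larger gaps indicate ladder problems worth a warning |
| `strip_threshold` | 0.1 | ratio | residual after/before-stripping signal above 10% risks probe carry-over between host and symbiont hybridizations |
| `low_signal_fraction` | 0.02 | fraction of mean ladder lane total | explicit, configurable proxy for the human "no/poor signal" exclusion |

All thresholds are logged by the command-line front end at the start of
each run, so exclusions remain auditable.

## What the simulators emulate — and what they do not

The generators exist so that every stage can be tested against known
truth. The migration model `row(L) = r0 + s·u + κ·u²`,
`u = log2(Lmax) − log2(L)`, is exactly log2-linear at κ = 0 and
compresses the high-MW region at κ > 0, which is precisely the situation
the two-segment calibration approximates (a test confirms that one
segment fits curved ladders strictly worse than two). Defaults — r0 = 40,
s = 160 rows per log2-kb, 0.5–60 kb — correspond to a ~1200-pixel lane, a
typical 200 µm phosphorimager scan. Smears default to a lognormal
fragment-length density (right-skewed, positive support, convenient
oracles), median 5 kb and σ = 0.3 on the log scale, matching the 3–10 kb
range typical of coral TRF smears; with probe bias on, rendered signal
density is `L·g(L)·|dL/drow|`, exactly the bias the I/L normalization
removes. Ground-truth summaries integrate the density truncated at 2 kb
(piecewise adaptive quadrature anchored at the distribution's quantiles,
so arbitrarily narrow smears are never stepped over), making recovery
comparisons like-for-like. Cohorts draw
`ln(TL) = intercept + island + community + β·diameter + ε` with island
and community effects sampled per level; the reported truth is computed
from the *realized* design (projection of the noiseless predictor onto
each predictor subset, with the designed residual variance in the
denominator), not merely the generative SDs, so recovery tests are not
confounded by island-sampling variability.

Not emulated: smile/geometric gel distortion, flat-field variation,
bubbles, partial digestion, lane bleed-through, and spatially correlated
membrane background. Passing tests therefore demonstrate correctness of
the *computational* procedure under clean-to-moderately-noisy
conditions, not robustness to every blot artifact — on real membranes
those failure modes are exactly what the observer-based QC exclusions
are for.

Two numerical properties of the procedure are worth stating explicitly,
since the simulators quantify them:

* **Background residual.** Subtracting the lane minimum removes a
  constant baseline exactly, but under white noise of standard
  deviation σ the lane minimum sits ≈3.3σ below the baseline (for a
  ~1000-row lane), leaving a positive residual on every row. Spread
  over the signal-free portion of the lane this inflates mean TL by
  roughly 0.3–0.4% per count of σ at the default geometry — a bias of
  the min-subtraction method itself, not of its implementation. The
  simulator's default profile noise (σ = 8 counts, baseline 200;
  peak-signal SNR ≈ 140) represents accepted-quality overnight
  exposures, where the residual costs ~2–3% on mean TL; lanes near the
  quality floor are the ones human observers discard.
* **Quantile quantization.** Step-convention quantiles resolve to one
  pixel, i.e. ~0.4% in size at the default resolution, and IQ = Q3 − Q1
  amplifies this relatively. The noiseless closure test therefore runs
  at s = 320 (a 100 µm scan) so that grid discretization sits below the
  0.5% tolerance being verified — standard grid-refinement practice.

## Degenerate inputs and tie-breaks

Deterministic behaviour on awkward inputs is part of the contract:
refinement ties go to the seed then the smaller row; equal-AIC ties go
to fewer parameters; equidistant ladder assignment goes left; a perfect
regression fit (RSS = 0) gets AIC = −∞ so it still ranks first rather
than producing NaN; a zero-variance response has R² defined as 0;
rank-deficient designs drop aliased columns with a warning; a lane with
no signal above 2 kb raises an error that the batch driver records in
`excluded.csv` — exclusion decisions are never silent.

## Problem sizes used in validation

The bundled checks run entirely on synthetic data at sizes chosen to
make sampling error negligible relative to the tolerances: 1,000 random
discrete distributions for the mean-formula identity (1e-12), 100 noisy
smear lanes for end-to-end recovery (median relative error well under
5%), 50 cohorts of 30 islands × 27 colonies at designed variance
fractions (island 50%, community 10%, residual 40%) for commonality
recovery within 8 percentage points, and 200 null cohorts for the 5%
type-I error of the model family. `scripts/acceptance.R` recomputes all
of these from a single `--seed`.

## Known limitations

* The I/L normalization is implemented as the standard probe-number
  correction; if a different published variant of the normalization is
  required, `normalize_by_size` is the single place to change it.
* Quantile conventions differ across software; the step convention here
  is deterministic but can differ from interpolating conventions by up
  to one pixel's worth of size.
* The commonality solver is exponential in the number of predictor
  blocks (capped at 10); this is inherent to all-subsets R²
  decomposition.
* Mixed-model (conditional/marginal R²) variance partitioning, sPLS and
  transcriptomic analyses are intentionally out of scope.
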