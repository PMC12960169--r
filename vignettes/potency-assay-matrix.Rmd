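---
title: "Quantifying MSC potency: CFSE proliferation, IC50 fitting and the quartile-scored matrix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying MSC potency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscpotency)
```

Mesenchymal stem/stromal cell (MSC) products vary between donors and
manufactured lots, and regulators require potency assays that demonstrate
consistent biological activity before clinical use. Direct functional
assays — suppressing activated T-cell proliferation in co-culture — are
hard to standardize because the responder cells themselves vary between
blood donors. The practical alternative is a *matrix* of surrogate
measurements, each validated against the function it stands in for:
%IDO1+ cells (T-cell suppression), secreted M-CSF (M2 macrophage
polarization), CD63 concentration (extracellular-vesicle abundance) and
CCL2 (monocyte chemoattraction). This package implements the full
quantitative chain: CFSE dye-dilution analysis, dose–response IC50
fitting, surrogate-vs-function correlation, and the quartile-scored
potency matrix — together with synthetic generators that emulate each
assay so the chain is verifiable end to end.

## CFSE dye dilution and the replication index

CFSE halves in intensity at each cell division, so a population that has
divided g times peaks at `gen0_center / 2^g`. `assign_generation()` puts
each event in the generation whose peak centre is nearest in log space;
the boundary between generations g and g+1 is the geometric midpoint
`gen0_center / 2^(g+1/2)`.

Two numerical choices matter here:

* **Boundary ties go to the more-divided generation.** Dye loss only
  lowers intensity, so an event sitting exactly between two peaks is
  more plausibly the divided one. Ties are detected with a 1e-9 relative
  tolerance in log2 units so that algebraically exact midpoints are not
  mis-assigned by floating-point rounding.
* **`max_generations` defaults to 8.** Beyond roughly eight divisions
  the peaks compress into the autofluorescence background on real
  cytometers; dimmer events collect in the last bin.

From a generation profile `counts[g]`, each observed cell in generation
g represents `1/2^g` of a seeded precursor. The statistics are:

* **Replication index (RI)** — fold-expansion of the precursors that
  responded: `sum(counts[g>=1]) / sum(counts[g>=1]/2^g)`. The
  originating assay references its RI formula to source data that is not
  part of the text, so this package adopts the standard dye-dilution
  definition and says so prominently; it is consistent with the axis
  ranges of the published curves. When no cell has divided the ratio is
  undefined and RI is fixed at 1 (no expansion), keeping dose–response
  curves total on their domain.
* **Division index** — mean divisions over *all* precursors.
* **Percent divided** — share of cells beyond generation 0.

All three are ratios of counts, hence invariant to the number of events
collected. `normalize_to_control()` divides a condition's RI by the
stimulated no-MSC control (assumed to be the normalization used for
published "normalized replication index" axes; a min–max rescaling was
the other reading and is not implemented), and
`replication_index_ratio()` exposes the same quotient for subset
comparisons such as FoxP3+ vs FoxP3− CD4 T cells.

For real data without truth labels, `estimate_gen0_center()` takes the
brightest (rightmost) kernel-density peak on log10 intensity with at
least 5% relative prominence — the undivided population is the brightest
peak even when it is no longer the most abundant. It is an explicit
argument everywhere, so a hand-gated value can always override it.

## Inhibition curves and IC50

`fit_inhibition_curve()` fits the four-parameter logistic

$$y = bottom + \frac{top - bottom}{1 + (dose/IC_{50})^{h}}$$

by least squares on log10(dose), the standard model for such assays
(the originating analysis names only "a nonlinear fit model"). The hill
slope is constrained positive; inhibition curves decrease with dose.
Optimization is Levenberg–Marquardt (via minpack.lm) from five
data-driven starts — top = max response, bottom = min response, IC50 at
the dose nearest mid-response or at the geometric-mean dose, hill in
{0.5, 1, 2} — taking the lowest residual sum of squares, ties to the
first start. Flat responses (SD below `flat_tol`, default 1e-3 on the
normalized scale) are rejected as unidentifiable rather than fitted.

Two IC50s are reported because they answer different questions.
`ic50_relative` is the dose at the curve's own midpoint
`(top+bottom)/2`. "Inhibited proliferation by 50%" on a
control-normalized scale is instead the *absolute* crossing of response
0.5, computed in closed form by `ic50_from_fit()`:

$$IC_{50}^{abs} = IC_{50}^{rel}\left(\frac{top - 0.5}{0.5 - bottom}\right)^{1/h}.$$

When the fitted curve never reaches 0.5 (e.g. `bottom > 0.5`) the
absolute IC50 is `NA` with a reason attribute — an incomplete curve is a
diagnostic, not an error. No confidence intervals are computed in this
version; the residual sum of squares is reported for diagnostics.
`fold_difference()` compares two donors' IC50s as a plain potency ratio.

## Surrogate validation

`pearson_with_t_test()` reports the product-moment r with significance
from `t = r * sqrt(n-2) / sqrt(1-r^2)` on n−2 degrees of freedom,
two-tailed — the convention used for published surrogate-vs-function
panels. Perfect correlations are reported with p = 0; incomplete pairs
are dropped listwise with a warning; p-values carry full floating
precision and no multiple-testing correction is applied (the validation
design tests a handful of pre-specified pairs, not a screen).
`calibration_fit()` is ordinary least squares of one platform on
another (e.g. CD63 ELISA against nanoparticle tracking counts) with
Pearson r as the agreement summary; Deming regression is out of scope.

## The potency matrix

For each factor across the donor panel, `factor_stats()` computes the
mean, sample SD (n−1), CV as a percent, and the three quartile
breakpoints. The quartile convention is linear interpolation between
order statistics with the p-quantile at position `1 + (n-1)p`
(`stats::quantile` type 7) — the most common spreadsheet and statistics
default; for well-separated panel values quartile membership does not
depend on the choice, and `quartile_type` makes the inclusive/exclusive
variants available for edge cases in small panels.

`assign_points()` awards 0–3 points: 0 below q1, 1 in [q1, q2), 2 in
[q2, q3), 3 at or above q3. Bins are half-open with breakpoint-equal
values promoted upward, which guarantees the panel maximum always scores
3 and the minimum 0 — the behaviour the scoring narrative implies
("lowest quartile → 0 points"). On a tie-free panel of n divisible by 4
this puts exactly n/4 donors in each bin.

`score_panel()` totals the points with per-factor weights.
`potency_weights()` ships three presets: `"unit"` (the unweighted
matrix), `"methods"` (IDO1 ×2, CD63 ×2, CCL2 ×0.5, M-CSF ×1 — the
default weighted preset) and `"results"` (M-CSF also ×2). Two presets
exist because descriptions of the weighting differ on whether M-CSF is
doubled; the package defaults to the variant stated in the procedural
description and leaves the choice explicit. Donors missing a factor
value are excluded from that factor's quartiles and from totals, with a
warning — no imputation. No release pass/fail threshold is built in:
thresholds are product-specific and belong in user configuration.
`rank_donors()` orders by descending total with competition (minimum)
ranks for ties and a deterministic secondary order by donor id.

## What the synthetic generators emulate

The generators define the study conditions every verification runs
under:

* **Donor panels** (`simulate_donor_panel()`): one value per donor per
  factor, lognormal by default — assay concentrations are nonnegative
  and right-skewed — moment-matched so the true mean and CV equal the
  spec (log-variance `log(1+CV^2)`). The default CVs are the observed
  between-donor heterogeneities: IDO1 47.3%, CCL2 60.5%, M-CSF 25.8%,
  CD63 20.5%. Per-donor raw values are published only as figures, so the
  means are free parameters; the defaults (50% IDO1+, 1000 pg/mL M-CSF,
  25 ng/mL CD63, 2500 pg/mL CCL2) are plausible assay scales fixed once.
  Values are never clipped.
* **CFSE events** (`simulate_cfse_events()`): a categorical generation
  draw followed by a lognormal fluorescence around `gen0_center / 2^g`
  with spread 0.05 in log10 units (a cytometry-convention spread under
  which neighbouring peaks are cleanly separable). Truth labels ride
  along in `true_generation`, which every analysis function ignores.
* **Suppression series** (`simulate_suppression_series()`): the 4PL
  evaluated at the dose grid plus Gaussian noise (default SD 0.05 on
  the normalized scale, typical of triplicate-well assays).
* **Correlated pairs** (`simulate_correlated_pairs()`): a bivariate
  normal with exact target Pearson correlation in expectation; the
  marginals may emit negative values, acceptable because the generator
  targets correlation structure, not marginal realism.

What passing tests on this synthetic data do **not** show: real CFSE
histograms have autofluorescence tails, peak broadening with generation
and debris; real dose–response noise is heteroscedastic; real donor
panels can have correlated factors. The generators deliberately omit
these, so the verification demonstrates correctness of the computations
under the assumed statistical structure, not robustness to every
cytometry artifact.

## Problem sizes used in verification

The shipped tests verify: generation recovery and RI agreement on 10^4
events per condition (≥99% label recovery, RI within 2% of the
truth-label RI); IC50 recovery over 100 simulated series of 8 doses
spanning two decades at noise SD 0.05 (median relative IC50 within 10%
of truth, noiseless recovery within 0.1%); the closed-form absolute IC50
against a dense grid-search oracle on 50 random parameter sets (within
0.1%); correlation machinery against explicit-sum formulas to 1e-12,
null calibration over 10^4 replicates at n = 20 (type-I rate 0.05 ±
0.01) and power at the 10-donor, rho = −0.9 design scale; quartile
scoring against a rank-counting oracle on 1000 random 8-donor panels;
and CV fidelity of the generators at 10^5 draws (within 1% of each
target). These sizes were chosen so each check is statistically decisive
while the full suite stays fast.

## Known limitations

* Nearest-centre binning, not mixture-model deconvolution: events from
  heavily overlapping peaks (log10 spread ≫ 0.05) will be misassigned
  at the boundaries. The spread at which this matters is visible in the
  recovery tests.
* The replication-index definition is the field's standard one, adopted
  because the originating formula is not printed; a different in-house
  definition would shift absolute RI values but not control-normalized
  ratios computed consistently.
* No confidence intervals on IC50s or on ranks; no 5PL or Emax model
  comparison; no heteroscedastic weighting.
* FCS parsing, compensation and gating are out of scope — event tables
  of positive intensities are the ingestion boundary.
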