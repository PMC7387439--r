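---
title: "Single-cell stable isotope probing with nanosip: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell stable isotope probing with nanosip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosip)
library(dplyr)
```

## The measurement problem

Stable isotope probing (SIP) at the single-cell level asks whether an
individual microbial cell incorporated a ¹³C- or ¹⁵N-labeled substrate
during an incubation. NanoSIMS rasters a Cs⁺ beam over a field of sorted
cells and counts secondary ions (¹²C⁻, ¹³C⁻, ¹²C¹⁴N⁻, ¹²C¹⁵N⁻, ³²S⁻)
per pixel, scan after scan. `nanosip` models the whole chain from those
counts to community-level physiology. This vignette records the models,
the defaults and why they were chosen, and what the synthetic tests do
and do not demonstrate.

## From counts to atom fractions

**Alignment.** Consecutive scans drift by a few pixels. Scans are
registered to the first scan by maximizing integer-offset
cross-correlation of the cyanide (¹²C¹⁴N⁻) channel — the channel on
which cells are recognized — over a ±10 px window (configurable). Ties
are broken toward the smallest offset magnitude, then row-major order, so
the result is deterministic. Only integer shifts are modeled: the
simulated drift is integer-valued, and sub-pixel interpolation would
redistribute counts and bias the Poisson statistics. Accumulated images
are only used inside the `valid_mask` of pixels covered by every shifted
scan. A degenerate (all-zero) reference channel cannot be aligned;
identity shifts are returned with a `degenerate_reference` status rather
than an error, so the measurement can proceed flagged.

**Ratio of sums, not mean of ratios.** Per-ROI ratios are computed by
summing each species over the ROI pixels and all scans and dividing the
sums. Per-pixel ratios are undefined at zero denominators and biased at
the few-count level; summing first is standard ion-microprobe practice.
The estimator is exactly invariant to splitting an ROI and pooling the
parts' summed counts (tested). A ROI whose denominator sum (¹²C⁻ or
¹²C¹⁴N⁻) is zero is flagged `defined_* = FALSE` rather than silently
reported as zero; a zero *numerator* is a defined zero (R = 0, F = 0).
Atom fractions are `F = R/(1+R)` exactly, stored as fractions everywhere
in memory and converted to atom % only in files.

**Calibration.** Instrumental mass fractionation is corrected by an
ordinary least-squares line mapping instrument ratios of standards
(e.g. *E. coli* of graded enrichment) onto their bulk reference ratios;
applying the curve clips at zero. With no standards the identity
pass-through is used, with a warning. The ¹⁵N/¹⁴N ratio is taken as
numerically equal to the measured ¹²C¹⁵N⁻/¹²C¹⁴N⁻ molecular-ion ratio.
No dead-time or quasi-simultaneous-arrival correction is applied;
multiplicative detector bias is absorbed by the calibration, which is a
known limitation at very high count rates.

## Activity and rates

**Thresholds.** A cell is called active for an isotope when its atom
fraction *strictly* exceeds the 99.7 % bound of the membrane background —
mean + 3 sample SD of cell-free membrane measurements
(`background_threshold()`), or the fixed defaults of 1.24 atom % (¹³C)
and 0.446 atom % (¹⁵N). Ties are inactive: the conservative reading of
"exceeding" the background interval. Undefined measurements are inactive
for that isotope. A cell is active overall when active for either
isotope.

**Rates.** Three quantities, all in day⁻¹ or days:

- `µ_B = (ln X_t − ln X_0)/t` from the cell-count series. Negative
  values (biomass decline) are returned as-is — decline is meaningful.
- `T_d = ln 2/µ_B`, not determinable for `µ_B ≤ 0`.
- `µ_S = −ln(1 − (F_t − F_nat)/(F_label − F_nat))/t` per cell. This
  assumes all biomass carbon (nitrogen) derives from the labeled pool,
  so it is a *biomass generation* rate covering maintenance turnover as
  well as division, and a lower bound whenever unlabeled native
  substrates contribute. `F_t` below `F_nat` is clamped to µ_S = 0
  (measurement noise, not excretion); `F_t ≥ F_label` is saturated and
  flagged not determinable. Following the conservative convention, µ_S
  is only computed for ROIs active for that isotope.

**Natural abundances and labeling strength.** Defaults `F_nat` = 0.0111
(¹³C) and 0.00366 (¹⁵N), the standard natural abundances; both
configurable. For substrates diluted into an ambient pool (bicarbonate
into porewater DIC), `labeling_strength()` computes the
concentration-weighted mixture; e.g. 15 µM of 99 atom % label into
2400 µM DIC gives F_label ≈ 1.72 atom %, which is why autotrophic
signals are weak even when uptake occurs.

**Originally active fraction.** With `A = X_t/X_0` and the observed
active ROI fraction `f_t`, assuming inactive cells neither divide nor
lyse, the original inactive pool `X_0(1 − f_0)` equals the final
inactive pool `X_t(1 − f_t)`, giving `f_0 = 1 − A(1 − f_t)`. The
estimate is reported not determinable (with a reason code) when
`A(1 − f_t) > 1` (would imply f_0 < 0), when `f_t = 1` with `A > 1`
(no sampling depth on the inactive side), or when fewer than `min_rois`
ROIs back `f_t`. `min_rois` defaults to 10 — a stand-in for the
sampling-depth rule such studies apply but do not quantify; it is the
one determinability knob and is configurable everywhere it appears.

Error amplification matters here: `f_0` is linear in `f_t` with slope
`−A`, so the binomial sampling error of `f_t` is multiplied by the
biomass increase factor. With strong regrowth (A ~ 50) even hundreds of
ROIs leave `f_0` with a sampling SD of several tens of percentage
points; the estimate is unbiased but noisy. The package's recovery tests
therefore use modest regrowth (µ_B = 0.05 d⁻¹ over 21 days, A ≈ 2.5)
and 2000 sampled cells, where the SD is ~0.02 and a ±0.05 check is
meaningful. Published-scale incubations with A in the tens should read
`f_0` as an order-of-magnitude constraint, not a point estimate.

**Aggregates.** `summarize_incubations()` reports mean/min/max doubling
time, the mean of determinable `f_0`, and the nitrogen:carbon rate ratio
computed as a **ratio of grand means** (mean of all ᴺµ_S entries over
mean of all determinable ᶜµ_S entries). Averaging per-row ratios instead
is rejected: rows with near-zero carbon rates dominate and the statistic
explodes; the grand-mean ratio reproduces the published summary from the
bundled table. Entries marked not-measurable are excluded only from the
aggregates they cannot contribute to.

**Rounding-interval consistency.** `check_doubling_consistency()` checks
a published table's (µ_B, T_d) columns against `T_d = ln 2/µ_B`. Both
printed columns are independently rounded, so the function reports both
exact round-equality of the recomputed value and the weaker — and for
published tables more appropriate — criterion that the two rounding
intervals overlap (some unrounded µ_B exists agreeing with both printed
values). On the bundled 24-row table, 20 rows match exactly and all 24
are interval-consistent; the 4 non-exact rows are what one expects when
authors round µ_B and T_d from unrounded inputs independently.

## Geochemical budgets

Two back-of-envelope checks for anaerobic control incubations. The
pore-water O₂ inventory is `µM × cm³ × porosity` (in nmol); porosity
defaults to 0.73, typical of deep abyssal clay. Headspace partitioning
uses a dimensionless Henry solubility `H = C_aq/C_gas`, default 0.032
(O₂ near 25 °C); incubations at 10 °C have somewhat higher solubility,
so the equilibrated aqueous concentration is treated as a consistency
band (14–19 nM for the worked 16.4 nmol case), not an exact target. Mass
balance is exact by construction and tested to 10⁻¹². TOC-supportable
biomass is `TOC weight fraction × dry bulk density × 10¹⁵ / (fg C per
cell)`, with 10 fg C per cell, the conventional subseafloor quota.

## Contaminant filtering

Low-biomass 16S libraries are dominated by reagent taxa. The filter
compares each OTU's *relative* abundance (raw counts confound library
size) between negative controls and experiment samples with a classical
one-way ANOVA (two groups, so identical to a pooled two-sided t-test)
and removes OTUs that are significant at α = 0.05 *and* more abundant in
the controls. The directionality condition makes the realized type-I
rate roughly α/2 under the null — the price of testing a one-sided
hypothesis with a two-sided p-value, and the behavior the type-I test
asserts (observed rate ~0.024 at α = 0.05 over 100 null tables).

Filtering runs **sequentially**: first against the extraction blanks,
then — after removal and renormalization — against the PCR no-template
controls. Sequential and simultaneous filtering genuinely differ: the
test suite constructs a table where an OTU becomes control-enriched only
after a dominant contaminant is removed. The flip side, visible in the
pipeline demo, is compositional: removing a large contaminant inflates
every remaining control-side proportion, so the second pass can flag
borderline OTUs a simultaneous test would keep. Users who prefer
family-wise control can set `adjust = "BH"`; it is off by default
because per-OTU p < 0.05 is the procedure being modeled.

No multiple-testing correction, OTU clustering, taxonomy assignment, or
ordination fitting is performed here; `bray_curtis()` produces the
dissimilarity matrix (via `vegan::vegdist` on relative abundances) that
downstream NMDS consumes.

## The synthetic generator

`sim_image_stack()` draws, per pixel and scan, a Poisson total count
split binomially between heavy and light isotopologues — exactly
equivalent to independent Poisson draws with means `F·λ` and `(1−F)·λ`,
but making the binomial oracle for the ratio estimator exact. Cells are
ellipses over a membrane background at natural abundance; drift is a
fixed integer offset per scan. `sim_incubation()` runs the forward
growth/labeling model (the exact inverse of the rate estimators, so
noise-free round trips are identities); lognormal count noise is off by
default and enabled only in robustness checks. `sim_otu_table()` draws
negative-binomial counts with contaminants enriched `effect_size`-fold
in both control groups, mirroring a control design of 8 extraction
blanks and 6 NTCs.

What passing synthetic tests shows: the estimators are implemented
correctly, unbiased at the stated count depths, and invert their own
forward model. What they do not show: robustness to real NanoSIMS
artifacts — sub-pixel drift, beam damage, topographic and matrix
effects, QSA, ROI segmentation error, or cells lost during sorting. The
simulation also samples cells independently per timepoint, ignoring the
possibility that FACS sorting biases toward active cells.

## Numerical and scale choices

Default test and acceptance problem sizes are desk-scale by design:
64–132 px fields (full instrument fields are 256 px), ≤ 5 scans, 225
cells per simulated field at ≥ 10⁴ counts per ROI, 2000 sampled cells
for `f_0` recovery, and 100 seeded tables for the type-I check. At these
sizes the whole suite runs in well under a minute while every tolerance
is derived from the relevant sampling distribution (3–4 Poisson/binomial
standard errors; 5 % for rate means; ±0.05 for `f_0`). All random
streams derive from explicit seeds; identical seeds give bit-identical
outputs, and the pipeline splits deterministic sub-seeds per stage from
one master seed.

## Known limitations

- Integer-pixel alignment only; no sub-pixel registration.
- No dead-time/QSA correction; calibration absorbs multiplicative bias
  only.
- `f_0` assumes inactive cells are inert (no death, no lysis) and is
  highly sensitive to `f_t` error at large `A`.
- The sequential ANOVA filter inherits the compositional artifacts of
  relative-abundance testing; it models the published procedure, not the
  state of the art (e.g. mixture-model decontamination).
- The N:C rate ratio is a ratio of grand means over unequal ROI sets;
  it is reproducible but not a per-cell stoichiometry.
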