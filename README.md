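# nanosip

Single-cell stable isotope probing (SIP) analysis for NanoSIMS ion
imaging of microbial communities.

`nanosip` is aimed at geomicrobiologists and single-cell ecophysiologists
who incubate environmental samples — e.g. energy-starved subseafloor
sediment — with ¹³C- and ¹⁵N-labeled substrates and then image individual
cells with nanometer-scale secondary ion mass spectrometry (NanoSIMS).
The package turns raw multi-scan ion-count stacks into per-cell isotope
enrichment, classifies cells as anabolically active, converts enrichment
and cell counts into growth and biomass-generation rates, and infers what
fraction of the original community was active. It also covers two side
calculations such studies need: the oxygen/organic-carbon budget of
anaerobic control incubations, and negative-control-based removal of
contaminant OTUs from low-biomass 16S rRNA gene profiles.

## The model

For each imaged cell (ROI), isotope ratios are computed from counts
summed over the ROI and all aligned scans, and converted to atom
fractions:

    R13 = Σ¹³C⁻ / Σ¹²C⁻        F = R / (1 + R)
    R15 = Σ¹²C¹⁵N⁻ / Σ¹²C¹⁴N⁻

A cell is **active** when F exceeds the 99.7 % (mean + 3 SD) bound of the
membrane background (defaults 1.24 atom % for ¹³C, 0.446 atom % for
¹⁵N). Three rate quantities follow:

- biomass-based specific growth rate, from the cell-count time series:
  `µ_B = (ln X_t − ln X_0) / t`, with doubling time `T_d = ln 2 / µ_B`;
- substrate-incorporation-based biomass generation rate per cell, from
  the labeling kinetics `F_t = F_label − (F_label − F_nat)·e^(−µ_S t)`
  inverted as `µ_S = −ln(1 − (F_t − F_nat)/(F_label − F_nat)) / t`;
- originally active fraction, from the observed active ROI fraction
  `f_t` and the biomass increase factor `A = X_t / X_0`:
  `f_0 = 1 − A(1 − f_t)`, determinable when `f_t < 1` and
  `A(1 − f_t) ≤ 1`.

The labeling strength accounts for dilution of the added dose into the
ambient pool (e.g. ¹³C-bicarbonate into porewater DIC):
`F_label = (c_add·F_add + c_amb·F_amb)/(c_add + c_amb)`.

A synthetic-data module simulates every input with known ground truth:
Poisson ion counting (heavy/light split as binomial thinning), integer
scan drift, bimodal active/inactive enrichment, exponential regrowth of
the active subpopulation, and negative-binomial OTU tables with
blank-enriched contaminants.

## Worked example

The package bundles a growth-characteristics reference table (24
microaerobic incubations of ancient abyssal clay and nannofossil ooze: 4
sediment samples × 6 substrates, 21 days each). Aggregating it:

```r
library(nanosip)
summarize_incubations(table1_growth())$aggregates
#> # A tibble: 1 × 7
#>   n_incubations mean_T_d min_T_d max_T_d mean_f0  n_f0 ratio_N_to_C
#>           <int>    <dbl>   <dbl>   <dbl>   <dbl> <int>        <dbl>
#> 1            24     4.91     1.4    17.9   0.777    15         3.10
```

Doubling times average 4.9 days (range 1.4–17.9); the mean determinable
originally active fraction is 77.7 %; nitrogen substrates were
incorporated on average 3.1× faster than carbon substrates (ratio of
grand mean rates).

Single-cell arithmetic:

```r
substrate_rate(0.4896, F_nat = 0.011, F_label = 0.99, t = 21)
#> [1] 0.03195828       # /day: a cell at 48.96 atom % 13C after 21 days
doubling_time(0.284)
#> [1] 2.440659         # days
original_active_fraction(A = 10, f_t = 0.95, n_rois = 100)$f_0
#> [1] 0.5
```

And the full synthetic pipeline — simulate, image, align, measure,
classify, rate, decontaminate, budget — in one call:

```r
run_pipeline(pipeline_config(seed = 7))
#> <pipeline_report>
#>   recovered shifts: (0,0) (1,1) (2,2)
#> <incubation_result: synthetic / mixed, t = 21 d>
#>   mu_B = 0.190 /d, T_d = 3.7 d, f_t = 0.990, f_0 = 46.5% (100 ROIs)
#>   OTUs removed by decontamination: 11 (truth: 5)
#>   O2 inventory: 16.4 nmol; equilibrated: 14.9 nM; TOC biomass: 1.3e+10 cells/cm3
```

The report prints the exactly recovered scan drift, the growth summary of
the simulated incubation (with 100 sampled cells and strong regrowth the
`f_0` estimate is noisy — see the vignette on error amplification by
`A`), the sequential decontamination outcome, and the oxygen/TOC budget.

## Documentation

The methods vignette (`vignettes/single-cell-sip.Rmd`) describes the
model, its assumptions, the tunable constants, the synthetic generator's
scope, and known limitations. Every exported function carries roxygen
documentation with examples.
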