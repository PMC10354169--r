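---
title: "Methods: isotope-tracing computations and the synthetic experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope-tracing computations and the synthetic experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuetrace)
library(dplyr)
```

## Scope and model

`cuetrace` implements the computation chain of a dual-isotope soil
incubation: soils labelled with ¹⁸O-enriched water (target 20 at% in the
final soil water, at 60% of water holding capacity) to measure microbial
growth via DNA synthesis, and in parallel with 10 at% ¹³C-glucose to
trace substrate carbon into CO₂, extractable organic carbon (EOC),
microbial biomass carbon (MBC) and phospholipid fatty acids (PLFA). The
experimental template is a two-site (agricultural vs beech-forest soil),
two-temperature (11 °C vs 1 °C, i.e. field temperature vs just above
freezing) incubation with four field-plot replicates and two 42 h assay
windows: an immediate-response window starting at time zero and an
acclimation window at 144–186 h.

The pipeline makes four modelling commitments, each the standard one for
these assays:

* **Ideal-gas headspace accounting.** CO₂ mixing ratios (ppm) convert to
  carbon mass through `n_air = PV/(RT)`; respiration is the t₁ − t₀
  difference divided by window length and dry soil mass. The gas removed
  at t₀ and replaced with synthetic air of known CO₂ content is
  accounted for by scaling the t₀ mass by the un-sampled headspace
  fraction and adding back the replacement contribution. The headspace
  volume is the vial volume minus soil volume (dry mass over an assumed
  bulk density); observations may instead carry an explicit
  `headspace_volume`, which always wins.
* **¹⁸O mass balance in DNA.** All oxygen in newly synthesised DNA is
  assumed to derive from soil water, so the labelled-minus-control ¹⁸O
  excess of the extract, scaled by the soil-water enrichment and DNA's
  average oxygen content (31.21% by mass), gives DNA produced. Growth in
  C units multiplies the produced-to-total DNA ratio by MBC — the MBC of
  the matched site/plot/temperature/window/amendment fumigation pair.
* **Two-pool mixing for ¹³C.** Every pool is a mixture of
  natural-abundance C and tracer C at the tracer's enrichment, so the
  tracer-derived fraction is the enrichment excess over the background
  divided by the tracer-background span. Backgrounds default to the
  paired water-only control vial of the same site, plot, temperature and
  window rather than a fixed −27 ‰, because the design carries such
  controls throughout.
* **k_EC on bulk MBC only.** MBC divides the fumigation flush by
  k_EC = 0.45; tracer incorporation into biomass is the uncorrected
  difference of tracer C between fumigated and unfumigated extracts,
  matching the literal method convention. A `kec_correct` switch applies
  the same factor to the tracer difference for labs that prefer a fully
  corrected quantity.

CUE is computed per replicate as `growth / (growth + respiration)` and
averaged afterwards; a ratio of group means cannot carry a standard
error, and per-replicate averaging is what makes the reported
`mean ± SE` form meaningful. Response ratios `RR = R₁₁/R₁` pair the two
temperatures within each field plot (each plot was split between the two
incubators, so the plot is the pairing unit) and are summarised across
plots.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `r13_vpdb` | 0.0111802 | – | VPDB ¹³C/¹²C ratio for δ conversions |
| `pressure_atm` | 1 | atm | sealed vials equilibrated at ambient pressure |
| `bulk_density` | 1.3 | g cm⁻³ | soil volume correction inside vials (≤ 2% for 0.4 g in 27 mL) |
| `kec` | 0.45 | – | fumigation extraction efficiency |
| `o_frac_dna` | 0.3121 | – | average oxygen mass fraction of DNA |
| tracer enrichment | 10 | at% ¹³C | glucose label |
| soil-water target | 20 | at% ¹⁸O | water label |
| glucose dose | 10 / 50 | µg C g⁻¹ | ~20% of each site's MBC |

All constants are overridable per call or via a flat key–value config
file (`read_constants()`). ¹⁸O is handled in atom percent throughout
(TC/EA output is at%); only ¹³C has a δ pathway, since gas and extract
IRMS reports δ ‰ vs VPDB.

## What the simulator emulates — and what it does not

`simulate_experiment()` is the exact forward image of the pipeline's
inverse: CO₂ trajectories are generated by inverse ideal-gas arithmetic
including the sampling/replacement event; DNA enrichment follows
`at% = at%_soilwater · DNA_new/DNA_total + background`; fumigation pairs
are the EOC baseline (plus residual unconsumed glucose) and the
k_EC-scaled biomass flush, with ¹³C placed per the tracer fate
fractions; PLFA marker amounts follow per-site abundance simplices with
the tracer distributed to hit the group-allocation and
unsaturated-share targets exactly. Consequently a zero-noise run is
inverted to machine precision — the test suite asserts ≤ 10⁻⁶ relative
error on every rate, CUE, fate fraction and allocation fraction, which
validates the algebra of both the generator and the pipeline.

Default truth values are the published two-site summary of this design:
pools and rates at 11 °C/42 h (e.g. agricultural respiration
119.9 ng C h⁻¹ g⁻¹, forest 975.2; MBC 45.15 vs 294.3 µg C g⁻¹), and
per-window response ratios inside the published ranges (respiration
3.30/3.28 at 42 h, falling at 186 h; growth RRs 2.7–5.9). Acclimation is
a multiplier on the 11 °C rates in the second window (respiration × 0.8
at both sites, biomass tracer incorporation × 1.3 in the agricultural
soil), chosen to reproduce the direction of the published 42 h → 186 h
changes. The CUE response ratios are deliberately *not* parameters: they
emerge from the respiration and growth RRs, and land on the published
values (0.89–1.18 at 42 h), which is a useful internal-consistency check
of the truth table.

Noise is multiplicative lognormal with mean exactly one
(`meanlog = −σ²/2`) for concentrations, amounts and areas — CV 3% for
gas, 5% for extracts, DNA amounts and marker areas — and additive
Gaussian with SD 0.02 at% for isotope values on the at% scale.
Plot-level biological variability defaults to zero: the published study
reports no replicate-level CVs, and keeping only instrument noise makes
recovery experiments attributable to stated measurement error. What the
generator therefore does **not** emulate: between-plot heterogeneity,
instrument drift and calibration offsets, priming of unlabelled
respiration by the glucose addition, temperature-dependent solubility of
CO₂ in soil water, or microbial community change within a window.
Passing recovery tests demonstrate that the computation chain is correct
and stable under measurement noise — not that field data will be as well
behaved.

## Numerical and design choices

* **Below-background excess** (labelled < control) is clipped to zero
  for downstream mass balance but flagged (`below_background`) and the
  raw value retained, so QC can surface it; negative respiration rates
  and negative fumigation flushes are flagged, not clipped.
* **Undefined quantities** (CUE at zero rates, RR over a zero
  denominator, allocation with no labelled marker) propagate as `NA`
  with flags, never as zeros.
* **Rounding of headline ratios** is half-away-from-zero at one decimal
  (975.2/119.9 → 8.1, 101.1/23.11 → 4.4); base R's half-to-even would
  disagree on exact halves.
* **Saturation classing** of PLFA markers parses the double-bond count
  from the `C:D` name: any `:n` with n ≥ 1 is unsaturated; cyclopropane
  rings and methyl branches are not C=C bonds, so `cy17:0`, `10Me16:0`
  etc. are saturated. The printed Gram-positive and bacterial marker
  lists overlap in two markers (`16:1w7`, `cy17:0`); for a disjoint
  allocation partition the package folds both lists into one bacterial
  group, with fungal `18:1w9c`/`18:2w6,9` and the remaining markers as
  general. The membership table is an editable CSV shipped with the
  package, not code.
* **Seed discipline**: one master seed; independent child seeds per
  table are drawn from it, so individual tables can be regenerated
  reproducibly.
* The command-line surface (`simulate`, `process`, `summarize`,
  `ratios`) is a thin Rscript over exported functions
  (`inst/scripts/cuetrace-cli.R`); the functions are the primary
  interface.

## Problem sizes

The test suite runs the full chain at 2–4 plots per site (64–128 vials,
seconds); the noise-recovery study uses 100 plots per site (3 200 vials,
~20 s), at which the pooled pipeline means sit within 2% of the true
respiration and growth and within 0.02 of true CUE. The acceptance
script simulates 100 plots per site.

## Known limitations

* **Ratio statistics at low signal.** At the default 3% gas CV, the
  agricultural soil's 1 °C respiration (~36 ng C h⁻¹ g⁻¹ in a 27 mL vial
  over 42 h, a ~36 ppm rise) is close to the CO₂ measurement noise
  floor. The per-plot ratio R₁₁/R₁ is then heavy-tailed and its mean is
  unstable (occasionally even negative when a plot's 1 °C estimate
  crosses zero). This is a real property of ratio estimators, not a
  pipeline defect; for such cells, report the rates themselves or use
  more accumulation time. The published per-plot SEs imply the actual
  instrument precision was better than this generic default.
* The published per-replicate values are not available, so only the
  formulas and the printed summary ratios — not replicate-exact means —
  can be reproduced; the published CUE of 0.420/0.364 differs from the
  ratio of printed mean rates (0.423/0.369) precisely because CUE was
  averaged per replicate.
* The printed growth site contrast (6.4×) is not derivable from the
  printed means (569.9/87.98 = 6.5); the package reports 6.5 and treats
  the discrepancy as a known rounding artefact of the source summary.
  Similarly the printed "19%" glucose/MBC figure for the agricultural
  soil is inconsistent with the printed MBC (10/45.15 = 22.1%); only the
  forest 17% is reproduced.
* MBC truth is constant across temperature and window in the simulator;
  the real experiment saw modest MBC dynamics, which affect growth
  scaling only through the matched-MBC choice and are not modelled.
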