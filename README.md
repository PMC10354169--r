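# cuetrace

Dual-isotope tracing pipeline for soil microbial physiology: computes
microbial growth and carbon use efficiency from ¹⁸O-water incorporation
into DNA, respiration from headspace CO₂ accounting, ¹³C-glucose
partitioning into respired CO₂ / extractable organic C / microbial
biomass / PLFA biomarkers, and temperature response ratios for
soil-cooling incubation experiments. It is written for soil
biogeochemists running the ¹⁸O-qSIP / CUE assay together with a ¹³C
substrate-tracing assay, and turns the raw per-vial measurement tables
into the per-sample rates, group summaries, and headline ratios such
studies report.

## The computations

**Growth and CUE (¹⁸O).** DNA produced over the assay window is obtained
from the ¹⁸O mass balance of the DNA extract,

    DNA_produced = O_DNA · (at%_labelled − at%_natural) / at%_soilwater · 100 / 31.21

where `O_DNA` is the oxygen amount in the extract and 31.21% the average
oxygen content of DNA. Growth in carbon units is
`C_growth = DNA_produced / DNA_total · MBC / Δt`, and carbon use
efficiency is

    CUE = C_growth / (C_growth + C_respiration)

computed per replicate. Respiration comes from the two-timepoint
headspace CO₂ difference (ideal-gas conversion of ppm to µg C), with the
gas removed at the first sampling and replaced by synthetic air of known
CO₂ concentration accounted for explicitly.

**¹³C partitioning.** Microbial biomass C is the chloroform
fumigation–extraction flush divided by k_EC = 0.45. Tracer-derived
fractions of every pool follow two-pool mixing,
`f = (at%_pool − at%_background) / (at%_tracer − at%_background)`, with
backgrounds taken from the paired water-only control vials. Tracer
incorporation into biomass is the fumigated-minus-unfumigated difference
of tracer C (uncorrected by k_EC, per the standard method text); tracer
respiration applies the same mixing to the headspace CO₂ at both
timepoints.

**PLFA.** Markers are quantified against a 19:0 internal standard,
grouped into fungal / bacterial / general biomarkers (and saturated vs
unsaturated chains), and ¹³C allocation per group is the group's share of
the total tracer C in all markers.

**Cooling response.** `RR = R₁₁ / R₁` per matched field-plot replicate,
summarised as mean ± SE across plots.

A seeded forward simulator (`simulate_experiment()`) generates the raw
tables of a full two-site (agricultural vs forest), two-temperature
(11 °C vs 1 °C), two-window (0–42 h, 144–186 h) incubation with known
truth, so every stage is verifiable by parameter recovery.

## Worked example

```r
library(cuetrace)
library(dplyr)

exp0 <- simulate_experiment(seed = 42, n_plots = 4)   # default instrument noise
res  <- process_experiment(exp0)

res$summary |>
  filter(temperature_c == 11, window == "42h", amendment == "water",
         parameter %in% c("respiration", "growth", "cue", "mbc"))
#>   site         temperature_c window amendment parameter      mean      se     n
#> 1 agricultural            11 42h    water     cue           0.384  0.0407     4
#> 2 agricultural            11 42h    water     growth       81.4    9.60       4
#> 3 agricultural            11 42h    water     mbc          42.8    4.30       4
#> 4 agricultural            11 42h    water     respiration 131.    11.9        4
#> 5 forest                  11 42h    water     cue           0.369  0.0271     4
#> 6 forest                  11 42h    water     growth      583.    53.1       4
#> 7 forest                  11 42h    water     mbc         301.    20.7       4
#> 8 forest                  11 42h    water     respiration 992.    33.8       4
```

Rates are in ng C h⁻¹ g⁻¹ dry soil, MBC in µg C g⁻¹ dry soil, CUE is
dimensionless: with four plots and realistic noise the recovered means sit
on the generating values (agricultural respiration 119.9, growth 87.98;
forest 975.2 and 569.9). Cooling response ratios, per plot and summarised:

```r
summarize_rr(res$rr) |>
  filter(window == "42h", amendment == "water", site == "forest")
#>   site   window amendment parameter   mean_rr   se_rr     n
#> 1 forest 42h    water     cue           1.07   0.0712     4
#> 2 forest 42h    water     growth        3.95   0.402      4
#> 3 forest 42h    water     respiration   3.56   0.249      4
```

i.e. cooling the forest soil by 10 °C cut respiration ~3.6-fold and
growth ~4-fold while CUE barely moved. The headline site contrasts come
from the packaged published summary:

```r
site_ratio(fixture_table1(), "respiration")
#>   parameter   forest_mean agricultural_mean ratio
#> 1 respiration        975.              120.   8.1
```

Single-formula helpers are exported too, e.g.
`dna_produced(10, 0.50, 0.20, 20)` → `0.4806` µg DNA.

A thin command-line wrapper with `simulate` / `process` / `summarize` /
`ratios` subcommands ships in `inst/scripts/cuetrace-cli.R`.

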