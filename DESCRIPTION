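Package: cuetrace
Title: Isotope-Tracing Pipeline for Soil Microbial Growth, Carbon Use
    Efficiency and Carbon Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computation chain for dual-isotope soil incubation assays:
    18O-water incorporation into DNA for microbial growth and carbon use
    efficiency, headspace CO2 accounting (with gas sampling/replacement
    correction) for respiration, 13C-glucose partitioning into respired CO2,
    extractable organic carbon, microbial biomass (chloroform
    fumigation-extraction) and phospholipid fatty acids (PLFA), PLFA
    biomarker grouping and 13C allocation, and temperature response ratios
    for cooling experiments. Includes a seeded forward simulator of a
    two-site cooling incubation so every stage can be verified by parameter
    recovery, plus tidy summaries of the standard reported quantities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
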