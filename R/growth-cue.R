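#' DNA produced during an 18O-water labelling assay
#'
#' Newly synthesised DNA incorporates oxygen from soil water; with the soil
#' water enriched to a known 18O atom percent, the amount of DNA produced
#' over the assay window is
#' \deqn{DNA_{produced} = O_{DNA} \cdot
#'   \frac{at\%_{L} - at\%_{n.a.}}{at\%_{soil water}} \cdot \frac{100}{31.21}}
#' where \eqn{O_{DNA}} is the oxygen amount in the DNA extract, the
#' numerator is the 18O excess of the labelled over the paired
#' natural-abundance extract, and 31.21% is the average oxygen mass
#' fraction of DNA.
#'
#' Below-background excess (labelled < control) yields 0 with a
#' `below_background` attribute, matching [atom_percent_excess()].
#'
#' @param o_dna_extract Oxygen in the DNA extract, ug (same soil basis as
#'   the downstream DNA pool, typically per g dry soil).
#' @param at_percent_labeled,at_percent_natural 18O at% of DNA from the
#'   labelled vial and the paired natural-abundance vial.
#' @param at_percent_soil_water 18O at% of the final soil water (> 0).
#' @param o_frac_dna Oxygen mass fraction of DNA (default 0.3121).
#' @return DNA produced, ug, with `below_background` attribute.
#' @examples
#' dna_produced(10, 0.50, 0.20, 20)
#' @export
dna_produced <- function(o_dna_extract, at_percent_labeled,
                         at_percent_natural, at_percent_soil_water,
                         o_frac_dna = ct_constants()$o_frac_dna) {
  if (any(at_percent_soil_water <= 0)) {
    rlang::abort("Soil-water 18O enrichment must be > 0.",
                 class = "cuetrace_domain_error")
  }
  ape <- atom_percent_excess(at_percent_labeled, at_percent_natural)
  out <- o_dna_extract * as.numeric(ape) / at_percent_soil_water /
    o_frac_dna
  attr(out, "below_background") <- attr(ape, "below_background")
  out
}

#' Microbial growth rate from DNA production
#'
#' Scales DNA production to carbon units: the produced DNA divided by the
#' total DNA pool gives the fraction of the community newly grown, which
#' multiplied by microbial biomass C (MBC) gives new biomass C, expressed
#' as a rate per hour.
#'
#' @param dna_prod DNA produced over the window, ug (per g dry soil).
#' @param dna_total Total DNA pool, ug (same basis).
#' @param mbc Microbial biomass C, ug C g-1 dry soil.
#' @param duration_h Assay window length, h.
#' @return Growth rate, ng C h-1 g-1 dry soil.
#' @examples
#' growth_rate(0.4806, 20, 294.3, 42)
#' @export
growth_rate <- function(dna_prod, dna_total, mbc, duration_h) {
  if (any(dna_total <= 0)) {
    rlang::abort("dna_total must be > 0.", class = "cuetrace_domain_error")
  }
  if (any(duration_h <= 0)) {
    rlang::abort("duration_h must be > 0.", class = "cuetrace_domain_error")
  }
  as.numeric(dna_prod) / dna_total * mbc * 1000 / duration_h
}

#' Carbon use efficiency
#'
#' The fraction of processed C allocated to growth,
#' `CUE = growth / (growth + respiration)`, computed per replicate
#' (averaging across replicates is a summary-stage concern). When both
#' rates are zero the CUE is undefined and `NA` is returned.
#'
#' @param growth,respiration Rates in the same units (ng C h-1 g-1).
#' @return CUE, dimensionless in \[0, 1\]; `NA` where undefined.
#' @examples
#' cue(87.98, 119.9)
#' @export
cue <- function(growth, respiration) {
  if (any(growth < 0, na.rm = TRUE) || any(respiration < 0, na.rm = TRUE)) {
    rlang::abort("Rates entering cue() must be non-negative.",
                 class = "cuetrace_domain_error")
  }
  total <- growth + respiration
  ifelse(total > 0, growth / total, NA_real_)
}

#' Response ratio to cooling
#'
#' The factor by which a parameter is reduced by cooling:
#' `RR = R11 / R1`, the value at 11 degrees C over the value at 1 degree C,
#' computed per matched field-plot replicate (each plot was split between
#' the two incubators) and summarised downstream as mean +/- SE across
#' plots.
#'
#' @param r11 Parameter value at 11 degrees C.
#' @param r1 Parameter value at 1 degree C; zeros yield `NA` (undefined RR).
#' @return Response ratio, dimensionless; `NA` where undefined.
#' @examples
#' response_ratio(975.2, 297.3)
#' @export
response_ratio <- function(r11, r1) {
  ifelse(is.na(r1) | r1 == 0, NA_real_, r11 / r1)
}
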