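#' Convert delta notation to heavy-isotope atom fraction
#'
#' Standard IRMS conversion: a delta value (permil deviation of the sample
#' isotope ratio from an international standard) is turned into the atom
#' fraction of the heavy isotope,
#' \deqn{F = \frac{R_{std}(\delta/1000 + 1)}{1 + R_{std}(\delta/1000 + 1)}.}
#'
#' @param delta Numeric vector, permil vs the standard. Must be > -1000
#'   (the physical lower bound where the heavy isotope vanishes).
#' @param reference_ratio Isotope ratio of the standard (dimensionless);
#'   defaults to the VPDB 13C/12C ratio.
#' @return Atom fraction in (0, 1).
#' @seealso [atom_fraction_to_delta()] for the inverse.
#' @examples
#' delta_to_atom_fraction(0)            # VPDB itself, ~0.011057
#' delta_to_atom_fraction(-27) * 100    # typical soil C, at%
#' @export
delta_to_atom_fraction <- function(delta,
                                   reference_ratio = ct_constants()$r13_vpdb) {
  if (any(!is.finite(delta)) || any(delta <= -1000)) {
    rlang::abort("`delta` must be finite and > -1000 permil.",
                 class = "cuetrace_invalid_isotope_value")
  }
  r <- reference_ratio * (delta / 1000 + 1)
  r / (1 + r)
}

#' Convert heavy-isotope atom fraction to delta notation
#'
#' Inverse of [delta_to_atom_fraction()].
#'
#' @param frac Atom fraction in (0, 1).
#' @inheritParams delta_to_atom_fraction
#' @return Delta value in permil vs the standard.
#' @export
atom_fraction_to_delta <- function(frac,
                                   reference_ratio = ct_constants()$r13_vpdb) {
  if (any(frac <= 0) || any(frac >= 1)) {
    rlang::abort("`frac` must lie strictly within (0, 1).",
                 class = "cuetrace_invalid_isotope_value")
  }
  r <- frac / (1 - frac)
  (r / reference_ratio - 1) * 1000
}

#' @rdname delta_to_atom_fraction
#' @export
delta_to_atom_percent <- function(delta,
                                  reference_ratio = ct_constants()$r13_vpdb) {
  100 * delta_to_atom_fraction(delta, reference_ratio)
}

#' @rdname atom_fraction_to_delta
#' @param at_percent Atom percent in (0, 100).
#' @export
atom_percent_to_delta <- function(at_percent,
                                  reference_ratio = ct_constants()$r13_vpdb) {
  atom_fraction_to_delta(at_percent / 100, reference_ratio)
}

#' Atom percent excess above a natural-abundance control
#'
#' The labelled-minus-control difference that underlies every tracer
#' calculation. Differences below background are clipped to zero for
#' downstream mass balance; the clipping is reported through the
#' `below_background` attribute so QC can surface it, and the unclipped
#' difference is kept in the `raw` attribute.
#'
#' @param sample,control Atom percent values in \[0, 100\].
#' @param clip If `TRUE` (default) negative excess is returned as 0.
#' @return Numeric vector of excess at%, with logical attribute
#'   `below_background` and numeric attribute `raw`.
#' @examples
#' atom_percent_excess(0.70, 0.20)
#' attr(atom_percent_excess(0.19, 0.20), "below_background")
#' @export
atom_percent_excess <- function(sample, control, clip = TRUE) {
  if (any(sample < 0 | sample > 100) || any(control < 0 | control > 100)) {
    rlang::abort("Atom percent values must lie in [0, 100].",
                 class = "cuetrace_invalid_isotope_value")
  }
  raw <- sample - control
  out <- if (clip) pmax(raw, 0) else raw
  attr(out, "below_background") <- raw < 0
  attr(out, "raw") <- raw
  out
}

#' Gravimetric soil water content
#'
#' Water content on a dry-soil basis, `(fresh - dry) / dry`, the
#' convention used for water-holding-capacity arithmetic.
#'
#' @param fresh_mass,dry_mass Masses in g; `0 < dry_mass <= fresh_mass`.
#' @return Water content as g water per g dry soil.
#' @export
water_content <- function(fresh_mass, dry_mass) {
  if (any(dry_mass <= 0) || any(dry_mass > fresh_mass)) {
    rlang::abort("Require 0 < dry_mass <= fresh_mass.",
                 class = "cuetrace_domain_error")
  }
  (fresh_mass - dry_mass) / dry_mass
}

#' Water and isotope-label addition arithmetic
#'
#' Given a soil's current gravimetric water content and its water holding
#' capacity (WHC), compute how much water must be added to reach a target
#' fraction of WHC, and what 18O enrichment the added water stock must have
#' so that the final soil water reaches a target atom percent. The stock
#' enrichment solves the two-pool mixing balance: the final enrichment is
#' the mass-weighted mean of the existing soil water (at natural abundance)
#' and the added stock.
#'
#' @param current_water Current water content, g per g dry soil.
#' @param whc Water holding capacity, g per g dry soil.
#' @param target_whc_fraction Fraction of WHC to reach (default 0.6).
#' @param target_at_percent Desired final soil-water enrichment, at%.
#' @param natural_at_percent Natural-abundance enrichment of the existing
#'   soil water, at%.
#' @return A tibble with columns `water_to_add` (g per g dry soil) and
#'   `stock_at_percent` (at% the added water must have).
#' @examples
#' water_and_label_addition(0.12, 0.40, 0.6, 20, 0.2)
#' @export
water_and_label_addition <- function(current_water, whc,
                                     target_whc_fraction = 0.6,
                                     target_at_percent = 20,
                                     natural_at_percent = 0.2) {
  target_water <- target_whc_fraction * whc
  if (any(target_water <= current_water)) {
    rlang::abort(
      "Soil is already at or above the target water content; no addition possible.",
      class = "cuetrace_no_addition_possible"
    )
  }
  if (any(target_at_percent < natural_at_percent)) {
    rlang::abort("target_at_percent must be >= natural_at_percent.",
                 class = "cuetrace_invalid_isotope_value")
  }
  add <- target_water - current_water
  stock <- (target_at_percent * target_water -
              natural_at_percent * current_water) / add
  tibble::tibble(water_to_add = add, stock_at_percent = stock)
}
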