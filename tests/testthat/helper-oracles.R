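# Independent oracles used to freeze expected values: each re-derives the
# quantity from first principles, without calling the package functions.

# moles of air in a volume (mL) at T (deg C), P (atm); R in L atm / (mol K)
oracle_mol_air <- function(volume_ml, temp_c, pressure_atm = 1) {
  pressure_atm * (volume_ml / 1000) / (0.082057 * (temp_c + 273.15))
}

# ug C held as CO2 at a given mixing ratio
oracle_ppm_mass <- function(ppm, volume_ml, temp_c, pressure_atm = 1) {
  ppm * 1e-6 * oracle_mol_air(volume_ml, temp_c, pressure_atm) * 12.011e6
}

# DNA produced, direct evaluation of the published formula
oracle_dna_produced <- function(o, at_l, at_na, at_sw) {
  o * (at_l - at_na) / at_sw * 100 / 31.21
}

oracle_cue <- function(g, r) g / (g + r)

oracle_mbc <- function(fum, non, kec = 0.45) (fum - non) / kec

oracle_rr <- function(r11, r1) r11 / r1

# minimal headspace observation row builder for tests
make_obs <- function(ppm0, ppm1, hv = 27, sampled = 0, repl = 0,
                     temp = 11, dur = 42, fresh = 1, dmf = 1,
                     d13_t0 = NULL, d13_t1 = NULL) {
  obs <- tibble::tibble(
    co2_ppm_t0 = ppm0, co2_ppm_t1 = ppm1, headspace_volume = hv,
    sampled_volume = sampled, replacement_co2_ppm = repl,
    temperature_c = temp, duration_h = dur, soil_fresh_mass = fresh,
    dry_mass_fraction = dmf
  )
  if (!is.null(d13_t0)) obs$delta13c_t0 <- d13_t0
  if (!is.null(d13_t1)) obs$delta13c_t1 <- d13_t1
  obs
}
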