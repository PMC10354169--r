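test_that("delta/atom-fraction conversions match the closed form and invert", {
  # VPDB itself: F = R/(1+R) = 0.0111802/1.0111802
  expect_equal(delta_to_atom_fraction(0, 0.0111802), 0.0110566,
               tolerance = 1e-5)
  expect_equal(delta_to_atom_fraction(0, 0.0111802),
               0.0111802 / 1.0111802, tolerance = 1e-12)

  # mutual inverses over the physically relevant delta range
  deltas <- c(-900, -50, -27, 0, 500, 10000)
  back <- atom_fraction_to_delta(delta_to_atom_fraction(deltas))
  expect_equal(back, deltas, tolerance = 1e-12)

  at <- delta_to_atom_percent(c(-27, 0, 1500))
  expect_equal(atom_percent_to_delta(at), c(-27, 0, 1500),
               tolerance = 1e-12)

  expect_error(delta_to_atom_fraction(-1000),
               class = "cuetrace_invalid_isotope_value")
  expect_error(atom_fraction_to_delta(0),
               class = "cuetrace_invalid_isotope_value")
})

test_that("atom percent excess clips below-background values and flags them", {
  expect_equal(as.numeric(atom_percent_excess(0.70, 0.20)), 0.50)
  expect_equal(as.numeric(atom_percent_excess(0.20, 0.20)), 0)

  clipped <- atom_percent_excess(0.19, 0.20)
  expect_equal(as.numeric(clipped), 0)
  expect_true(attr(clipped, "below_background"))
  expect_equal(attr(clipped, "raw"), -0.01)

  vec <- atom_percent_excess(c(0.5, 0.1), c(0.2, 0.2))
  expect_equal(attr(vec, "below_background"), c(FALSE, TRUE))

  expect_error(atom_percent_excess(101, 0.2),
               class = "cuetrace_invalid_isotope_value")
})

test_that("ppm-to-mass conversion follows the ideal gas law", {
  # 400 ppm in a 27 mL headspace at 11 C
  expect_equal(ppm_to_mass_c(400, 27, 11), 5.57, tolerance = 0.01 / 5.57)
  expect_equal(ppm_to_mass_c(400, 27, 11), oracle_ppm_mass(400, 27, 11),
               tolerance = 1e-12)
  expect_equal(ppm_to_mass_c(0, 27, 11), 0)

  # linear in ppm and volume, strictly decreasing in temperature
  expect_equal(ppm_to_mass_c(800, 27, 11), 2 * ppm_to_mass_c(400, 27, 11))
  expect_equal(ppm_to_mass_c(400, 54, 11), 2 * ppm_to_mass_c(400, 27, 11))
  temps <- c(1, 11, 21, 37)
  masses <- ppm_to_mass_c(400, 27, temps)
  expect_true(all(diff(masses) < 0))

  expect_error(ppm_to_mass_c(400, -1, 11), class = "cuetrace_domain_error")
  expect_error(ppm_to_mass_c(400, 27, -300), class = "cuetrace_domain_error")
})

test_that("respiration rate accounts for the sampling/replacement event", {
  # steady state without sampling: zero rate
  expect_equal(respiration_rate(make_obs(400, 400))$respiration, 0)

  # accumulation example frozen from the ideal-gas oracle
  expected <- (oracle_ppm_mass(600, 27, 11) - oracle_ppm_mass(400, 27, 11)) *
    1000 / 42 / 1
  expect_equal(respiration_rate(make_obs(400, 600))$respiration, expected,
               tolerance = 1e-12)
  expect_equal(expected, 66.3, tolerance = 0.5 / 66.3)

  # CO2-free replacement: t1 concentration diluted exactly by the sampling
  obs <- make_obs(400, 400 * (1 - 5 / 27), sampled = 5, repl = 0)
  expect_equal(respiration_rate(obs)$respiration, 0, tolerance = 1e-12)

  # negative rates are flagged, not clipped
  neg <- respiration_rate(make_obs(600, 400))
  expect_lt(neg$respiration, 0)
  expect_true(neg$negative_rate)

  expect_error(respiration_rate(make_obs(NA, 400)),
               class = "cuetrace_incomplete_observation")
  expect_error(respiration_rate(make_obs(400, 600, sampled = 30)),
               class = "cuetrace_domain_error")
})

test_that("respiration rate is additive over sub-windows", {
  # a window split by an intermediate measurement without sampling gives
  # sub-rates whose duration-weighted mean is the full-window rate
  full <- respiration_rate(make_obs(400, 700, dur = 42))$respiration
  first <- respiration_rate(make_obs(400, 520, dur = 18))$respiration
  second <- respiration_rate(make_obs(520, 700, dur = 24))$respiration
  expect_equal((first * 18 + second * 24) / 42, full, tolerance = 1e-12)
})

test_that("water content and label-addition arithmetic are exact", {
  expect_equal(water_content(6.0, 5.0), 0.20)
  expect_equal(water_content(5.0, 5.0), 0)
  expect_equal(water_content(12.08, 10.0), 0.208)
  expect_error(water_content(5, 6), class = "cuetrace_domain_error")

  add <- water_and_label_addition(0.12, 0.40, 0.6, 20, 0.2)
  expect_equal(add$water_to_add, 0.12)
  expect_equal(add$stock_at_percent, (20 * 0.24 - 0.2 * 0.12) / 0.12,
               tolerance = 1e-12)
  expect_equal(add$stock_at_percent, 39.8, tolerance = 1e-12)

  # degenerate: no enrichment requested
  none <- water_and_label_addition(0.12, 0.40, 0.6, 0.2, 0.2)
  expect_equal(none$stock_at_percent, 0.2)

  expect_error(water_and_label_addition(0.24, 0.40, 0.6),
               class = "cuetrace_no_addition_possible")
})

test_that("label addition output closes the forward mixing balance", {
  set.seed(42)
  for (i in 1:20) {
    whc <- runif(1, 0.2, 0.9)
    cur <- runif(1, 0.05, 0.5) * whc
    frac <- runif(1, 0.55, 0.95)
    target_at <- runif(1, 5, 50)
    add <- water_and_label_addition(cur, whc, frac, target_at, 0.2)
    final <- (0.2 * cur + add$stock_at_percent * add$water_to_add) /
      (cur + add$water_to_add)
    expect_equal(final, target_at, tolerance = 1e-10)
  }
})

test_that("constants can be overridden and read from a flat config file", {
  expect_equal(ct_constants(kec = 0.38)$kec, 0.38)
  expect_error(ct_constants(nonsense = 1), class = "cuetrace_config_error")

  cfg <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# lab overrides", "bulk_density = 1.1", "kec = 0.40"), cfg)
  const <- read_constants(cfg)
  expect_equal(const$bulk_density, 1.1)
  expect_equal(const$kec, 0.40)
  expect_equal(const$r13_vpdb, 0.0111802)
})
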