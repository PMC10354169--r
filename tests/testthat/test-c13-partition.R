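test_that("fumigation-extraction MBC applies the efficiency factor", {
  expect_equal(as.numeric(mbc(30, 12)), 40)
  expect_equal(as.numeric(mbc(12, 12)), 0)
  expect_equal(as.numeric(mbc(30, 12, kec = 1)), 18)

  neg <- mbc(10, 12)
  expect_true(is.na(as.numeric(neg)))
  expect_true(attr(neg, "negative_flush"))

  expect_error(mbc(30, 12, kec = 0), class = "cuetrace_config_error")
})

test_that("label fraction is two-pool mixing, clipped to [0, 1]", {
  expect_equal(as.numeric(label_fraction(1.08, 1.08, 10)), 0)
  expect_equal(as.numeric(label_fraction(10, 1.08, 10)), 1)
  expect_equal(as.numeric(label_fraction(1.50, 1.08, 10)), 0.0471,
               tolerance = 1e-3)
  expect_equal(as.numeric(label_fraction(1.50, 1.08, 10)),
               (1.50 - 1.08) / (10 - 1.08), tolerance = 1e-12)

  lo <- label_fraction(1.00, 1.08, 10)
  expect_equal(as.numeric(lo), 0)
  expect_true(attr(lo, "below_background"))

  expect_error(label_fraction(1.5, 10, 10), class = "cuetrace_domain_error")

  # strictly increasing in pool enrichment
  ats <- seq(1.1, 9.9, length.out = 25)
  expect_true(all(diff(as.numeric(label_fraction(ats, 1.08, 10))) > 0))

  # a measurement reported in delta notation gives the same fraction once
  # converted, including when the background is delta-derived
  d_bg <- -27
  d_pool <- 250
  f_delta <- label_fraction(delta_to_atom_percent(d_pool),
                            delta_to_atom_percent(d_bg), 10)
  f_direct <- (delta_to_atom_percent(d_pool) - delta_to_atom_percent(d_bg)) /
    (10 - delta_to_atom_percent(d_bg))
  expect_equal(as.numeric(f_delta), f_direct, tolerance = 1e-12)
})

test_that("label mass in pools is linear bookkeeping", {
  expect_equal(label_in_pool(100, 0.0471), 4.71)
  expect_equal(label_in_pool(100, 0), 0)
  expect_equal(label_in_pool(2 * 100, 0.3), 2 * label_in_pool(100, 0.3))
  expect_error(label_in_pool(-1, 0.5), class = "cuetrace_domain_error")
})

test_that("label incorporation into biomass is the extract difference", {
  # enrichments chosen so the fumigated pool holds 5% and the
  # non-fumigated 1% tracer C: 30*0.05 - 12*0.01 = 1.38
  ctrl <- 1.08
  at_fum <- ctrl + 0.05 * (10 - ctrl)
  at_non <- ctrl + 0.01 * (10 - ctrl)
  expect_equal(label_in_mbc(30, 12, at_fum, at_non, ctrl), 1.38,
               tolerance = 1e-12)
  expect_equal(label_in_mbc(30, 12, at_fum, at_non, ctrl,
                            kec_correct = TRUE),
               1.38 / 0.45, tolerance = 1e-12)
  expect_equal(label_in_mbc(30, 12, at_non, at_non, ctrl),
               (30 - 12) * 0.01, tolerance = 1e-12)
  expect_error(label_in_mbc(30, 12, NA, at_non, ctrl),
               class = "cuetrace_incomplete_observation")
})

test_that("difference structure: shifting both pools only cancels at equal enrichment", {
  ctrl <- 1.08
  at_eq <- ctrl + 0.03 * (10 - ctrl)
  base <- label_in_mbc(30, 12, at_eq, at_eq, ctrl)
  shifted <- label_in_mbc(30 + 50, 12 + 50, at_eq, at_eq, ctrl)
  expect_equal(shifted, base, tolerance = 1e-12)
  expect_equal(as.numeric(mbc(30 + 50, 12 + 50)), as.numeric(mbc(30, 12)))
  # with unequal enrichments the shift does change the incorporation
  at_hi <- ctrl + 0.05 * (10 - ctrl)
  expect_false(isTRUE(all.equal(
    label_in_mbc(30 + 50, 12 + 50, at_hi, at_eq, ctrl),
    label_in_mbc(30, 12, at_hi, at_eq, ctrl))))
})

test_that("tracer respiration recovers a known rate and zeroes at background", {
  d_na <- -27
  at_na <- delta_to_atom_percent(d_na)

  flat <- make_obs(400, 600, hv = 43.6, temp = 11, fresh = 10, dmf = 0.81,
                   d13_t0 = d_na, d13_t1 = d_na)
  expect_equal(label_respiration(flat, at_na)$label_respiration, 0,
               tolerance = 1e-9)

  # forward-model a vial with known tracer respiration, then invert
  true_rate <- 23.1  # ng label-C h-1 g-1
  hv <- 43.6; dry <- 10 * 0.81
  m0 <- oracle_ppm_mass(420, hv, 11)
  m1 <- m0 + (119.9 + true_rate) * 42 * dry / 1000
  label1 <- true_rate * 42 * dry / 1000
  at1 <- at_na + label1 / m1 * (10 - at_na)
  obs <- make_obs(420, m1 / oracle_ppm_mass(1, hv, 11), hv = hv,
                  temp = 11, fresh = 10, dmf = 0.81,
                  d13_t0 = d_na, d13_t1 = atom_percent_to_delta(at1))
  est <- label_respiration(obs, at_na)$label_respiration
  expect_equal(est, true_rate, tolerance = 1e-9)

  expect_error(label_respiration(make_obs(400, 600), at_na),
               class = "cuetrace_incomplete_observation")
})

test_that("dose as a fraction of biomass reproduces the reported percentages", {
  expect_equal(dose_as_fraction_of_mbc(50, 294.3), 17.0,
               tolerance = 0.05 / 17)
  expect_equal(dose_as_fraction_of_mbc(294.3, 294.3), 100)
  expect_equal(dose_as_fraction_of_mbc(10, 45.15), 22.1,
               tolerance = 0.05 / 22.1)
  expect_error(dose_as_fraction_of_mbc(50, 0),
               class = "cuetrace_domain_error")
})

test_that("extract concentrations convert to a dry-soil basis", {
  # 15 mL of a 10 mg C/L extract from 2 g fresh soil at dmf 0.8:
  # 150 ug C / 1.6 g dry soil
  expect_equal(extract_to_soil_basis(10, 0.8), 150 / 1.6)
  expect_error(extract_to_soil_basis(10, 0), class = "cuetrace_domain_error")
})
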