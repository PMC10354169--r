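#' Default truth parameters for the synthetic cooling experiment
#'
#' Returns the generative parameters of the simulated two-site soil-cooling
#' incubation: a temperate agricultural and a temperate beech-forest soil,
#' incubated at 11 and 1 degrees C, assayed over two 42 h windows (the
#' immediate 0-42 h response and the 144-186 h acclimation window), with
#' four field-plot replicates, 18O-water labelling to 20 at% soil water,
#' and 10 at% 13C-glucose doses of 10 (agricultural) and 50 (forest)
#' ug C g-1 dry soil.
#'
#' Pool sizes and 11 degree rates are set to the published site-contrast
#' summary (see [fixture_table1()]); cooling response ratios per window are
#' set inside the published ranges; acclimation is a multiplier on the 11
#' degree rates for the second window. Noise defaults: multiplicative
#' lognormal with CV 3% for gas concentrations and 5% for extract C, DNA
#' amounts and chromatogram areas; additive Gaussian with SD 0.02 at% for
#' all isotope values.
#'
#' @return A `cuetrace_truth` list: `sites`, `rr`, `accl`, `alloc`,
#'   `abund`, `assay`, `isotopes`, `noise`, `n_plots`.
#' @seealso [simulate_experiment()], [truth_cells()]
#' @export
default_truth <- function() {
  truth <- list(
    sites = tibble::tibble(
      site            = c("agricultural", "forest"),
      soc_mg_g        = c(8.864, 45.641),
      mbc_ug_g        = c(45.15, 294.3),
      dna_total_ug_g  = c(10, 50),
      eoc_ug_g        = c(40, 200),
      plfa_total_nmol_g = c(145.3, 1975),
      respiration_11  = c(119.9, 975.2),   # ng C h-1 g-1, water vials, 42 h window
      growth_11       = c(87.98, 569.9),
      label_respiration_11 = c(23.11, 101.1),
      label_mbc_rate_11    = c(58.29, 229.4),
      label_plfa_rate_11   = c(7.14, 47.6),
      glucose_dose_ug_g = c(10, 50),
      whc_g_g         = c(0.385, 0.75),
      dry_mass_fraction = c(1 / 1.231, 1 / 1.45)  # soils wetted to 60% WHC
    ),
    rr = tibble::tibble(
      site   = rep(c("agricultural", "forest"), each = 2),
      window = rep(c("42h", "186h"), 2),
      rr_respiration       = c(3.30, 2.61, 3.28, 2.79),
      rr_growth            = c(2.74, 5.92, 4.26, 3.43),
      rr_label_respiration = c(1.41, 1.36, 1.20, 1.34),
      rr_label_mbc         = c(0.78, 0.97, 1.04, 0.98),
      rr_label_plfa        = c(1.51, 1.42, 1.60, 1.19)
    ),
    accl = tibble::tibble(
      site = c("agricultural", "forest"),
      m_respiration       = c(0.80, 0.80),
      m_growth            = c(1.00, 0.85),
      m_label_respiration = c(1.00, 1.00),
      m_label_mbc         = c(1.30, 1.00),
      m_label_plfa        = c(1.00, 0.80)
    ),
    alloc = tibble::tibble(
      site          = rep(c("agricultural", "forest"), each = 2),
      temperature_c = rep(c(11, 1), 2),
      bacterial = c(0.50, 0.48, 0.40, 0.48),
      fungal    = c(0.12, 0.16, 0.22, 0.20),
      general   = c(0.38, 0.36, 0.38, 0.32),
      unsaturated = c(0.45, 0.58, 0.45, 0.58)
    ),
    abund = tibble::tibble(
      site = c("agricultural", "forest"),
      fungal    = c(0.12, 0.28),
      bacterial = c(0.46, 0.40),
      general   = c(0.42, 0.32)
    ),
    assay = list(
      o18_vial_volume = 27, o18_soil_fresh = 0.4, o18_sampled_volume = 1,
      c13_vial_volume = 50, c13_soil_fresh = 10, c13_sampled_volume = 15,
      plfa_soil_fresh = c(agricultural = 2, forest = 1),
      ambient_co2_ppm = 420, replacement_co2_ppm = 420,
      is_amount_nmol = 5, is_area = 1e5,
      duration_h = 42
    ),
    isotopes = list(
      at_sw = 20, at_na_18o = 0.2, tracer_at = 10, delta13c_na = -27
    ),
    noise = list(cv_gas = 0.03, sd_at = 0.02, cv_extract = 0.05,
                 cv_area = 0.05),
    n_plots = 4
  )
  class(truth) <- c("cuetrace_truth", class(truth))
  validate_truth(truth)
  truth
}

#' A fully silent noise model (all instrument CVs zero)
#'
#' @return Noise list usable as the `noise` argument of
#'   [simulate_experiment()].
#' @export
no_noise <- function() {
  list(cv_gas = 0, sd_at = 0, cv_extract = 0, cv_area = 0)
}

#' Validate truth parameters
#'
#' Checks positivity of pools and rates, validity of the allocation
#' simplices (sum to 1, unsaturated target reachable given the fungal
#' share), and tracer mass conservation in every site x temperature x
#' window cell: respired label plus biomass-incorporated label (flush
#' corrected by k_EC) must not exceed the dose, and the label placed in
#' PLFAs must fit inside the biomass label.
#'
#' @param truth A `cuetrace_truth` list.
#' @param constants Constant set.
#' @return `truth`, invisibly; aborts on violation.
#' @export
validate_truth <- function(truth, constants = ct_constants()) {
  s <- truth$sites
  rate_cols <- c("mbc_ug_g", "dna_total_ug_g", "eoc_ug_g",
                 "plfa_total_nmol_g", "respiration_11", "growth_11",
                 "label_respiration_11", "label_mbc_rate_11",
                 "label_plfa_rate_11", "glucose_dose_ug_g")
  if (any(as.matrix(s[rate_cols]) <= 0)) {
    rlang::abort("All pools and rates must be positive.",
                 class = "cuetrace_config_error")
  }
  if (any(as.matrix(truth$rr[-(1:2)]) <= 0)) {
    rlang::abort("Response ratios must be positive.",
                 class = "cuetrace_config_error")
  }
  al <- truth$alloc
  if (any(abs(al$bacterial + al$fungal + al$general - 1) > 1e-9)) {
    rlang::abort("Allocation simplex must sum to 1.",
                 class = "cuetrace_config_error")
  }
  if (any(al$unsaturated < al$fungal) || any(al$unsaturated > 1)) {
    rlang::abort(
      "Unsaturated allocation must be >= the fungal share (fungal markers are all unsaturated) and <= 1.",
      class = "cuetrace_config_error"
    )
  }
  ab <- truth$abund
  if (any(abs(ab$fungal + ab$bacterial + ab$general - 1) > 1e-9)) {
    rlang::abort("Abundance simplex must sum to 1.",
                 class = "cuetrace_config_error")
  }
  cells <- truth_cells(truth)
  dur <- truth$assay$duration_h
  dose <- s$glucose_dose_ug_g[match(cells$site, s$site)]
  resp_ug <- cells$label_respiration * dur / 1000
  mbc_meas_ug <- cells$label_mbc_rate * dur / 1000
  plfa_ug <- cells$label_plfa_rate * dur / 1000
  if (any(resp_ug + mbc_meas_ug / constants$kec >= dose)) {
    rlang::abort("Tracer fate fractions exceed the dose in at least one cell.",
                 class = "cuetrace_config_error")
  }
  if (any(plfa_ug > mbc_meas_ug / constants$kec)) {
    rlang::abort("PLFA label cannot exceed the biomass label.",
                 class = "cuetrace_config_error")
  }
  invisible(truth)
}

#' Expand truth parameters to per-cell true rates
#'
#' One row per site x temperature x window with the true water-vial
#' respiration, growth, tracer respiration, tracer incorporation rate into
#' biomass, and tracer rate into PLFAs. The 11 degree rate in the
#' acclimation window is the 42 h rate times the acclimation multiplier;
#' the 1 degree rate is the 11 degree rate of the same window divided by
#' that window's response ratio.
#'
#' @param truth A `cuetrace_truth` list.
#' @return Tibble keyed by `site`, `temperature_c`, `window`.
#' @export
truth_cells <- function(truth) {
  params <- c("respiration", "growth", "label_respiration", "label_mbc",
              "label_plfa")
  grid <- tidyr::expand_grid(
    site = truth$sites$site,
    temperature_c = c(11, 1),
    window = c("42h", "186h")
  )
  si <- match(grid$site, truth$sites$site)
  ai <- match(grid$site, truth$accl$site)
  ri <- match(paste(grid$site, grid$window),
              paste(truth$rr$site, truth$rr$window))
  for (p in params) {
    base_col <- switch(p,
      respiration = "respiration_11", growth = "growth_11",
      label_respiration = "label_respiration_11",
      label_mbc = "label_mbc_rate_11", label_plfa = "label_plfa_rate_11")
    base <- truth$sites[[base_col]][si] *
      ifelse(grid$window == "186h", truth$accl[[paste0("m_", p)]][ai], 1)
    rr <- truth$rr[[paste0("rr_", p)]][ri]
    out_col <- if (p == "label_mbc") "label_mbc_rate" else
      if (p == "label_plfa") "label_plfa_rate" else p
    grid[[out_col]] <- ifelse(grid$temperature_c == 11, base, base / rr)
  }
  grid
}

#' Published two-site summary fixture
#'
#' The published site-contrast summary of the cooling incubation (means
#' +/- standard errors at 11 degrees C after the 0-42 h window) packaged
#' as a tidy fixture for ratio checks: soil organic C, microbial biomass
#' C, total PLFA, microbial respiration and growth, CUE, tracer-derived
#' respiration and tracer incorporation into biomass. Values are stored
#' exactly as printed in the source summary table (provenance:
#' `published_table`); they are reference data, not outputs of this
#' package.
#'
#' @return Tibble with `parameter`, `unit`, `site`, `mean`, `se`,
#'   `provenance`.
#' @export
fixture_table1 <- function() {
  pars <- c("soc", "mbc", "total_plfa", "respiration", "growth", "cue",
            "label_respiration", "label_mbc")
  units <- c("mg C g-1 dry soil", "ug C g-1 dry soil",
             "nmol C g-1 dry soil", "ng C h-1 g-1 dry soil",
             "ng C h-1 g-1 dry soil", "dimensionless",
             "ng C h-1 g-1 dry soil", "ng C h-1 g-1 dry soil")
  tibble::tibble(
    parameter = rep(pars, each = 2),
    unit = rep(units, each = 2),
    site = rep(c("agricultural", "forest"), times = length(pars)),
    mean = c(8.864, 45.641, 45.15, 294.3, 145.3, 1975, 119.9, 975.2,
             87.98, 569.9, 0.420, 0.364, 23.11, 101.1, 58.29, 229.4),
    se = c(0.213, 2.365, 3.894, 27.64, 44.77, 215.3, 2.482, 68.00,
           8.884, 86.7, 0.027, 0.026, 0.077, 111.6, 1.471, 33.38),
    provenance = "published_table"
  )
}
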