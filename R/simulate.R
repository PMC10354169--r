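# Lognormal multiplicative noise with mean exactly 1 at the given CV.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Additive Gaussian noise for isotope values (at% scale).
rnorm_sd <- function(n, sd) {
  if (sd <= 0) return(rep(0, n))
  stats::rnorm(n, 0, sd)
}

# Per-marker C weights for one site: group C share split equally within
# each primary group.
marker_weights <- function(truth, site, table = plfa_marker_table()) {
  ab <- truth$abund[truth$abund$site == site, ]
  share <- c(fungal = ab$fungal, bacterial = ab$bacterial,
             general = ab$general)
  n_g <- table(factor(table$primary_group,
                      levels = c("fungal", "bacterial", "general")))
  w <- share[table$primary_group] / as.numeric(n_g[table$primary_group])
  names(w) <- table$marker
  w
}

# Distribute a total tracer mass over markers so that the primary-group
# allocation and the overall unsaturated share are hit exactly. Fungal
# markers are all unsaturated; the remaining unsaturated label is spread
# over the bacterial and general groups with a common within-group
# unsaturated share, and within each (group, saturation class) the label
# follows the C weights.
marker_label_split <- function(total_label, alloc, weights,
                               table = plfa_marker_table()) {
  u <- alloc$unsaturated
  g <- c(fungal = alloc$fungal, bacterial = alloc$bacterial,
         general = alloc$general)
  s_nonfungal <- (u - g[["fungal"]]) / (1 - g[["fungal"]])
  if (s_nonfungal < 0 || s_nonfungal > 1) {
    rlang::abort("Unsaturated allocation target unreachable.",
                 class = "cuetrace_config_error")
  }
  label <- stats::setNames(numeric(nrow(table)), table$marker)
  for (grp in names(g)) {
    members <- table$primary_group == grp
    uns <- members & table$unsaturated
    sat <- members & !table$unsaturated
    grp_label <- total_label * g[[grp]]
    s <- if (!any(sat)) 1 else if (!any(uns)) 0 else s_nonfungal
    if (any(uns)) {
      w <- weights[table$marker[uns]]
      label[table$marker[uns]] <- grp_label * s * w / sum(w)
    }
    if (any(sat)) {
      w <- weights[table$marker[sat]]
      label[table$marker[sat]] <- grp_label * (1 - s) * w / sum(w)
    }
  }
  label
}

#' Simulate the full two-site cooling incubation
#'
#' Forward model of the dual-isotope assay design: for every site x plot x
#' temperature x window x amendment cell it generates the raw measurement
#' tables that the pipeline consumes, from known true rates
#' ([truth_cells()]), so that every computation stage is testable by
#' inversion.
#'
#' Generated per cell:
#' \itemize{
#'   \item an 18O-assay headspace CO2 record (27 mL vial, 0.4 g soil,
#'     sampling/replacement event at t0) whose concentration trajectory is
#'     the inverse ideal-gas image of the true respiration rate;
#'   \item a DNA isotope record whose 18O enrichment follows
#'     `at% = at%_soil_water * (DNA_new / DNA_total) + background`;
#'   \item a 13C-assay headspace record (50 mL vial, 10 g soil, 15 mL
#'     sampled) with delta13C trajectories from the tracer respiration;
#'   \item a fumigation pair built from the k_EC flush of MBC plus the EOC
#'     baseline, with 13C placed per the tracer fate fractions;
#'   \item a PLFA profile (areas against a 19:0 internal standard) with
#'     tracer placed per the group-allocation simplex.
#' }
#' Glucose-amended vials respire the tracer on top of the basal rate;
#' water-amended vials are the natural-abundance controls. Noise is
#' multiplicative lognormal (mean 1) for amounts/areas/concentrations and
#' additive Gaussian on the at% scale for isotope values. One master seed
#' deterministically derives independent child seeds per table.
#'
#' @param truth Truth parameters, see [default_truth()].
#' @param seed Integer master seed.
#' @param n_plots Number of field-plot replicates per site.
#' @param noise Noise model (`cv_gas`, `sd_at`, `cv_extract`, `cv_area`);
#'   defaults to `truth$noise`. Use [no_noise()] for a silent run.
#' @param constants Constant set.
#' @return A `cuetrace_experiment` list: tables `samples`, `headspace`,
#'   `dna`, `fumigation`, `plfa`, the per-vial `truth_vials`, and `truth`.
#' @examples
#' exp0 <- simulate_experiment(seed = 1, noise = no_noise())
#' names(exp0)
#' @export
simulate_experiment <- function(truth = default_truth(), seed = 1L,
                                n_plots = truth$n_plots,
                                noise = truth$noise,
                                constants = ct_constants()) {
  validate_truth(truth, constants)
  set.seed(as.integer(seed))
  child <- sample.int(.Machine$integer.max - 1L, 4L)

  cells <- truth_cells(truth)
  grid <- tidyr::expand_grid(
    site = truth$sites$site,
    plot = seq_len(n_plots),
    temperature_c = c(11, 1),
    window = c("42h", "186h"),
    amendment = c("water", "glucose")
  ) |>
    dplyr::left_join(cells, by = c("site", "temperature_c", "window")) |>
    dplyr::left_join(truth$sites, by = "site")

  dur <- truth$assay$duration_h
  iso <- truth$isotopes
  at_na13 <- delta_to_atom_percent(iso$delta13c_na, constants$r13_vpdb)

  # vial-level truths: glucose vials respire the tracer on top of basal C
  grid <- grid |>
    dplyr::mutate(
      glucose = .data$amendment == "glucose",
      resp_vial = .data$respiration +
        ifelse(.data$glucose, .data$label_respiration, 0),
      label_resp_vial = ifelse(.data$glucose, .data$label_respiration, 0),
      label_mbc_ug = ifelse(.data$glucose,
                            .data$label_mbc_rate * dur / 1000, 0),
      label_plfa_ug = ifelse(.data$glucose,
                             .data$label_plfa_rate * dur / 1000, 0),
      resp_label_ug = ifelse(.data$glucose,
                             .data$label_respiration * dur / 1000, 0),
      label_eoc_ug = ifelse(
        .data$glucose,
        .data$glucose_dose_ug_g - .data$resp_label_ug -
          .data$label_mbc_ug / constants$kec, 0),
      cue_vial = cue(.data$growth, .data$resp_vial),
      cell_id = paste(.data$site, .data$plot, .data$temperature_c,
                      .data$window, .data$amendment, sep = "_")
    )

  samples <- dplyr::bind_rows(
    grid |> dplyr::transmute(
      sample_id = paste0(.data$cell_id, "_o18"), assay = "o18",
      site = .data$site, plot = .data$plot,
      temperature_c = .data$temperature_c, window = .data$window,
      amendment = .data$amendment),
    grid |> dplyr::transmute(
      sample_id = paste0(.data$cell_id, "_c13"), assay = "c13",
      site = .data$site, plot = .data$plot,
      temperature_c = .data$temperature_c, window = .data$window,
      amendment = .data$amendment)
  )

  ## ---- headspace tables ----------------------------------------------
  set.seed(child[1])
  make_headspace <- function(g, assay) {
    vv <- if (assay == "o18") truth$assay$o18_vial_volume else
      truth$assay$c13_vial_volume
    fresh <- if (assay == "o18") truth$assay$o18_soil_fresh else
      truth$assay$c13_soil_fresh
    sampled <- if (assay == "o18") truth$assay$o18_sampled_volume else
      truth$assay$c13_sampled_volume
    hv <- headspace_volume(vv, fresh, g$dry_mass_fraction,
                           constants$bulk_density)
    dry <- fresh * g$dry_mass_fraction
    ppm0 <- truth$assay$ambient_co2_ppm
    per_ppm <- ppm_to_mass_c(1, hv, g$temperature_c,
                             constants$pressure_atm, constants)
    m0 <- ppm0 * per_ppm
    # replacement at the same ppm: post-sampling CO2-C equals m0 exactly
    m0_adj <- m0 * (1 - sampled / hv) +
      ppm_to_mass_c(truth$assay$replacement_co2_ppm, sampled,
                    g$temperature_c, constants$pressure_atm, constants)
    m1 <- m0_adj + g$resp_vial * dur * dry / 1000
    ppm1 <- m1 / per_ppm
    n <- nrow(g)
    out <- tibble::tibble(
      sample_id = paste0(g$cell_id, "_", assay),
      vial_volume = vv, soil_fresh_mass = fresh,
      dry_mass_fraction = g$dry_mass_fraction,
      headspace_volume = hv,
      co2_ppm_t0 = ppm0 * rlnorm_cv(n, noise$cv_gas),
      co2_ppm_t1 = ppm1 * rlnorm_cv(n, noise$cv_gas),
      sampled_volume = sampled,
      replacement_co2_ppm = truth$assay$replacement_co2_ppm,
      temperature_c = g$temperature_c,
      pressure_atm = constants$pressure_atm,
      duration_h = dur
    )
    if (assay == "c13") {
      label1 <- g$label_resp_vial * dur * dry / 1000
      at1 <- at_na13 + label1 / m1 * (iso$tracer_at - at_na13)
      out$delta13c_t0 <- atom_percent_to_delta(
        pmin(pmax(at_na13 + rnorm_sd(n, noise$sd_at), 1e-6), 99.999),
        constants$r13_vpdb)
      out$delta13c_t1 <- atom_percent_to_delta(
        pmin(pmax(at1 + rnorm_sd(n, noise$sd_at), 1e-6), 99.999),
        constants$r13_vpdb)
    }
    out
  }
  headspace <- dplyr::bind_rows(make_headspace(grid, "o18"),
                                make_headspace(grid, "c13"))

  ## ---- DNA isotope table (18O assay) ---------------------------------
  set.seed(child[2])
  n <- nrow(grid)
  f_new <- grid$growth * dur / (1000 * grid$mbc_ug_g)
  dna <- tibble::tibble(
    sample_id = paste0(grid$cell_id, "_o18"),
    o_dna_extract = grid$dna_total_ug_g * constants$o_frac_dna *
      rlnorm_cv(n, noise$cv_extract),
    at_percent_labeled = pmax(iso$at_na_18o + iso$at_sw * f_new +
                                rnorm_sd(n, noise$sd_at), 0),
    at_percent_natural = pmax(iso$at_na_18o + rnorm_sd(n, noise$sd_at), 0),
    at_percent_soil_water = iso$at_sw,
    dna_total = grid$dna_total_ug_g * rlnorm_cv(n, noise$cv_extract),
    duration_h = dur,
    dry_soil = truth$assay$o18_soil_fresh * grid$dry_mass_fraction
  )

  ## ---- fumigation pairs (13C assay) ----------------------------------
  set.seed(child[3])
  eoc_non <- grid$eoc_ug_g + grid$label_eoc_ug
  eoc_fum <- eoc_non + grid$mbc_ug_g * constants$kec
  at_non <- at_na13 + grid$label_eoc_ug / eoc_non *
    (iso$tracer_at - at_na13)
  at_fum <- at_na13 + (grid$label_eoc_ug + grid$label_mbc_ug) / eoc_fum *
    (iso$tracer_at - at_na13)
  fumigation <- tibble::tibble(
    sample_id = paste0(grid$cell_id, "_c13"),
    eoc_fumigated = eoc_fum * rlnorm_cv(n, noise$cv_extract),
    eoc_nonfumigated = eoc_non * rlnorm_cv(n, noise$cv_extract),
    c13_fumigated_at = pmax(at_fum + rnorm_sd(n, noise$sd_at), 0),
    c13_nonfumigated_at = pmax(at_non + rnorm_sd(n, noise$sd_at), 0),
    extraction_efficiency = constants$kec
  )

  ## ---- PLFA profiles (13C assay) -------------------------------------
  set.seed(child[4])
  table <- plfa_marker_table()
  plfa_list <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    w <- marker_weights(truth, g$site, table)
    amounts <- g$plfa_total_nmol_g * w                   # nmol C g-1
    alloc <- truth$alloc[truth$alloc$site == g$site &
                           truth$alloc$temperature_c == g$temperature_c, ]
    label <- marker_label_split(g$label_plfa_ug, alloc, w, table)
    amounts <- unname(amounts)
    amounts_ug <- amounts * constants$molar_mass_c / 1000
    f_i <- unname(label[table$marker]) / amounts_ug
    at_i <- at_na13 + f_i * (iso$tracer_at - at_na13)
    dry_plfa <- truth$assay$plfa_soil_fresh[[g$site]] * g$dry_mass_fraction
    nm <- nrow(table)
    tibble::tibble(
      sample_id = paste0(g$cell_id, "_c13"),
      marker = table$marker,
      area = amounts * dry_plfa / truth$assay$is_amount_nmol *
        truth$assay$is_area * rlnorm_cv(nm, noise$cv_area),
      is_area = truth$assay$is_area,
      is_amount_nmol = truth$assay$is_amount_nmol,
      dry_soil_g = dry_plfa,
      at_percent = pmax(at_i + rnorm_sd(nm, noise$sd_at), 0)
    )
  })
  plfa <- dplyr::bind_rows(plfa_list)

  ## ---- per-vial truth -------------------------------------------------
  alloc_truth <- dplyr::rename(
    truth$alloc, alloc_bacterial = "bacterial", alloc_fungal = "fungal",
    alloc_general = "general", alloc_unsaturated = "unsaturated")
  truth_vials <- dplyr::bind_rows(
    grid |> dplyr::transmute(
      sample_id = paste0(.data$cell_id, "_o18"),
      site = .data$site, temperature_c = .data$temperature_c,
      respiration = .data$resp_vial, growth = .data$growth,
      cue = .data$cue_vial, mbc = .data$mbc_ug_g),
    grid |> dplyr::transmute(
      sample_id = paste0(.data$cell_id, "_c13"),
      site = .data$site, temperature_c = .data$temperature_c,
      respiration = .data$resp_vial,
      label_respiration = .data$label_resp_vial,
      mbc = .data$mbc_ug_g, eoc = .data$eoc_ug_g + .data$label_eoc_ug,
      label_mbc_ug = .data$label_mbc_ug,
      label_mbc_rate = .data$label_mbc_ug * 1000 / dur,
      label_eoc_ug = .data$label_eoc_ug,
      label_plfa_ug = .data$label_plfa_ug,
      label_plfa_rate = .data$label_plfa_ug * 1000 / dur,
      glucose_dose_ug_g = ifelse(.data$glucose, .data$glucose_dose_ug_g, 0))
  ) |>
    dplyr::left_join(alloc_truth, by = c("site", "temperature_c"))

  out <- list(samples = samples, headspace = headspace, dna = dna,
              fumigation = fumigation, plfa = plfa,
              truth_vials = truth_vials, truth = truth)
  class(out) <- c("cuetrace_experiment", class(out))
  out
}
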