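#' Process a dual-isotope incubation experiment
#'
#' Runs the full computation chain over the raw measurement tables of an
#' experiment (simulated via [simulate_experiment()] or read from CSVs via
#' [read_experiment()]):
#' \enumerate{
#'   \item headspace CO2 accounting to respiration rates for every vial;
#'   \item fumigation-extraction to MBC;
#'   \item 18O-DNA assay to DNA production, growth and CUE (the MBC
#'     entering growth is the matched site/plot/temperature/window/
#'     amendment fumigation-derived MBC);
#'   \item 13C partitioning: tracer respiration and tracer incorporation
#'     into EOC and biomass, backgrounds taken from the paired water-only
#'     control of the same site/plot/temperature/window;
#'   \item PLFA quantification, totals, and tracer allocation to the
#'     fungal/bacterial/general and saturation groupings.
#' }
#'
#' @param exp A `cuetrace_experiment` (list of tables `samples`,
#'   `headspace`, `dna`, `fumigation`, `plfa`).
#' @param tracer_at Tracer enrichment, at%.
#' @param kec_correct Apply k_EC to the biomass tracer difference too?
#' @param constants Constant set.
#' @return A `cuetrace_results` list: `rates` (18O assay), `partition`
#'   (13C assay), `plfa` (totals + allocations), `long` (tidy long table
#'   of all per-sample parameters), `rr` (per-plot response ratios),
#'   `summary` (group means +/- SE), `qc` (flag counts).
#' @export
process_experiment <- function(exp, tracer_at = 10, kec_correct = FALSE,
                               constants = ct_constants()) {
  samples <- exp$samples
  keys <- c("site", "plot", "temperature_c", "window")

  hs <- dplyr::inner_join(exp$headspace, samples, by = "sample_id",
                          suffix = c("", ".meta"))
  hs$respiration <- respiration_rate(hs, constants)$respiration

  ## MBC per cell from the fumigation pairs (13C assay vials)
  fum <- dplyr::inner_join(exp$fumigation, samples, by = "sample_id")
  fum$mbc <- as.numeric(mbc(fum$eoc_fumigated, fum$eoc_nonfumigated,
                            fum$extraction_efficiency))
  mbc_cells <- dplyr::select(fum, dplyr::all_of(c(keys, "amendment")),
                             "mbc")

  ## ---- 18O assay: growth and CUE -------------------------------------
  o18_hs <- dplyr::filter(hs, .data$assay == "o18")
  dna <- dplyr::inner_join(exp$dna, samples, by = "sample_id")
  dna_prod <- dna_produced(dna$o_dna_extract, dna$at_percent_labeled,
                           dna$at_percent_natural,
                           dna$at_percent_soil_water,
                           constants$o_frac_dna)
  dna$dna_prod <- as.numeric(dna_prod)
  dna$below_background <- attr(dna_prod, "below_background")
  rates <- dna |>
    dplyr::left_join(
      dplyr::select(o18_hs, "sample_id", "respiration"),
      by = "sample_id") |>
    dplyr::left_join(mbc_cells, by = c(keys, "amendment")) |>
    dplyr::mutate(
      growth = growth_rate(.data$dna_prod, .data$dna_total, .data$mbc,
                           .data$duration_h),
      cue = cue(pmax(.data$growth, 0), pmax(.data$respiration, 0)),
      negative_respiration = .data$respiration < 0
    ) |>
    dplyr::select(dplyr::all_of(c("sample_id", keys, "amendment",
                                  "respiration", "growth", "cue", "mbc",
                                  "dna_prod", "below_background",
                                  "negative_respiration")))

  ## ---- 13C assay: tracer partitioning --------------------------------
  c13_hs <- dplyr::filter(hs, .data$assay == "c13")
  ctrl_hs <- c13_hs |>
    dplyr::filter(.data$amendment == "water") |>
    dplyr::mutate(control_at = delta_to_atom_percent(.data$delta13c_t1,
                                                     constants$r13_vpdb)) |>
    dplyr::select(dplyr::all_of(keys), "control_at")
  ctrl_ext <- fum |>
    dplyr::filter(.data$amendment == "water") |>
    dplyr::select(dplyr::all_of(keys),
                  control_ext_at = "c13_nonfumigated_at")

  glu_hs <- c13_hs |>
    dplyr::filter(.data$amendment == "glucose") |>
    dplyr::left_join(ctrl_hs, by = keys)
  glu_hs$label_respiration <- label_respiration(
    glu_hs, glu_hs$control_at, tracer_at, constants)$label_respiration

  partition <- fum |>
    dplyr::filter(.data$amendment == "glucose") |>
    dplyr::left_join(ctrl_ext, by = keys) |>
    dplyr::left_join(
      dplyr::select(glu_hs, "sample_id", "respiration",
                    "label_respiration", "duration_h"),
      by = "sample_id") |>
    dplyr::mutate(
      eoc = .data$eoc_nonfumigated,
      label_mbc_ug = label_in_mbc(
        .data$eoc_fumigated, .data$eoc_nonfumigated,
        .data$c13_fumigated_at, .data$c13_nonfumigated_at,
        .data$control_ext_at, tracer_at, kec_correct,
        .data$extraction_efficiency),
      label_mbc_rate = .data$label_mbc_ug * 1000 / .data$duration_h,
      label_eoc_ug = label_in_pool(
        .data$eoc_nonfumigated,
        label_fraction(.data$c13_nonfumigated_at, .data$control_ext_at,
                       tracer_at)),
      negative_flush = is.na(.data$mbc)
    ) |>
    dplyr::select(dplyr::all_of(c("sample_id", keys, "amendment",
                                  "respiration", "label_respiration",
                                  "eoc", "mbc", "label_mbc_ug",
                                  "label_mbc_rate", "label_eoc_ug",
                                  "duration_h", "negative_flush")))

  ## ---- PLFA ----------------------------------------------------------
  plfa_raw <- dplyr::inner_join(exp$plfa, samples, by = "sample_id")
  quant <- plfa_raw |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, k) {
      q <- quantify_markers(d[, c("marker", "area")], d$is_area[1],
                            d$is_amount_nmol[1], d$dry_soil_g[1])
      q$at_percent <- d$at_percent
      q
    }) |>
    dplyr::ungroup() |>
    dplyr::inner_join(samples, by = "sample_id")

  ctrl_plfa <- quant |>
    dplyr::filter(.data$amendment == "water") |>
    dplyr::select(dplyr::all_of(keys), "marker",
                  control_marker_at = "at_percent")
  table <- plfa_marker_table()
  glu_quant <- quant |>
    dplyr::filter(.data$amendment == "glucose") |>
    dplyr::left_join(ctrl_plfa, by = c(keys, "marker"))

  plfa_res <- glu_quant |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", keys,
                                                  "amendment")))) |>
    dplyr::group_modify(function(d, k) {
      prof <- d[, c("marker", "c_amount", "at_percent")]
      prim <- label_allocation(prof, table, "primary",
                               d$control_marker_at, tracer_at)
      satu <- label_allocation(prof, table, "saturation",
                               d$control_marker_at, tracer_at)
      f <- label_fraction(d$at_percent, d$control_marker_at, tracer_at)
      label_ug <- sum(d$c_amount * as.numeric(f)) *
        ct_constants()$molar_mass_c / 1000
      pick <- function(tab, grp) {
        v <- tab$fraction[tab$group == grp]
        if (length(v)) v else 0
      }
      tibble::tibble(
        total_plfa = total_plfa(d[, c("marker", "c_amount")]),
        label_plfa_ug = label_ug,
        alloc_fungal = pick(prim, "fungal"),
        alloc_bacterial = pick(prim, "bacterial"),
        alloc_general = pick(prim, "general"),
        alloc_unsaturated = pick(satu, "unsaturated"),
        alloc_saturated = pick(satu, "saturated")
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(
      dplyr::select(partition, "sample_id", "duration_h"),
      by = "sample_id") |>
    dplyr::mutate(label_plfa_rate = .data$label_plfa_ug * 1000 /
                    .data$duration_h)

  total_plfa_all <- quant |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample_id", keys,
                                                  "amendment")))) |>
    dplyr::summarise(total_plfa = total_plfa(
      dplyr::pick("marker", "c_amount")), .groups = "drop")

  ## ---- tidy long table ------------------------------------------------
  id_cols <- c("sample_id", keys, "amendment")
  long <- dplyr::bind_rows(
    tidyr::pivot_longer(
      dplyr::select(rates, dplyr::all_of(c(id_cols, "respiration",
                                           "growth", "cue", "mbc"))),
      cols = -dplyr::all_of(id_cols),
      names_to = "parameter", values_to = "value"),
    tidyr::pivot_longer(
      dplyr::select(partition,
                    dplyr::all_of(c(id_cols, "label_respiration",
                                    "label_mbc_rate", "label_mbc_ug",
                                    "label_eoc_ug", "eoc"))),
      cols = -dplyr::all_of(id_cols),
      names_to = "parameter", values_to = "value"),
    tidyr::pivot_longer(
      dplyr::select(total_plfa_all, dplyr::all_of(c(id_cols, "total_plfa"))),
      cols = -dplyr::all_of(id_cols),
      names_to = "parameter", values_to = "value"),
    tidyr::pivot_longer(
      dplyr::select(plfa_res,
                    dplyr::all_of(c(id_cols, "label_plfa_rate",
                                    "label_plfa_ug", "alloc_fungal",
                                    "alloc_bacterial", "alloc_general",
                                    "alloc_unsaturated",
                                    "alloc_saturated"))),
      cols = -dplyr::all_of(id_cols),
      names_to = "parameter", values_to = "value")
  )

  rr <- response_ratio_table(long)
  summary <- summarize_results(long)
  qc <- tibble::tibble(
    flag = c("dna_below_background", "negative_respiration",
             "negative_fumigation_flush", "undefined_cue"),
    n = c(sum(rates$below_background), sum(hs$respiration < 0),
          sum(is.na(fum$mbc)), sum(is.na(rates$cue)))
  )

  out <- list(rates = rates, partition = partition, plfa = plfa_res,
              long = long, rr = rr, summary = summary, qc = qc)
  class(out) <- c("cuetrace_results", class(out))
  out
}

#' Per-plot response ratios to cooling
#'
#' Pairs the two incubation temperatures within each site x plot x window
#' x amendment x parameter combination (plots are the replication unit:
#' each field plot was split between the 11 and 1 degree incubators) and
#' computes `RR = value(11 C) / value(1 C)`.
#'
#' @param long Tidy long table with columns `site`, `plot`,
#'   `temperature_c`, `window`, `amendment`, `parameter`, `value`.
#' @return Tibble with per-plot `rr` plus the paired values `r11`, `r1`.
#' @export
response_ratio_table <- function(long) {
  wide <- long |>
    dplyr::filter(.data$temperature_c %in% c(1, 11)) |>
    dplyr::select(-dplyr::any_of("sample_id")) |>
    tidyr::pivot_wider(names_from = "temperature_c",
                       values_from = "value", names_prefix = "r") |>
    dplyr::filter(!is.na(.data$r11) & !is.na(.data$r1))
  wide$rr <- response_ratio(wide$r11, wide$r1)
  wide
}

#' Group summaries of per-sample results
#'
#' Means and standard errors (sample SD over the square root of n) across
#' plot replicates for every site x temperature x window x amendment x
#' parameter group. `NA` values (flagged/undefined records) are excluded
#' and counted.
#'
#' @param long Tidy long table as in [response_ratio_table()].
#' @return Tibble with `mean`, `se`, `n`, `n_excluded`.
#' @export
summarize_results <- function(long) {
  long |>
    dplyr::group_by(.data$site, .data$temperature_c, .data$window,
                    .data$amendment, .data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$value[!is.na(.data$value)]),
      se = stats::sd(.data$value[!is.na(.data$value)]) /
        sqrt(sum(!is.na(.data$value))),
      n = sum(!is.na(.data$value)),
      n_excluded = sum(is.na(.data$value)),
      .groups = "drop"
    )
}
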