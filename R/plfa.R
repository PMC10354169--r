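#' Saturation class of a PLFA marker from its name
#'
#' Markers are named `C:D` (chain length : number of C=C double bonds) with
#' optional prefixes `i`/`a` (branched), `10Me` (methyl) and `cy`
#' (cyclopropane), and an omega position suffix (written with ASCII `w`,
#' e.g. `16:1w7`). A marker is unsaturated when its double-bond count is
#' at least one; cyclopropane rings and methyl branches are not double
#' bonds, so all `:0` markers are saturated.
#'
#' @param marker Character vector of marker names.
#' @return Logical vector, `TRUE` for unsaturated.
#' @examples
#' classify_saturation(c("16:1w7", "cy17:0", "18:2w6,9", "10Me16:0"))
#' @export
classify_saturation <- function(marker) {
  m <- regmatches(marker, regexpr(":[0-9]+", marker))
  if (length(m) != length(marker)) {
    rlang::abort("Unparseable marker name(s); expected a ':<double bonds>' field.",
                 class = "cuetrace_domain_error")
  }
  as.integer(sub(":", "", m)) >= 1L
}

#' Packaged PLFA biomarker group table
#'
#' The marker-to-group assignment used for relative abundance and 13C
#' allocation. Group logic: fungal markers `18:1w9c` and `18:2w6,9`;
#' bacterial markers are the union of the Gram-positive set (`a15:0`,
#' `i16:0`, `16:1w7`, `10Me16:0`, `a17:0`, `cy17:0`, `10Me18:0`) and the
#' cyclopropane/monounsaturated bacterial set (`16:1w7`, `cy17:0`,
#' `cy19:0`); the remaining quantified markers are general (not diagnostic
#' of bacteria or fungi). `primary_group` is the disjoint, exhaustive
#' partition used for label allocation; the saturation class is derived
#' from the marker name via [classify_saturation()]. Greek omega is
#' written as ASCII `w`. The table is shipped as an editable CSV
#' (`extdata/plfa_markers.csv`), so lab-specific marker panels can replace
#' it.
#'
#' @param path Optional path to a custom marker table CSV with columns
#'   `marker`, `fungal`, `gram_positive`, `bacterial`, `general`,
#'   `primary_group`.
#' @return Tibble with the columns above plus `unsaturated`.
#' @export
plfa_marker_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "plfa_markers.csv", package = "cuetrace")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$unsaturated <- classify_saturation(tab$marker)
  if (anyDuplicated(tab$marker)) {
    rlang::abort("Duplicate marker names in marker table.",
                 class = "cuetrace_config_error")
  }
  if (!all(tab$primary_group %in% c("fungal", "bacterial", "general"))) {
    rlang::abort("primary_group must be fungal/bacterial/general.",
                 class = "cuetrace_config_error")
  }
  tibble::as_tibble(tab)
}

#' Quantify PLFA markers against an internal standard
#'
#' Single-point quantification: each marker's detector response is scaled
#' by the internal-standard response and amount, referenced to dry soil,
#' `amount_i = area_i / is_area * is_amount * rf_i / dry_soil_g`.
#' Response factors default to 1 for every marker.
#'
#' @param areas Data frame with columns `marker` and `area` (detector
#'   response); the internal standard must not be among the rows.
#' @param is_area Internal-standard detector response (> 0).
#' @param is_amount Internal-standard amount, nmol C.
#' @param dry_soil_g Dry soil mass extracted, g.
#' @param response_factor Scalar or per-marker named vector of response
#'   factors.
#' @return Tibble with `marker` and `c_amount` (nmol C g-1 dry soil).
#' @export
quantify_markers <- function(areas, is_area, is_amount, dry_soil_g,
                             response_factor = 1) {
  if (any(!is.finite(is_area)) || any(is_area <= 0)) {
    rlang::abort("Internal standard response missing or non-positive.",
                 class = "cuetrace_quantification_error")
  }
  rf <- if (length(response_factor) > 1 || !is.null(names(response_factor))) {
    unname(response_factor[areas$marker])
  } else {
    response_factor
  }
  amount <- areas$area / is_area * is_amount * rf / dry_soil_g
  if (all(amount == 0)) {
    rlang::warn("All marker areas are zero; empty profile.")
  }
  tibble::tibble(marker = areas$marker, c_amount = amount)
}

#' Total PLFA content of a profile
#'
#' Sum of biomarker C amounts, excluding the internal standard.
#'
#' @param profile Data frame with `marker` and `c_amount` (nmol C g-1).
#' @param internal_standard Marker name to exclude (default `"19:0"`).
#' @return Total PLFA, nmol C g-1 dry soil.
#' @export
total_plfa <- function(profile,
                       internal_standard = ct_constants()$internal_standard) {
  keep <- profile$marker != internal_standard
  sum(profile$c_amount[keep])
}

#' Relative abundance of PLFA markers
#'
#' Each biomarker's C amount divided by the summed biomarker C (internal
#' standard excluded).
#'
#' @inheritParams total_plfa
#' @return Tibble with `marker` and `fraction`; fractions sum to 1.
#' @export
relative_abundance <- function(profile,
                               internal_standard = ct_constants()$internal_standard) {
  prof <- profile[profile$marker != internal_standard, , drop = FALSE]
  tot <- sum(prof$c_amount)
  if (!is.finite(tot) || tot <= 0) {
    rlang::abort("Total biomarker C must be positive.",
                 class = "cuetrace_domain_error")
  }
  tibble::tibble(marker = prof$marker, fraction = prof$c_amount / tot)
}

#' 13C label allocation to PLFA groups
#'
#' Per-marker tracer C is the marker's C amount times its excess-based
#' tracer fraction (two-pool mixing against the natural-abundance
#' background); a group's allocation is its summed tracer C over the total
#' tracer C in all markers. With a disjoint, exhaustive grouping
#' (`primary` = fungal/bacterial/general, or `saturation`) the fractions
#' sum to 1.
#'
#' @param profile Data frame with `marker`, `c_amount` and `at_percent`
#'   (13C enrichment of the marker).
#' @param table Marker table from [plfa_marker_table()].
#' @param grouping `"primary"` or `"saturation"`.
#' @param control_at Natural-abundance marker background, at%; scalar or
#'   per-row vector (paired water-only control by convention).
#' @param tracer_at Tracer enrichment, at%.
#' @param internal_standard Marker to exclude.
#' @return Tibble with `group`, `label_c` (same units as
#'   `c_amount` x fraction) and `fraction` summing to 1.
#' @export
label_allocation <- function(profile, table = plfa_marker_table(),
                             grouping = c("primary", "saturation"),
                             control_at = 1.08, tracer_at = 10,
                             internal_standard = ct_constants()$internal_standard) {
  grouping <- match.arg(grouping)
  keep <- profile$marker != internal_standard
  prof <- profile[keep, , drop = FALSE]
  ctrl <- if (length(control_at) > 1) control_at[keep] else control_at
  f <- label_fraction(prof$at_percent, ctrl, tracer_at)
  label_c <- prof$c_amount * as.numeric(f)
  total <- sum(label_c)
  if (!is.finite(total) || total <= 0) {
    rlang::abort("No labelled marker; allocation undefined.",
                 class = "cuetrace_undefined_allocation")
  }
  idx <- match(prof$marker, table$marker)
  if (anyNA(idx)) {
    rlang::abort(
      paste0("Marker(s) absent from marker table: ",
             paste(unique(prof$marker[is.na(idx)]), collapse = ", ")),
      class = "cuetrace_config_error"
    )
  }
  group <- if (grouping == "primary") {
    table$primary_group[idx]
  } else {
    ifelse(table$unsaturated[idx], "unsaturated", "saturated")
  }
  out <- tibble::tibble(group = group, label_c = label_c) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(label_c = sum(.data$label_c), .groups = "drop") |>
    dplyr::mutate(fraction = .data$label_c / total)
  out
}
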