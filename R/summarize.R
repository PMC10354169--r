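#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals (0.05 -> 0.1), the
#' convention used when reporting one-decimal ratios; base R's `round()`
#' rounds half to even instead.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Forest-to-agricultural site ratio of a summarised parameter
#'
#' The "times higher in forest soil" headline numbers: the ratio of the
#' forest mean to the agricultural mean of one parameter, rounded half
#' away from zero to one decimal.
#'
#' @param summary A summary table with columns `site`, `parameter` and
#'   `mean` — either [fixture_table1()] or a filtered
#'   [summarize_results()] output (one row per site for the chosen
#'   parameter).
#' @param parameter Parameter name to ratio.
#' @return Tibble with `parameter`, `forest_mean`, `agricultural_mean`,
#'   `ratio`.
#' @examples
#' site_ratio(fixture_table1(), "soc")
#' @export
site_ratio <- function(summary, parameter) {
  rows <- summary[summary$parameter == parameter, ]
  f <- rows$mean[rows$site == "forest"]
  a <- rows$mean[rows$site == "agricultural"]
  if (length(f) != 1 || length(a) != 1) {
    rlang::abort(
      paste0("Need exactly one forest and one agricultural mean for '",
             parameter, "'."),
      class = "cuetrace_domain_error"
    )
  }
  tibble::tibble(parameter = parameter, forest_mean = f,
                 agricultural_mean = a,
                 ratio = round_half_up(f / a, 1))
}

#' All site ratios of a summary table
#'
#' @inheritParams site_ratio
#' @return Tibble with one row per parameter, as [site_ratio()].
#' @export
site_ratios <- function(summary) {
  dplyr::bind_rows(lapply(unique(summary$parameter),
                          function(p) site_ratio(summary, p)))
}

#' Summarise per-plot response ratios
#'
#' Mean +/- SE of the per-plot response ratios across plots, per site x
#' window x amendment x parameter.
#'
#' @param rr Per-plot RR table from [response_ratio_table()].
#' @return Tibble with `mean_rr`, `se_rr`, `n`.
#' @export
summarize_rr <- function(rr) {
  rr |>
    dplyr::filter(!is.na(.data$rr)) |>
    dplyr::group_by(.data$site, .data$window, .data$amendment,
                    .data$parameter) |>
    dplyr::summarise(mean_rr = mean(.data$rr),
                     se_rr = stats::sd(.data$rr) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}
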