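#' Write an experiment's raw measurement tables to CSV
#'
#' Writes the five raw tables (`samples`, `headspace`, `dna`,
#' `fumigation`, `plfa`) of an experiment as RFC-4180 CSVs into a
#' directory, so the pipeline can be driven from files. Truth parameters
#' of a simulated experiment, when present, are written as
#' `truth_vials.csv` for recovery checks.
#'
#' @param exp A `cuetrace_experiment`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("samples", "headspace", "dna", "fumigation", "plfa")
  for (nm in tables) {
    utils::write.csv(exp[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(exp$truth_vials)) {
    utils::write.csv(exp$truth_vials, file.path(dir, "truth_vials.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read an experiment's raw measurement tables from CSV
#'
#' Inverse of [write_experiment()]. Validates that every non-sample table
#' references only known `sample_id`s and that required columns are
#' present, aborting with a per-table column report otherwise.
#'
#' @param dir Directory holding the CSVs.
#' @return A `cuetrace_experiment` list.
#' @export
read_experiment <- function(dir) {
  required <- list(
    samples = c("sample_id", "site", "plot", "temperature_c", "window",
                "amendment", "assay"),
    headspace = c("sample_id", "co2_ppm_t0", "co2_ppm_t1",
                  "sampled_volume", "replacement_co2_ppm",
                  "temperature_c", "duration_h", "soil_fresh_mass",
                  "dry_mass_fraction"),
    dna = c("sample_id", "o_dna_extract", "at_percent_labeled",
            "at_percent_natural", "at_percent_soil_water", "dna_total",
            "duration_h"),
    fumigation = c("sample_id", "eoc_fumigated", "eoc_nonfumigated",
                   "c13_fumigated_at", "c13_nonfumigated_at",
                   "extraction_efficiency"),
    plfa = c("sample_id", "marker", "area", "is_area", "is_amount_nmol",
             "dry_soil_g", "at_percent")
  )
  exp <- lapply(names(required), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      rlang::abort(paste0("Missing table: ", path),
                   class = "cuetrace_schema_error")
    }
    tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
    missing_cols <- setdiff(required[[nm]], names(tab))
    if (length(missing_cols)) {
      rlang::abort(
        paste0("Table '", nm, "' is missing column(s): ",
               paste(missing_cols, collapse = ", ")),
        class = "cuetrace_schema_error"
      )
    }
    tab
  })
  names(exp) <- names(required)
  orphan <- lapply(exp[-1], function(tab)
    setdiff(tab$sample_id, exp$samples$sample_id))
  n_orphan <- vapply(orphan, length, integer(1))
  if (any(n_orphan > 0)) {
    rlang::abort(
      paste0("sample_id(s) not present in samples.csv: ",
             paste(unique(unlist(orphan)), collapse = ", ")),
      class = "cuetrace_schema_error"
    )
  }
  truth_path <- file.path(dir, "truth_vials.csv")
  if (file.exists(truth_path)) {
    exp$truth_vials <- tibble::as_tibble(
      utils::read.csv(truth_path, stringsAsFactors = FALSE))
  }
  class(exp) <- c("cuetrace_experiment", class(exp))
  exp
}

#' Run the full pipeline on a directory of raw tables
#'
#' Reads the raw measurement CSVs, executes [process_experiment()], and
#' writes the result tables (per-sample results, long table, response
#' ratios, group summaries, site ratios at 11 degrees C / first window,
#' and the QC flag report) into `outdir`.
#'
#' @param input_dir Directory with the raw tables (see
#'   [read_experiment()]), or a `cuetrace_experiment` object.
#' @param outdir Output directory; `NULL` to skip writing.
#' @param tracer_at Tracer enrichment, at%.
#' @param constants Constant set.
#' @return The `cuetrace_results` list, invisibly when writing.
#' @export
run_pipeline <- function(input_dir, outdir = NULL, tracer_at = 10,
                         constants = ct_constants()) {
  exp <- if (inherits(input_dir, "cuetrace_experiment")) input_dir
         else read_experiment(input_dir)
  res <- process_experiment(exp, tracer_at = tracer_at,
                            constants = constants)
  w <- unique(res$summary$window)
  first_window <- w[order(as.numeric(sub("h$", "", w)))][1]
  ref <- res$summary |>
    dplyr::filter(.data$temperature_c == max(.data$temperature_c),
                  .data$window == first_window,
                  .data$amendment == ifelse(
                    grepl("^label|^alloc", .data$parameter),
                    "glucose", "water"))
  res$ratios <- site_ratios(ref)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("rates", "partition", "plfa", "long", "rr", "summary",
                 "ratios", "qc")) {
      utils::write.csv(res[[nm]], file.path(outdir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    return(invisible(res))
  }
  res
}
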