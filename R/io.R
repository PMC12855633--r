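## All interchange files are plain CSV (comma, UTF-8, "." decimal,
## ISO-8601 dates) with one leading schema-version comment line.

SCHEMA_PREFIX <- "# ionbudget-schema: "

write_schema_csv <- function(x, path, schema) {
  readr::write_lines(paste0(SCHEMA_PREFIX, schema), path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read sampling-period chemistry from CSV
#'
#' Expected columns: `period_start`, `period_end` (ISO dates),
#' `compartment`, `species`, `concentration_ueq_per_L`, `pH` (nullable).
#' Rows with species absent from the registry, non-ISO dates or negative
#' concentrations are rejected with the offending row numbers. An empty
#' file with a valid header yields an empty tibble with a warning.
#'
#' @param path CSV path (schema-comment lines starting with `#` are
#'   skipped).
#' @param registry Species registry used to validate the `species` column.
#' @return A chemistry tibble, see [generate_scenario()].
#' @export
read_chemistry_csv <- function(path, registry = default_species()) {
  expected <- c("period_start", "period_end", "compartment", "species",
                "concentration_ueq_per_L", "pH")
  header <- names(readr::read_csv(path, comment = "#", n_max = 0,
                                  show_col_types = FALSE))
  if (!identical(sort(header), sort(expected))) {
    abort(paste0("chemistry CSV schema mismatch; expected columns: ",
                 paste(expected, collapse = ", ")))
  }
  chem <- suppressWarnings(readr::read_csv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      period_start = readr::col_date(format = "%Y-%m-%d"),
      period_end = readr::col_date(format = "%Y-%m-%d"),
      compartment = readr::col_character(),
      species = readr::col_character(),
      concentration_ueq_per_L = readr::col_double(),
      pH = readr::col_double()
    )
  ))
  probs <- readr::problems(chem)
  if (nrow(probs) > 0) {
    abort(paste0("malformed chemistry rows (data row ",
                 paste(unique(probs$row), collapse = ", "), "): ",
                 probs$expected[1], " vs. ", probs$actual[1]))
  }
  if (nrow(chem) == 0) {
    warn("chemistry file is empty")
    return(chem)
  }
  bad_dates <- which(is.na(chem$period_start) | is.na(chem$period_end))
  if (length(bad_dates) > 0) {
    abort(paste0("non-ISO or missing dates in chemistry rows: ",
                 paste(bad_dates, collapse = ", ")))
  }
  bad_sp <- which(!chem$species %in% registry$name)
  if (length(bad_sp) > 0) {
    abort(paste0("unknown species '",
                 paste(unique(chem$species[bad_sp]), collapse = "', '"),
                 "' in chemistry rows: ",
                 paste(head(bad_sp, 10), collapse = ", ")))
  }
  bad_neg <- which(chem$concentration_ueq_per_L < 0)
  if (length(bad_neg) > 0) {
    abort(paste0("negative concentrations in chemistry rows: ",
                 paste(bad_neg, collapse = ", ")))
  }
  chem
}

#' Read daily water fluxes from CSV
#'
#' Expected columns: `date` (ISO), `compartment`, `water_mm`. Duplicate
#' (date, compartment) pairs are an error; gaps in the daily coverage of a
#' compartment are reported as a warning.
#'
#' @inheritParams read_chemistry_csv
#' @return A water-flux tibble (`date`, `compartment`, `water_mm`).
#' @export
read_waterflux_csv <- function(path) {
  water <- suppressWarnings(readr::read_csv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      date = readr::col_date(format = "%Y-%m-%d"),
      compartment = readr::col_character(),
      water_mm = readr::col_double()
    )
  ))
  if (!identical(sort(names(water)), sort(c("date", "compartment", "water_mm")))) {
    abort("water-flux CSV schema mismatch; expected date, compartment, water_mm")
  }
  if (anyNA(water$date)) {
    abort(paste0("non-ISO dates in water-flux rows: ",
                 paste(which(is.na(water$date)), collapse = ", ")))
  }
  dup <- duplicated(water[c("date", "compartment")])
  if (any(dup)) {
    abort(paste0("duplicate (date, compartment) in water-flux rows: ",
                 paste(which(dup), collapse = ", ")))
  }
  if (any(water$water_mm < 0)) abort("negative water fluxes")
  gaps <- water |>
    dplyr::group_by(.data$compartment) |>
    dplyr::summarise(
      n_missing = as.integer(diff(range(.data$date))) + 1 - dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_missing > 0)
  if (nrow(gaps) > 0) {
    warn(paste0("gaps in daily water-flux coverage: ",
                paste(gaps$compartment, "(", gaps$n_missing, " days)",
                      collapse = ", ")))
  }
  water
}

#' Read an emission series from CSV
#'
#' Expected columns: `year`, `gas`, `amount_gmol`, `source`.
#'
#' @inheritParams read_chemistry_csv
#' @return An emission series tibble.
#' @export
read_emissions_csv <- function(path) {
  em <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      year = readr::col_integer(),
      gas = readr::col_character(),
      amount_gmol = readr::col_double(),
      source = readr::col_character()
    )
  )
  if (any(em$amount_gmol < 0)) abort("negative emission amounts")
  em
}

#' Write a monitoring dataset to a directory of CSV files
#'
#' Writes `chemistry.csv`, `waterflux.csv` and (if ground truth is
#' present) the sidecar `truth.csv`, each with a schema-version header
#' line. The sidecar keeps the generator's ground truth out of the data
#' files proper so that reading the data back never mixes truth with
#' measurements.
#'
#' @param dataset A `monitoring_dataset`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "monitoring_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_schema_csv(dataset$chemistry, file.path(dir, "chemistry.csv"),
                   "chemistry/1")
  write_schema_csv(dataset$water, file.path(dir, "waterflux.csv"),
                   "waterflux/1")
  if (!is.null(dataset$truth)) {
    write_schema_csv(dataset$truth, file.path(dir, "truth.csv"), "truth/1")
  }
  invisible(dir)
}

#' Write an annual flux table to CSV
#'
#' @param table Annual flux table from [annual_fluxes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annual_flux_csv <- function(table, path) {
  write_schema_csv(table, path, "annual_flux/1")
}
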