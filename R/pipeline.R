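#' Pipeline configuration
#'
#' Bundles data sources and analysis options for [run_pipeline()].
#' Exactly one of `scenario` (a [scenario_config()] to generate synthetic
#' data from) or `paths` (a list with `chemistry` and `water` CSV paths)
#' must be given.
#'
#' @param scenario A [scenario_config()], or `NULL`.
#' @param paths A list `list(chemistry = , water = )` of CSV paths, or
#'   `NULL`.
#' @param registry Species registry.
#' @param degrees Named list of polynomial degrees:
#'   `deposition` (bulk/throughfall series, default 3), `seepage`
#'   (default 5), `proton_load` (default 5), `delta_s` (default 3).
#' @param threshold_rounding Rounding mode for [fluctuation_threshold()].
#' @param fixed_threshold If non-`NULL`, overrides the MAE-derived
#'   remobilization threshold with a fixed value (mmol_IE m^-2).
#' @param percentile Percentile for [endpoint_change_interpretable()].
#' @param initial_s_stock Initial topsoil S stock, mmol S m^-2.
#' @param s_uptake_ie Constant net tree S uptake subtracted in the S
#'   balance, mmol_IE m^-2 yr^-1 (default 0, i.e. neglected).
#' @param n_demand_kg,s_demand_kg Stand demand, kg element ha^-1 yr^-1,
#'   used for the surplus factors.
#' @param output_dir If non-`NULL`, result CSVs and a summary JSON are
#'   written there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, paths = NULL,
                            registry = default_species(),
                            degrees = list(deposition = 3, seepage = 5,
                                           proton_load = 5, delta_s = 3),
                            threshold_rounding = "nearest10",
                            fixed_threshold = NULL,
                            percentile = 90,
                            initial_s_stock = 2281.3,
                            s_uptake_ie = 0,
                            n_demand_kg = 9.7,
                            s_demand_kg = 0.9,
                            output_dir = NULL) {
  if (is.null(scenario) == is.null(paths)) {
    abort("exactly one of scenario or paths must be given")
  }
  if (!is.null(paths)) {
    missing_files <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing_files) > 0) {
      abort(paste0("input files not found: ",
                   paste(missing_files, collapse = ", ")))
    }
  }
  structure(
    list(scenario = scenario, paths = paths, registry = registry,
         degrees = degrees, threshold_rounding = threshold_rounding,
         fixed_threshold = fixed_threshold, percentile = percentile,
         initial_s_stock = initial_s_stock, s_uptake_ie = s_uptake_ie,
         n_demand_kg = n_demand_kg, s_demand_kg = s_demand_kg,
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "': ", conditionMessage(e)))
  })
}

#' Run the full element-budget analysis
#'
#' End-to-end composition of the package: acquire data (generate the
#' synthetic scenario or read the CSVs), aggregate annual fluxes, estimate
#' dry deposition, fit polynomial trends, assemble the proton budget and
#' its buffering statistics, compute the sulfur balance, derive the
#' fluctuation threshold and detect the remobilization window, accumulate
#' the storage trajectory, and compute throughfall S/N ratios. Every stage
#' failure is re-raised with the stage name. With an `output_dir`
#' configured, result tables are written as schema-versioned CSVs plus a
#' `summary.json`.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `budget_report` with elements `annual_fluxes`,
#'   `dry_deposition`, `trend_fits` (named list of `trend_fit`s),
#'   `proton_budget`, `s_balance`, `storage`, `window`, `sn_throughfall`,
#'   `summary` (named list of headline numbers) and, for synthetic runs,
#'   `dataset`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  dataset <- NULL
  if (!is.null(config$scenario)) {
    dataset <- with_stage("generate",
      generate_scenario(config$scenario, config$registry))
    chem <- dataset$chemistry
    water <- dataset$water
  } else {
    chem <- with_stage("read_chemistry",
      read_chemistry_csv(config$paths$chemistry, config$registry))
    water <- with_stage("read_waterflux",
      read_waterflux_csv(config$paths$water))
  }

  fluxes <- with_stage("annual_fluxes", annual_fluxes(chem, water))

  dry <- with_stage("dry_deposition", {
    sp <- intersect(c("SO4", "NH4", "NO3"), unique(fluxes$species))
    purrr::map_dfr(sp, function(s) dry_deposition_estimate(fluxes, s))
  })

  series_of <- function(cp, sp) {
    fluxes |>
      dplyr::filter(.data$compartment == cp, .data$species == sp) |>
      dplyr::transmute(year = .data$year, value = .data$flux_mmol_ie_m2)
  }

  fits <- with_stage("trend_fits", {
    dep <- tidyr::expand_grid(compartment = c("bulk", "throughfall"),
                              species = c("SO4", "NH4", "NO3"))
    fits <- purrr::pmap(dep, function(compartment, species) {
      fit_polynomial(series_of(compartment, species),
                     config$degrees$deposition)
    })
    names(fits) <- paste(dep$compartment, dep$species, sep = "_")
    for (sp in c("SO4", "NO3")) {
      fits[[paste0("seepage40_", sp)]] <-
        fit_polynomial(series_of("seepage40", sp), config$degrees$seepage)
    }
    fits
  })

  interpretable <- with_stage("endpoint_tests", {
    purrr::imap_dfr(fits, function(f, nm) {
      dplyr::mutate(endpoint_change_interpretable(f, config$percentile),
                    series = nm, .before = 1)
    })
  })

  protons <- with_stage("proton_budget", proton_budget(fluxes))
  fits$proton_load <- with_stage("proton_trend", fit_polynomial(
    dplyr::transmute(protons, year = .data$year, value = .data$total_load),
    config$degrees$proton_load
  ))

  sbal <- with_stage("s_balance",
    annual_s_balance(fluxes, uptake_ie = config$s_uptake_ie))
  fits$delta_s <- with_stage("delta_s_trend", fit_polynomial(
    dplyr::transmute(sbal, year = .data$year, value = .data$delta_ie),
    config$degrees$delta_s
  ))

  threshold <- with_stage("threshold", {
    config$fixed_threshold %||%
      fluctuation_threshold(fits$delta_s, config$threshold_rounding)
  })
  window <- with_stage("window",
    detect_remobilization_window(fits$delta_s, threshold))
  storage <- with_stage("storage_trajectory",
    storage_trajectory(sbal, config$initial_s_stock))

  sn <- with_stage("sn_ratio", {
    tf <- fluxes |>
      dplyr::filter(.data$compartment == "throughfall",
                    .data$species %in% c("SO4", "NH4", "NO3")) |>
      dplyr::select("year", "species", "flux_mmol_ie_m2") |>
      tidyr::pivot_wider(names_from = "species",
                         values_from = "flux_mmol_ie_m2")
    tibble::tibble(
      year = tf$year,
      sn_equivalent = purrr::pmap_dbl(tf, function(year, SO4, NH4, NO3)
        sn_ratio(SO4, c(NH4, NO3), basis = "equivalent")),
      sn_molar = purrr::pmap_dbl(tf, function(year, SO4, NH4, NO3)
        sn_ratio(SO4, c(NH4, NO3), basis = "molar",
                 registry = config$registry))
    )
  })

  r2 <- with_stage("load_no3_r2", {
    no3 <- series_of("seepage40", "NO3")
    joined <- dplyr::inner_join(protons, no3, by = "year")
    correlation_r2(joined$total_load, joined$value)
  })

  years <- sort(unique(protons$year))
  first5 <- head(years, 5)
  last5 <- tail(years, 5)
  summary <- list(
    n_years = length(years),
    threshold_mmol_ie_m2 = threshold,
    delta_s_mae = fits$delta_s$mae,
    window = if (is.null(window)) NULL else as.list(window),
    cumulative_change_mmol_m2 = tail(storage$cumulative_change, 1),
    remaining_fraction_percent = tail(storage$remaining_fraction, 1),
    buffered_percent_first5 =
      mean(protons$buffered_percent[protons$year %in% first5]),
    buffered_percent_last5 =
      mean(protons$buffered_percent[protons$year %in% last5]),
    r2_proton_load_no3_seepage = r2,
    sn_equivalent_first = sn$sn_equivalent[which.min(sn$year)],
    sn_equivalent_last = sn$sn_equivalent[which.max(sn$year)],
    surplus_n = surplus_factor(
      equivalent_flux_to_mass_flux(
        tail(series_of("throughfall", "NH4")$value, 1), "NH4",
        config$registry) +
        equivalent_flux_to_mass_flux(
          tail(series_of("throughfall", "NO3")$value, 1), "NO3",
          config$registry),
      config$n_demand_kg),
    surplus_s = surplus_factor(
      equivalent_flux_to_mass_flux(
        tail(series_of("throughfall", "SO4")$value, 1), "SO4",
        config$registry),
      config$s_demand_kg)
  )

  report <- structure(
    list(annual_fluxes = fluxes, dry_deposition = dry, trend_fits = fits,
         endpoint_tests = interpretable, proton_budget = protons,
         s_balance = sbal, storage = storage, window = window,
         threshold = threshold, sn_throughfall = sn, summary = summary,
         dataset = dataset, config = config),
    class = "budget_report"
  )

  if (!is.null(config$output_dir)) {
    with_stage("write_outputs", write_report(report, config$output_dir))
  }
  report
}

#' @export
print.budget_report <- function(x, ...) {
  s <- x$summary
  cat("<budget_report> ", s$n_years, " years\n", sep = "")
  if (!is.null(s$window)) {
    cat("  S remobilization window: ", s$window$start_year, "-",
        s$window$end_year, " (", s$window$duration, " years, threshold ",
        s$threshold_mmol_ie_m2, " mmol_IE m-2)\n", sep = "")
  }
  cat("  remaining topsoil S: ",
      sprintf("%.1f%%", s$remaining_fraction_percent), "\n", sep = "")
  cat("  buffered protons first/last 5 years: ",
      sprintf("%.1f%% / %.1f%%", s$buffered_percent_first5,
              s$buffered_percent_last5), "\n", sep = "")
  invisible(x)
}

#' Write a budget report to disk
#'
#' Writes the annual flux table, proton budget, S balance and storage
#' trajectory as schema-versioned CSVs, a per-series trend report
#' (degree, MAE, threshold, window, interpretability), and a
#' `summary.json` with the headline numbers.
#'
#' @param report A `budget_report` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annual_flux_csv(report$annual_fluxes,
                        file.path(dir, "annual_fluxes.csv"))
  write_schema_csv(report$proton_budget, file.path(dir, "proton_budget.csv"),
                   "proton_budget/1")
  write_schema_csv(dplyr::left_join(report$s_balance, report$storage,
                                    by = c("year", "delta_ie")),
                   file.path(dir, "s_storage.csv"), "s_storage/1")
  trend_report <- purrr::imap_dfr(report$trend_fits, function(f, nm) {
    tibble::tibble(series = nm, degree = f$degree, mae = f$mae)
  })
  write_schema_csv(trend_report, file.path(dir, "trend_report.csv"),
                   "trend_report/1")
  write_schema_csv(report$sn_throughfall, file.path(dir, "sn_throughfall.csv"),
                   "sn_ratio/1")
  jsonlite::write_json(report$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
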