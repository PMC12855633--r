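#' Scenario configuration for the synthetic monitoring-data generator
#'
#' Builds the configuration object consumed by [generate_scenario()]. The
#' defaults emulate a 36-year (1985-2020) spruce-stand monitoring record:
#' roughly biweekly sampling of bulk precipitation, throughfall and seepage
#' at 40 cm; strongly declining sulfate and ammonium throughfall inputs, a
#' roughly flat nitrate input; high inter-annual variability of seepage
#' fluxes; and a set of drought years with strongly reduced seepage.
#'
#' Two noise levels are distinguished. `annual_flux_cv` perturbs the annual
#' flux of each compartment/species around its configured trend
#' (lognormal, mean 1); `concentration_cv` scatters the per-period
#' concentrations within a year. Period concentrations are always rescaled
#' so that their water-weighted sum reproduces the (noisy) annual flux
#' exactly; with both CVs zero the realized annual fluxes equal the
#' configured trend to floating-point precision.
#'
#' @param start_year,end_year Calendar span (inclusive), `end_year > start_year`.
#' @param sampling_interval_days Sampling-period length in days (default 14).
#'   Periods restart on 1 January, the last period of a year is truncated at
#'   31 December.
#' @param trends Tibble with columns `compartment`, `species`, `flux_start`,
#'   `flux_end` (mmol_IE m^-2 yr^-1) and `shape` (`"linear"` or
#'   `"exponential"` decay/growth between the endpoints).
#' @param concentration_cv Relative per-period concentration noise (lognormal).
#' @param annual_flux_cv Named vector of relative annual flux noise per
#'   compartment.
#' @param annual_precip_mean_mm,annual_precip_cv Mean and relative SD of
#'   annual bulk precipitation (lognormal across years).
#' @param throughfall_fraction Fraction of bulk water reaching the forest
#'   floor (canopy interception remainder).
#' @param seepage_fraction_normal,seepage_fraction_dry Fraction of bulk
#'   precipitation leaving the rooting zone as seepage in normal and in dry
#'   years.
#' @param dry_years Calendar years treated as drought years (reduced
#'   precipitation and strongly reduced seepage).
#' @param dry_precip_factor Multiplier on annual precipitation in dry years.
#' @param ph_bulk,ph_throughfall,ph_seepage Length-2 vectors `(start, end)`;
#'   pH interpolates linearly between them over the span.
#' @param ph_noise_sd Additive Gaussian noise on per-period pH.
#' @param seepage_cation_weights Named weights splitting the non-H+ cation
#'   charge among seepage cations; normalized to sum to 1. Seepage is
#'   constructed charge-balanced: cation equivalents (incl. H+ from pH)
#'   equal the anion equivalents each year.
#' @param correlated_bulk_throughfall If `TRUE`, bulk and throughfall use
#'   the same noise stream, so shared species receive identical noise
#'   realizations (the collectors stand 1 km apart in the emulated design;
#'   whether their sampling noise is correlated is a modelling choice).
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   dataset.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(start_year = 1985,
                            end_year = 2020,
                            sampling_interval_days = 14,
                            trends = default_trends(),
                            concentration_cv = 0.25,
                            annual_flux_cv = c(bulk = 0.12,
                                               throughfall = 0.12,
                                               seepage40 = 0.30),
                            annual_precip_mean_mm = 752,
                            annual_precip_cv = 0.18,
                            throughfall_fraction = 0.75,
                            seepage_fraction_normal = 0.35,
                            seepage_fraction_dry = 0.10,
                            dry_years = c(1997, 2003, 2018, 2019, 2020),
                            dry_precip_factor = 0.75,
                            ph_bulk = c(4.5, 5.2),
                            ph_throughfall = c(4.6, 5.9),
                            ph_seepage = c(4.55, 4.70),
                            ph_noise_sd = 0.08,
                            seepage_cation_weights = c(Al = 0.45, Ca = 0.27,
                                                       Mg = 0.12, K = 0.07,
                                                       Na = 0.09),
                            correlated_bulk_throughfall = FALSE,
                            seed = 1L) {
  if (missing(dry_years)) {
    # the default drought years only apply where the span covers them
    dry_years <- dry_years[dry_years >= start_year & dry_years <= end_year]
  }
  cfg <- list(
    start_year = as.integer(start_year),
    end_year = as.integer(end_year),
    sampling_interval_days = as.integer(sampling_interval_days),
    trends = tibble::as_tibble(trends),
    concentration_cv = concentration_cv,
    annual_flux_cv = annual_flux_cv,
    annual_precip_mean_mm = annual_precip_mean_mm,
    annual_precip_cv = annual_precip_cv,
    throughfall_fraction = throughfall_fraction,
    seepage_fraction_normal = seepage_fraction_normal,
    seepage_fraction_dry = seepage_fraction_dry,
    dry_years = as.integer(dry_years),
    dry_precip_factor = dry_precip_factor,
    ph_bulk = ph_bulk,
    ph_throughfall = ph_throughfall,
    ph_seepage = ph_seepage,
    ph_noise_sd = ph_noise_sd,
    seepage_cation_weights = seepage_cation_weights /
      sum(seepage_cation_weights),
    correlated_bulk_throughfall = isTRUE(correlated_bulk_throughfall),
    seed = as.integer(seed)
  )
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

#' Default flux trends of the synthetic scenario
#'
#' Annual charge-equivalent fluxes (mmol_IE m^-2 yr^-1) at the start and
#' end of the span per compartment and species, with the interpolation
#' shape between them. Throughfall sulfate falls from 160 to 10 and
#' ammonium from 150 to 70 (exponential decay), nitrate stays roughly flat
#' (70 to 60); seepage nitrate drifts upward with large configured
#' inter-annual noise on top.
#'
#' @return A tibble with columns `compartment`, `species`, `flux_start`,
#'   `flux_end`, `shape`.
#' @export
default_trends <- function() {
  tibble::tribble(
    ~compartment,   ~species, ~flux_start, ~flux_end, ~shape,
    "bulk",         "SO4",             60,        10, "exponential",
    "bulk",         "NH4",             40,        30, "linear",
    "bulk",         "NO3",             40,        20, "linear",
    "bulk",         "Cl",              20,        12, "linear",
    "throughfall",  "SO4",            160,        10, "exponential",
    "throughfall",  "NH4",            150,        70, "exponential",
    "throughfall",  "NO3",             70,        60, "linear",
    "throughfall",  "Cl",              30,        20, "linear",
    "seepage40",    "SO4",            150,        40, "linear",
    "seepage40",    "NO3",            150,       250, "linear",
    "seepage40",    "NH4",              5,         5, "linear",
    "seepage40",    "Cl",              45,        30, "linear"
  )
}

validate_scenario_config <- function(cfg) {
  if (cfg$end_year <= cfg$start_year) abort("end_year must exceed start_year")
  if (cfg$sampling_interval_days < 1) abort("sampling_interval_days must be >= 1")
  tr <- cfg$trends
  needed <- c("compartment", "species", "flux_start", "flux_end", "shape")
  if (!all(needed %in% names(tr))) {
    abort("trends must have columns compartment, species, flux_start, flux_end, shape")
  }
  if (!all(tr$compartment %in% COMPARTMENTS)) {
    abort(paste0("unknown compartment in trends; expected one of: ",
                 paste(COMPARTMENTS, collapse = ", ")))
  }
  if (!all(tr$shape %in% c("linear", "exponential"))) {
    abort("trend shape must be 'linear' or 'exponential'")
  }
  if (any(tr$flux_start < 0 | tr$flux_end < 0)) abort("trend fluxes must be >= 0")
  if (any(tr$shape == "exponential" & (tr$flux_start <= 0 | tr$flux_end <= 0))) {
    abort("exponential trends need strictly positive endpoints")
  }
  fracs <- c(cfg$throughfall_fraction, cfg$seepage_fraction_normal,
             cfg$seepage_fraction_dry, cfg$dry_precip_factor)
  if (any(fracs <= 0 | fracs > 1)) abort("fractions must lie in (0, 1]")
  cvs <- c(cfg$concentration_cv, cfg$annual_flux_cv, cfg$annual_precip_cv,
           cfg$ph_noise_sd)
  if (any(cvs < 0)) abort("noise parameters must be >= 0")
  if (!all(COMPARTMENTS %in% names(cfg$annual_flux_cv))) {
    abort("annual_flux_cv must be named for every compartment")
  }
  if (length(cfg$dry_years) > 0 &&
      (any(cfg$dry_years < cfg$start_year) || any(cfg$dry_years > cfg$end_year))) {
    abort("dry_years must fall within the scenario span")
  }
  for (ph in list(cfg$ph_bulk, cfg$ph_throughfall, cfg$ph_seepage)) {
    if (length(ph) != 2 || any(ph <= 0) || any(ph >= 14)) {
      abort("pH endpoints must be length 2 and lie strictly within (0, 14)")
    }
  }
  invisible(cfg)
}

## interpolate a trend over n_years years
trend_values <- function(flux_start, flux_end, shape, n_years) {
  t <- seq(0, 1, length.out = n_years)
  if (shape == "linear") {
    flux_start + (flux_end - flux_start) * t
  } else {
    flux_start * (flux_end / flux_start)^t
  }
}

## lognormal multipliers with mean 1 and relative SD cv
lognormal_multipliers <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

year_of <- function(dates) as.integer(format(dates, "%Y"))

## biweekly (or other interval) periods restarting each 1 January
build_periods <- function(start_year, end_year, interval) {
  purrr::map_dfr(start_year:end_year, function(y) {
    first <- as.Date(sprintf("%d-01-01", y))
    last <- as.Date(sprintf("%d-12-31", y))
    starts <- seq(first, last, by = interval)
    tibble::tibble(
      period_start = starts,
      period_end = c(starts[-1] - 1, last)
    )
  })
}

## daily water fluxes for the three compartments; seeded sub-stream
generate_water <- function(cfg, stream_seed) {
  set.seed(stream_seed)
  years <- cfg$start_year:cfg$end_year
  annual_precip <- cfg$annual_precip_mean_mm *
    lognormal_multipliers(length(years), cfg$annual_precip_cv)
  dry <- years %in% cfg$dry_years
  annual_precip[dry] <- annual_precip[dry] * cfg$dry_precip_factor

  purrr::map2_dfr(years, annual_precip, function(y, precip) {
    dates <- seq(as.Date(sprintf("%d-01-01", y)),
                 as.Date(sprintf("%d-12-31", y)), by = 1)
    nd <- length(dates)
    ## skewed daily pattern: many near-dry days, a few wet ones
    w_rain <- rgamma(nd, shape = 0.3)
    w_rain <- w_rain / sum(w_rain)
    ## seepage drains more smoothly than rain falls
    w_seep <- rgamma(nd, shape = 5)
    w_seep <- w_seep / sum(w_seep)
    seep_frac <- if (y %in% cfg$dry_years) cfg$seepage_fraction_dry else
      cfg$seepage_fraction_normal
    dplyr::bind_rows(
      tibble::tibble(date = dates, compartment = "bulk",
                     water_mm = precip * w_rain),
      tibble::tibble(date = dates, compartment = "throughfall",
                     water_mm = precip * cfg$throughfall_fraction * w_rain),
      tibble::tibble(date = dates, compartment = "seepage40",
                     water_mm = precip * seep_frac * w_seep)
    )
  })
}

## water-flux sum per sampling period for one compartment
period_water_totals <- function(water_one, periods) {
  idx <- findInterval(as.integer(water_one$date),
                      as.integer(periods$period_start))
  totals <- vapply(seq_len(nrow(periods)), function(i) {
    sum(water_one$water_mm[idx == i])
  }, numeric(1))
  dplyr::mutate(periods, water_l_m2 = totals,
                year = year_of(.data$period_start))
}

## per-period concentrations for one species in one compartment:
## lognormal scatter rescaled so period fluxes sum to the annual truth
species_concentrations <- function(flux_truth_by_year, pw, concentration_cv) {
  z <- lognormal_multipliers(nrow(pw), concentration_cv)
  conc <- numeric(nrow(pw))
  for (i in seq_along(flux_truth_by_year)) {
    yr <- as.integer(names(flux_truth_by_year)[i])
    in_year <- pw$year == yr
    f <- flux_truth_by_year[[i]]
    denom <- sum(z[in_year] * pw$water_l_m2[in_year])
    conc[in_year] <- if (f <= 0 || denom <= 0) 0 else
      1000 * f * z[in_year] / denom
  }
  conc
}

## chemistry + truth for one compartment (one seeded stream per compartment)
generate_compartment_chemistry <- function(cfg, compartment, pw, stream_seed) {
  set.seed(stream_seed)
  years <- cfg$start_year:cfg$end_year
  n_years <- length(years)
  dry_ratio <- cfg$seepage_fraction_dry / cfg$seepage_fraction_normal
  acv <- cfg$annual_flux_cv[[compartment]]

  trows <- dplyr::arrange(
    dplyr::filter(cfg$trends, .data$compartment == !!compartment),
    .data$species
  )

  chem <- list()
  truth <- list()
  for (k in seq_len(nrow(trows))) {
    tr <- trows[k, ]
    flux_config <- trend_values(tr$flux_start, tr$flux_end, tr$shape, n_years)
    if (compartment == "seepage40") {
      flux_config[years %in% cfg$dry_years] <-
        flux_config[years %in% cfg$dry_years] * dry_ratio
    }
    flux_truth <- flux_config * lognormal_multipliers(n_years, acv)
    names(flux_truth) <- years
    conc <- species_concentrations(flux_truth, pw, cfg$concentration_cv)
    chem[[k]] <- tibble::tibble(
      period_start = pw$period_start, period_end = pw$period_end,
      compartment = compartment, species = tr$species,
      concentration_ueq_per_L = conc
    )
    truth[[k]] <- tibble::tibble(
      year = years, compartment = compartment, species = tr$species,
      flux_config = flux_config, flux_truth = unname(flux_truth)
    )
  }

  ## period pH: linear drift over the span plus measurement noise
  ph_range <- switch(compartment,
    bulk = cfg$ph_bulk, throughfall = cfg$ph_throughfall,
    seepage40 = cfg$ph_seepage)
  frac <- (pw$year - cfg$start_year) / (n_years - 1)
  ph <- ph_range[1] + (ph_range[2] - ph_range[1]) * frac
  if (cfg$ph_noise_sd > 0) ph <- ph + rnorm(nrow(pw), 0, cfg$ph_noise_sd)
  ph <- pmin(pmax(ph, 2.5), 9.5)

  h_conc <- 10^(6 - ph)
  chem$H <- tibble::tibble(
    period_start = pw$period_start, period_end = pw$period_end,
    compartment = compartment, species = "H",
    concentration_ueq_per_L = h_conc
  )

  if (compartment == "seepage40") {
    ## construct seepage charge-balanced at the annual scale: the anion
    ## equivalents are matched by H+ (from pH) plus the base/metal cations
    truth_tbl <- dplyr::bind_rows(truth)
    reg <- default_species()
    anions <- reg$name[reg$charge < 0]
    anion_total <- truth_tbl |>
      dplyr::filter(.data$species %in% anions) |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(total = sum(.data$flux_truth), .groups = "drop")
    trended_cations <- truth_tbl |>
      dplyr::filter(!.data$species %in% anions) |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(trended = sum(.data$flux_truth), .groups = "drop")
    h_flux <- tibble::tibble(year = pw$year,
                             f = h_conc * pw$water_l_m2 * 1e-3) |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(h = sum(.data$f), .groups = "drop")
    cat_total <- anion_total |>
      dplyr::left_join(h_flux, by = "year") |>
      dplyr::left_join(trended_cations, by = "year") |>
      dplyr::mutate(rest = pmax(.data$total - .data$h -
                                  dplyr::coalesce(.data$trended, 0), 0))
    weights <- cfg$seepage_cation_weights
    for (cat_name in sort(names(weights))) {
      flux_truth <- setNames(cat_total$rest * weights[[cat_name]],
                             cat_total$year)
      conc <- species_concentrations(flux_truth, pw, cfg$concentration_cv)
      chem[[paste0("cat_", cat_name)]] <- tibble::tibble(
        period_start = pw$period_start, period_end = pw$period_end,
        compartment = compartment, species = cat_name,
        concentration_ueq_per_L = conc
      )
      truth[[paste0("cat_", cat_name)]] <- tibble::tibble(
        year = cat_total$year, compartment = compartment, species = cat_name,
        flux_config = unname(flux_truth), flux_truth = unname(flux_truth)
      )
    }
  }

  chem_tbl <- dplyr::bind_rows(chem)
  ph_tbl <- tibble::tibble(period_start = pw$period_start, ph_value = ph)
  chem_tbl <- dplyr::left_join(chem_tbl, ph_tbl, by = "period_start") |>
    dplyr::rename(pH = "ph_value")
  list(chemistry = chem_tbl, truth = dplyr::bind_rows(truth))
}

#' Generate a synthetic monitoring dataset
#'
#' Produces sampling-period solution chemistry (concentrations in
#' ueq L^-1 plus pH) and daily water fluxes for the three compartments,
#' together with the ground-truth annual fluxes the chemistry was
#' constructed from. Per-period concentrations are rescaled so that their
#' water-weighted sum reproduces the (noisy) annual flux exactly, which
#' makes downstream flux aggregation exactly invertible on noise-free
#' configurations. H+ concentrations are derived from the period pH, and
#' seepage is constructed charge-balanced at the annual scale.
#'
#' One random sub-stream is drawn per compartment plus one for water, all
#' derived from `config$seed`, so the same (config, seed) pair yields a
#' bit-identical dataset.
#'
#' @param config A [scenario_config()].
#' @param registry Species registry used to classify charges.
#' @return An object of class `monitoring_dataset`: a list with tibbles
#'   `chemistry` (`period_start`, `period_end`, `compartment`, `species`,
#'   `concentration_ueq_per_L`, `pH`), `water` (`date`, `compartment`,
#'   `water_mm`), `truth` (`year`, `compartment`, `species`, `flux_config`,
#'   `flux_truth` in mmol_IE m^-2 yr^-1) and the `config`.
#' @export
#' @examples
#' ds <- generate_scenario(scenario_config(start_year = 2000, end_year = 2005))
#' head(ds$chemistry)
generate_scenario <- function(config, registry = default_species()) {
  stopifnot(inherits(config, "scenario_config"))
  validate_scenario_config(config)
  unknown <- setdiff(unique(config$trends$species), registry$name)
  if (length(unknown) > 0) {
    abort(paste0("trend species not in registry: ",
                 paste(unknown, collapse = ", ")))
  }

  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 4)
  names(sub_seeds) <- c("water", "bulk", "throughfall", "seepage40")
  if (config$correlated_bulk_throughfall) {
    sub_seeds[["throughfall"]] <- sub_seeds[["bulk"]]
  }

  water <- generate_water(config, sub_seeds[["water"]])
  periods <- build_periods(config$start_year, config$end_year,
                           config$sampling_interval_days)

  parts <- purrr::map(COMPARTMENTS, function(cp) {
    pw <- period_water_totals(water[water$compartment == cp, ], periods)
    generate_compartment_chemistry(config, cp, pw, sub_seeds[[cp]])
  })

  structure(
    list(
      chemistry = dplyr::bind_rows(purrr::map(parts, "chemistry")),
      water = water,
      truth = dplyr::bind_rows(purrr::map(parts, "truth")),
      config = config
    ),
    class = "monitoring_dataset"
  )
}

#' @export
print.monitoring_dataset <- function(x, ...) {
  cfg <- x$config
  cat("<monitoring_dataset> ", cfg$start_year, "-", cfg$end_year,
      ", ", nrow(x$chemistry), " chemistry records, ",
      nrow(x$water), " water-flux days\n", sep = "")
  invisible(x)
}

#' Scale seepage water fluxes in selected drought years
#'
#' Multiplies the daily seepage water fluxes of the listed years by
#' `seepage_multiplier`, leaving the chemistry untouched. Because period
#' ion fluxes are concentration times water, the annual seepage ion flux
#' of an affected year scales by exactly the same factor when
#' concentrations are held fixed; the stored ground truth is rescaled
#' accordingly so the dataset stays self-consistent.
#'
#' @param dataset A `monitoring_dataset`.
#' @param years Calendar years to scale; must lie within the dataset span.
#' @param seepage_multiplier Multiplier in `[0, 1)`; 1 would be a no-op and
#'   is rejected.
#' @return The modified `monitoring_dataset`.
#' @export
inject_dry_years <- function(dataset, years, seepage_multiplier) {
  stopifnot(inherits(dataset, "monitoring_dataset"))
  if (seepage_multiplier < 0 || seepage_multiplier >= 1) {
    abort("seepage_multiplier must lie in [0, 1)")
  }
  span <- range(year_of(dataset$water$date))
  if (any(years < span[1]) || any(years > span[2])) {
    abort("years outside the dataset span")
  }
  hit_w <- dataset$water$compartment == "seepage40" &
    year_of(dataset$water$date) %in% years
  dataset$water$water_mm[hit_w] <-
    dataset$water$water_mm[hit_w] * seepage_multiplier
  hit_t <- dataset$truth$compartment == "seepage40" &
    dataset$truth$year %in% years
  dataset$truth$flux_truth[hit_t] <-
    dataset$truth$flux_truth[hit_t] * seepage_multiplier
  dataset$truth$flux_config[hit_t] <-
    dataset$truth$flux_config[hit_t] * seepage_multiplier
  dataset
}

#' Generate an annual emission series from piecewise-linear nodes
#'
#' Interpolates per-gas `(year, Gmol)` nodes linearly onto the integer
#' years between the first and last node of each gas; a single node yields
#' a single constant value. This is the synthetic stand-in for a national
#' emission inventory with break points (e.g. a sharp decline around 1990).
#'
#' @param nodes Tibble with columns `gas`, `year`, `amount_gmol`; the years
#'   of each gas must be strictly increasing.
#' @param source Source tag attached to the output (default `"synthetic"`).
#' @return An emission series tibble (`year`, `gas`, `amount_gmol`, `source`).
#' @export
#' @examples
#' generate_emission_series(tibble::tibble(
#'   gas = "SO2", year = c(1890, 1950, 1970), amount_gmol = c(20, 63, 124)))
generate_emission_series <- function(nodes, source = "synthetic") {
  nodes <- tibble::as_tibble(nodes)
  needed <- c("gas", "year", "amount_gmol")
  if (!all(needed %in% names(nodes))) {
    abort("nodes must have columns gas, year, amount_gmol")
  }
  if (any(nodes$amount_gmol < 0)) abort("amounts must be >= 0")
  nodes |>
    dplyr::group_by(.data$gas) |>
    dplyr::group_modify(function(df, key) {
      if (is.unsorted(df$year, strictly = TRUE)) {
        abort(paste0("nodes for gas '", key$gas,
                     "' must have strictly increasing years"))
      }
      if (nrow(df) == 1) {
        return(tibble::tibble(year = df$year, amount_gmol = df$amount_gmol))
      }
      yrs <- seq(min(df$year), max(df$year))
      tibble::tibble(
        year = yrs,
        amount_gmol = approx(df$year, df$amount_gmol, xout = yrs)$y
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(source = source) |>
    dplyr::select("year", "gas", "amount_gmol", "source") |>
    dplyr::arrange(.data$gas, .data$year)
}

#' Default emission-inventory nodes for the synthetic scenario
#'
#' Piecewise-linear nodes (Gmol yr^-1) sketching the historical German
#' emission record: SO2 rising from about 20 Gmol (1890) through 63 Gmol
#' (1950) to a 124 Gmol plateau (1970-1987) followed by a steep decline;
#' NOx rising from about 27 Gmol (1950) to 82 Gmol (1986) then falling;
#' NH3 peaking in the late 1980s and settling near 36 Gmol.
#'
#' @return A node tibble for [generate_emission_series()].
#' @export
default_emission_nodes <- function() {
  tibble::tribble(
    ~gas,  ~year, ~amount_gmol,
    "SO2",  1890,          20,
    "SO2",  1950,          63,
    "SO2",  1970,         124,
    "SO2",  1987,         124,
    "SO2",  2000,          20,
    "SO2",  2020,           4,
    "NOx",  1890,           5,
    "NOx",  1950,          27,
    "NOx",  1986,          82,
    "NOx",  1990,          78,
    "NOx",  2020,          25,
    "NH3",  1890,          15,
    "NH3",  1988,          55,
    "NH3",  1991,          36,
    "NH3",  2017,          36,
    "NH3",  2020,          33
  )
}
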