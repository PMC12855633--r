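#' Ion flux of one sampling period
#'
#' The flux of a sampling period is the mean solution concentration of the
#' period multiplied by the summed daily water fluxes of that period:
#' \eqn{F = c \cdot \sum_d q_d \cdot 10^{-3}} mmol_IE m^-2, with the
#' concentration in umol_IE L^-1 (= ueq L^-1) and daily water fluxes in mm
#' (1 mm = 1 L m^-2). The operation is linear in both arguments.
#'
#' @param mean_concentration Mean concentration over the period, ueq L^-1.
#' @param daily_water_fluxes Numeric vector of daily water fluxes in mm.
#' @return Period flux in mmol_IE m^-2.
#' @export
#' @examples
#' period_flux(100, rep(2, 14)) # 2.8
period_flux <- function(mean_concentration, daily_water_fluxes) {
  if (any(mean_concentration < 0)) abort("concentration must be >= 0")
  if (length(daily_water_fluxes) == 0) abort("period has no water-flux days")
  if (any(daily_water_fluxes < 0)) abort("water fluxes must be >= 0")
  mean_concentration * sum(daily_water_fluxes) * 1e-3
}

## fill missing period concentrations by linear interpolation in time
## (period midpoints) within compartment x species; endpoints take the
## nearest observed value
interpolate_concentrations <- function(chem) {
  chem <- dplyr::mutate(
    chem,
    .mid = as.numeric(.data$period_start) +
      (as.numeric(.data$period_end) - as.numeric(.data$period_start)) / 2,
    interpolated = is.na(.data$concentration_ueq_per_L)
  )
  chem |>
    dplyr::group_by(.data$compartment, .data$species) |>
    dplyr::group_modify(function(df, key) {
      ok <- !df$interpolated
      if (!any(ok)) {
        abort(paste0("no non-missing concentrations for ",
                     key$compartment, "/", key$species))
      }
      if (any(!ok)) {
        if (sum(ok) == 1) {
          df$concentration_ueq_per_L[!ok] <- df$concentration_ueq_per_L[ok]
        } else {
          df$concentration_ueq_per_L[!ok] <- approx(
            df$.mid[ok], df$concentration_ueq_per_L[ok],
            xout = df$.mid[!ok], rule = 2
          )$y
        }
      }
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-".mid")
}

#' Annual ion fluxes from period chemistry and daily water fluxes
#'
#' Computes, for every calendar year, compartment and species, the annual
#' flux in mmol_IE m^-2 yr^-1 as the sum of the period fluxes
#' (concentration x period water). Periods spanning a year boundary are
#' split pro-rata by the water flux falling into each year, which keeps
#' the annual fluxes exactly additive over periods. Missing period
#' concentrations are filled by linear interpolation in time between
#' neighbouring periods of the same compartment and species (nearest value
#' at the series ends); the water-weighted share of interpolated periods
#' is reported per year, and years above `low_confidence_fraction` are
#' flagged.
#'
#' @param x A `monitoring_dataset`, or a chemistry tibble (see
#'   [generate_scenario()] for the schema) when `water` is supplied.
#' @param water Daily water-flux tibble (`date`, `compartment`,
#'   `water_mm`); ignored when `x` is a `monitoring_dataset`.
#' @param low_confidence_fraction Years whose interpolated water-weighted
#'   coverage exceeds this fraction are flagged (default 0.25).
#' @return A tibble with columns `year`, `compartment`, `species`,
#'   `flux_mmol_ie_m2`, `n_periods`, `interpolated_fraction`,
#'   `low_confidence`.
#' @export
annual_fluxes <- function(x, water = NULL, low_confidence_fraction = 0.25) {
  if (inherits(x, "monitoring_dataset")) {
    chem <- x$chemistry
    water <- x$water
  } else {
    chem <- tibble::as_tibble(x)
    if (is.null(water)) abort("water fluxes required")
  }
  if (any(chem$period_end < chem$period_start)) {
    abort("period_end before period_start")
  }
  if (any(water$water_mm < 0)) abort("water fluxes must be >= 0")
  chem <- interpolate_concentrations(chem)
  if (any(chem$concentration_ueq_per_L < 0)) {
    abort("concentrations must be >= 0")
  }

  water <- dplyr::mutate(water, year = year_of(.data$date))

  ## water per (compartment, period, year): computed once per distinct
  ## period, then joined to all species sharing it
  periods <- dplyr::distinct(chem, .data$compartment, .data$period_start,
                             .data$period_end)
  period_year_water <- periods |>
    dplyr::group_by(.data$compartment) |>
    dplyr::group_modify(function(df, key) {
      w <- water[water$compartment == key$compartment, ]
      df <- dplyr::arrange(df, .data$period_start)
      if (nrow(df) > 1 &&
          any(df$period_start[-1] != df$period_end[-nrow(df)] + 1)) {
        abort(paste0("sampling periods for ", key$compartment,
                     " are not contiguous"))
      }
      idx <- findInterval(as.integer(w$date), as.integer(df$period_start))
      keep <- idx >= 1 & as.integer(w$date) <=
        as.integer(df$period_end)[pmax(idx, 1)]
      tibble::tibble(
        period_start = df$period_start[idx[keep]],
        period_end = df$period_end[idx[keep]],
        year = w$year[keep],
        water_l_m2 = w$water_mm[keep]
      ) |>
        dplyr::group_by(.data$period_start, .data$period_end, .data$year) |>
        dplyr::summarise(water_l_m2 = sum(.data$water_l_m2), .groups = "drop")
    }) |>
    dplyr::ungroup()

  chem |>
    dplyr::inner_join(period_year_water,
                      by = c("compartment", "period_start", "period_end"),
                      relationship = "many-to-many") |>
    dplyr::mutate(flux = .data$concentration_ueq_per_L *
                    .data$water_l_m2 * 1e-3) |>
    dplyr::group_by(.data$year, .data$compartment, .data$species) |>
    dplyr::summarise(
      flux_mmol_ie_m2 = sum(.data$flux),
      n_periods = dplyr::n(),
      interpolated_fraction = if (sum(.data$water_l_m2) > 0) {
        sum(.data$water_l_m2[.data$interpolated]) / sum(.data$water_l_m2)
      } else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(low_confidence =
                    .data$interpolated_fraction > low_confidence_fraction) |>
    dplyr::arrange(.data$year, .data$compartment, .data$species)
}

#' Dry-deposition estimate as throughfall minus bulk flux
#'
#' For ions with negligible canopy exchange (sulfate in particular), the
#' difference between the throughfall flux and the bulk-precipitation flux
#' estimates dry deposition to the canopy. Negative differences are
#' reported as-is and flagged.
#'
#' @param table An annual flux table from [annual_fluxes()].
#' @param species Species name (default `"SO4"`).
#' @return A tibble `year`, `species`, `throughfall`, `bulk`,
#'   `dry_deposition`, `negative`.
#' @export
dry_deposition_estimate <- function(table, species = "SO4") {
  sel <- dplyr::filter(table, .data$species == !!species,
                       .data$compartment %in% c("bulk", "throughfall"))
  wide <- tidyr::pivot_wider(
    dplyr::select(sel, "year", "compartment", "flux_mmol_ie_m2"),
    names_from = "compartment", values_from = "flux_mmol_ie_m2"
  )
  if (!all(c("bulk", "throughfall") %in% names(wide)) ||
      anyNA(wide[c("bulk", "throughfall")])) {
    abort(paste0("both bulk and throughfall fluxes required for ", species))
  }
  wide |>
    dplyr::transmute(
      year = .data$year, species = !!species,
      throughfall = .data$throughfall, bulk = .data$bulk,
      dry_deposition = .data$throughfall - .data$bulk,
      negative = .data$dry_deposition < 0
    ) |>
    dplyr::arrange(.data$year)
}

#' Cation/anion balance of one compartment-year
#'
#' Sums cation and anion fluxes (in mmol_IE, so the sums are directly
#' comparable as charge) for one year and compartment, reports the
#' relative imbalance `(cations - anions) / mean(cations, anions)` and each
#' cation's share of the cation sum (for leachate, aluminium typically
#' dominates in acid forest soils).
#'
#' @param table An annual flux table from [annual_fluxes()].
#' @param year Calendar year.
#' @param compartment Compartment name.
#' @param registry Species registry supplying the charge signs.
#' @return A list with `cation_sum`, `anion_sum`, `relative_imbalance` and
#'   a tibble `cation_shares` (`species`, `flux`, `share`).
#' @export
cation_anion_balance <- function(table, year, compartment,
                                 registry = default_species()) {
  sel <- dplyr::filter(table, .data$year == !!year,
                       .data$compartment == !!compartment)
  if (nrow(sel) == 0) abort("no fluxes for that year/compartment")
  sel <- dplyr::inner_join(sel, registry[c("name", "charge")],
                           by = c(species = "name"))
  cations <- dplyr::filter(sel, .data$charge > 0)
  anions <- dplyr::filter(sel, .data$charge < 0)
  if (nrow(cations) == 0 || nrow(anions) == 0) {
    abort("both cations and anions are required for a charge balance")
  }
  cat_sum <- sum(cations$flux_mmol_ie_m2)
  an_sum <- sum(anions$flux_mmol_ie_m2)
  list(
    cation_sum = cat_sum,
    anion_sum = an_sum,
    relative_imbalance = (cat_sum - an_sum) / ((cat_sum + an_sum) / 2),
    cation_shares = cations |>
      dplyr::transmute(species = .data$species,
                       flux = .data$flux_mmol_ie_m2,
                       share = .data$flux / cat_sum) |>
      dplyr::arrange(dplyr::desc(.data$share))
  )
}
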