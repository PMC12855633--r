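#' Proton load from nitrogen transformations
#'
#' Net proton production of the topsoil caused by nitrogen turnover,
#' derived from the ammonium and nitrate fluxes entering with throughfall
#' and leaving with seepage. The stoichiometric rules are: one proton is
#' consumed per nitrate removed (plant uptake, denitrification); one
#' proton is consumed per ammonium formed (ammonification); one proton is
#' released per ammonium removed (plant uptake or nitrification); and one
#' additional proton is released per nitrate formed from ammonium
#' (nitrification releases two in total). For any set of non-negative
#' process rates consistent with the flux mass balances, the rule-level sum
#' collapses to the closed form
#' \deqn{L = (NH_4^{in} - NH_4^{out}) + (NO_3^{out} - NO_3^{in})}
#' which is what this function computes. Negative values (net proton
#' consumption) are returned as-is.
#'
#' @param nh4_in,no3_in Throughfall fluxes, mmol_IE m^-2 yr^-1.
#' @param nh4_out,no3_out Seepage fluxes, mmol_IE m^-2 yr^-1.
#' @return Net proton load in mmol_IE m^-2 yr^-1 (vectorized).
#' @export
#' @examples
#' n_transformation_proton_load(150, 0, 70, 300) # 380
n_transformation_proton_load <- function(nh4_in, nh4_out, no3_in, no3_out) {
  if (any(c(nh4_in, nh4_out, no3_in, no3_out) < 0)) {
    abort("fluxes must be non-negative")
  }
  (nh4_in - nh4_out) + (no3_out - no3_in)
}

#' Annual proton budget of the topsoil
#'
#' Assembles, per year, the direct proton input with throughfall, the
#' proton load from nitrogen transformations
#' ([n_transformation_proton_load()]), their sum (the total load), the
#' proton output with seepage at 40 cm, and the percentage of the load
#' buffered within the topsoil:
#' `buffered = 100 * (total_load - seepage_output) / total_load`.
#'
#' @param table An annual flux table from [annual_fluxes()] containing H,
#'   NH4 and NO3 for the throughfall and seepage40 compartments.
#' @param years Years to include (default: all years in the table).
#' @return A tibble with columns `year`, `direct_input`,
#'   `n_transformation_load`, `total_load`, `seepage_output`,
#'   `buffered_percent`.
#' @export
proton_budget <- function(table, years = NULL) {
  need <- tidyr::expand_grid(
    compartment = c("throughfall", "seepage40"),
    species = c("H", "NH4", "NO3")
  )
  sel <- dplyr::semi_join(table, need, by = c("compartment", "species"))
  if (!is.null(years)) sel <- dplyr::filter(sel, .data$year %in% years)
  wide <- sel |>
    dplyr::select("year", "compartment", "species", "flux_mmol_ie_m2") |>
    tidyr::pivot_wider(names_from = c("compartment", "species"),
                       values_from = "flux_mmol_ie_m2")
  need_cols <- c("throughfall_H", "throughfall_NH4", "throughfall_NO3",
                 "seepage40_H", "seepage40_NH4", "seepage40_NO3")
  missing <- setdiff(need_cols, names(wide))
  if (length(missing) > 0 || anyNA(wide[need_cols])) {
    abort(paste0("proton budget needs H, NH4 and NO3 fluxes for ",
                 "throughfall and seepage40",
                 if (length(missing) > 0)
                   paste0("; missing: ", paste(missing, collapse = ", "))))
  }
  wide |>
    dplyr::transmute(
      year = .data$year,
      direct_input = .data$throughfall_H,
      n_transformation_load = n_transformation_proton_load(
        .data$throughfall_NH4, .data$seepage40_NH4,
        .data$throughfall_NO3, .data$seepage40_NO3
      ),
      total_load = .data$direct_input + .data$n_transformation_load,
      seepage_output = .data$seepage40_H,
      buffered_percent = dplyr::if_else(
        .data$total_load > 0,
        100 * (.data$total_load - .data$seepage_output) / .data$total_load,
        NA_real_
      )
    ) |>
    dplyr::arrange(.data$year)
}

#' Annual topsoil sulfur balance
#'
#' The change in topsoil S storage of a year, estimated as sulfate input
#' to the soil with throughfall minus sulfate output with seepage at
#' 40 cm, in mmol_IE m^-2. Negative values indicate a net loss of soil
#' sulfur; tree uptake and litterfall are neglected by default (they
#' roughly compensate in the long term) but a constant net-uptake term can
#' be subtracted.
#'
#' @param table An annual flux table from [annual_fluxes()].
#' @param years Years to include (default: all).
#' @param uptake_ie Optional constant net tree S uptake to subtract from
#'   the input, mmol_IE m^-2 yr^-1 (default 0).
#' @return A tibble `year`, `input`, `output`, `delta_ie`.
#' @export
annual_s_balance <- function(table, years = NULL, uptake_ie = 0) {
  sel <- dplyr::filter(table, .data$species == "SO4",
                       .data$compartment %in% c("throughfall", "seepage40"))
  if (!is.null(years)) sel <- dplyr::filter(sel, .data$year %in% years)
  wide <- tidyr::pivot_wider(
    dplyr::select(sel, "year", "compartment", "flux_mmol_ie_m2"),
    names_from = "compartment", values_from = "flux_mmol_ie_m2"
  )
  if (!all(c("throughfall", "seepage40") %in% names(wide)) ||
      anyNA(wide[c("throughfall", "seepage40")])) {
    abort("SO4 fluxes for throughfall and seepage40 are both required")
  }
  wide |>
    dplyr::transmute(
      year = .data$year,
      input = .data$throughfall,
      output = .data$seepage40,
      delta_ie = .data$throughfall - uptake_ie - .data$seepage40
    ) |>
    dplyr::arrange(.data$year)
}

#' Cumulative sulfur storage trajectory of the topsoil
#'
#' Accumulates annual input-output deltas against an initial topsoil S
#' stock. Fluxes are carried in charge equivalents (mmol_IE m^-2) while
#' stocks are element-molar (mmol S m^-2), so each delta is divided by the
#' sulfate charge (2) before summation. The remaining stock is never
#' clamped; years where it falls below zero are flagged `stock_exhausted`.
#'
#' @param deltas A tibble with columns `year` and `delta_ie` (e.g. from
#'   [annual_s_balance()]).
#' @param initial_stock Initial topsoil stock in mmol element m^-2 (> 0).
#' @param charge Charge-per-element of the carrier ion (2 for sulfate-S).
#' @return A tibble with columns `year`, `delta_ie`, `delta_molar`,
#'   `cumulative_change` (mmol m^-2), `remaining_stock`,
#'   `remaining_fraction` (percent) and `stock_exhausted`.
#' @export
#' @examples
#' tr <- storage_trajectory(
#'   tibble::tibble(year = 1:2, delta_ie = c(-1000, -1012.3)), 2281.3)
#' tr$remaining_fraction[2] # ~11.8
storage_trajectory <- function(deltas, initial_stock, charge = 2) {
  if (initial_stock <= 0) abort("initial_stock must be positive")
  deltas <- dplyr::arrange(tibble::as_tibble(deltas), .data$year)
  deltas |>
    dplyr::mutate(
      delta_molar = .data$delta_ie / abs(charge),
      cumulative_change = cumsum(.data$delta_molar),
      remaining_stock = initial_stock + .data$cumulative_change,
      remaining_fraction = 100 * .data$remaining_stock / initial_stock,
      stock_exhausted = .data$remaining_stock < 0
    )
}

#' Deposition surplus factor relative to stand demand
#'
#' Ratio of an annual deposition flux to the annual nutrient demand of the
#' stand; both arguments must be expressed in the same unit.
#'
#' @param deposition Annual deposition flux.
#' @param demand Annual stand demand (> 0), same unit.
#' @return Dimensionless factor (vectorized).
#' @export
surplus_factor <- function(deposition, demand) {
  if (any(demand <= 0)) abort("demand must be positive")
  deposition / demand
}

#' Livestock units from cattle and pig head counts
#'
#' Standardized animal count weighting species by size; the default
#' coefficients (cattle 1.0, pig 0.16) reproduce published district totals
#' to within one unit.
#'
#' @param cattle,pigs Head counts (non-negative).
#' @param coefficients Named per-head weights, `c(cattle = , pig = )`.
#' @return Livestock units (not rounded).
#' @export
#' @examples
#' livestock_units(1069900, 642540) # ~1172706
livestock_units <- function(cattle, pigs,
                            coefficients = c(cattle = 1.0, pig = 0.16)) {
  if (any(c(cattle, pigs) < 0)) abort("head counts must be non-negative")
  if (any(coefficients <= 0)) abort("coefficients must be positive")
  cattle * coefficients[["cattle"]] + pigs * coefficients[["pig"]]
}
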