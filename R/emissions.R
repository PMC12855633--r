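#' Default gas registry for emission inventories
#'
#' Molar masses used to put emission inventories on a molar basis. NOx is
#' expressed as NO2 (the standard inventory convention); override the
#' table to use a different convention.
#'
#' @return A tibble `gas`, `molar_mass` (g/mol).
#' @export
default_gases <- function() {
  tibble::tribble(
    ~gas,  ~molar_mass,
    "SO2",       64.07,
    "NH3",      17.031,
    "NOx",      46.006
  )
}

#' Convert emission masses to a molar basis
#'
#' Converts kilotonnes per year to gigamoles per year:
#' `Gmol = kt / molar_mass` (1 kt = 1e9 g, 1 Gmol = 1e9 mol). 64.07 kt of
#' SO2 is exactly 1 Gmol.
#'
#' @param amount_kt Emission in kt yr^-1 (non-negative, vectorized).
#' @param gas Gas name(s), recycled against `amount_kt`.
#' @param gases Gas registry, see [default_gases()].
#' @return Emission in Gmol yr^-1.
#' @export
#' @examples
#' mass_to_molar_emissions(64.07, "SO2") # 1
mass_to_molar_emissions <- function(amount_kt, gas, gases = default_gases()) {
  if (any(amount_kt < 0)) abort("amounts must be non-negative")
  m <- gases$molar_mass[match(gas, gases$gas)]
  if (anyNA(m)) {
    abort(paste0("unregistered gas: ",
                 paste(unique(gas[is.na(m)]), collapse = ", ")))
  }
  amount_kt / m
}

#' Splice a historical emission series onto an inventory series
#'
#' Older reconstructions and modern inventories rarely agree in level, so
#' the historical series is standardized to the inventory at the first
#' year both cover: every historical value is multiplied by
#' `inventory(anchor) / historical(anchor)`, historical years before the
#' anchor are kept (scaled) and inventory values are used from the anchor
#' year on. Applying the operation to an already anchored series is a
#' no-op.
#'
#' @param historical,inventory Emission tibbles with columns `year`,
#'   `gas`, `amount_gmol` (a `source` column is preserved if present).
#' @param anchor_year Year present in both series (per gas).
#' @return A combined emission series tibble with a `source` column
#'   tagging scaled-historical vs. inventory rows.
#' @export
harmonize_historical <- function(historical, inventory, anchor_year) {
  historical <- tibble::as_tibble(historical)
  inventory <- tibble::as_tibble(inventory)
  gases <- intersect(unique(historical$gas), unique(inventory$gas))
  if (length(gases) == 0) abort("no shared gases between the series")
  purrr::map_dfr(gases, function(g) {
    h <- historical[historical$gas == g, ]
    v <- inventory[inventory$gas == g, ]
    ha <- h$amount_gmol[h$year == anchor_year]
    va <- v$amount_gmol[v$year == anchor_year]
    if (length(ha) != 1 || length(va) != 1) {
      abort(paste0("anchor year ", anchor_year,
                   " must be present exactly once in both series for ", g))
    }
    if (ha == 0) abort("historical anchor value is zero; cannot scale")
    scale <- va / ha
    dplyr::bind_rows(
      h |>
        dplyr::filter(.data$year < anchor_year) |>
        dplyr::mutate(amount_gmol = .data$amount_gmol * scale,
                      source = "historical_scaled"),
      v |>
        dplyr::filter(.data$year >= anchor_year) |>
        dplyr::mutate(source = "inventory")
    )
  }) |>
    dplyr::select("year", "gas", "amount_gmol", "source") |>
    dplyr::arrange(.data$gas, .data$year)
}

#' Combine the emission series of two territories
#'
#' Year-wise sum of two emission series covering the same gases (e.g. two
#' states prior to a unification). Years present in only one of the series
#' are an error: a partial sum would silently understate the total.
#'
#' @param a,b Emission tibbles (`year`, `gas`, `amount_gmol`).
#' @param source Source tag for the combined rows (default `"combined"`).
#' @return A combined emission series tibble.
#' @export
combine_territories <- function(a, b, source = "combined") {
  a <- tibble::as_tibble(a)
  b <- tibble::as_tibble(b)
  gases <- union(unique(a$gas), unique(b$gas))
  purrr::map_dfr(gases, function(g) {
    ya <- a[a$gas == g, ]
    yb <- b[b$gas == g, ]
    if (nrow(ya) == 0 || nrow(yb) == 0 ||
        length(intersect(ya$year, yb$year)) == 0) {
      abort(paste0("series for ", g, " have no overlapping years"))
    }
    extra <- c(setdiff(ya$year, yb$year), setdiff(yb$year, ya$year))
    if (length(extra) > 0) {
      abort(paste0("years covered by only one territory for ", g, ": ",
                   paste(sort(extra), collapse = ", ")))
    }
    dplyr::inner_join(
      ya[c("year", "amount_gmol")], yb[c("year", "amount_gmol")],
      by = "year", suffix = c("_a", "_b")
    ) |>
      dplyr::transmute(year = .data$year, gas = g,
                       amount_gmol = .data$amount_gmol_a + .data$amount_gmol_b,
                       source = source)
  }) |>
    dplyr::arrange(.data$gas, .data$year)
}

#' Molar S/N ratio of an emission series
#'
#' Per-year ratio of SO2 emissions to the sum of NH3 and NOx emissions on
#' the molecule-molar (Gmol) basis. All three gases must be present for a
#' year to be reported.
#'
#' @param series Emission tibble (`year`, `gas`, `amount_gmol`) containing
#'   SO2, NH3 and NOx.
#' @return A tibble `year`, `sn_ratio`.
#' @export
emission_sn_ratio <- function(series) {
  wide <- series |>
    dplyr::select("year", "gas", "amount_gmol") |>
    tidyr::pivot_wider(names_from = "gas", values_from = "amount_gmol")
  missing <- setdiff(c("SO2", "NH3", "NOx"), names(wide))
  if (length(missing) > 0) {
    abort(paste0("series lacks gases: ", paste(missing, collapse = ", ")))
  }
  wide <- tidyr::drop_na(wide, "SO2", "NH3", "NOx")
  n_total <- wide$NH3 + wide$NOx
  if (any(n_total <= 0)) abort("total N emission must be positive")
  tibble::tibble(year = wide$year, sn_ratio = wide$SO2 / n_total) |>
    dplyr::arrange(.data$year)
}
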