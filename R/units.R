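#' Convert an element mass flux to a charge-equivalent flux
#'
#' Deposition and demand figures are often quoted as kg of element per
#' hectare and year, while budget arithmetic runs in millimoles of ion
#' equivalents (mmol_IE, i.e. millimoles of charge) per square metre and
#' year. The conversion is
#' \deqn{q_{IE} = \frac{100\, q_{mass}}{M_{el}} \cdot \frac{|z|}{s}}
#' where \eqn{M_{el}} is the molar mass of the element, \eqn{z} the ionic
#' charge of the carrier species and \eqn{s} its element stoichiometry
#' (1 kg ha^-1 = 100 mg m^-2). A stand N demand of 9.7 kg ha^-1 yr^-1
#' carried as NH4+ is about 69 mmol_IE m^-2 yr^-1; an S demand of
#' 0.9 kg ha^-1 yr^-1 carried as sulfate is about 5.6 mmol_IE m^-2 yr^-1.
#'
#' @param mass_flux Element mass flux in kg ha^-1 yr^-1 (non-negative).
#' @param species Species name carrying the element (e.g. `"SO4"`).
#' @param registry Species registry, see [species_registry()].
#' @return Flux in mmol_IE m^-2 yr^-1.
#' @export
#' @examples
#' mass_flux_to_equivalent_flux(9.7, "NH4") # ~69
#' mass_flux_to_equivalent_flux(0.9, "SO4") # ~5.6
mass_flux_to_equivalent_flux <- function(mass_flux, species,
                                         registry = default_species()) {
  if (any(mass_flux < 0)) abort("mass_flux must be non-negative")
  sp <- check_charged(get_species(species, registry))
  mass_flux * 100 / sp$element_molar_mass * abs(sp$charge) /
    sp$element_stoichiometry
}

#' Convert a charge-equivalent flux back to an element mass flux
#'
#' Exact algebraic inverse of [mass_flux_to_equivalent_flux()]; the
#' round-trip is the identity to floating-point precision.
#'
#' @param eq_flux Flux in mmol_IE m^-2 yr^-1 (non-negative).
#' @inheritParams mass_flux_to_equivalent_flux
#' @return Element mass flux in kg ha^-1 yr^-1.
#' @export
equivalent_flux_to_mass_flux <- function(eq_flux, species,
                                         registry = default_species()) {
  if (any(eq_flux < 0)) abort("eq_flux must be non-negative")
  sp <- check_charged(get_species(species, registry))
  eq_flux / 100 * sp$element_molar_mass / abs(sp$charge) *
    sp$element_stoichiometry
}

#' Convert a molar element stock to a mass stock
#'
#' A topsoil sulfur stock of 2281.3 mmol m^-2 corresponds to about
#' 731.5 kg ha^-1 (1 mg m^-2 = 0.01 kg ha^-1).
#'
#' @param stock Stock in mmol element m^-2 (non-negative).
#' @param molar_mass Element molar mass in g mol^-1.
#' @return Stock in kg ha^-1.
#' @export
#' @examples
#' molar_stock_to_mass_stock(2281.3, 32.065)
molar_stock_to_mass_stock <- function(stock, molar_mass) {
  if (any(stock < 0)) abort("stock must be non-negative")
  if (any(molar_mass <= 0)) abort("molar_mass must be positive")
  stock * molar_mass * 0.01
}

#' Proton flux from pH and water flux
#'
#' Converts a solution pH and the water flux of a sampling period into a
#' proton flux, equating activity with concentration (appropriate for
#' dilute precipitation and soil solution):
#' \eqn{F_{H^+} = 10^{-pH} \cdot q_w \cdot 10^3} mmol_IE m^-2, with the
#' water flux in L m^-2 (= mm).
#'
#' @param ph pH value(s), strictly between 0 and 14.
#' @param water_flux Water flux over the period in L m^-2; non-negative.
#' @return Proton flux in mmol_IE m^-2.
#' @export
#' @examples
#' ph_to_proton_flux(4.0, 1000) # 100 mmol_IE m^-2
ph_to_proton_flux <- function(ph, water_flux) {
  if (any(ph <= 0 | ph >= 14)) abort("ph must lie strictly between 0 and 14")
  if (any(water_flux < 0)) abort("water_flux must be non-negative")
  10^(-ph) * water_flux * 1000
}

#' Sulfur-to-nitrogen ratio of deposition fluxes
#'
#' The S/N ratio can be formed on two bases: `"equivalent"` divides summed
#' charge-equivalent S fluxes by summed charge-equivalent N fluxes as
#' given; `"molar"` first converts every flux to millimoles of element
#' (dividing by |charge| and multiplying by the element stoichiometry).
#' For sulfate over ammonium + nitrate the equivalent-basis ratio is twice
#' the molar one, because sulfate carries two charges per S.
#'
#' @param s_fluxes Numeric vector of sulfur-species fluxes (mmol_IE m^-2 yr^-1).
#' @param n_fluxes Numeric vector of nitrogen-species fluxes (same unit).
#' @param basis `"equivalent"` (default) or `"molar"`.
#' @param s_species,n_species Species names parallel to `s_fluxes` and
#'   `n_fluxes`; only needed on the molar basis.
#' @param registry Species registry.
#' @return Dimensionless ratio.
#' @export
#' @examples
#' sn_ratio(160, c(150, 70))                  # ~0.73 on the equivalent basis
#' sn_ratio(160, c(150, 70), basis = "molar") # ~0.36
sn_ratio <- function(s_fluxes, n_fluxes,
                     basis = c("equivalent", "molar"),
                     s_species = "SO4", n_species = c("NH4", "NO3"),
                     registry = default_species()) {
  basis <- match.arg(basis)
  if (any(s_fluxes < 0) || any(n_fluxes < 0)) {
    abort("fluxes must be non-negative")
  }
  if (basis == "molar") {
    s_species <- rep_len(s_species, length(s_fluxes))
    n_species <- rep_len(n_species, length(n_fluxes))
    to_molar <- function(flux, name) {
      sp <- check_charged(get_species(name, registry))
      flux / abs(sp$charge) * sp$element_stoichiometry
    }
    s_fluxes <- purrr::map2_dbl(s_fluxes, s_species, to_molar)
    n_fluxes <- purrr::map2_dbl(n_fluxes, n_species, to_molar)
  }
  n_total <- sum(n_fluxes)
  if (n_total <= 0) abort("total nitrogen flux must be positive")
  sum(s_fluxes) / n_total
}
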