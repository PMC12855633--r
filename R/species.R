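#' Default ion species registry
#'
#' The registry is a tibble with one row per dissolved species and carries
#' everything the unit conversions need: the molar mass of the species, its
#' signed ionic charge, the budget element it transports (S, N, ...), the
#' stoichiometry (mol of element per mol of species) and the molar mass of
#' that element. All charge-equivalent ("IE", ion-equivalent) arithmetic in
#' the package goes through this table, so a consistent set of molar masses
#' is used everywhere: S = 32.06, N = 14.007 g mol^-1.
#'
#' The default covers the analytes of a typical forest monitoring plot:
#' H+, NH4+, NO3-, SO4^2-, Cl-, Ca2+, Mg2+, K+, Na+, Al3+, Mn2+, Fe3+.
#' Metals measured as total element are treated as their free cations
#' (aluminium as Al3+), which is the convention for acid forest soils.
#'
#' @return A tibble with columns `name`, `formula`, `molar_mass` (g/mol of
#'   species), `charge` (signed integer), `element`, `element_stoichiometry`
#'   and `element_molar_mass` (g/mol of element).
#' @export
#' @examples
#' default_species()
default_species <- function() {
  tibble::tribble(
    ~name,  ~formula,  ~molar_mass, ~charge, ~element, ~element_stoichiometry, ~element_molar_mass,
    "H",    "H+",            1.008,      1L, "H",      1L,   1.008,
    "NH4",  "NH4+",         18.039,      1L, "N",      1L,  14.007,
    "NO3",  "NO3-",         62.004,     -1L, "N",      1L,  14.007,
    "SO4",  "SO4^2-",       96.060,     -2L, "S",      1L,  32.060,
    "Cl",   "Cl-",          35.450,     -1L, "Cl",     1L,  35.450,
    "Ca",   "Ca^2+",        40.078,      2L, "Ca",     1L,  40.078,
    "Mg",   "Mg^2+",        24.305,      2L, "Mg",     1L,  24.305,
    "K",    "K+",           39.098,      1L, "K",      1L,  39.098,
    "Na",   "Na+",          22.990,      1L, "Na",     1L,  22.990,
    "Al",   "Al^3+",        26.982,      3L, "Al",     1L,  26.982,
    "Mn",   "Mn^2+",        54.938,      2L, "Mn",     1L,  54.938,
    "Fe",   "Fe^3+",        55.845,      3L, "Fe",     1L,  55.845
  )
}

#' Build a species registry, optionally overriding or adding species
#'
#' @param overrides A data frame with the same columns as
#'   [default_species()] (any subset of rows). Rows with a `name` already in
#'   the default registry replace it; new names are appended.
#' @return A validated registry tibble.
#' @export
species_registry <- function(overrides = NULL) {
  reg <- default_species()
  if (!is.null(overrides)) {
    overrides <- tibble::as_tibble(overrides)
    missing_cols <- setdiff(names(reg), names(overrides))
    if (length(missing_cols) > 0) {
      abort(paste0("species overrides lack columns: ",
                   paste(missing_cols, collapse = ", ")))
    }
    overrides <- overrides[names(reg)]
    reg <- dplyr::bind_rows(
      dplyr::anti_join(reg, overrides, by = "name"),
      overrides
    )
  }
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  if (anyDuplicated(reg$name) > 0) {
    abort("duplicate species names in registry")
  }
  if (any(reg$molar_mass <= 0) || any(reg$element_molar_mass <= 0)) {
    abort("molar masses must be positive")
  }
  stoich <- reg$element_stoichiometry
  if (any(stoich < 1) || any(stoich != as.integer(stoich))) {
    abort("element_stoichiometry must be a positive integer")
  }
  invisible(reg)
}

#' Look up one species in a registry
#'
#' @param name Species name (e.g. `"SO4"`).
#' @param registry A registry tibble, by default [default_species()].
#' @return The single matching registry row.
#' @export
get_species <- function(name, registry = default_species()) {
  row <- registry[registry$name == name, ]
  if (nrow(row) == 0) {
    abort(paste0("unknown species: ", name))
  }
  row
}

## equivalent conversions are undefined for uncharged species
check_charged <- function(sp) {
  if (any(abs(sp$charge) < 1)) {
    abort(paste0("species without ionic charge cannot be expressed in ",
                 "charge equivalents: ", paste(sp$name, collapse = ", ")))
  }
  invisible(sp)
}

#' Read / write a species registry as CSV
#'
#' The registry is serialized as a plain CSV with the columns of
#' [default_species()]; a copy of the default ships in
#' `system.file("extdata", "species.csv", package = "ionbudget")`.
#'
#' @param path File path.
#' @return `read_species_csv()` returns a validated registry tibble;
#'   `write_species_csv()` returns `path` invisibly.
#' @export
read_species_csv <- function(path) {
  reg <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      name = readr::col_character(),
      formula = readr::col_character(),
      molar_mass = readr::col_double(),
      charge = readr::col_integer(),
      element = readr::col_character(),
      element_stoichiometry = readr::col_integer(),
      element_molar_mass = readr::col_double()
    )
  )
  validate_registry(reg)
  reg
}

#' @rdname read_species_csv
#' @param registry Registry tibble to serialize.
#' @export
write_species_csv <- function(registry, path) {
  validate_registry(registry)
  write_schema_csv(registry, path, "species/1")
}
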