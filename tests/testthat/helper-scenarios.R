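# Shared fixtures, generated in code. The default scenario is cached per
# test run because several files exercise it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_dataset <- function() {
  cached("default_ds", generate_scenario(scenario_config()))
}

default_flux_table <- function() {
  cached("default_fluxes", annual_fluxes(default_dataset()))
}

noise_free_config <- function(...) {
  scenario_config(
    concentration_cv = 0,
    annual_flux_cv = c(bulk = 0, throughfall = 0, seepage40 = 0),
    annual_precip_cv = 0,
    ph_noise_sd = 0,
    dry_years = integer(0),
    ...
  )
}

noise_free_dataset <- function() {
  cached("noise_free_ds", generate_scenario(noise_free_config()))
}

# small hand-built chemistry/water pair: one compartment, one species,
# equal daily water fluxes, concentrations chosen per test
toy_chemistry <- function(starts, ends, conc, compartment = "throughfall",
                          species = "SO4", ph = NA_real_) {
  tibble::tibble(
    period_start = as.Date(starts), period_end = as.Date(ends),
    compartment = compartment, species = species,
    concentration_ueq_per_L = conc, pH = ph
  )
}

toy_water <- function(from, to, mm = 2, compartment = "throughfall") {
  dates <- seq(as.Date(from), as.Date(to), by = 1)
  tibble::tibble(date = dates, compartment = compartment, water_mm = mm)
}

# independent rule-level oracle for the nitrogen-transformation proton
# load: draws integer process rates (nitrification n, NH4 uptake u_a,
# NO3 uptake + denitrification u_n, ammonification m) consistent with the
# flux mass balances, and sums protons rule by rule:
#   +2 per nitrification, +1 per NH4 uptake, -1 per NO3 removed,
#   -1 per ammonification
draw_consistent_rates <- function(n_cases, max_flux = 500L) {
  nh4_in <- sample.int(max_flux, n_cases, replace = TRUE)
  no3_in <- sample.int(max_flux, n_cases, replace = TRUE)
  m <- sample.int(max_flux, n_cases, replace = TRUE)      # ammonification
  avail <- nh4_in + m
  consumed <- floor(runif(n_cases) * (avail + 1))          # n + u_a <= avail
  n <- floor(runif(n_cases) * (consumed + 1))              # nitrification
  u_a <- consumed - n
  no3_avail <- no3_in + n
  u_n <- floor(runif(n_cases) * (no3_avail + 1))
  tibble::tibble(
    nh4_in = nh4_in, no3_in = no3_in, m = m, n = n, u_a = u_a, u_n = u_n,
    nh4_out = nh4_in + m - n - u_a,
    no3_out = no3_in + n - u_n,
    rule_sum = 2 * n + u_a - u_n - m
  )
}
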