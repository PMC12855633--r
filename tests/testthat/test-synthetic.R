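test_that("identical config and seed give bit-identical datasets", {
  cfg <- scenario_config(start_year = 2000, end_year = 2006, seed = 42)
  a <- generate_scenario(cfg)
  b <- generate_scenario(cfg)
  expect_identical(a$chemistry, b$chemistry)
  expect_identical(a$water, b$water)
  expect_identical(a$truth, b$truth)
})

test_that("different seeds change the noise but not the configured truth", {
  a <- generate_scenario(scenario_config(start_year = 2000, end_year = 2006,
                                         seed = 1))
  b <- generate_scenario(scenario_config(start_year = 2000, end_year = 2006,
                                         seed = 2))
  expect_false(identical(a$chemistry$concentration_ueq_per_L,
                         b$chemistry$concentration_ueq_per_L))
  # configured trends are seed-independent (the balance-derived seepage
  # cations inherit the anion noise, so only trended species qualify)
  trended <- dplyr::semi_join(a$truth, a$config$trends,
                              by = c("compartment", "species"))
  trended_b <- dplyr::semi_join(b$truth, b$config$trends,
                                by = c("compartment", "species"))
  expect_identical(trended$flux_config, trended_b$flux_config)
})

test_that("noise-free scenario realizes configured trends exactly", {
  ds <- noise_free_dataset()
  cfg <- ds$config
  # truth equals the configured trend
  expect_equal(ds$truth$flux_truth, ds$truth$flux_config, tolerance = 1e-12)
  # endpoints of each trended series match the config table
  tr <- cfg$trends
  for (i in seq_len(nrow(tr))) {
    first <- ds$truth$flux_truth[ds$truth$compartment == tr$compartment[i] &
                                   ds$truth$species == tr$species[i] &
                                   ds$truth$year == cfg$start_year]
    last <- ds$truth$flux_truth[ds$truth$compartment == tr$compartment[i] &
                                  ds$truth$species == tr$species[i] &
                                  ds$truth$year == cfg$end_year]
    expect_equal(first, tr$flux_start[i], tolerance = 1e-9)
    expect_equal(last, tr$flux_end[i], tolerance = 1e-9)
  }
})

test_that("period contributions sum exactly to the stored annual truth", {
  ds <- default_dataset()
  fl <- annual_fluxes(ds)
  cmp <- dplyr::inner_join(fl, ds$truth,
                           by = c("year", "compartment", "species"))
  expect_gt(nrow(cmp), 0)
  expect_equal(cmp$flux_mmol_ie_m2, cmp$flux_truth, tolerance = 1e-9)
})

test_that("dry years have strongly reduced seepage water", {
  ds <- default_dataset()
  cfg <- ds$config
  seep <- ds$water |>
    dplyr::filter(compartment == "seepage40") |>
    dplyr::mutate(year = as.integer(format(date, "%Y"))) |>
    dplyr::group_by(year) |>
    dplyr::summarise(annual = sum(water_mm))
  med <- median(seep$annual)
  dry <- seep$annual[seep$year %in% cfg$dry_years]
  expect_true(all(dry < 0.5 * med))
})

test_that("scenario config validation rejects inconsistent settings", {
  expect_error(scenario_config(start_year = 2000, end_year = 2000),
               "end_year")
  expect_error(scenario_config(dry_years = 1950), "span")
  expect_error(scenario_config(throughfall_fraction = 1.5), "fractions")
  expect_error(scenario_config(concentration_cv = -0.1), "noise")
  bad_trends <- default_trends()
  bad_trends$shape[1] <- "cubic"
  expect_error(scenario_config(trends = bad_trends), "shape")
  exp_zero <- default_trends()
  exp_zero$flux_end[exp_zero$shape == "exponential"] <- 0
  expect_error(scenario_config(trends = exp_zero), "positive")
})

test_that("inject_dry_years scales seepage ion fluxes exactly linearly", {
  ds <- generate_scenario(noise_free_config(start_year = 2000,
                                            end_year = 2004))
  base <- annual_fluxes(ds) |> dplyr::filter(compartment == "seepage40")
  scaled <- inject_dry_years(ds, 2002, seepage_multiplier = 0.4)
  out <- annual_fluxes(scaled) |> dplyr::filter(compartment == "seepage40")
  cmp <- dplyr::inner_join(base, out, by = c("year", "compartment", "species"))
  hit <- cmp$year == 2002
  expect_equal(cmp$flux_mmol_ie_m2.y[hit], 0.4 * cmp$flux_mmol_ie_m2.x[hit],
               tolerance = 1e-9)
  expect_equal(cmp$flux_mmol_ie_m2.y[!hit], cmp$flux_mmol_ie_m2.x[!hit],
               tolerance = 1e-12)
  # chemistry untouched
  expect_identical(scaled$chemistry, ds$chemistry)
})

test_that("inject_dry_years boundary conditions", {
  ds <- generate_scenario(noise_free_config(start_year = 2000,
                                            end_year = 2002))
  zeroed <- inject_dry_years(ds, 2001, seepage_multiplier = 0)
  out <- annual_fluxes(zeroed) |>
    dplyr::filter(compartment == "seepage40", year == 2001)
  expect_true(all(out$flux_mmol_ie_m2 == 0))
  expect_error(inject_dry_years(ds, 2001, 1), "\\[0, 1\\)")
  expect_error(inject_dry_years(ds, 1990, 0.5), "span")
})

test_that("emission series interpolates piecewise-linear nodes exactly", {
  so2 <- generate_emission_series(tibble::tibble(
    gas = "SO2", year = c(1890, 1950, 1970), amount_gmol = c(20, 63, 124)))
  expect_equal(so2$amount_gmol[so2$year == 1950], 63)
  expect_equal(so2$amount_gmol[so2$year == 1890], 20)
  expect_equal(so2$amount_gmol[so2$year == 1920],
               20 + (63 - 20) * 30 / 60)
  nox <- generate_emission_series(tibble::tibble(
    gas = "NOx", year = c(1950, 1986), amount_gmol = c(27, 82)))
  expect_equal(nox$amount_gmol[nox$year == 1986], 82)
  expect_equal(nrow(nox), 1986 - 1950 + 1)
  single <- generate_emission_series(tibble::tibble(
    gas = "NH3", year = 2000, amount_gmol = 36))
  expect_equal(single$amount_gmol, 36)
  expect_error(generate_emission_series(tibble::tibble(
    gas = "SO2", year = c(1950, 1890), amount_gmol = c(63, 20))),
    "increasing")
})

test_that("correlated bulk/throughfall switch shares the noise stream", {
  cfg_ind <- scenario_config(start_year = 2000, end_year = 2003, seed = 7)
  cfg_cor <- scenario_config(start_year = 2000, end_year = 2003, seed = 7,
                             correlated_bulk_throughfall = TRUE)
  ind <- generate_scenario(cfg_ind)
  cor_ds <- generate_scenario(cfg_cor)
  ratio_of <- function(ds) {
    ch <- ds$chemistry
    b <- ch[ch$compartment == "bulk" & ch$species == "SO4", ]
    t <- ch[ch$compartment == "throughfall" & ch$species == "SO4", ]
    cor(b$concentration_ueq_per_L, t$concentration_ueq_per_L)
  }
  expect_gt(ratio_of(cor_ds), ratio_of(ind))
})
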