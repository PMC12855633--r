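test_that("nitrogen-transformation proton load: closed form examples", {
  expect_equal(n_transformation_proton_load(150, 0, 70, 300), 380)
  expect_equal(n_transformation_proton_load(87, 87, 41, 41), 0)
  # net nitrate consumption gives a negative (proton-consuming) load
  expect_equal(n_transformation_proton_load(100, 100, 50, 30), -20)
  expect_error(n_transformation_proton_load(-1, 0, 0, 0), "non-negative")
})

test_that("closed form equals rule-level accounting for random consistent rates", {
  # the central stoichiometric identity: for any non-negative process
  # rates satisfying the NH4 and NO3 mass balances, summing protons rule
  # by rule (+2 nitrification, +1 NH4 uptake, -1 NO3 removal,
  # -1 ammonification) equals (nh4_in - nh4_out) + (no3_out - no3_in)
  set.seed(421)
  rates <- draw_consistent_rates(10000)
  expect_true(all(rates$nh4_out >= 0))
  expect_true(all(rates$no3_out >= 0))
  closed <- n_transformation_proton_load(rates$nh4_in, rates$nh4_out,
                                         rates$no3_in, rates$no3_out)
  expect_identical(closed, as.numeric(rates$rule_sum))
})

test_that("proton budget assembles loads and buffering percentages", {
  tab <- tibble::tibble(
    year = 1990,
    compartment = rep(c("throughfall", "seepage40"), each = 3),
    species = rep(c("H", "NH4", "NO3"), 2),
    flux_mmol_ie_m2 = c(10, 150, 70, 3, 5, 145)
  )
  pb <- proton_budget(tab)
  expect_equal(pb$direct_input, 10)
  expect_equal(pb$n_transformation_load, (150 - 5) + (145 - 70))
  expect_equal(pb$total_load, pb$direct_input + pb$n_transformation_load)
  expect_equal(pb$seepage_output, 3)
  expect_equal(pb$buffered_percent,
               100 * (pb$total_load - 3) / pb$total_load)

  # percentage arithmetic on a constructed total load of 100:
  # direct 30 + (150 - 110) + (100 - 70) = 100
  tab2 <- tab
  tab2$flux_mmol_ie_m2 <- c(30, 150, 70, 3, 110, 100)
  pb2 <- proton_budget(tab2)
  expect_equal(pb2$total_load, 100)
  expect_equal(pb2$buffered_percent, 97)
  tab2$flux_mmol_ie_m2[4] <- 6.6
  expect_equal(proton_budget(tab2)$buffered_percent, 93.4)
  tab2$flux_mmol_ie_m2[4] <- 0
  expect_equal(proton_budget(tab2)$buffered_percent, 100)

  expect_error(proton_budget(tab[-1, ]), "missing")
})

test_that("buffered percent never exceeds 100 for non-negative seepage", {
  fl <- default_flux_table()
  pb <- proton_budget(fl)
  expect_true(all(pb$buffered_percent <= 100, na.rm = TRUE))
})

test_that("annual sulfur balance is input minus output", {
  tab <- tibble::tibble(
    year = rep(c(1985, 1995, 2019), each = 2),
    compartment = rep(c("throughfall", "seepage40"), 3),
    species = "SO4",
    flux_mmol_ie_m2 = c(160, 160, 40, 200, 10, 0)
  )
  sb <- annual_s_balance(tab)
  expect_equal(sb$delta_ie, c(0, -160, 10))
  # optional constant tree-uptake term shifts every delta
  sb_up <- annual_s_balance(tab, uptake_ie = 5.5)
  expect_equal(sb_up$delta_ie, sb$delta_ie - 5.5)
  expect_error(annual_s_balance(tab[tab$compartment == "throughfall", ]),
               "required")
})

test_that("storage trajectory reproduces the remaining-fraction example", {
  # cumulative change of -2012.3 mmol m-2 on an initial stock of 2281.3:
  # deltas are charge equivalents, so they are halved before summation
  deltas <- tibble::tibble(year = 1985:1986,
                           delta_ie = c(-2000 * 2, -12.3 * 2))
  tr <- storage_trajectory(deltas, initial_stock = 2281.3)
  expect_equal(tail(tr$cumulative_change, 1), -2012.3)
  expect_equal(tail(tr$remaining_stock, 1), 269.0)
  expect_equal(tail(tr$remaining_fraction, 1), 100 * 269 / 2281.3,
               tolerance = 1e-12)
  expect_equal(round(tail(tr$remaining_fraction, 1)), 12) # "about 11%"
  expect_false(any(tr$stock_exhausted))
})

test_that("storage trajectory boundary and flag behaviour", {
  flat <- storage_trajectory(
    tibble::tibble(year = 1:5, delta_ie = 0), 100)
  expect_true(all(flat$remaining_fraction == 100))
  gone <- storage_trajectory(
    tibble::tibble(year = 1:2, delta_ie = c(-100, -100)), 100)
  expect_equal(tail(gone$remaining_fraction, 1), 0)
  over <- storage_trajectory(
    tibble::tibble(year = 1:3, delta_ie = c(-100, -100, -100)), 100)
  expect_true(tail(over$stock_exhausted, 1))
  expect_lt(tail(over$remaining_stock, 1), 0) # not clamped
  expect_error(storage_trajectory(tibble::tibble(year = 1, delta_ie = 0), 0),
               "positive")
})

test_that("storage trajectory is translation-consistent", {
  set.seed(99)
  deltas <- tibble::tibble(year = 1:20, delta_ie = rnorm(20, -30, 40))
  base <- storage_trajectory(deltas, 500)
  shifted <- storage_trajectory(
    dplyr::mutate(deltas, delta_ie = delta_ie + 10), 500)
  expect_equal(tail(shifted$cumulative_change, 1),
               tail(base$cumulative_change, 1) + 10 * 20 / 2,
               tolerance = 1e-9)
})

test_that("surplus factor is deposition over demand", {
  expect_equal(surplus_factor(9.7, 9.7), 1)
  expect_equal(surplus_factor(19.4, 9.7), 2)
  expect_equal(surplus_factor(1.26, 0.9), 1.4)
  expect_error(surplus_factor(1, 0), "positive")
})

test_that("livestock units reproduce the printed district totals", {
  expect_equal(floor(livestock_units(1069900, 642540)), 1172706)
  expect_equal(floor(livestock_units(605700, 512840)), 687754)
  expect_equal(livestock_units(0, 0), 0)
  # the overall decrease in livestock units is about 41%
  dec <- 1 - livestock_units(605700, 512840) / livestock_units(1069900, 642540)
  expect_equal(round(100 * dec), 41)
  expect_error(livestock_units(-1, 0), "non-negative")
})

test_that("proton load tracks nitrate seepage on the default scenario", {
  fl <- default_flux_table()
  pb <- proton_budget(fl)
  no3 <- fl |>
    dplyr::filter(compartment == "seepage40", species == "NO3")
  joined <- dplyr::inner_join(pb, no3, by = "year")
  expect_gt(correlation_r2(joined$total_load, joined$flux_mmol_ie_m2), 0.9)
})
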