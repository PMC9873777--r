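test_that("planting density comes from the reciprocal of the spacings", {
  expect_equal(planting_density(0.75, 0.15), 8.9)
  expect_equal(planting_density(1, 1), 1)
  expect_equal(planting_density(0.5, 0.2), 10)
  expect_error(planting_density(0, 0.2), class = "input_error")
})

test_that("management rules validate their window and density", {
  expect_error(management_rules("05-01", "04-01"), class = "input_error")
  expect_error(management_rules("04-01", "05-20", density = 5,
                                row_spacing_m = 0.75, plant_spacing_m = 0.15),
               class = "input_error")
  ok <- management_rules("04-01", "05-20", density = 8.9,
                         row_spacing_m = 0.75, plant_spacing_m = 0.15)
  expect_s3_class(ok, "management_rules")
})

test_that("the rain trigger finds the first qualifying day in the window", {
  w <- constant_weather(120, rain = 0, start = as.Date("2019-03-01"))
  rules <- management_rules("04-01", "05-20", min_events = 3,
                            min_event_mm = 5, cum_mm = 25, lookback_days = 10)
  # bone dry: no sowing
  expect_true(is.na(find_sowing_date(w, rules, 2019)))
  # 10 mm on window days 1, 3, 5: trigger satisfied on day 5
  w2 <- w
  w2$rain[w2$date %in% (as.Date("2019-04-01") + c(0, 2, 4))] <- 10
  expect_equal(find_sowing_date(w2, rules, 2019), as.Date("2019-04-05"))
  # trigger met before the window only: no sowing
  w3 <- w
  w3$rain[w3$date %in% (as.Date("2019-03-05") + c(0, 2, 4))] <- 10
  expect_true(is.na(find_sowing_date(w3, rules, 2019)))
  # window outside the record is an input error
  expect_error(find_sowing_date(w, rules, 2023), class = "input_error")
})

test_that("a crop with no water fails with zero yield", {
  w <- constant_weather(200, tmax = 32, tmin = 18, rain = 0,
                        start = as.Date("2019-01-01"))
  dead_soil <- two_layer_profile(sw = c(0.10, 0.10)) # at cll
  r <- run_season(w, dead_soil, meko(), as.Date("2019-01-05"))
  expect_true(r$failed)
  expect_equal(r$grain_yield, 0)
  expect_equal(r$total_biomass, 0)
})

test_that("identical inputs give a bit-identical daily trace", {
  wx <- generate_weather(climate_preset("melkassa_like"), 1, seed = 77,
                         start_year = 2014)
  soil <- soil_fixture("melkassa")
  cfg <- sim_config(irrigation = irrigation_rule())
  a <- run_season(wx, soil, meko(), as.Date("2014-06-09"), config = cfg,
                  trace = TRUE)
  b <- run_season(wx, soil, meko(), as.Date("2014-06-09"), config = cfg,
                  trace = TRUE)
  expect_identical(a$trace, b$trace)
  expect_identical(a$grain_yield, b$grain_yield)
})

test_that("every season respects date order and yield <= biomass", {
  wx <- generate_weather(climate_preset("miesso_like"), 13, seed = 4)
  soil <- soil_fixture("miesso")
  for (y in 2002:2013) {
    sow <- as.Date(sprintf("%d-07-08", y))
    r <- run_season(wx, soil, if (y %% 2) meko() else jigurti(), sow)
    expect_lte(r$grain_yield, r$total_biomass + 1e-9)
    if (!r$failed) {
      expect_true(r$emergence_date > r$sowing_date)
      expect_true(r$anthesis_date > r$pi_date)
      expect_true(r$maturity_date > r$anthesis_date)
      expect_gte(r$harvest_index, 0)
      expect_lt(r$harvest_index, 1)
    }
  }
})

test_that("the well-watered fixture reproduces the genotype contrasts", {
  fx <- run_fixture("melkassa2014")
  expect_true(all(fx$checks$passed))
  expect_gt(fx$jigurti$total_biomass, fx$meko$total_biomass)
  expect_gt(fx$meko$harvest_index, fx$jigurti$harvest_index)
  expect_lt(fx$meko$maturity_date, fx$jigurti$maturity_date)
})

test_that("the dryland fixture shows terminal stress and escape by earliness", {
  fx <- run_fixture("miesso2016")
  expect_true(all(fx$checks$passed))
  expect_lt(fx$jigurti$final_green_lai, 0.1)
  expect_gte(fx$meko$grain_yield, fx$jigurti$grain_yield)
  expect_error(run_fixture("nowhere1999"))
})

test_that("genotype parameter files round-trip through YAML", {
  g <- jigurti()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_genotype(g, tmp)
  g2 <- read_genotype(tmp)
  expect_equal(g2, g)
  bundled <- read_genotype("meko")
  expect_equal(bundled, meko())
})
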