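test_that("curve-number runoff partitioning matches the formula", {
  p <- two_layer_profile()
  expect_equal(partition_rain(0, p)$runoff, 0)
  expect_equal(partition_rain(0, p)$infiltration, 0)
  # below the initial abstraction (0.2S = 12.7 at CN 80) all rain infiltrates
  r5 <- partition_rain(5, p, cn = 80)
  expect_equal(r5$runoff, 0)
  expect_equal(r5$infiltration, 5)
  # above it, the SCS relation applies
  s <- 25400 / 80 - 254
  r50 <- partition_rain(50, p, cn = 80)
  expect_equal(r50$runoff, (50 - 0.2 * s)^2 / (50 + 0.8 * s))
  expect_equal(r50$runoff, 13.80, tolerance = 0.01)
})

test_that("drainage cascades water above the drained upper limit", {
  p <- two_layer_profile(sw = c(0.30, 0.30)) # exactly at dul
  expect_equal(drain(p)$drainage, 0)
  one <- soil_profile(0, 20, 1.2, dul = 0.30, cll = 0.10, sw = 0.35)
  d <- drain(one, swcon = 0.3)
  # 10 mm above dul: 3 mm leaves, 7 mm retained above dul
  expect_equal(d$drainage, 3)
  expect_equal((d$profile$sw - 0.30) * 200, 7)
  # repeated drainage converges to dul geometrically
  cur <- one
  excess <- numeric(10)
  for (i in 1:10) {
    res <- drain(cur, 0.3); cur <- res$profile
    excess[i] <- (cur$sw - 0.30) * 200
  }
  expect_equal(excess, 10 * 0.7^(1:10), tolerance = 1e-9)
})

test_that("soil evaporation respects cover, supply and the stage-1 cap", {
  p <- two_layer_profile()
  es <- evap_state_init()
  full_cover <- soil_evaporation(p, es, 20, 30, 15, cover = 1)
  expect_equal(full_cover$evaporation, 0)
  dry <- two_layer_profile(sw = c(0.05, 0.05)) # at air-dry (0.5 * cll)
  expect_equal(soil_evaporation(dry, es, 20, 30, 15, cover = 0)$evaporation, 0)
  wet <- soil_evaporation(p, es, 25, 35, 20, cover = 0, infiltration = 20)
  expect_lte(wet$evaporation, 6)
  pot <- 0.75 * reference_evap_demand(25, 35, 20)
  expect_lte(wet$evaporation, pot)
})

test_that("vapour pressure deficit follows the saturation-pressure span", {
  expect_equal(vpd_estimate(20, 20), 0)
  svp <- function(t) 0.6106 * exp(17.27 * t / (t + 237.3))
  expect_equal(vpd_estimate(30, 15), 0.75 * (svp(30) - svp(15)))
  expect_equal(vpd_estimate(30, 15), 1.90, tolerance = 0.005)
  expect_gt(vpd_estimate(35, 15), vpd_estimate(30, 15))
})

test_that("supply, demand and the stress index behave at the boundaries", {
  p <- two_layer_profile(sw = c(0.10, 0.10)) # at cll
  sd0 <- supply_and_demand(p, 40, potential_growth = 10, vpd = 2)
  expect_equal(sd0$supply, 0)
  expect_equal(sd0$sd_ratio, 0)
  nodem <- supply_and_demand(p, 40, potential_growth = 0, vpd = 2)
  expect_equal(nodem$sd_ratio, 1)
  # transpiration-efficiency units: 9 Pa at 2 kPa is 4.5 g m^-2 mm^-1
  wetp <- two_layer_profile()
  d <- supply_and_demand(wetp, 40, potential_growth = 20, vpd = 2, te_coeff = 9)
  expect_equal(d$demand, 20 / 4.5)
})

test_that("transpiration extraction is proportional and bounded by cll", {
  p <- two_layer_profile()  # kl-limited supply: 2 * 0.08 * 0.10 * 200 = 3.2 mm
  same <- extract_transpiration(p, 40, 3)
  expect_equal(unname(same$extracted), c(1.5, 1.5))
  expect_identical(extract_transpiration(p, 40, 0)$profile$sw, p$sw)
  # unequal layers: proportional to kl * available * root fraction
  uneq <- soil_profile(c(0, 20), c(20, 40), c(1.2, 1.2),
                       dul = c(0.30, 0.30), cll = c(0.10, 0.10),
                       sw = c(0.30, 0.15), kl = c(0.08, 0.04))
  avail <- uneq$kl * (uneq$sw - uneq$cll) * 200
  ex <- extract_transpiration(uneq, 40, 3)
  expect_equal(unname(ex$extracted), 3 * avail / sum(avail), tolerance = 1e-12)
  expect_true(all(ex$profile$sw >= ex$profile$cll - 1e-9))
  expect_error(extract_transpiration(p, 40, 100), class = "contract_violation")
})

test_that("no operation moves layers outside physical bounds", {
  set.seed(33)
  for (i in 1:20) {
    p <- random_profile()
    p2 <- partition_rain(runif(1, 0, 80), p)$profile
    p3 <- drain(p2)$profile
    es <- soil_evaporation(p3, evap_state_init(), 22, 33, 18, cover = 0)$profile
    expect_true(all(es$sw <= es$dul + 0.05 + 1e-9))
    expect_true(all(es$sw >= 0.5 * es$cll - 1e-9))
  }
})
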