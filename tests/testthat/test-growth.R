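test_that("light interception and growth follow their closed forms", {
  expect_equal(light_interception(0), 0)
  expect_equal(light_interception(log(2) / 0.4, k = 0.4), 0.5)
  expect_gt(light_interception(50), 0.999)
  expect_equal(daily_growth(20, 0.5, 1.25, 1), 12.5)
  expect_equal(daily_growth(20, 0.5, 1.25, 0), 0)
  # genotype contrast in radiation use efficiency
  expect_equal(daily_growth(20, 0.5, jigurti()$rue) /
                 daily_growth(20, 0.5, meko()$rue), 1.65 / 1.25)
})

test_that("leaf fraction declines with leaf count and partitioning factor", {
  expect_equal(partition_vegetative(10, 0, 0.0073)$to_leaf, 10)
  f_meko <- partition_vegetative(1, 15, 0.0073)$to_leaf
  expect_equal(f_meko, 1 / (1 + 0.0073 * 225))
  f_jig <- partition_vegetative(1, 15, 0.0106)$to_leaf
  expect_lt(f_jig, f_meko) # the taller landrace stems harder
  expect_equal(partition_vegetative(8, 10, 0.0073, past_flag = TRUE)$to_leaf, 0)
  pv <- partition_vegetative(7, 9, 0.0106)
  expect_equal(pv$to_leaf + pv$to_stem, 7)
})

test_that("grain number scales the flowering-window growth rate", {
  expect_equal(set_grain_number(0, 0.00083, 8.9), 0)
  meko_gn <- set_grain_number(0.9, 0.00083, 8.9)
  expect_equal(meko_gn / 8.9, 0.9 / 0.00083) # ~1084 grains per plant
  expect_equal(round(meko_gn / 8.9), 1084)
  jig_gn <- set_grain_number(0.9, 0.0014, 8.9)
  expect_equal(round(jig_gn / 8.9), 643)
  expect_lt(jig_gn, meko_gn) # lower grain set per unit growth when tall
})

test_that("grain filling obeys source, sink and translocation rules", {
  g <- meko()
  mk_pools <- function(number, stem, stem_anth = stem) {
    p <- pools_init()
    p$grain_number <- number; p$stem <- stem; p$stem_at_anthesis <- stem_anth
    p
  }
  # zero sink: all growth to stem
  p0 <- grain_fill(mk_pools(0, 100), d_biomass = 8, d_tt = 10,
                   fill_tt_total = 100, genotype = g)
  expect_equal(p0$grain, 0)
  expect_equal(p0$stem, 108)
  # demand 5, growth 8: grain +5, stem +3
  n <- 5 / (g$max_kernel_wt * 0.1) # demand = n * mkw * (10/100) = 5
  p1 <- grain_fill(mk_pools(n, 100), 8, 10, 100, g)
  expect_equal(p1$grain, 5)
  expect_equal(p1$stem, 103)
  # demand 8, growth 5: shortfall from stem reserves
  n2 <- 8 / (g$max_kernel_wt * 0.1)
  p2 <- grain_fill(mk_pools(n2, 100), 5, 10, 100, g)
  expect_equal(p2$grain, 8)
  expect_equal(p2$stem, 97)
  # translocation stops at the cumulative cap
  p3 <- mk_pools(n2, 100)
  for (i in 1:30) p3 <- grain_fill(p3, 0, 10, 100, g)
  expect_equal(p3$transloc_used, g$stem_transloc_frac * 100)
  # kernel mass cap binds
  expect_lte(p3$grain, p3$grain_number * g$max_kernel_wt + 1e-9)
  expect_error(grain_fill(pools_init(), 5, 10, 100, g), class = "state_error")
})

test_that("senescence conserves mass and reaches the right limits", {
  mk <- function(lai, leaf) {
    canopy <- canopy_init(); canopy$lai_green <- lai
    pools <- pools_init(); pools$leaf <- leaf; pools$stem <- 50
    list(canopy = canopy, pools = pools)
  }
  s <- mk(3, 60)
  # no stress, pre-anthesis: nothing happens
  none <- senesce(s$pools, s$canopy, sd_ratio = 1, post_anthesis = FALSE)
  expect_equal(none$lai_lost, 0)
  # total above-ground mass is unchanged by senescence
  sev <- senesce(s$pools, s$canopy, sd_ratio = 0, post_anthesis = FALSE)
  before <- s$pools$leaf + s$pools$stem
  after <- sev$pools$leaf + sev$pools$stem + sev$pools$dead_leaf
  expect_equal(after, before)
  # permanent total stress drives green LAI to near zero
  cur <- mk(3, 60)
  for (i in 1:200) {
    r <- senesce(cur$pools, cur$canopy, 0, FALSE)
    cur$pools <- r$pools; cur$canopy <- r$canopy
  }
  expect_lt(cur$canopy$lai_green, 1e-3)
  # age route: 85% of the anthesis LAI remains at mid-fill without stress
  aged <- mk(3, 60)
  r <- senesce(aged$pools, aged$canopy, 1, TRUE, tt_frac_fill = 0.5,
               lai_at_anthesis = 3)
  expect_equal(r$canopy$lai_green, 3 * 0.85)
})
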