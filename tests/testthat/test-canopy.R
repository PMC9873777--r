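test_that("blade area applies the flag/non-flag shape factors", {
  expect_equal(blade_area(60, 5, FALSE), 213)
  expect_equal(blade_area(40, 4, TRUE), 101.6)
  expect_equal(blade_area(10, 1, FALSE), 7.1)
})

test_that("the bell curve peaks at x0 and respects its domain", {
  p <- profile_from_tln(15, meko())
  expect_equal(p$x0, 0.83 * 15)
  expect_equal(p$y0, 36.9 * 15 - 95.2) # 458.3
  expect_equal(leaf_area_at(p$x0, p), p$y0)
  expect_error(leaf_area_at(0.5, p), class = "domain_error")
  expect_error(leaf_area_at(16, p), class = "domain_error")
  # even function around x0 when the skew term is off
  sym <- leaf_size_profile(15, y0 = 400, x0 = 8, b = 0)
  expect_equal(leaf_area_at(8 + 2, sym), leaf_area_at(8 - 2, sym))
  # x0 stays the maximum for any skew (it is always a critical point);
  # the skew shows as asymmetry in the direction of sign(b)
  pos <- leaf_size_profile(15, y0 = 400, x0 = 8, b = 5e-4)
  neg <- leaf_size_profile(15, y0 = 400, x0 = 8, b = -5e-4)
  grid <- seq(1, 15, by = 0.01)
  expect_equal(grid[which.max(leaf_area_at(grid, pos))], 8)
  expect_gt(leaf_area_at(8 + 3, pos), leaf_area_at(8 - 3, pos))
  expect_lt(leaf_area_at(8 + 3, neg), leaf_area_at(8 - 3, neg))
})

test_that("profile regressions on total leaf number give the quoted leaf positions", {
  j <- profile_from_tln(19, jigurti())
  expect_equal(j$x0, 14.06)
  expect_equal(round_half_up(j$x0), 14)
  expect_equal(j$y0, 13.2 * 19 + 318) # 568.8
  # a regression predicting non-positive area is rejected
  bad <- profile_regression(0.8, 0, y0_slope = 1, y0_intercept = -100)
  expect_error(profile_from_tln(10, bad), class = "invalid_regression")
})

test_that("profile fitting recovers generating parameters", {
  # noise-free: exact recovery and perfect regressions
  plants <- synthetic_plants(c(14, 16, 18, 20))
  fit <- fit_profile_regressions(plants)
  expect_equal(fit$regression$x0_slope, 0.80, tolerance = 1e-6)
  expect_equal(fit$regression$y0_slope, 30, tolerance = 1e-6)
  expect_equal(unname(fit$r2["x0"]), 1, tolerance = 1e-9)
  expect_equal(unname(fit$r2["y0"]), 1, tolerance = 1e-9)
  # two plants interpolate exactly
  fit2 <- fit_profile_regressions(synthetic_plants(c(15, 19)))
  expect_equal(unname(fit2$r2["y0"]), 1, tolerance = 1e-9)
  # 1% noise: slopes recovered within 5%
  set.seed(101)
  noisy <- synthetic_plants(c(13, 15, 17, 19, 21), noise_sd = 0.01)
  fitn <- fit_profile_regressions(noisy)
  expect_lt(abs(fitn$regression$x0_slope - 0.80) / 0.80, 0.05)
  expect_lt(abs(fitn$regression$y0_slope - 30) / 30, 0.05)
  # degenerate designs fail loudly
  expect_error(fit_profile_regressions(synthetic_plants(c(15, 15))),
               class = "fit_error")
  expect_error(fit_profile_regressions(synthetic_plants(15)[1:4, ]),
               class = "fit_error")
})

test_that("canopy expansion tracks thermal time, stress and the leaf cap", {
  g <- meko()
  st <- canopy_init()
  st1 <- canopy_update(st, g$lar, g, density = 8.9)
  expect_equal(st1$appeared_leaves, 1)
  # stress = 0 blocks expansion but not appearance
  st0 <- canopy_update(st, g$lar, g, density = 8.9, stress = 0)
  expect_equal(st0$lai_green, 0)
  expect_equal(st0$appeared_leaves, 1)
  # full unstressed season reaches the closed-form peak LAI
  full <- canopy_init()
  for (i in 1:200) full <- canopy_update(full, 21, g, density = 8.9)
  prof <- profile_from_tln(g$tln, g)
  expect_equal(full$lai_green,
               8.9 * sum(leaf_area_at(1:15, prof)) * 1e-4, tolerance = 1e-9)
  expect_equal(full$appeared_leaves, g$tln)
  # peak LAI grows with total leaf number, all else equal
  peak_for <- function(tln) {
    gg <- g; gg$tln <- tln
    p <- profile_from_tln(tln, gg)
    8.9 * sum(leaf_area_at(1:tln, p)) * 1e-4
  }
  peaks <- vapply(10:19, peak_for, 0)
  expect_true(all(diff(peaks) > 0))
  # no update after anthesis
  expect_identical(canopy_update(full, 21, g, 8.9, post_anthesis = TRUE), full)
})
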