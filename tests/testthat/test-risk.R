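test_that("least squares via normal equations matches closed forms", {
  x <- 1:10
  f <- ols_fit(x, x)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0)
  expect_equal(f$r2, 1)
  fc <- ols_fit(x, rep(3, 10))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r2, 0)
  set.seed(12)
  xr <- rnorm(40); yr <- 2 + 0.5 * xr + rnorm(40)
  fr <- ols_fit(xr, yr)
  lmf <- lm(yr ~ xr)
  expect_equal(fr$slope, unname(coef(lmf)[2]), tolerance = 1e-10)
  expect_equal(fr$intercept, unname(coef(lmf)[1]), tolerance = 1e-10)
  expect_equal(fr$r2, summary(lmf)$r.squared, tolerance = 1e-10)
  expect_error(ols_fit(c(1, 1, 1), c(1, 2, 3)), class = "fit_error")
  expect_error(ols_fit(1:2, 1:2), class = "fit_error")
})

test_that("distribution summaries use interpolated order statistics", {
  s <- distribution_summary(1:100)
  expect_equal(unname(s$percentiles["25%"]), 25.75)
  expect_equal(unname(s$percentiles["50%"]), 50.5)
  expect_equal(unname(s$percentiles["75%"]), 75.25)
  expect_equal(s$mean, 50.5)
  expect_equal(s$median, 50.5)
  cst <- distribution_summary(rep(7, 9))
  expect_true(all(cst$percentiles == 7))
  one <- distribution_summary(42)
  expect_true(all(one$percentiles == 42) && one$mean == 42)
  expect_error(distribution_summary(numeric(0)), class = "input_error")
})

test_that("paired experiments are reproducible and symmetric by construction", {
  a <- run_paired_experiment("bimodal_babile_like", n_years = 3, seed = 21)
  b <- run_paired_experiment("bimodal_babile_like", n_years = 3, seed = 21)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 3)
  # two copies of the same strategy give identical columns
  st <- default_strategies()
  twin <- list(
    strategy_spec("a_side", st$late_early_maturing$genotype,
                  st$late_early_maturing$rules),
    strategy_spec("b_side", st$late_early_maturing$genotype,
                  st$late_early_maturing$rules))
  tw <- run_paired_experiment("bimodal_babile_like", n_years = 3, seed = 21,
                              strategies = twin)
  expect_equal(tw$a_side_yield, tw$b_side_yield)
  expect_equal(tw$a_side_biomass, tw$b_side_biomass)
})

test_that("summary statistics are invariant to year order", {
  p <- run_paired_experiment("bimodal_babile_like", n_years = 8, seed = 13)
  perm <- p[sample(nrow(p)), ]
  attr(perm, "labels") <- attr(p, "labels")
  class(perm) <- class(p)
  s1 <- tradeoff_summary(p)
  s2 <- tradeoff_summary(perm)
  expect_equal(s1$yield_fit, s2$yield_fit)
  expect_equal(s1$distributions, s2$distributions)
  c1 <- classify_seasons(p)
  c2 <- classify_seasons(perm)
  expect_equal(c1$means[order(c1$means$tercile), -1],
               c2$means[order(c2$means$tercile), -1], tolerance = 1e-12)
})

test_that("season classification flags the constructed dominance pattern", {
  # synthetic paired data where the late strategy wins grain everywhere
  d <- data.frame(
    year = 2001:2012,
    early_yield = seq(100, 650, 50),
    early_biomass = seq(500, 1600, 100),
    late_yield = seq(100, 650, 50) + 80,
    late_biomass = seq(500, 1600, 100) - 120,
    early_failed = FALSE, late_failed = FALSE)
  names(d) <- c("year", "e_yield", "e_biomass", "l_yield", "l_biomass",
                "e_failed", "l_failed")
  names(d) <- sub("^e_", "early_late_maturing_", names(d))
  names(d) <- sub("^l_", "late_early_maturing_", names(d))
  attr(d, "labels") <- c("early_late_maturing", "late_early_maturing")
  class(d) <- c("paired_years", "data.frame")
  cs <- classify_seasons(d)
  expect_true(all(cs$means$late_yield >= cs$means$early_yield))
  expect_true(cs$patterns[["late_more_grain_except_good"]])
  expect_error(classify_seasons(d[1:4, ]), class = "input_error")
})
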