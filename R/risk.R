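# The headline experiment: long-term paired simulation of early sowing
# with the late-maturing landrace vs late sowing with the early-maturing
# variety, trade-off regression and distribution summaries, and season
# classification into poor/average/good terciles.

#' Specification of a sowing strategy
#'
#' @param label strategy label.
#' @param genotype a [genotype_params()].
#' @param rules a [management_rules()].
#' @return object of class `strategy_spec`.
#' @export
strategy_spec <- function(label, genotype, rules) {
  structure(list(label = label, genotype = genotype, rules = rules),
            class = "strategy_spec")
}

#' The two default sowing strategies
#'
#' * `early_late_maturing`: the late-maturing landrace (Jigurti) sown at
#'   the onset of rains, from April 1 to June 15, once 3 rain events of
#'   at least 5 mm have accumulated 25 mm over 15 days ("after 3--4 rain
#'   showers"); in bimodal climates this sows on the April peak, in
#'   unimodal climates at the true onset in May--June;
#' * `late_early_maturing`: the early-maturing variety (Meko) sown in
#'   July after a single planting rain of at least 15 mm.
#'
#' @return named list of two [strategy_spec()]s.
#' @export
default_strategies <- function() {
  list(
    early_late_maturing = strategy_spec(
      "early_late_maturing", jigurti(),
      management_rules("04-01", "06-15", min_events = 3, min_event_mm = 5,
                       cum_mm = 25, lookback_days = 15)),
    late_early_maturing = strategy_spec(
      "late_early_maturing", meko(),
      management_rules("07-01", "07-31", min_events = 1, min_event_mm = 15,
                       cum_mm = 15, lookback_days = 5))
  )
}

#' Default soil profile for a climate preset
#'
#' The experimental-site presets use the bundled field-characterized
#' profiles; the regional presets use synthetic 1 m Vertisol-like profiles
#' with plant available water capacity around 120--135 mm, matching the
#' shallow profiles typical of the long-term study sites.
#'
#' @param preset a [climate_preset()] name.
#' @return a [soil_profile()].
#' @export
preset_soil <- function(preset) {
  switch(preset,
    melkassa_like = soil_fixture("melkassa"),
    miesso_like = soil_fixture("miesso"),
    unimodal_shiraro_like = soil_profile(
      top_cm = c(0, 15, 30, 60), bottom_cm = c(15, 30, 60, 100),
      bd = c(1.25, 1.25, 1.3, 1.3),
      dul = c(0.32, 0.32, 0.31, 0.30), cll = c(0.19, 0.19, 0.19, 0.18),
      site = "shiraro_synthetic"),
    bimodal_babile_like = soil_profile(
      top_cm = c(0, 15, 30, 60), bottom_cm = c(15, 30, 60, 100),
      bd = c(1.25, 1.25, 1.3, 1.3),
      dul = c(0.33, 0.33, 0.32, 0.31), cll = c(0.19, 0.19, 0.19, 0.18),
      site = "babile_synthetic"),
    abort(paste("unknown preset:", preset), "input_error")
  )
}

#' Long-term paired sowing-strategy experiment
#'
#' For each simulated year both strategies face the same weather
#' realization (a paired design). Seasons are initialized independently:
#' each year the profile is reset to the crop lower limit on 1 October of
#' the preceding year -- the state a harvested crop leaves behind -- and
#' carried to the strategy's sowing date by a bare-soil fallow run, so
#' off-season and pre-season rains are banked by the weather itself
#' rather than by assumption. A year whose sowing trigger never fires, or
#' whose crop dies before anthesis, scores zero yield and biomass with a
#' flag -- failure risk is part of the analysis.
#'
#' @param preset a [climate_preset()] name (or a `climate_normals`).
#' @param n_years number of years to simulate (>= 2).
#' @param seed weather seed.
#' @param soil a [soil_profile()]; defaults to [preset_soil()].
#' @param strategies list of two [strategy_spec()]s, default
#'   [default_strategies()].
#' @param config a [sim_config()].
#' @param fallow_start_md month-day (`"mm-dd"`) of the preceding year on
#'   which the reset-to-CLL fallow begins.
#' @return object of class `paired_years`: a data frame with one row per
#'   year and per-strategy columns `<label>_yield`, `<label>_biomass`
#'   (g m^-2), `<label>_failed`.
#' @export
run_paired_experiment <- function(preset = "bimodal_babile_like",
                                  n_years = 30, seed = 1,
                                  soil = NULL, strategies = default_strategies(),
                                  config = sim_config(),
                                  fallow_start_md = "10-01") {
  if (n_years < 2) abort("need at least 2 years", "input_error")
  normals <- if (inherits(preset, "climate_normals")) preset else climate_preset(preset)
  preset_name <- attr(normals, "site")
  if (is.null(soil)) soil <- preset_soil(preset_name)
  # one extra lead year so lookback windows never under-run the record
  wx <- generate_weather(normals, n_years = n_years + 1L, seed = seed)
  years <- sort(unique(wx$year))[-1]
  base_profile <- soil
  base_profile$sw <- base_profile$cll

  one_strategy <- function(strat, year) {
    sow <- find_sowing_date(wx, strat$rules, year)
    if (is.na(sow)) {
      return(list(yield = 0, biomass = 0, failed = TRUE,
                  reason = "sowing trigger never met"))
    }
    prof <- simulate_fallow(wx, base_profile,
                            from = as.Date(sprintf("%d-%s", year - 1L,
                                                   fallow_start_md)),
                            to = sow, config = config)
    res <- run_season(wx, prof, strat$genotype, sow,
                      density = strat$rules$density, config = config)
    list(yield = res$grain_yield, biomass = res$total_biomass,
         failed = res$failed, reason = res$fail_reason)
  }

  labels <- vapply(strategies, `[[`, "", "label")
  rows <- lapply(years, function(y) {
    out <- list(year = y)
    for (s in strategies) {
      r <- one_strategy(s, y)
      out[[paste0(s$label, "_yield")]] <- r$yield
      out[[paste0(s$label, "_biomass")]] <- r$biomass
      out[[paste0(s$label, "_failed")]] <- r$failed
    }
    as.data.frame(out)
  })
  d <- do.call(rbind, rows)
  attr(d, "site") <- preset_name
  attr(d, "labels") <- unname(labels)
  class(d) <- c("paired_years", "data.frame")
  d
}

#' Ordinary least squares via the normal equations
#'
#' @param x,y numeric vectors, `n >= 3`, `var(x) > 0`.
#' @return list with `slope`, `intercept`, `r2`.
#' @export
ols_fit <- function(x, y) {
  n <- length(x)
  if (n < 3 || length(y) != n) abort("need n >= 3 paired observations", "fit_error")
  if (stats::var(x) == 0) abort("zero variance in x: regression undefined", "fit_error")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' Percentile/mean summary of a distribution
#'
#' Percentiles 5/25/50/75/95 by linear interpolation between order
#' statistics (the default type-7 convention), plus mean and median
#' (the 50th percentile).
#'
#' @param values numeric vector, non-empty.
#' @return named list with `percentiles` (named vector), `mean`, `median`.
#' @export
distribution_summary <- function(values) {
  if (length(values) == 0) abort("empty input", "input_error")
  q <- stats::quantile(values, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                       type = 7, names = TRUE)
  list(percentiles = q, mean = mean(values), median = unname(q["50%"]))
}

#' Classify seasons into quality terciles and compare strategies
#'
#' Season quality is proxied by the early strategy's total biomass rank
#' (configurable): the early-sown long-duration crop integrates the whole
#' season's water, so its biomass separates poor from good years. Years
#' are split into terciles and per-tercile strategy means reported,
#' along with whether the two exception patterns hold: the late strategy
#' yields more grain except in very good seasons, and less biomass except
#' in poor seasons.
#'
#' @param paired a [run_paired_experiment()] result.
#' @param by ranking variable: `"early_biomass"` (default) or
#'   `"late_biomass"`.
#' @return list with `terciles` (per-year assignment), `means` (data
#'   frame of per-tercile strategy means) and `patterns` (named logicals).
#' @export
classify_seasons <- function(paired, by = c("early_biomass", "late_biomass")) {
  by <- match.arg(by)
  if (nrow(paired) < 6) abort("need at least 6 years to form terciles", "input_error")
  labels <- attr(paired, "labels")
  early <- labels[1]; late <- labels[2]
  rank_var <- paired[[paste0(if (by == "early_biomass") early else late,
                             "_biomass")]]
  terc <- cut(rank(rank_var, ties.method = "first"),
              breaks = stats::quantile(rank(rank_var, ties.method = "first"),
                                       probs = c(0, 1/3, 2/3, 1)),
              labels = c("poor", "average", "good"), include.lowest = TRUE)
  agg <- function(col) tapply(paired[[col]], terc, mean)
  means <- data.frame(
    tercile = c("poor", "average", "good"),
    early_yield = as.numeric(agg(paste0(early, "_yield"))),
    late_yield = as.numeric(agg(paste0(late, "_yield"))),
    early_biomass = as.numeric(agg(paste0(early, "_biomass"))),
    late_biomass = as.numeric(agg(paste0(late, "_biomass")))
  )
  patterns <- c(
    late_more_grain_except_good =
      all(means$late_yield[means$tercile != "good"] >=
            means$early_yield[means$tercile != "good"]),
    late_less_biomass_except_poor =
      all(means$late_biomass[means$tercile != "poor"] <=
            means$early_biomass[means$tercile != "poor"]),
    late_reduced_risk_in_poor =
      means$late_biomass[means$tercile == "poor"] >=
        means$early_biomass[means$tercile == "poor"]
  )
  list(terciles = data.frame(year = paired$year, tercile = terc),
       means = means, patterns = patterns)
}

#' Trade-off summary across paired years
#'
#' The regression of late-strategy on early-strategy outcomes (grain
#' yield and total biomass, kg ha^-1) plus per-strategy distribution
#' summaries -- the scatter-plus-boxplot view of the trade-off.
#'
#' @param paired a [run_paired_experiment()] result.
#' @return list with `yield_fit`, `biomass_fit` (from [ols_fit()], on the
#'   kg ha^-1 scale) and `distributions` (per strategy, per variable).
#' @export
tradeoff_summary <- function(paired) {
  labels <- attr(paired, "labels")
  early <- labels[1]; late <- labels[2]
  ey <- paired[[paste0(early, "_yield")]] * 10
  ly <- paired[[paste0(late, "_yield")]] * 10
  eb <- paired[[paste0(early, "_biomass")]] * 10
  lb <- paired[[paste0(late, "_biomass")]] * 10
  list(
    yield_fit = ols_fit(ey, ly),
    biomass_fit = ols_fit(eb, lb),
    distributions = list(
      early = list(yield = distribution_summary(ey),
                   biomass = distribution_summary(eb)),
      late = list(yield = distribution_summary(ly),
                  biomass = distribution_summary(lb))
    )
  )
}
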