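# Season orchestration: the fixed daily order of weather -> water ->
# phenology -> growth -> canopy, sowing-rule evaluation, bare-soil fallow
# runs, and the two bundled validation fixtures.

#' Simulation configuration
#'
#' Collects the numerical constants of the water balance and canopy
#' routines. Defaults are conventional values for a semi-arid clay-soil
#' sorghum system; none of the headline comparisons depend on their exact
#' values.
#'
#' @param cn USDA runoff curve number.
#' @param swcon daily drainage fraction of water above DUL.
#' @param u_evap stage-1 soil evaporation capacity (mm).
#' @param alpha_evap stage-2 soil evaporation coefficient (mm day^-0.5).
#' @param te_coeff transpiration-efficiency coefficient (Pa).
#' @param root_advance root front advance (cm per degC d) from emergence
#'   until flag leaf.
#' @param root_init_cm rooting depth at emergence (cm).
#' @param senes_max_frac daily cap on stress-senesced LAI fraction.
#' @param stress_senes_threshold supply/demand ratio below which leaves
#'   are senesced for lack of water.
#' @param fail_days consecutive fully-stressed (`sd_ratio = 0`)
#'   pre-anthesis days that kill the crop.
#' @param max_days hard stop on season length (days after sowing).
#' @param irrigation `NULL` for dryland, or an [irrigation_rule()].
#' @return a named list.
#' @export
sim_config <- function(cn = 80, swcon = 0.3, u_evap = 6, alpha_evap = 3.5,
                       te_coeff = 9, root_advance = 0.1, root_init_cm = 10,
                       senes_max_frac = 0.1, stress_senes_threshold = 0.3,
                       fail_days = 15, max_days = 250,
                       irrigation = NULL) {
  list(cn = cn, swcon = swcon, u_evap = u_evap, alpha_evap = alpha_evap,
       te_coeff = te_coeff, root_advance = root_advance,
       root_init_cm = root_init_cm, senes_max_frac = senes_max_frac,
       stress_senes_threshold = stress_senes_threshold,
       fail_days = fail_days, max_days = max_days, irrigation = irrigation)
}

#' Irrigation rule
#'
#' Models "irrigated every n days" furrow irrigation as refilling the top
#' `depth_cm` of soil to the drained upper limit every `interval_days`
#' from sowing to maturity; applied depths are whatever that deficit is.
#'
#' @param interval_days days between irrigations.
#' @param depth_cm wetted depth (cm).
#' @return a named list.
#' @export
irrigation_rule <- function(interval_days = 5, depth_cm = 60) {
  list(interval_days = interval_days, depth_cm = depth_cm)
}

#' Planting density from row and plant spacing
#'
#' @param row_spacing_m,plant_spacing_m spacings (m).
#' @return plants per m^2, reported to one decimal.
#' @export
#' @examples
#' planting_density(0.75, 0.15) # 8.9
planting_density <- function(row_spacing_m, plant_spacing_m) {
  if (row_spacing_m <= 0 || plant_spacing_m <= 0) {
    abort("spacings must be positive", "input_error")
  }
  round(1 / (row_spacing_m * plant_spacing_m), 1)
}

#' Management rules for a sowing strategy
#'
#' @param window_start,window_end sowing window as `"mm-dd"` strings.
#' @param min_events minimum number of qualifying rain days in the
#'   lookback window.
#' @param min_event_mm rain (mm) for a day to qualify as an event.
#' @param cum_mm minimum cumulative rain (mm) over the lookback window.
#' @param lookback_days length of the lookback window (days, inclusive of
#'   the candidate day).
#' @param density plants m^-2; if `row_spacing_m` and `plant_spacing_m`
#'   are given the density must agree with them within 1%.
#' @param row_spacing_m,plant_spacing_m optional spacings (m).
#' @return object of class `management_rules`.
#' @export
management_rules <- function(window_start, window_end,
                             min_events = 1, min_event_mm = 10,
                             cum_mm = 10, lookback_days = 7,
                             density = 8.9,
                             row_spacing_m = NULL, plant_spacing_m = NULL) {
  parse_md <- function(s) {
    p <- as.integer(strsplit(s, "-")[[1]])
    if (length(p) != 2 || any(is.na(p))) abort("window dates must be 'mm-dd'", "input_error")
    p
  }
  ws <- parse_md(window_start); we <- parse_md(window_end)
  if (ws[1] * 100 + ws[2] >= we[1] * 100 + we[2]) {
    abort("sowing window start must precede its end", "input_error")
  }
  if (!is.null(row_spacing_m) && !is.null(plant_spacing_m)) {
    implied <- 1 / (row_spacing_m * plant_spacing_m)
    if (abs(density - implied) / implied > 0.01) {
      abort("density disagrees with row/plant spacing by more than 1%", "input_error")
    }
  }
  structure(list(window_start = window_start, window_end = window_end,
                 min_events = min_events, min_event_mm = min_event_mm,
                 cum_mm = cum_mm, lookback_days = lookback_days,
                 density = density),
            class = "management_rules")
}

#' Find the sowing date triggered by rain within a window
#'
#' Scans the sowing window of `year` for the first day on which, over the
#' preceding `lookback_days` (inclusive), at least `min_events` days had
#' rain of at least `min_event_mm` and cumulative rain reached `cum_mm`.
#'
#' @param weather a `weather_series`.
#' @param rules a [management_rules()].
#' @param year calendar year to scan.
#' @return the sowing `Date`, or `NA` if the trigger is never met.
#' @export
find_sowing_date <- function(weather, rules, year) {
  w_start <- as.Date(sprintf("%d-%s", year, rules$window_start))
  w_end <- as.Date(sprintf("%d-%s", year, rules$window_end))
  if (w_start < min(weather$date) || w_end > max(weather$date)) {
    abort("sowing window falls outside the weather record", "input_error")
  }
  idx <- which(weather$date >= w_start & weather$date <= w_end)
  for (i in idx) {
    lb <- max(1L, i - rules$lookback_days + 1L):i
    r <- weather$rain[lb]
    if (sum(r >= rules$min_event_mm) >= rules$min_events &&
        sum(r) >= rules$cum_mm) {
      return(weather$date[i])
    }
  }
  as.Date(NA)
}

#' Bare-soil fallow water balance
#'
#' Runs rain partitioning, drainage and soil evaporation (no crop, zero
#' cover) over a date span; used to carry the profile from the start of a
#' year to a sowing date so pre-season rains are stored realistically.
#'
#' @param weather a `weather_series` covering the span.
#' @param soil a [soil_profile()].
#' @param from,to `Date` bounds (inclusive of `from`, exclusive of `to`).
#' @param config a [sim_config()].
#' @return the updated `soil_profile`.
#' @export
simulate_fallow <- function(weather, soil, from, to, config = sim_config()) {
  idx <- which(weather$date >= from & weather$date < to)
  evap <- evap_state_init(config$u_evap)
  for (i in idx) {
    pr <- partition_rain(weather$rain[i], soil, cn = config$cn)
    soil <- pr$profile
    dr <- drain(soil, swcon = config$swcon)
    soil <- dr$profile
    se <- soil_evaporation(soil, evap, weather$radn[i], weather$tmax[i],
                           weather$tmin[i], cover = 0,
                           infiltration = pr$infiltration,
                           u = config$u_evap, alpha = config$alpha_evap)
    soil <- se$profile
    evap <- se$evap_state
  }
  soil
}

#' Simulate one cropping season
#'
#' Runs the daily loop from sowing to physiological maturity (or failure)
#' in a fixed order: (1) irrigation and rain partitioning with drainage,
#' (2) soil evaporation, (3) thermal time and stage advance, (4) potential
#' growth from the previous day's canopy, (5) water supply/demand and the
#' stress index, (6) actual growth and transpiration extraction,
#' (7) partitioning / grain fill, (8) canopy expansion and senescence,
#' (9) root advance, (10) water- and carbon-closure assertions. A crop
#' fully stressed (`sd_ratio = 0`) for `fail_days` consecutive days before
#' anthesis is recorded as failed with zero yield.
#'
#' @param weather a `weather_series` covering the season.
#' @param soil a [soil_profile()] with `sw` set to the water content at
#'   sowing (it is copied, not modified).
#' @param genotype a [genotype_params()].
#' @param sowing_date `Date`, must exist in `weather`.
#' @param density plants m^-2.
#' @param config a [sim_config()].
#' @param trace logical; also return the daily trace data frame.
#' @return object of class `season_result`: dates of emergence, panicle
#'   initiation, anthesis and maturity; `grain_yield` and `total_biomass`
#'   (g m^-2, with `yield_kg_ha = grain_yield * 10`); `peak_lai`,
#'   `final_green_lai`, `harvest_index`, `grain_number`; `failed` flag and
#'   reason; cumulative water terms; and optionally `trace`.
#' @export
run_season <- function(weather, soil, genotype, sowing_date, density = 8.9,
                       config = sim_config(), trace = FALSE) {
  i0 <- match(as.Date(sowing_date), weather$date)
  if (is.na(i0)) abort("sowing date not found in the weather series", "input_error")
  i1 <- min(i0 + config$max_days, nrow(weather))

  profile <- soil
  pheno <- pheno_init("sown")
  canopy <- canopy_init()
  pools <- pools_init()
  evap <- evap_state_init(config$u_evap)
  leaf_profile <- profile_from_tln(genotype$tln, genotype,
                                   a = genotype$a, b = genotype$b)
  max_root <- max(profile$bottom_cm)
  root_depth <- 0
  cum <- c(growth = 0, infil = 0, irrig = 0, runoff = 0, drain = 0,
           evap = 0, transp = 0)
  window_growth <- 0; window_days <- 0L
  peak_lai <- 0; lai_at_anthesis <- NA_real_
  dates <- list(emergence = as.Date(NA), pi = as.Date(NA),
                anthesis = as.Date(NA), maturity = as.Date(NA))
  failed <- FALSE; fail_reason <- NA_character_
  stress_run <- 0L
  rows <- if (trace) vector("list", i1 - i0 + 1L) else NULL

  for (i in i0:i1) {
    day <- weather$date[i]
    das <- as.integer(i - i0)
    storage0 <- sum(profile$sw * layer_thickness_mm(profile))

    # (1) irrigation deficit refill, then rain partitioning and drainage
    irrig <- 0
    if (!is.null(config$irrigation) && das > 0 &&
        das %% config$irrigation$interval_days == 0) {
      fr <- root_fraction(profile, config$irrigation$depth_cm)
      deficit <- sum(pmax(0, profile$dul - profile$sw) *
                       layer_thickness_mm(profile) * fr)
      if (deficit > 0) {
        res <- add_water_top_down(profile, deficit)
        profile <- res$profile
        irrig <- deficit - res$overflow
      }
    }
    pr <- partition_rain(weather$rain[i], profile, cn = config$cn)
    profile <- pr$profile
    # profile overflow is treated as water that entered and immediately
    # drained, so it appears on both sides of the closure
    water_in <- irrig + pr$infiltration
    dr <- drain(profile, swcon = config$swcon)
    profile <- dr$profile
    drainage <- dr$drainage + pr$overflow

    # (2) soil evaporation under the previous day's cover
    cover <- light_interception(canopy$lai_green, genotype$extinction_k)
    se <- soil_evaporation(profile, evap, weather$radn[i], weather$tmax[i],
                           weather$tmin[i], cover = cover,
                           infiltration = pr$infiltration + irrig,
                           u = config$u_evap, alpha = config$alpha_evap)
    profile <- se$profile
    evap <- se$evap_state

    # (3) thermal time and stage advance
    d_tt_pre <- daily_thermal_time(weather$tmax[i], weather$tmin[i],
                                   genotype$pre_anthesis, "pre_anthesis")
    d_tt_post <- daily_thermal_time(weather$tmax[i], weather$tmin[i],
                                    genotype$post_anthesis, "post_anthesis")
    stage_before <- pheno$stage
    pheno <- pheno_advance(pheno, d_tt_pre, d_tt_post, genotype)
    stage <- pheno$stage
    if (is.na(dates$emergence) && stage != "sown") dates$emergence <- day
    if (is.na(dates$pi) && match(stage, STAGES) >= match("pi", STAGES)) {
      dates$pi <- day
    }
    entering_anthesis <- match(stage_before, STAGES) < match("anthesis", STAGES) &&
      match(stage, STAGES) >= match("anthesis", STAGES)
    if (entering_anthesis) {
      dates$anthesis <- day
      pools$stem_at_anthesis <- pools$stem
      lai_at_anthesis <- canopy$lai_green
    }
    post_anthesis <- match(stage, STAGES) >= match("anthesis", STAGES)

    # (4) potential growth from yesterday's canopy
    growing <- stage %in% c("emerged", "pi", "flag", "anthesis", "grainfill")
    f_int <- light_interception(canopy$lai_green, genotype$extinction_k)
    pot_growth <- if (growing) weather$radn[i] * f_int * genotype$rue else 0

    # (5) supply, demand, stress
    vpd <- vpd_estimate(weather$tmax[i], weather$tmin[i])
    sdm <- supply_and_demand(profile, root_depth, pot_growth, vpd,
                             te_coeff = config$te_coeff)
    sd_ratio <- sdm$sd_ratio

    # (6) actual growth and transpiration
    actual <- pot_growth * sd_ratio
    transp <- min(sdm$demand * sd_ratio, sdm$supply)
    if (transp > 0) {
      ex <- extract_transpiration(profile, root_depth, transp)
      profile <- ex$profile
    }
    cum["growth"] <- cum["growth"] + actual

    # (7) partitioning and grain fill
    entering_fill <- stage_before != "grainfill" && stage == "grainfill"
    if (entering_fill) {
      mean_pgr <- if (window_days > 0) window_growth / window_days / density else 0
      pools$grain_number <- set_grain_number(mean_pgr,
                                             genotype$grain_number_factor,
                                             density)
    }
    if (stage %in% c("pi", "flag", "anthesis")) {
      window_growth <- window_growth + actual
      window_days <- window_days + 1L
    }
    if (stage == "grainfill" ||
        (stage == "mature" && stage_before == "grainfill")) {
      fill_total <- genotype$tt_anthesis_to_maturity - genotype$tt_anthesis_to_startgf
      pools <- grain_fill(pools, actual, d_tt_post, fill_total, genotype)
    } else if (growing) {
      past_flag <- match(stage, STAGES) >= match("flag", STAGES)
      pv <- partition_vegetative(actual, canopy$appeared_leaves,
                                 genotype$partition_k, past_flag = past_flag)
      pools$leaf <- pools$leaf + pv$to_leaf
      pools$stem <- pools$stem + pv$to_stem
    }

    # (8) canopy expansion and senescence
    if (stage %in% c("emerged", "pi", "flag")) {
      canopy <- canopy_update(canopy, d_tt_pre, genotype, density,
                              stress = sd_ratio, post_anthesis = FALSE,
                              profile = leaf_profile)
    }
    peak_lai <- max(peak_lai, canopy$lai_green)
    if (stage %in% c("emerged", "pi", "flag", "anthesis", "grainfill", "mature")) {
      tt_frac <- pheno$tt_since_anthesis / genotype$tt_anthesis_to_maturity
      sn <- senesce(pools, canopy, sd_ratio, post_anthesis, tt_frac,
                    lai_at_anthesis, k = genotype$extinction_k,
                    max_frac = config$senes_max_frac,
                    stress_threshold = config$stress_senes_threshold)
      pools <- sn$pools
      canopy <- sn$canopy
    }

    # (9) root advance from emergence to flag leaf
    if (stage %in% c("emerged", "pi")) {
      if (root_depth == 0) root_depth <- config$root_init_cm
      root_depth <- min(root_depth + config$root_advance * d_tt_pre, max_root)
    }

    # (10) closure assertions (bug traps, never swallowed)
    storage1 <- sum(profile$sw * layer_thickness_mm(profile))
    water_resid <- (storage1 - storage0) -
      (water_in - drainage - se$evaporation - transp)
    if (abs(water_resid) > 1e-6) {
      stop(sprintf("water balance closure violated on %s: residual %.3g mm",
                   format(day), water_resid))
    }
    carbon <- pools$leaf + pools$stem + pools$grain + pools$dead_leaf
    if (abs(carbon - cum["growth"]) > 1e-6) {
      stop(sprintf("carbon closure violated on %s: pools %.6f vs growth %.6f",
                   format(day), carbon, cum["growth"]))
    }

    cum["infil"] <- cum["infil"] + pr$infiltration
    cum["irrig"] <- cum["irrig"] + irrig
    cum["runoff"] <- cum["runoff"] + pr$runoff
    cum["drain"] <- cum["drain"] + drainage
    cum["evap"] <- cum["evap"] + se$evaporation
    cum["transp"] <- cum["transp"] + transp

    if (trace) {
      rows[[i - i0 + 1L]] <- data.frame(
        date = day, das = das, stage = stage, tt = pheno$tt_since_emergence,
        lai_green = canopy$lai_green, leaf = pools$leaf, stem = pools$stem,
        grain = pools$grain, dead_leaf = pools$dead_leaf, total = carbon,
        sd_ratio = sd_ratio, sw_available_mm = profile_available_sw(profile))
    }

    # crop failure: fully stressed before anthesis
    if (!post_anthesis && growing && sd_ratio <= 0) {
      stress_run <- stress_run + 1L
    } else {
      stress_run <- 0L
    }
    if (stress_run >= config$fail_days) {
      failed <- TRUE
      fail_reason <- sprintf("crop death: supply/demand ratio 0 for %d days pre-anthesis",
                             config$fail_days)
      break
    }
    if (stage == "mature") {
      dates$maturity <- day
      break
    }
  }
  if (!failed && is.na(dates$maturity)) {
    failed <- TRUE
    fail_reason <- "season ended before physiological maturity"
  }

  total <- pools$leaf + pools$stem + pools$grain + pools$dead_leaf
  grain <- if (failed) 0 else pools$grain
  total_out <- if (failed) 0 else total
  res <- list(
    genotype = genotype$name,
    sowing_date = as.Date(sowing_date),
    emergence_date = dates$emergence, pi_date = dates$pi,
    anthesis_date = dates$anthesis, maturity_date = dates$maturity,
    grain_yield = grain, yield_kg_ha = grain * 10,
    total_biomass = total_out, biomass_kg_ha = total_out * 10,
    harvest_index = if (total_out > 0) grain / total_out else 0,
    peak_lai = peak_lai, final_green_lai = canopy$lai_green,
    grain_number = pools$grain_number,
    failed = failed, fail_reason = fail_reason,
    water = as.list(cum), final_profile = profile
  )
  if (trace) res$trace <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  class(res) <- "season_result"
  res
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf("Season result for %s, sown %s\n", x$genotype,
              format(x$sowing_date)))
  if (x$failed) cat("  FAILED:", x$fail_reason, "\n")
  cat(sprintf("  anthesis %s, maturity %s\n",
              format(x$anthesis_date), format(x$maturity_date)))
  cat(sprintf("  grain yield %.0f g/m^2 (%.0f kg/ha), biomass %.0f g/m^2, HI %.2f, peak LAI %.2f\n",
              x$grain_yield, x$yield_kg_ha, x$total_biomass,
              x$harvest_index, x$peak_lai))
  invisible(x)
}

#' Run a bundled validation fixture
#'
#' Pairs a field-characterized soil profile with seeded synthetic weather
#' resembling the site's season and runs both reference genotypes:
#'
#' * `melkassa2014`: sown 9 June, irrigated every 5 days (well-watered);
#' * `miesso2016`: sown 8 July, dryland, profile water at sowing as
#'   measured.
#'
#' Because the true station weather is not distributed, the checks are
#' directional (which genotype accumulates more biomass, who senesces,
#' plausible harvest-index range), never numeric point matches.
#'
#' @param name `"melkassa2014"` or `"miesso2016"`.
#' @param seed seed for the weather realization.
#' @return list with per-genotype `season_result`s and a `checks` data
#'   frame of named logical outcomes.
#' @export
run_fixture <- function(name = c("melkassa2014", "miesso2016"), seed = 1406) {
  name <- match.arg(name)
  if (name == "melkassa2014") {
    soil <- soil_fixture("melkassa")
    wx <- generate_weather(climate_preset("melkassa_like"), n_years = 1,
                           seed = seed, start_year = 2014)
    cfg <- sim_config(irrigation = irrigation_rule(5, 60))
    sow <- as.Date("2014-06-09")
  } else {
    soil <- soil_fixture("miesso")
    # the dryland experiment season had little rain after early August and
    # ended in terminal water stress; the fixture uses normals for such a
    # below-average year, not the site's long-term average
    nm <- climate_preset("miesso_like")
    dry <- climate_normals(
      rain_total = c(10, 15, 55, 80, 45, 40, 80, 30, 10, 0, 0, 0),
      rain_days = c(1, 2, 5, 7, 5, 4, 7, 3, 1, 0, 0, 0),
      tmax_mean = nm$tmax_mean, tmin_mean = nm$tmin_mean,
      radn_mean = nm$radn_mean, site = "miesso_2016_like_dry",
      latitude = attr(nm, "latitude"))
    wx <- generate_weather(dry, n_years = 1, seed = seed, start_year = 2016)
    cfg <- sim_config()
    sow <- as.Date("2016-07-08")
  }
  res_m <- run_season(wx, soil, meko(), sow, density = 8.9, config = cfg)
  res_j <- run_season(wx, soil, jigurti(), sow, density = 8.9, config = cfg)
  checks <- if (name == "melkassa2014") {
    data.frame(
      check = c("jigurti_biomass_gt_meko", "meko_hi_gt_jigurti",
                "hi_in_plausible_range", "meko_matures_first"),
      passed = c(res_j$total_biomass > res_m$total_biomass,
                 res_m$harvest_index > res_j$harvest_index,
                 all(c(res_m$harvest_index, res_j$harvest_index) > 0.2 &
                       c(res_m$harvest_index, res_j$harvest_index) < 0.55),
                 res_m$maturity_date < res_j$maturity_date))
  } else {
    data.frame(
      check = c("jigurti_fully_senesced", "meko_yield_ge_jigurti"),
      passed = c(res_j$final_green_lai < 0.1,
                 res_m$grain_yield >= res_j$grain_yield))
  }
  list(fixture = name, meko = res_m, jigurti = res_j, checks = checks)
}
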