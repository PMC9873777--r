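# Daily layered soil-water accounting: curve-number runoff, cascading
# drainage, two-stage soil evaporation, root-zone supply, transpiration
# extraction, and the supply/demand ratio that couples water to growth.
#
# The water state is carried on the `sw` column of a soil_profile plus a
# few scalar accumulators; every operation returns the updated profile (or
# a list holding it) so the daily loop stays purely functional.

air_dry_sw <- function(profile) 0.5 * profile$cll
saturation_sw <- function(profile) profile$dul + 0.05

#' Partition daily rain into runoff and infiltration
#'
#' Runoff follows the USDA curve-number relation with retention
#' `S = 25400 / CN - 254` (mm): runoff is
#' `(rain - 0.2 S)^2 / (rain + 0.8 S)` once rain exceeds the initial
#' abstraction `0.2 S`, else zero. Infiltration (rain minus runoff) fills
#' layers from the top down, each to saturation before spilling deeper;
#' water pushed below the bottom layer is lost as deep drainage.
#'
#' @param rain daily rain (mm).
#' @param profile a [soil_profile()] carrying current `sw`.
#' @param cn curve number (default 80).
#' @return list with `runoff` (mm), `infiltration` (mm), `overflow` (mm
#'   passed below the profile) and the updated `profile`.
#' @export
partition_rain <- function(rain, profile, cn = 80) {
  if (rain < 0) abort("rain must be non-negative", "invalid_weather")
  s <- 25400 / cn - 254
  runoff <- if (rain > 0.2 * s) (rain - 0.2 * s)^2 / (rain + 0.8 * s) else 0
  infil <- rain - runoff
  res <- add_water_top_down(profile, infil)
  list(runoff = runoff, infiltration = infil, overflow = res$overflow,
       profile = res$profile)
}

# fill layers top-down to saturation; returns overflow below the profile
add_water_top_down <- function(profile, amount_mm) {
  thick <- layer_thickness_mm(profile)
  sat <- saturation_sw(profile)
  remaining <- amount_mm
  for (i in seq_len(nrow(profile))) {
    if (remaining <= 0) break
    room <- (sat[i] - profile$sw[i]) * thick[i]
    take <- min(remaining, max(room, 0))
    profile$sw[i] <- profile$sw[i] + take / thick[i]
    remaining <- remaining - take
  }
  list(profile = profile, overflow = remaining)
}

#' Drain water held above the drained upper limit
#'
#' Cascading bucket: in each layer, a fraction `swcon` of the water held
#' above DUL moves down one layer per day; flux out of the bottom layer
#' leaves the profile as deep drainage.
#'
#' @param profile a [soil_profile()].
#' @param swcon daily drainage fraction in `[0, 1]` (default 0.3).
#' @return list with `drainage` (mm leaving the profile) and `profile`.
#' @export
drain <- function(profile, swcon = 0.3) {
  if (swcon < 0 || swcon > 1) abort("swcon must lie in [0, 1]", "input_error")
  thick <- layer_thickness_mm(profile)
  sat <- saturation_sw(profile)
  flux_in <- 0
  n <- nrow(profile)
  for (i in seq_len(n)) {
    sw_mm <- profile$sw[i] * thick[i] + flux_in
    dul_mm <- profile$dul[i] * thick[i]
    flux_out <- swcon * max(0, sw_mm - dul_mm)
    sw_mm <- sw_mm - flux_out
    # anything a layer cannot hold joins the downward flux immediately
    over_sat <- max(0, sw_mm - sat[i] * thick[i])
    flux_out <- flux_out + over_sat
    profile$sw[i] <- (sw_mm - over_sat) / thick[i]
    flux_in <- flux_out
  }
  list(drainage = flux_in, profile = profile)
}

#' Atmospheric evaporative demand proxy
#'
#' Radiation/temperature-driven reference demand of Hargreaves form:
#' `0.0023 * (0.408 * radn) * (tmean + 17.8) * sqrt(tmax - tmin)`
#' (mm day^-1); the 0.408 factor converts radiation from MJ m^-2 to its
#' evaporation equivalent in mm, as the formula requires.
#'
#' @param radn daily shortwave radiation (MJ m^-2).
#' @param tmax,tmin daily temperature extremes (degC).
#' @return reference evaporative demand (mm).
#' @export
reference_evap_demand <- function(radn, tmax, tmin) {
  if (any(tmax < tmin)) abort("tmax below tmin", "invalid_weather")
  0.0023 * 0.408 * radn * ((tmax + tmin) / 2 + 17.8) * sqrt(pmax(tmax - tmin, 0))
}

#' Two-stage soil evaporation
#'
#' Potential soil evaporation is 0.75 of the reference demand reduced by
#' canopy cover. After wetting, evaporation proceeds at the potential rate
#' until a cumulative `u` mm has evaporated (stage 1), then declines as
#' `alpha * (sqrt(t) - sqrt(t - 1))` per day (stage 2). Water is taken
#' from the top layer only and never below air-dry.
#'
#' @param profile a [soil_profile()].
#' @param evap_state list with `stage1_remaining` (mm) and `t2` (days in
#'   stage 2); start a season with `evap_state_init()`.
#' @param radn,tmax,tmin the day's weather.
#' @param cover fractional canopy cover in `[0, 1]`.
#' @param infiltration today's infiltration (mm), which rewets the surface
#'   and restores stage-1 capacity.
#' @param u stage-1 capacity (mm, default 6).
#' @param alpha stage-2 coefficient (mm day^-0.5, default 3.5).
#' @return list with `evaporation` (mm), `profile`, `evap_state`.
#' @export
soil_evaporation <- function(profile, evap_state, radn, tmax, tmin,
                             cover, infiltration = 0, u = 6, alpha = 3.5) {
  if (cover < 0 || cover > 1) abort("cover must lie in [0, 1]", "input_error")
  pot <- 0.75 * reference_evap_demand(radn, tmax, tmin) * (1 - cover)
  # infiltration refills stage-1 storage; a full rewetting restarts stage 1
  evap_state$stage1_remaining <- min(u, evap_state$stage1_remaining + infiltration)
  if (evap_state$stage1_remaining > 0) evap_state$t2 <- 0
  if (evap_state$stage1_remaining > 0) {
    es <- min(pot, evap_state$stage1_remaining)
    evap_state$stage1_remaining <- evap_state$stage1_remaining - es
  } else {
    evap_state$t2 <- evap_state$t2 + 1
    es <- min(pot, alpha * (sqrt(evap_state$t2) - sqrt(evap_state$t2 - 1)))
  }
  thick1 <- layer_thickness_mm(profile)[1]
  extractable <- max(0, (profile$sw[1] - air_dry_sw(profile)[1]) * thick1)
  es <- min(es, extractable)
  profile$sw[1] <- profile$sw[1] - es / thick1
  list(evaporation = es, profile = profile, evap_state = evap_state)
}

#' @rdname soil_evaporation
#' @export
evap_state_init <- function(u = 6) list(stage1_remaining = u, t2 = 0)

#' Daytime vapour pressure deficit estimate
#'
#' Tanner--Sinclair convention: 0.75 of the saturation vapour pressure
#' span between the daily extremes, with
#' `svp(T) = 0.6106 * exp(17.27 * T / (T + 237.3))` kPa.
#'
#' @param tmax,tmin daily temperature extremes (degC).
#' @return VPD (kPa).
#' @export
vpd_estimate <- function(tmax, tmin) {
  if (any(tmax < tmin)) abort("tmax below tmin", "invalid_weather")
  svp <- function(t) 0.6106 * exp(17.27 * t / (t + 237.3))
  0.75 * (svp(tmax) - svp(tmin))
}

# per-layer root penetration fractions for a rooting depth (cm)
root_fraction <- function(profile, root_depth_cm) {
  pmin(pmax((root_depth_cm - profile$top_cm) /
              (profile$bottom_cm - profile$top_cm), 0), 1)
}

#' Root-zone water supply, transpiration demand, and their ratio
#'
#' Supply is the kl-limited extractable water over the rooted zone,
#' `sum(kl * (sw - cll) * thickness)` with the deepest rooted layer
#' pro-rated by root penetration. Demand converts the day's potential
#' (radiation-limited) growth to water via the transpiration-efficiency
#' coefficient: `TE = te_coeff / vpd` g m^-2 mm^-1, so
#' `demand = potential_growth / TE`. The stress index is
#' `sd_ratio = min(1, supply / demand)`, defined as 1 when demand is zero.
#'
#' @param profile a [soil_profile()].
#' @param root_depth_cm current rooting depth (cm).
#' @param potential_growth potential biomass increment (g m^-2).
#' @param vpd vapour pressure deficit (kPa), floored at 0.1.
#' @param te_coeff transpiration-efficiency coefficient (Pa, default 9).
#' @return list with `supply` (mm), `demand` (mm), `sd_ratio` in `[0, 1]`.
#' @export
supply_and_demand <- function(profile, root_depth_cm, potential_growth, vpd,
                              te_coeff = 9) {
  if (potential_growth < 0) abort("potential growth must be >= 0", "input_error")
  fr <- root_fraction(profile, root_depth_cm)
  supply <- sum(profile$kl * pmax(0, profile$sw - profile$cll) *
                  layer_thickness_mm(profile) * fr)
  te <- te_coeff / max(vpd, 0.1) # g biomass per m^2 per mm water
  demand <- potential_growth / te
  sd_ratio <- if (demand <= 0) 1 else min(1, supply / demand)
  list(supply = supply, demand = demand, sd_ratio = sd_ratio)
}

#' Extract transpiration water from the rooted profile
#'
#' Removes `amount` mm distributed over rooted layers in proportion to
#' each layer's kl-limited available water (`kl * (sw - cll) * thickness *
#' root fraction`); no layer is drawn below its crop lower limit. The
#' caller must keep `amount` within the current supply.
#'
#' @param profile a [soil_profile()].
#' @param root_depth_cm rooting depth (cm).
#' @param amount transpiration to extract (mm).
#' @return list with `extracted` (per-layer mm) and `profile`.
#' @export
extract_transpiration <- function(profile, root_depth_cm, amount) {
  if (amount < 0) abort("extraction must be non-negative", "input_error")
  thick <- layer_thickness_mm(profile)
  fr <- root_fraction(profile, root_depth_cm)
  avail <- profile$kl * pmax(0, profile$sw - profile$cll) * thick * fr
  total <- sum(avail)
  if (amount > total + 1e-9) {
    abort("transpiration request exceeds root-zone supply", "contract_violation")
  }
  take <- if (total > 0) amount * avail / total else avail * 0
  # guard against floating-point undershoot of the crop lower limit
  # (evaporation may hold the top layer below cll already; never add water)
  profile$sw <- pmax(profile$sw - take / thick,
                     pmin(profile$sw, profile$cll))
  list(extracted = take, profile = profile)
}
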