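---
title: "Simulating sorghum growth and sowing-strategy risk in the Ethiopian dry lowlands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating sorghum growth and sowing-strategy risk in the Ethiopian dry lowlands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorghumsim)
```

## The problem

Dry-lowland Ethiopian sorghum farmers choose between two production
systems: sowing a late-maturing, tall landrace (here parameterized as
*Jigurti*) on the first small rains in April, or waiting for the main
rains and sowing a short, early-maturing improved variety (*Meko*) in
July. The early system promises more total biomass -- stover matters as
much as grain in these crop--livestock systems -- but risks dry spells
between the two rainfall peaks; the late system is safer and often
yields more grain, but produces less biomass. `sorghumsim` implements a
daily crop growth and soil-water model for these two genotypes, a
stochastic weather generator for the region's unimodal and bimodal
rainfall climates, and a paired long-term simulation experiment that
quantifies the productivity--risk trade-off between the two systems.

Everything runs from synthetic inputs: the only measured data bundled
are the two field-characterized soil profiles (`soil_fixture()`) and the
genotype coefficient sets (`meko()`, `jigurti()`).

## Soil characterization

Field soil characterization follows the standard core-sampling
equations: gravimetric water content `((wet - dry)/dry) * 100`, bulk
density `dry mass / core volume`, and volumetric water content as their
product (`gravimetric_water_pct()`, `bulk_density()`,
`volumetric_pct()`). A profile is an ordered set of contiguous layers,
each carrying bulk density, drained upper limit (DUL), crop lower limit
(CLL), current water content and a root-extraction coefficient `kl`.
Plant-available water capacity is `sum((DUL - CLL) * thickness)`; the
bundled Miesso profile (heavy clay, 1.8 m) yields 504 mm and holds
about 186 mm above CLL at sowing, while the Melkassa profile (silty
clay loam, 1.6 m) sums to about 219 mm capacity. The Melkassa table is
kept verbatim even though rounded totals quoted alongside it are
somewhat higher; we do not rescale measured layers to match a printed
total.

`kl` is not part of the field tables. The default profile
(`default_kl()`) is 0.08 day^-1 at the surface declining by 0.01 per
layer to a floor of 0.02 -- conventional values for a deep-rooted
cereal on clay -- and is configurable per layer in the profile CSV.

## Phenology

Development is driven by daily thermal time on the mean temperature
`(tmax + tmin)/2` with a broken-linear response
(`daily_thermal_time()`): zero at the base temperature, rising to
`t_opt - t_base` degree-days at the optimum. Before anthesis the
response declines to zero at a ceiling temperature (42 degC); after
anthesis it plateaus at the optimum and does not decline. Using the
daily mean rather than a sub-daily interpolation is a documented
simplification; at the temperatures of these climates the two rarely
differ by more than a few percent of a day's increment. There is no
photoperiod response, consistent with the phenology calibration of
these genotypes.

The stage sequence is sowing, emergence, panicle initiation (PI), flag
leaf, anthesis, start of grain fill, and physiological maturity. Two of
the targets are derived rather than supplied, which keeps the genotype
table internally consistent:

* emergence to PI: `(TLN - 4) * LIR` -- four leaf initials are present
  in the seed and the apex initiates the remaining leaves at `LIR`
  degree-days each before switching to panicle production. For Meko
  (TLN 15, LIR 31.5) this derives 346.5, quoted rounded as 347 degCd;
  for Jigurti the quoted 450 back-solves to an effective leaf number of
  19.5 at LIR 29, which the parameter set carries as `tln_phen`
  alongside the 19-leaf canopy profile -- the same tension exists in
  the source calibration, and we keep both numbers rather than force
  agreement.
* PI to flag leaf: the remainder of `TLN * LAR` after the PI target,
  so flag-leaf timing emerges from leaf appearance.

Two targets are not measurable from the available calibrations and are
decided here: sowing to emergence (40 degCd) and an anthesis-to-start-
of-grain-fill lag (100 degCd) taken out of the anthesis-to-maturity
target. Both are exposed in `genotype_params()`. Stage advance carries
surplus degree-days across promotions so no thermal time is lost; the
day that crosses anthesis converts its surplus onto the post-anthesis
response proportionally.

## Canopy

Individual leaf area follows the bell-shaped profile
`Y = Y0 * exp(a (X - X0)^2 + b (X - X0)^3)` where `X0` and `Y0` are the
position and area of the largest leaf, predicted from total leaf number
by linear regressions (`profile_from_tln()`); the breadth and skewness
coefficients `a` and `b` are fixed to externally calibrated linear
functions of TLN (`leaf_a_coeff()`, `leaf_b_coeff()`) rather than
refitted from sparse local data -- only `Y0` and `X0` are free when
fitting measured plants (`fit_profile_regressions()`, nonlinear least
squares per plant, then ordinary least squares on TLN). Note that `X0`
remains the curve's maximum for any skew value; `b` controls asymmetry
around it. The fractional `X0` is used as-is in the curve; the
"largest leaf" reported to users rounds half-up (leaf 14 for a 19-leaf
plant at slope 0.74).

Daily canopy dynamics: leaves appear at `1/LAR` per degree-day, capped
at TLN and halted at anthesis. Green leaf area gains the bell-curve
area of newly expanding leaf positions, scaled by plant density and by
the day's water supply/demand ratio -- expansion forfeited under stress
is not recovered, which is why a dry spell during the mid-canopy window
permanently stunts the stand. Senescence is owned by the growth module
so leaf mass and leaf area move together.

## Water balance

A layered cascading bucket:

* runoff by USDA curve number (default CN 80), infiltration filling
  layers to saturation top-down;
* drainage of a fraction `swcon` (0.3 day^-1) of water above DUL per
  layer per day, cascading downward;
* two-stage soil evaporation from the top layer: potential rate is 0.75
  of a Hargreaves-form reference demand
  (`0.0023 * 0.408 * radn * (tmean + 17.8) * sqrt(tmax - tmin)`;
  the 0.408 converts MJ m^-2 to mm of evaporation equivalent) shaded by
  canopy cover, at full rate until 6 mm have evaporated since wetting
  (stage 1), then declining as `3.5 * (sqrt(t) - sqrt(t-1))` (stage 2);
* root-zone supply `sum(kl * (sw - cll) * thickness)` over rooted
  layers, with roots advancing 0.1 cm per pre-anthesis degree-day from
  emergence to flag leaf;
* transpiration demand from the day's potential growth divided by
  transpiration efficiency `te_coeff / vpd` (9 Pa; VPD is 0.75 of the
  saturation-pressure span between tmax and tmin, floored at 0.1 kPa).

The stress index `sd_ratio = min(1, supply/demand)` multiplies growth
and leaf expansion. Extraction is distributed over rooted layers in
proportion to their kl-limited available water and never draws a layer
below CLL. Every simulated day asserts closure: the change in stored
water equals infiltration plus irrigation minus drainage, soil
evaporation and transpiration to within 1e-6 mm, and the biomass pools
sum to cumulative growth to within 1e-6 g m^-2. These assertions are
hard errors, not warnings.

## Growth, grain and senescence

Biomass accumulates as `radn * (1 - exp(-k * LAI)) * RUE * sd_ratio`
with extinction coefficient 0.4 and RUE applied to total incident
shortwave radiation. Vegetative growth is split between leaf and stem
with a leaf fraction `1/(1 + partition_k * n_leaves^2)` -- a decided
functional form in which the larger partitioning factor of the tall
landrace sends more growth to stem, as its habit requires; this form is
a stand-in whose direction, not magnitude, is the tested contract.

Grain number is set once, at the start of grain fill, as the mean
plant growth rate over the PI-to-start-of-fill window divided by the
grain-number factor (0.00083 g per grain for Meko, 0.0014 for
Jigurti). The rate interpretation (g plant^-1 day^-1) is used because
it is the only reading of the printed factors that produces
agronomically plausible grain numbers (~10^3 per plant). Grain fills
toward `number * max_kernel_wt` in proportion to grain-fill thermal
time, drawing first on the day's growth, then on stem reserves up to
20% of the stem mass at anthesis; surplus growth accumulates in the
stem, which is how a sink-limited tall landrace gains stem mass after
anthesis and ends with a lower harvest index. Maximum kernel weights
(30 mg Meko, 38 mg Jigurti) are decided constants reflecting the
small-grained improved variety versus the large-grained landrace.

Senescence has two routes, both moving leaf mass to a dead-leaf pool in
proportion to area lost: an age route after anthesis (linear decline to
70% of the anthesis LAI by maturity, 85% at mid-fill), and a
water-stress route that engages only under severe stress
(`sd_ratio < 0.3`) and relaxes the canopy toward the LAI whose demand
the current supply could meet, with a 10-day time constant capped at
10% of green LAI per day. The threshold matters: mild stress slows
growth without destroying canopy, so a crop can ride out a dry spell,
while persistent severe stress -- the dryland site's terminal drought
-- drives complete senescence. An earlier formulation that shed canopy
under any stress level destroyed stands days before rains returned and
could not reproduce the observed persistence of stressed crops.

## Synthetic weather

`generate_weather()` is a compact WGEN-family generator driven by
monthly normals: first-order two-state Markov rainfall occurrence with
`p11 = min(0.8, 2 p01)` and `p01` calibrated so expected wet days match
the normals; gamma wet-day amounts (shape 0.8); temperatures as
mean-preserving smooth interpolation of monthly normals plus a shared
AR(1) anomaly (sd 1.5 degC, lag-1 correlation 0.6) with a re-centred
2 degC wet-day depression of tmax; radiation as a latitude/day-of-year
clear-sky envelope scaled to the monthly mean with a 25% wet-day
reduction, floored at 3 MJ m^-2. Years are 365 days (leap days
dropped), all streams come from one seeded generator, and equal seeds
give identical series.

The four presets (`climate_preset()`) are authored normals with
structural guarantees, not station transcriptions: the unimodal preset
carries 74% of its ~710 mm in June--September with a small
Kobo-like belg (small-rains) season sufficient to trigger April--June
sowing in about three-quarters of years; the bimodal preset has April
and August maxima with a June trough; the `melkassa_like` and
`miesso_like` presets resemble the two experimental sites. What the
generator does *not* emulate: spatial correlation, multi-day storm
structure beyond first-order persistence, El Nino-scale interannual
regimes, and real historical years -- so passing tests show the model
behaves correctly across a realistic range of season types, not that
it reproduces any particular observed season.

## Season orchestration and the two fixtures

`run_season()` executes a fixed daily order (water in, evaporation,
phenology, potential growth from yesterday's canopy, supply/demand,
actual growth and extraction, partitioning/grain fill, canopy update
and senescence, root advance, closure assertions). A crop whose
supply/demand ratio is zero for 15 consecutive pre-anthesis days is
recorded as failed with zero yield. Sowing dates come from
`find_sowing_date()`: the first day in a window whose trailing
15 days (configurable) contain enough qualifying rain events.

`run_fixture()` bundles two validation scenarios: the well-watered
season (sown 9 June, irrigated every 5 days by refilling the top 60 cm
to DUL) and the dryland season (sown 8 July on the measured profile
water, with authored below-average normals whose rains end in early
August, because that experiment is defined by its terminal stress).
Since the true station weather is not distributed, both fixtures check
directions, not numbers: the landrace accumulates more biomass and the
variety a higher harvest index under good water; under terminal
drought the landrace senesces fully (final green LAI < 0.1) while the
variety's earliness lets it escape with at least equal grain yield.

## The paired sowing-strategy experiment

`run_paired_experiment()` simulates both strategies against the same
weather realization in every year (a paired design). The default early
strategy sows Jigurti between 1 April and 15 June once 3 rain events of
at least 5 mm have accumulated 25 mm within 15 days; the late strategy
sows Meko in July after a single rain of at least 15 mm. The early
window deliberately extends past April: the strategy means "sow the
landrace at the onset of rains", and in unimodal climates onset falls
in late May or June, so closing the window on 20 May would make the
traditional system infeasible in a third of years for reasons of
calendar, not climate.

Seasons are initialized independently rather than carrying soil water
across years (carryover is a known influence on these decisions; here
it is deliberately excluded so year-to-year variation comes from
weather alone): each year the profile is set to CLL on 1 October
of the preceding year -- the state a harvested crop leaves behind --
and a bare-soil fallow run banks whatever the off-season and pre-season
rains deliver. Years with no sowing trigger or pre-anthesis crop death
enter the records as zeros with a failure flag; risk is the point of
the analysis. Season quality for the tercile classification
(`classify_seasons()`) is proxied by the early strategy's biomass rank,
since the long-duration crop integrates the whole season's water; the
ranking variable is configurable. `ols_fit()` (normal equations,
cross-checked against `lm()` in the tests) and `distribution_summary()`
(type-7 interpolated percentiles) provide the trade-off regression and
box-plot summaries.

The test suite asserts the qualitative outcomes of 40-year seeded runs:
on the bimodal preset the late strategy has the higher mean grain yield
and lower mean biomass, and dominates the poor-season tercile on both
variables (the risk-reduction result); on the unimodal preset the early
strategy wins biomass in the good tercile. These contrasts emerge from
the mechanisms above -- grain set of the early crop happens in the dry
gap while its biomass rides the full double season; the late crop
develops entirely inside the main rains -- and not from any per-claim
calibration. The grain-yield contrast on the bimodal preset is the
thinnest of the four (the corresponding published regression sits close
to the 1:1 line), and flips sign for some weather realizations at 40
years.

## Numerical choices and problem sizes

Tolerances: water and carbon closure at 1e-6 (mm, g m^-2) per day;
exact-arithmetic tests at machine precision; parameter recovery at
1e-6 relative on noise-free data and 5% under 1% noise. Degenerate
inputs are errors with typed condition classes (`invalid_sample`,
`invalid_weather`, `fit_error`, ...) rather than silent defaults. Ties
in the sowing trigger resolve to the earliest qualifying day. The
test suite sizes its simulations as 500 random synthetic seasons for
the closure sweep, 40-year paired experiments for the strategy
contrasts, and 1000 generated years for weather convergence (sized so
the 15% rainfall tolerance sits at roughly three standard errors of
the driest months' means); all are seeded and complete in a few
minutes on one core.

## Known limitations

* Thermal-time targets compress the landrace's real April-to-November
  calendar into ~130--150 days at these temperatures; the strategy
  contrasts are therefore qualitative reproductions, not date-faithful
  ones.
* No nitrogen or phosphorus limitation (the calibration experiments
  were fertilized to non-limiting levels), no tillering, lodging,
  pests, or plant-height simulation (height enters only through the
  parameter values of the tall landrace).
* The partitioning, grain-number and senescence functional forms are
  documented stand-ins for the equations of the full cropping-systems
  models this package simplifies; their
  directional behaviour, not their magnitudes, is the tested contract.
* Biomass is above-ground only; root carbon is not tracked.
* The weather generator and presets are structural emulations; no
  reproduction of specific historical seasons is attempted.
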