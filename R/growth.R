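# Daily carbon economy: light interception, radiation- and water-limited
# biomass accumulation, leaf/stem partitioning, grain-number
# determination, grain filling with stem translocation, and senescence.

#' Fractional light interception from LAI (Beer's law)
#'
#' @param lai green leaf area index (m^2 m^-2).
#' @param k extinction coefficient (default 0.4).
#' @return intercepted fraction in `[0, 1)`.
#' @export
light_interception <- function(lai, k = 0.4) {
  if (any(lai < 0)) abort("LAI must be non-negative", "input_error")
  1 - exp(-k * lai)
}

#' Daily biomass increment
#'
#' Radiation-use-efficiency growth reduced by the water supply/demand
#' ratio: `radn * f_int * rue * sd_ratio` (g m^-2).
#'
#' @param radn incident shortwave radiation (MJ m^-2).
#' @param f_int intercepted fraction.
#' @param rue radiation use efficiency (g MJ^-1).
#' @param sd_ratio water stress index in `[0, 1]`.
#' @return biomass increment (g m^-2).
#' @export
daily_growth <- function(radn, f_int, rue, sd_ratio = 1) {
  if (any(c(radn, f_int, rue, sd_ratio) < 0) || f_int > 1 || sd_ratio > 1) {
    abort("inputs out of range in daily_growth", "input_error")
  }
  radn * f_int * rue * sd_ratio
}

#' Partition new vegetative biomass between leaf and stem
#'
#' The leaf fraction declines with the number of appeared leaves as
#' `f = 1 / (1 + partition_k * n_leaves^2)`; a larger partitioning factor
#' (the tall landrace) sends more growth to stem. After flag-leaf full
#' expansion everything goes to stem (`f = 0`).
#'
#' @param d_biomass biomass increment (g m^-2).
#' @param n_leaves appeared leaf count.
#' @param partition_k leaf--stem partitioning factor.
#' @param past_flag logical; after flag-leaf expansion no leaf growth.
#' @return list with `to_leaf` and `to_stem` (g m^-2).
#' @export
partition_vegetative <- function(d_biomass, n_leaves, partition_k,
                                 past_flag = FALSE) {
  if (d_biomass < 0) abort("biomass increment must be >= 0", "input_error")
  f <- if (past_flag) 0 else 1 / (1 + partition_k * n_leaves^2)
  list(to_leaf = f * d_biomass, to_stem = (1 - f) * d_biomass)
}

#' Grain number from plant growth rate around flowering
#'
#' Grain number is set once, at the start of grain filling, from the mean
#' plant growth rate over the window from panicle initiation to the start
#' of grain fill, divided by the genotype's grain-number factor
#' (g of window growth required per grain set):
#' `grains m^-2 = (mean_pgr / gnf) * density`.
#'
#' @param mean_pgr mean plant growth rate over the window
#'   (g plant^-1 day^-1).
#' @param gnf grain number factor (g grain^-1).
#' @param density plants m^-2.
#' @return grain number (grains m^-2).
#' @export
set_grain_number <- function(mean_pgr, gnf, density) {
  if (mean_pgr < 0) abort("mean plant growth rate must be >= 0", "input_error")
  if (gnf <= 0) abort("grain number factor must be positive", "invalid_genotype")
  (mean_pgr / gnf) * density
}

#' Initialize biomass pools and grain state
#' @return list of pools (`leaf`, `stem`, `grain`, `dead_leaf`, g m^-2)
#'   plus grain state (`grain_number`, `stem_at_anthesis`,
#'   `transloc_used`).
#' @export
pools_init <- function() {
  list(leaf = 0, stem = 0, grain = 0, dead_leaf = 0,
       grain_number = NA_real_, stem_at_anthesis = 0, transloc_used = 0)
}

#' One day of grain filling
#'
#' Grain demand is the thermal-time share of the season's potential grain
#' mass, `grain_number * max_kernel_wt * (d_tt / fill_tt_total)`. Demand
#' is met first from the day's new biomass; any shortfall is drawn from
#' stem reserves up to a cumulative cap of `stem_transloc_frac` of the
#' stem mass at anthesis; new biomass beyond demand accumulates in the
#' stem (the sink-limitation route that lets the tall landrace gain stem
#' mass after anthesis). Grain mass never exceeds
#' `grain_number * max_kernel_wt`.
#'
#' @param pools a [pools_init()] list with `grain_number` set.
#' @param d_biomass the day's biomass increment (g m^-2).
#' @param d_tt the day's post-anthesis thermal time (degC d).
#' @param fill_tt_total total grain-fill thermal time (degC d).
#' @param genotype a [genotype_params()].
#' @return the updated pools list.
#' @export
grain_fill <- function(pools, d_biomass, d_tt, fill_tt_total, genotype) {
  if (is.na(pools$grain_number)) {
    abort("grain number must be set before grain fill", "state_error")
  }
  capacity <- pools$grain_number * genotype$max_kernel_wt
  demand <- min(capacity * d_tt / fill_tt_total, capacity - pools$grain)
  demand <- max(demand, 0)
  from_new <- min(demand, d_biomass)
  shortfall <- demand - from_new
  transloc_cap <- genotype$stem_transloc_frac * pools$stem_at_anthesis
  from_stem <- min(shortfall, transloc_cap - pools$transloc_used, pools$stem)
  from_stem <- max(from_stem, 0)
  pools$grain <- pools$grain + from_new + from_stem
  pools$stem <- pools$stem - from_stem + (d_biomass - from_new)
  pools$transloc_used <- pools$transloc_used + from_stem
  pools
}

#' Daily leaf senescence
#'
#' Two routes, both moving leaf mass to the dead-leaf pool in proportion
#' to the green area lost (total above-ground mass is conserved):
#'
#' * age senescence after anthesis: green LAI is drawn down linearly with
#'   grain-fill thermal time toward 70% of its value at anthesis by
#'   maturity (85% remains at mid-fill);
#' * water-stress senescence: under severe stress (supply/demand ratio
#'   below `stress_threshold`, default 0.3) green area is shed toward the
#'   LAI whose demand the current supply could meet, with a
#'   `time_const`-day relaxation (default 10) and at most `max_frac`
#'   (default 10%) of green LAI per day. Milder stress reduces growth and
#'   expansion but does not destroy canopy, so a crop can ride out a dry
#'   spell; persistent severe stress drives complete senescence, the
#'   terminal-drought behaviour of the dryland site.
#'
#' @param pools biomass pools ([pools_init()]).
#' @param canopy a `canopy_state`.
#' @param sd_ratio the day's supply/demand ratio.
#' @param post_anthesis logical.
#' @param tt_frac_fill fraction of anthesis-to-maturity thermal time
#'   elapsed (0 before anthesis).
#' @param lai_at_anthesis green LAI recorded at anthesis (for the age
#'   route; ignored pre-anthesis).
#' @param k extinction coefficient (to invert interception for the stress
#'   target).
#' @param max_frac daily cap on the stress-senescence fraction.
#' @param stress_threshold supply/demand ratio below which stress
#'   senescence is triggered.
#' @param time_const relaxation time (days) toward the supply-supported
#'   LAI under stress.
#' @return list with updated `pools`, `canopy` and `lai_lost`.
#' @export
senesce <- function(pools, canopy, sd_ratio, post_anthesis, tt_frac_fill = 0,
                    lai_at_anthesis = NA_real_, k = 0.4, max_frac = 0.1,
                    stress_threshold = 0.3, time_const = 10) {
  lai <- canopy$lai_green
  loss_age <- 0
  if (post_anthesis && !is.na(lai_at_anthesis)) {
    target_age <- lai_at_anthesis * (1 - 0.30 * min(tt_frac_fill, 1))
    loss_age <- max(0, lai - target_age)
  }
  loss_stress <- 0
  if (sd_ratio < stress_threshold && lai > 0) {
    f_now <- 1 - exp(-k * lai)
    f_target <- f_now * sd_ratio
    lai_target <- -log(1 - min(f_target, 1 - 1e-9)) / k
    loss_stress <- min(max(0, lai - lai_target) / time_const, max_frac * lai)
  }
  loss <- min(lai, loss_age + loss_stress)
  if (loss > 0 && lai > 0) {
    dead_mass <- pools$leaf * loss / lai
    pools$leaf <- pools$leaf - dead_mass
    pools$dead_leaf <- pools$dead_leaf + dead_mass
    canopy$lai_green <- lai - loss
    canopy$lai_senesced <- canopy$lai_senesced + loss
  }
  list(pools = pools, canopy = canopy, lai_lost = loss)
}
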