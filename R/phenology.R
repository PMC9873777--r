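# Thermal-time phenology: broken-linear temperature response with
# phase-specific cardinal temperatures, and stage bookkeeping for
# sowing -> emergence -> panicle initiation -> flag leaf -> anthesis ->
# grain fill -> physiological maturity.

#' Ordered crop stages
#' @export
STAGES <- c("presow", "sown", "emerged", "pi", "flag", "anthesis",
            "grainfill", "mature")

#' Cardinal temperatures of a development phase
#'
#' @param t_base base temperature (degC) below which development ceases.
#' @param t_opt optimum temperature (degC).
#' @param t_max ceiling temperature (degC) above which development ceases,
#'   or `NA` for a plateau phase where the response stays at its optimum
#'   value at all higher temperatures (the post-anthesis behaviour).
#' @return object of class `cardinal_temps`.
#' @export
cardinal_temps <- function(t_base, t_opt, t_max = NA_real_) {
  if (t_base >= t_opt) abort("t_base must be below t_opt", "invalid_genotype")
  if (!is.na(t_max) && t_opt >= t_max) {
    abort("t_opt must be below t_max when t_max is given", "invalid_genotype")
  }
  structure(list(t_base = t_base, t_opt = t_opt, t_max = t_max),
            class = "cardinal_temps")
}

#' Daily thermal time from max/min temperature
#'
#' Broken-linear response on the daily mean temperature
#' `T = (tmax + tmin)/2`: zero at or below `t_base`, rising linearly to
#' `t_opt - t_base` degree-days at `t_opt`. Above the optimum the two
#' phases differ: before anthesis the response declines linearly to zero
#' at `t_max` (and is zero above), while after anthesis it stays on the
#' plateau at `t_opt - t_base` for all warmer days.
#'
#' @param tmax,tmin daily maximum and minimum temperature (degC),
#'   vectorized.
#' @param cardinals a [cardinal_temps()] object.
#' @param phase `"pre_anthesis"` or `"post_anthesis"`.
#' @return thermal time (degC d), non-negative.
#' @export
#' @examples
#' daily_thermal_time(27, 27, cardinal_temps(6, 27, 42)) # 21
daily_thermal_time <- function(tmax, tmin, cardinals,
                               phase = c("pre_anthesis", "post_anthesis")) {
  phase <- match.arg(phase)
  if (any(tmax < tmin)) abort("tmax below tmin in weather input", "invalid_weather")
  tm <- (tmax + tmin) / 2
  tb <- cardinals$t_base
  to <- cardinals$t_opt
  peak <- to - tb
  tt <- pmin(pmax(tm - tb, 0), peak)
  if (phase == "pre_anthesis") {
    if (is.na(cardinals$t_max)) {
      abort("pre-anthesis phase requires a ceiling temperature", "invalid_genotype")
    }
    tc <- cardinals$t_max
    hot <- tm > to
    tt[hot] <- pmax(0, peak * (tc - tm[hot]) / (tc - to))
  }
  tt
}

#' Thermal time from emergence to panicle initiation
#'
#' Derived from the total leaf number, the four leaf initials already
#' present in the seed, and the leaf initiation rate: the apex must
#' initiate `tln - 4` further leaves at `lir` degree-days each before it
#' switches to panicle production.
#'
#' @param tln total leaf number (must exceed 4).
#' @param lir leaf initiation rate (degC d per leaf).
#' @return thermal time (degC d).
#' @export
#' @examples
#' tt_emergence_to_pi(15, 31.5) # 346.5, quoted rounded as 347
tt_emergence_to_pi <- function(tln, lir) {
  if (any(tln <= 4)) {
    abort("total leaf number must exceed the 4 seed leaf initials",
          "invalid_genotype")
  }
  if (any(lir <= 0)) abort("leaf initiation rate must be positive", "invalid_genotype")
  (tln - 4) * lir
}

#' Thermal time from emergence to flag-leaf full expansion
#'
#' All `tln` leaves must appear at `lar` degree-days each.
#'
#' @param tln total leaf number.
#' @param lar leaf appearance rate (degC d per leaf).
#' @return thermal time (degC d).
#' @export
tt_emergence_to_flag <- function(tln, lar) {
  if (any(tln <= 0) || any(lar <= 0)) {
    abort("leaf number and appearance rate must be positive", "invalid_genotype")
  }
  tln * lar
}

# per-stage thermal-time targets implied by a genotype's parameters;
# the pi -> flag duration emerges from leaf appearance (tln * lar minus the
# emergence -> PI target) so the quantities stay mutually consistent
stage_targets <- function(genotype) {
  g <- genotype
  c(presow = 0,
    sown = g$tt_sow_to_emerg,
    emerged = g$tt_emerg_to_pi,
    pi = g$tt_emerg_to_flag - g$tt_emerg_to_pi,
    flag = g$tt_flag_to_anthesis,
    anthesis = g$tt_anthesis_to_startgf,
    grainfill = g$tt_anthesis_to_maturity - g$tt_anthesis_to_startgf,
    mature = Inf)
}

#' Initialize a phenology state
#'
#' @param stage starting stage, default `"sown"`.
#' @return object of class `pheno_state`.
#' @export
pheno_init <- function(stage = "sown") {
  structure(list(stage = stage, tt_in_stage = 0, tt_since_emergence = 0,
                 tt_since_anthesis = 0, days_after_sowing = 0L),
            class = "pheno_state")
}

# stages developing on the pre-anthesis temperature response
PRE_ANTHESIS_STAGES <- c("presow", "sown", "emerged", "pi", "flag")

#' Advance phenology by one day
#'
#' Accumulates the phase-appropriate daily thermal time and promotes the
#' stage whenever the current stage's target is reached, carrying any
#' surplus degree-days into the next stage so no thermal time is lost
#' (several promotions in one day are possible). The day that crosses
#' anthesis carries its surplus into the post-anthesis accumulator.
#'
#' @param state a [pheno_init()] state.
#' @param d_tt_pre daily thermal time on the pre-anthesis response (degC d).
#' @param d_tt_post daily thermal time on the post-anthesis response.
#' @param genotype a [genotype_params()] object.
#' @return the updated `pheno_state`.
#' @export
pheno_advance <- function(state, d_tt_pre, d_tt_post, genotype) {
  targets <- stage_targets(genotype)
  if (state$stage == "mature") return(state)
  state$days_after_sowing <- state$days_after_sowing + 1L
  pre <- state$stage %in% PRE_ANTHESIS_STAGES
  budget <- if (pre) d_tt_pre else d_tt_post
  repeat {
    if (budget <= 0 || state$stage == "mature") break
    target <- targets[[state$stage]]
    use <- min(budget, target - state$tt_in_stage)
    state$tt_in_stage <- state$tt_in_stage + use
    budget <- budget - use
    if (state$stage %in% c("emerged", "pi", "flag")) {
      state$tt_since_emergence <- state$tt_since_emergence + use
    } else if (state$stage %in% c("anthesis", "grainfill")) {
      state$tt_since_anthesis <- state$tt_since_anthesis + use
    }
    if (is.finite(target) && state$tt_in_stage >= target - 1e-12) {
      crossing_anthesis <- state$stage == "flag"
      state$stage <- STAGES[match(state$stage, STAGES) + 1L]
      state$tt_in_stage <- 0
      if (crossing_anthesis) {
        # surplus accumulated on the pre-anthesis response is re-expressed
        # on the post-anthesis response so the day keeps one temperature
        budget <- if (d_tt_pre > 0) budget / d_tt_pre * d_tt_post else 0
      }
    }
  }
  state
}
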