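# Canopy development: bell-shaped individual leaf-area profiles, the
# regressions of their parameters on total leaf number, and daily green
# leaf-area dynamics (appearance and expansion; senescence lives with the
# carbon bookkeeping in the growth module).

#' Leaf blade area from length and width
#'
#' Blade area is length times maximal width times a shape correction
#' factor: 0.635 for flag leaves and 0.71 for all other leaves.
#'
#' @param length_cm blade length, ligule to tip (cm).
#' @param width_cm maximal blade width (cm).
#' @param is_flag logical, flag leaf or not.
#' @return blade area (cm^2).
#' @export
blade_area <- function(length_cm, width_cm, is_flag = FALSE) {
  if (any(length_cm <= 0) || any(width_cm <= 0)) {
    abort("blade length and width must be positive", "input_error")
  }
  length_cm * width_cm * ifelse(is_flag, 0.635, 0.71)
}

#' Construct a bell-shaped leaf-size profile
#'
#' Fully expanded area of leaf `x` follows
#' `Y = y0 * exp(a * (x - x0)^2 + b * (x - x0)^3)`, where `y0` is the area
#' of the largest leaf, `x0` its (possibly fractional) position, and `a`
#' (negative) and `b` control the breadth and skewness of the profile.
#'
#' @param tln total leaf number.
#' @param y0 area of the largest leaf (cm^2).
#' @param x0 leaf position of the largest leaf.
#' @param a breadth coefficient (< 0); defaults to [leaf_a_coeff()] at `tln`.
#' @param b skewness coefficient; defaults to [leaf_b_coeff()] at `tln`.
#' @return object of class `leaf_size_profile`.
#' @export
leaf_size_profile <- function(tln, y0, x0,
                              a = leaf_a_coeff(tln), b = leaf_b_coeff(tln)) {
  if (y0 <= 0) abort("largest-leaf area must be positive", "invalid_regression")
  if (x0 <= 0 || x0 >= tln + 1) {
    abort("largest-leaf position must lie within the leaf range", "invalid_regression")
  }
  if (a >= 0) abort("breadth coefficient `a` must be negative", "invalid_regression")
  structure(list(tln = tln, y0 = y0, x0 = x0, a = a, b = b),
            class = "leaf_size_profile")
}

#' Individual leaf area at a leaf position
#'
#' @param x leaf position (1 to `tln`), vectorized.
#' @param profile a [leaf_size_profile()].
#' @return leaf area (cm^2).
#' @export
leaf_area_at <- function(x, profile) {
  if (any(x < 1 - 1e-9) || any(x > profile$tln + 1e-9)) {
    abort("leaf position outside [1, tln]", "domain_error")
  }
  d <- x - profile$x0
  profile$y0 * exp(profile$a * d^2 + profile$b * d^3)
}

#' Regressions of the profile parameters on total leaf number
#'
#' Largest-leaf position and area scale linearly with total leaf number:
#' `x0 = x0_slope * tln + x0_intercept` and
#' `y0 = y0_slope * tln + y0_intercept`.
#'
#' @param x0_slope,x0_intercept position regression; the slope must lie in
#'   (0, 1] (the largest leaf sits below the flag leaf).
#' @param y0_slope,y0_intercept area regression (cm^2 per leaf; cm^2).
#' @return object of class `profile_regression`.
#' @export
profile_regression <- function(x0_slope, x0_intercept = 0,
                               y0_slope, y0_intercept = 0) {
  if (x0_slope <= 0 || x0_slope > 1) {
    abort("x0 slope must lie in (0, 1]", "invalid_regression")
  }
  structure(list(x0_slope = x0_slope, x0_intercept = x0_intercept,
                 y0_slope = y0_slope, y0_intercept = y0_intercept),
            class = "profile_regression")
}

#' Leaf-size profile predicted from total leaf number
#'
#' @param tln total leaf number (> 4).
#' @param reg a [profile_regression()], or a [genotype_params()] whose
#'   regression coefficients are used.
#' @param a,b bell-curve coefficients; default to the TLN-dependent
#'   empirical forms [leaf_a_coeff()] / [leaf_b_coeff()].
#' @return a [leaf_size_profile()]. The fractional `x0` is used directly in
#'   the bell curve; round half-up for the "largest leaf" reported to users.
#' @export
#' @examples
#' p <- profile_from_tln(19, profile_regression(0.74, 0, 13.2, 318))
#' round_half_up(p$x0) # leaf 14
profile_from_tln <- function(tln, reg,
                             a = leaf_a_coeff(tln), b = leaf_b_coeff(tln)) {
  if (tln <= 4) abort("total leaf number must exceed 4", "invalid_genotype")
  if (inherits(reg, "genotype_params")) {
    reg <- profile_regression(reg$x0_slope, reg$x0_intercept,
                              reg$y0_slope, reg$y0_intercept)
  }
  x0 <- reg$x0_slope * tln + reg$x0_intercept
  y0 <- reg$y0_slope * tln + reg$y0_intercept
  if (y0 <= 0) {
    abort("regression predicts a non-positive largest-leaf area", "invalid_regression")
  }
  leaf_size_profile(tln, y0 = y0, x0 = x0, a = a, b = b)
}

#' Fit leaf-size profiles and their TLN regressions
#'
#' Per plant, fits the bell curve to measured individual leaf areas by
#' nonlinear least squares with the breadth/skewness coefficients `a`, `b`
#' held fixed at their supplied (externally calibrated) values, leaving
#' only `y0` and `x0` free. The per-plant estimates are then regressed on
#' total leaf number by ordinary least squares.
#'
#' @param plants data frame with columns `plant_id`, `tln`, `leaf_no` and
#'   either `area_cm2` or `length_cm`,`width_cm` (+ optional `is_flag`)
#'   from which blade areas are computed via [blade_area()].
#' @param a,b functions of TLN giving the fixed bell-curve coefficients
#'   (defaults: the empirical forms), or single numbers.
#' @param x0_through_origin logical; fit the position regression through
#'   the origin (`x0 = slope * tln`), the conventional zero-intercept form.
#' @return list with `plants` (per-plant `tln`, `x0`, `y0`, `a`, `b`),
#'   `regression` (a [profile_regression()]) and `r2` (named vector with
#'   the R^2 of the two regressions).
#' @export
fit_profile_regressions <- function(plants,
                                    a = leaf_a_coeff, b = leaf_b_coeff,
                                    x0_through_origin = TRUE) {
  if (!("area_cm2" %in% names(plants))) {
    plants$area_cm2 <- blade_area(plants$length_cm, plants$width_cm,
                                  plants$is_flag %||% FALSE)
  }
  ids <- unique(plants$plant_id)
  if (length(ids) < 2) abort("need at least two plants", "fit_error")
  a_fun <- if (is.function(a)) a else function(tln) a
  b_fun <- if (is.function(b)) b else function(tln) b
  fits <- lapply(ids, function(id) {
    d <- plants[plants$plant_id == id, ]
    if (nrow(d) < 5) {
      abort(sprintf("plant %s has fewer than 5 measured leaves", id), "fit_error")
    }
    tln <- d$tln[1]
    af <- a_fun(tln); bf <- b_fun(tln)
    start <- list(y0 = max(d$area_cm2), x0 = d$leaf_no[which.max(d$area_cm2)])
    fit <- minpack.lm::nlsLM(
      area_cm2 ~ y0 * exp(af * (leaf_no - x0)^2 + bf * (leaf_no - x0)^3),
      data = d, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- stats::coef(fit)
    data.frame(plant_id = id, tln = tln, x0 = cf[["x0"]], y0 = cf[["y0"]],
               a = af, b = bf)
  })
  per_plant <- do.call(rbind, fits)
  if (stats::var(per_plant$tln) == 0) {
    abort("all plants have the same total leaf number: the TLN regression is singular",
          "fit_error")
  }
  x0_fit <- if (x0_through_origin) {
    stats::lm(x0 ~ tln + 0, data = per_plant)
  } else {
    stats::lm(x0 ~ tln, data = per_plant)
  }
  y0_fit <- stats::lm(y0 ~ tln, data = per_plant)
  # R^2 about the mean for both, so the through-origin fit is comparable
  r2_about_mean <- function(fit, y) {
    1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  }
  cx <- stats::coef(x0_fit)
  cy <- stats::coef(y0_fit)
  list(
    plants = per_plant,
    regression = profile_regression(
      x0_slope = unname(cx[["tln"]]),
      x0_intercept = if (x0_through_origin) 0 else unname(cx[["(Intercept)"]]),
      y0_slope = unname(cy[["tln"]]),
      y0_intercept = unname(cy[["(Intercept)"]])
    ),
    r2 = c(x0 = r2_about_mean(x0_fit, per_plant$x0),
           y0 = r2_about_mean(y0_fit, per_plant$y0))
  )
}

#' Read leaf blade measurements from CSV
#'
#' Expected columns: `plant_id,tln,leaf_no,length_cm,width_cm,is_flag`.
#'
#' @param path file path.
#' @return data frame suitable for [fit_profile_regressions()].
#' @export
read_leaf_measurements <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plant_id", "tln", "leaf_no", "length_cm", "width_cm")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort(paste("leaf measurement file missing columns:",
                paste(miss, collapse = ", ")), "input_error")
  }
  d$is_flag <- as.logical(d$is_flag %||% FALSE)
  d
}

#' Initialize a canopy state
#' @return object of class `canopy_state`: appeared leaf count (fractional),
#'   green and senesced leaf area index (m^2 m^-2), and the cumulative
#'   potential area already expanded (cm^2 per plant, internal).
#' @export
canopy_init <- function() {
  structure(list(appeared_leaves = 0, lai_green = 0, lai_senesced = 0,
                 expanded_area_cm2 = 0),
            class = "canopy_state")
}

# cumulative fully-expanded area of the first n leaves (cm^2 per plant),
# with the marginal leaf pro-rated linearly over its appearance interval;
# the total over all tln leaves is sum(leaf_area_at(1:tln))
cumulative_leaf_area <- function(n, profile) {
  n <- min(max(n, 0), profile$tln)
  full <- floor(n)
  area <- if (full >= 1) sum(leaf_area_at(seq_len(full), profile)) else 0
  frac <- n - full
  if (frac > 0 && full < profile$tln) {
    area <- area + frac * leaf_area_at(full + 1, profile)
  }
  area
}

#' Advance the canopy by one day
#'
#' Leaf appearance is thermal-time driven (`d_tt / lar` leaves per day,
#' capped at `tln` and halted after anthesis). Green LAI gains the area of
#' newly expanding leaves from the genotype's leaf-size profile, scaled by
#' plant density and reduced by the water-stress expansion multiplier
#' (area not expanded under stress is forgone, not deferred).
#'
#' @param state a [canopy_init()] state.
#' @param d_tt daily thermal time on the pre-anthesis response (degC d).
#' @param genotype a [genotype_params()].
#' @param density plants per m^2.
#' @param stress expansion multiplier in `[0, 1]` (the water supply/demand
#'   ratio); 0 fully inhibits expansion.
#' @param post_anthesis logical; no new leaves appear after anthesis.
#' @param profile optional precomputed [leaf_size_profile()] (avoids
#'   rebuilding it inside a daily loop).
#' @return the updated `canopy_state`.
#' @export
canopy_update <- function(state, d_tt, genotype, density, stress = 1,
                          post_anthesis = FALSE, profile = NULL) {
  if (stress < 0 || stress > 1) abort("stress must lie in [0, 1]", "input_error")
  if (post_anthesis || d_tt <= 0) return(state)
  if (is.null(profile)) {
    profile <- profile_from_tln(genotype$tln, genotype,
                                a = genotype$a, b = genotype$b)
  }
  n0 <- state$appeared_leaves
  n1 <- min(n0 + d_tt / genotype$lar, genotype$tln)
  gain_cm2 <- (cumulative_leaf_area(n1, profile) -
               cumulative_leaf_area(n0, profile)) * stress
  state$appeared_leaves <- n1
  state$expanded_area_cm2 <- state$expanded_area_cm2 + gain_cm2
  state$lai_green <- state$lai_green + gain_cm2 * density * 1e-4
  state
}
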