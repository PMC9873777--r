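# Genotype parameter sets for the two reference cultivars:
# Meko  -- early-maturing, short, improved variety (late-sowing system)
# Jigurti -- late-maturing, tall landrace (early-sowing system)

#' Empirical breadth/skewness coefficients of the leaf-area bell curve
#'
#' The breadth (`a`, negative) and skewness (`b`) coefficients of the
#' individual-leaf-area profile are taken as linear functions of total leaf
#' number, following the comprehensive maize leaf-size study that the
#' sorghum canopy routine borrows them from. They are deliberately not
#' refitted from sparse local data.
#'
#' @param tln total leaf number.
#' @return coefficient value.
#' @export
leaf_a_coeff <- function(tln) -0.0344 - 0.000186 * tln

#' @rdname leaf_a_coeff
#' @export
leaf_b_coeff <- function(tln) 0.00175 - 0.0000449 * tln

#' Construct a genotype parameter set
#'
#' Bundles phenology (cardinal temperatures and thermal-time targets),
#' canopy development (leaf appearance/initiation rates, total leaf number,
#' leaf-size regressions) and crop growth (partitioning, grain number
#' factor, radiation use efficiency) coefficients for one cultivar.
#'
#' The emergence-to-panicle-initiation target is derived, not supplied:
#' `(tln_phen - 4) * lir`, because four leaf initials are already present
#' in the seed and leaf initiation proceeds at `lir` degree-days per leaf
#' until panicle initiation ends it. `tln_phen` defaults to `tln` but may
#' differ when the phenology calibration implies a slightly different leaf
#' number than the measured leaf-size profiles (as it does for Jigurti).
#'
#' @param name cultivar label.
#' @param t_base_veg,t_opt_veg,t_max_veg cardinal temperatures (degC) for
#'   development before anthesis (thermal time declines above `t_opt_veg`
#'   and is zero at/above `t_max_veg`).
#' @param t_base_gf,t_opt_gf cardinal temperatures (degC) after anthesis;
#'   the response plateaus at `t_opt_gf` and does not decline.
#' @param tt_flag_to_anthesis,tt_anthesis_to_maturity thermal-time targets
#'   (degC d).
#' @param tt_sow_to_emerg sowing-to-emergence target (degC d); not measured
#'   in the field studies, default 40.
#' @param tt_anthesis_to_startgf lag from anthesis to the start of linear
#'   grain fill (degC d), taken out of the anthesis-to-maturity target;
#'   default 100. The grain-number determination window runs from panicle
#'   initiation to this point.
#' @param lar leaf appearance rate (degC d per leaf).
#' @param lir leaf initiation rate (degC d per leaf), approximately
#'   `lar / 2`; a warning is given if it strays more than 15% from that.
#' @param tln total leaf number (canopy).
#' @param tln_phen leaf number used by the phenology derivation.
#' @param x0_slope,x0_intercept regression of largest-leaf position on TLN.
#' @param y0_slope,y0_intercept regression of largest-leaf area (cm^2) on TLN.
#' @param partition_k leaf--stem partitioning factor (dimensionless).
#' @param grain_number_factor grain number per unit plant growth rate
#'   (g grain^-1).
#' @param rue radiation use efficiency (g biomass per MJ intercepted
#'   shortwave radiation).
#' @param extinction_k canopy light extinction coefficient.
#' @param max_kernel_wt maximum single-kernel weight (g).
#' @param stem_transloc_frac fraction of anthesis stem mass available for
#'   retranslocation to grain.
#' @return object of class `genotype_params` (a list).
#' @seealso [meko()], [jigurti()], [read_genotype()]
#' @export
genotype_params <- function(name,
                            t_base_veg, t_opt_veg, t_max_veg,
                            t_base_gf, t_opt_gf,
                            tt_flag_to_anthesis, tt_anthesis_to_maturity,
                            lar, lir, tln,
                            tln_phen = tln,
                            tt_sow_to_emerg = 40,
                            tt_anthesis_to_startgf = 100,
                            x0_slope, x0_intercept = 0,
                            y0_slope, y0_intercept = 0,
                            partition_k, grain_number_factor, rue,
                            extinction_k = 0.4,
                            max_kernel_wt = 0.028,
                            stem_transloc_frac = 0.2) {
  for (v in c("t_base_veg", "t_opt_veg", "t_max_veg", "t_base_gf", "t_opt_gf",
              "tt_flag_to_anthesis", "tt_anthesis_to_maturity", "lar", "lir",
              "tln", "tln_phen", "tt_sow_to_emerg", "tt_anthesis_to_startgf",
              "partition_k", "grain_number_factor", "rue", "extinction_k",
              "max_kernel_wt", "stem_transloc_frac")) {
    stopifnot_scalar(get(v), v)
  }
  if (t_base_veg >= t_opt_veg || t_opt_veg >= t_max_veg) {
    abort("pre-anthesis cardinal temperatures must satisfy base < opt < max",
          "invalid_genotype")
  }
  if (t_base_gf >= t_opt_gf) {
    abort("post-anthesis cardinal temperatures must satisfy base < opt",
          "invalid_genotype")
  }
  if (tln_phen <= 4) abort("total leaf number must exceed the 4 seed initials",
                           "invalid_genotype")
  if (tt_anthesis_to_startgf >= tt_anthesis_to_maturity) {
    abort("start of grain fill must precede maturity", "invalid_genotype")
  }
  if (abs(lir - lar / 2) > 0.15 * (lar / 2)) {
    warning("leaf initiation rate deviates more than 15% from lar/2")
  }
  g <- list(
    name = name,
    pre_anthesis = cardinal_temps(t_base_veg, t_opt_veg, t_max_veg),
    post_anthesis = cardinal_temps(t_base_gf, t_opt_gf, NA_real_),
    tt_sow_to_emerg = tt_sow_to_emerg,
    tt_emerg_to_pi = tt_emergence_to_pi(tln_phen, lir),
    tt_emerg_to_flag = tt_emergence_to_flag(tln, lar),
    tt_flag_to_anthesis = tt_flag_to_anthesis,
    tt_anthesis_to_startgf = tt_anthesis_to_startgf,
    tt_anthesis_to_maturity = tt_anthesis_to_maturity,
    lar = lar, lir = lir, tln = tln, tln_phen = tln_phen,
    x0_slope = x0_slope, x0_intercept = x0_intercept,
    y0_slope = y0_slope, y0_intercept = y0_intercept,
    a = leaf_a_coeff(tln), b = leaf_b_coeff(tln),
    partition_k = partition_k,
    grain_number_factor = grain_number_factor,
    rue = rue,
    extinction_k = extinction_k,
    max_kernel_wt = max_kernel_wt,
    stem_transloc_frac = stem_transloc_frac
  )
  if (g$tt_emerg_to_flag <= g$tt_emerg_to_pi) {
    abort("flag-leaf thermal time must exceed the panicle-initiation target",
          "invalid_genotype")
  }
  class(g) <- "genotype_params"
  g
}

#' @export
print.genotype_params <- function(x, ...) {
  cat(sprintf(
    paste0("Genotype '%s': TLN %g, LAR %g degCd/leaf, RUE %g g/MJ\n",
           "  thermal time em->PI %.1f, em->flag %.1f, flag->anth %g, ",
           "anth->mat %g degCd\n"),
    x$name, x$tln, x$lar, x$rue,
    x$tt_emerg_to_pi, x$tt_emerg_to_flag, x$tt_flag_to_anthesis,
    x$tt_anthesis_to_maturity
  ))
  invisible(x)
}

#' Reference genotype: Meko (early-maturing improved variety)
#'
#' Early-maturing, short-statured improved variety used in the late-sowing
#' system. 15 leaves; emergence-to-panicle-initiation target derives to
#' 346.5 degC d (quoted as 347 when rounded).
#'
#' @return a [genotype_params()] object.
#' @export
meko <- function() {
  genotype_params(
    name = "Meko",
    t_base_veg = 6.0, t_opt_veg = 27, t_max_veg = 42,
    t_base_gf = 5.7, t_opt_gf = 23.5,
    tt_flag_to_anthesis = 207, tt_anthesis_to_maturity = 819,
    lar = 63, lir = 31.5, tln = 15,
    x0_slope = 0.83, x0_intercept = 0,
    y0_slope = 36.9, y0_intercept = -95.2,
    partition_k = 0.0073, grain_number_factor = 0.00083, rue = 1.25,
    max_kernel_wt = 0.030
  )
}

#' Reference genotype: Jigurti (late-maturing tall landrace)
#'
#' Late-maturing, tall landrace used in the traditional early-sowing
#' system. The phenology calibration implies 19.5 leaves (target 449.5,
#' quoted as 450 degC d) while the measured leaf-size profiles use a
#' 19-leaf plant; both are carried.
#'
#' @return a [genotype_params()] object.
#' @export
jigurti <- function() {
  genotype_params(
    name = "Jigurti",
    t_base_veg = 6.6, t_opt_veg = 27, t_max_veg = 42,
    t_base_gf = 5.7, t_opt_gf = 23.5,
    tt_flag_to_anthesis = 222, tt_anthesis_to_maturity = 801,
    lar = 58, lir = 29, tln = 19, tln_phen = 19.5,
    x0_slope = 0.74, x0_intercept = 0,
    y0_slope = 13.2, y0_intercept = 318,
    partition_k = 0.0106, grain_number_factor = 0.0014, rue = 1.65,
    max_kernel_wt = 0.038
  )
}

#' Read or write a genotype parameter file (YAML)
#'
#' The file holds the arguments of [genotype_params()] as a flat YAML
#' mapping. Bundled fixtures `meko.yaml` and `jigurti.yaml` mirror
#' [meko()] and [jigurti()].
#'
#' @param path file path, or for the bundled fixtures just `"meko"` /
#'   `"jigurti"`.
#' @return a `genotype_params` object.
#' @export
read_genotype <- function(path) {
  if (path %in% c("meko", "jigurti")) {
    path <- system.file("extdata", paste0(path, ".yaml"), package = "sorghumsim")
  }
  vals <- yaml::read_yaml(path)
  do.call(genotype_params, vals)
}

#' @rdname read_genotype
#' @param genotype a `genotype_params` object.
#' @export
write_genotype <- function(genotype, path) {
  g <- genotype
  out <- list(
    name = g$name,
    t_base_veg = g$pre_anthesis$t_base, t_opt_veg = g$pre_anthesis$t_opt,
    t_max_veg = g$pre_anthesis$t_max,
    t_base_gf = g$post_anthesis$t_base, t_opt_gf = g$post_anthesis$t_opt,
    tt_flag_to_anthesis = g$tt_flag_to_anthesis,
    tt_anthesis_to_maturity = g$tt_anthesis_to_maturity,
    tt_sow_to_emerg = g$tt_sow_to_emerg,
    tt_anthesis_to_startgf = g$tt_anthesis_to_startgf,
    lar = g$lar, lir = g$lir, tln = g$tln, tln_phen = g$tln_phen,
    x0_slope = g$x0_slope, x0_intercept = g$x0_intercept,
    y0_slope = g$y0_slope, y0_intercept = g$y0_intercept,
    partition_k = g$partition_k,
    grain_number_factor = g$grain_number_factor,
    rue = g$rue, extinction_k = g$extinction_k,
    max_kernel_wt = g$max_kernel_wt,
    stem_transloc_frac = g$stem_transloc_frac
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
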