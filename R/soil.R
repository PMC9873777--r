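# Soil characterization: field equations for bulk density, drained upper
# limit (DUL) and crop lower limit (CLL), and the layered plant-available
# water arithmetic that parameterizes the simulator's water bucket.

#' Gravimetric water content from core weights
#'
#' Water mass as a percentage of oven-dry soil mass, from the wet and dry
#' weights of a soil core. Used for both DUL cores (wet-up and drained) and
#' CLL cores (profile dried down by a rain-excluded crop).
#'
#' @param wet_weight wet sample weight (g).
#' @param dry_weight oven-dry sample weight (g), must be positive.
#' @return gravimetric water content (%), `((wet - dry)/dry) * 100`.
#' @export
#' @examples
#' gravimetric_water_pct(120, 100) # 20
gravimetric_water_pct <- function(wet_weight, dry_weight) {
  if (any(dry_weight <= 0)) {
    abort("dry weight must be positive", "invalid_sample")
  }
  if (any(wet_weight < dry_weight)) {
    abort("wet weight below dry weight: not a valid soil sample", "invalid_sample")
  }
  (wet_weight - dry_weight) / dry_weight * 100
}

#' Bulk density of a soil core
#'
#' @param dry_weight oven-dry soil weight (g).
#' @param core_volume total core volume (cm^3), from tube diameter and length.
#' @return bulk density (g cm^-3). A warning (not an error) is raised for
#'   values outside the plausible field range 0.7--1.9 g cm^-3.
#' @export
bulk_density <- function(dry_weight, core_volume) {
  if (any(core_volume <= 0)) abort("core volume must be positive", "invalid_sample")
  if (any(dry_weight <= 0)) abort("dry weight must be positive", "invalid_sample")
  bd <- dry_weight / core_volume
  if (any(bd < 0.7 | bd > 1.9)) {
    warning("bulk density outside the plausible 0.7-1.9 g cm^-3 range")
  }
  bd
}

#' Volumetric water content from gravimetric content and bulk density
#'
#' Converts gravimetric water (% of dry mass) to volumetric water
#' (% of soil volume); applied identically for DUL and CLL.
#'
#' @param gravimetric_pct gravimetric water content (%).
#' @param bulk_density bulk density (g cm^-3).
#' @return volumetric water content (%).
#' @export
volumetric_pct <- function(gravimetric_pct, bulk_density) {
  if (any(gravimetric_pct < 0) || any(bulk_density < 0)) {
    abort("gravimetric water and bulk density must be non-negative", "invalid_sample")
  }
  gravimetric_pct * bulk_density
}

#' Default root water-extraction coefficients for a profile
#'
#' kl declines with depth: 0.08 day^-1 in the top layer, minus 0.01 per
#' successive layer, floored at 0.02. These are conventional values for a
#' deep-rooted cereal on clay soils; the tables they accompany do not
#' report kl.
#'
#' @param n_layers number of soil layers.
#' @param top kl of the surface layer (day^-1).
#' @param step decline per layer (day^-1).
#' @param floor minimum kl (day^-1).
#' @return numeric vector of kl values, one per layer.
#' @export
default_kl <- function(n_layers, top = 0.08, step = 0.01, floor = 0.02) {
  pmax(top - step * (seq_len(n_layers) - 1), floor)
}

#' Construct a layered soil profile
#'
#' A soil profile is a data frame with one row per layer, ordered from the
#' surface down, with contiguous depths. Volumetric water contents are
#' fractions (mm water per mm soil).
#'
#' @param top_cm,bottom_cm layer boundaries (cm); `top_cm[1]` must be 0 and
#'   each top must equal the previous bottom.
#' @param bd bulk density (g cm^-3).
#' @param dul drained upper limit (volumetric fraction).
#' @param cll crop lower limit (volumetric fraction).
#' @param sw current volumetric water content; defaults to `cll` (empty
#'   profile). Clamped to `[0.5 * cll, dul + 0.05]` (air-dry to saturation).
#' @param kl root extraction coefficient per layer (day^-1); defaults to
#'   [default_kl()].
#' @param site site label.
#' @return object of class `soil_profile` (a data frame).
#' @export
soil_profile <- function(top_cm, bottom_cm, bd, dul, cll,
                         sw = cll, kl = default_kl(length(top_cm)),
                         site = "") {
  n <- length(top_cm)
  if (n < 1L) abort("a soil profile needs at least one layer", "input_error")
  if (length(bottom_cm) != n || length(bd) != n || length(dul) != n ||
      length(cll) != n) {
    abort("layer columns must all have the same length", "input_error")
  }
  sw <- rep_len(sw, n)
  kl <- rep_len(kl, n)
  if (abs(top_cm[1]) > 1e-9) abort("first layer must start at 0 cm", "input_error")
  if (any(bottom_cm <= top_cm)) abort("layer bottoms must exceed tops", "input_error")
  if (n > 1 && any(abs(top_cm[-1] - bottom_cm[-n]) > 1e-9)) {
    abort("layers must be contiguous (each top = previous bottom)", "input_error")
  }
  if (any(cll < 0) || any(cll > dul) || any(dul >= 1)) {
    abort("need 0 <= cll <= dul < 1 in every layer", "input_error")
  }
  if (any(kl <= 0) || any(kl > 0.12)) {
    abort("kl must lie in (0, 0.12] day^-1", "input_error")
  }
  prof <- data.frame(
    top_cm = top_cm, bottom_cm = bottom_cm, bd = bd,
    dul = dul, cll = cll,
    sw = pmin(pmax(sw, 0.5 * cll), dul + 0.05),
    kl = kl
  )
  attr(prof, "site") <- site
  class(prof) <- c("soil_profile", "data.frame")
  prof
}

# layer thicknesses in mm (depths are tabulated in cm)
layer_thickness_mm <- function(profile) {
  (profile$bottom_cm - profile$top_cm) * 10
}

#' Plant-available water of each layer
#'
#' `(dul - cll) * thickness`, in mm of water, per layer.
#'
#' @param profile a [soil_profile()].
#' @return numeric vector, one value per layer (mm).
#' @export
layer_paw <- function(profile) {
  (profile$dul - profile$cll) * layer_thickness_mm(profile)
}

#' Plant-available water capacity of a profile
#'
#' Sum of per-layer `(DUL - CLL) * thickness` over the whole profile: the
#' maximum water a crop can extract from a full profile, in mm.
#'
#' @inheritParams layer_paw
#' @return PAWC (mm).
#' @export
profile_pawc <- function(profile) {
  sum(layer_paw(profile))
}

#' Currently available soil water in a profile
#'
#' Water stored above the crop lower limit, summed over layers:
#' `sum(max(0, sw - cll) * thickness)`, in mm.
#'
#' @inheritParams layer_paw
#' @return available soil water (mm).
#' @export
profile_available_sw <- function(profile) {
  sum(pmax(0, profile$sw - profile$cll) * layer_thickness_mm(profile))
}

#' @export
print.soil_profile <- function(x, ...) {
  site <- attr(x, "site")
  cat(sprintf(
    "Soil profile%s: %d layers to %g cm, PAWC %.1f mm, available SW %.1f mm\n",
    if (nzchar(site)) paste0(" '", site, "'") else "",
    nrow(x), max(x$bottom_cm), profile_pawc(x), profile_available_sw(x)
  ))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read / write a soil profile CSV
#'
#' The file format has columns `top_cm,bottom_cm,bd,dul,cll,sw,kl`; `sw`
#' and `kl` are optional on read.
#'
#' @param path file path.
#' @param site site label (defaults to the file name).
#' @return [read_soil_profile()] returns a `soil_profile`.
#' @export
read_soil_profile <- function(path, site = sub("\\.csv$", "", basename(path))) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("top_cm", "bottom_cm", "bd", "dul", "cll")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    abort(paste("soil profile file missing columns:", paste(miss, collapse = ", ")),
          "input_error")
  }
  soil_profile(d$top_cm, d$bottom_cm, d$bd, d$dul, d$cll,
               sw = d$sw %||% d$cll,
               kl = d$kl %||% default_kl(nrow(d)),
               site = site)
}

#' @rdname read_soil_profile
#' @param profile a `soil_profile`.
#' @export
write_soil_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled field-characterized soil profiles
#'
#' Per-layer bulk density, DUL, CLL and water content at sowing measured at
#' the Melkassa (silty clay loam, 1.6 m) and Miesso (heavy clay, 1.8 m)
#' experimental sites. Values are transcribed verbatim from the field
#' characterization tables; note that the Melkassa profile sums to about
#' 219 mm PAWC and 206 mm available water, somewhat below the rounded
#' totals quoted alongside it (244/232 mm) -- the tabulated layers are kept
#' as-is rather than rescaled.
#'
#' @param name `"melkassa"` or `"miesso"`.
#' @return a [soil_profile()] with the `sw` column set to the measured
#'   water content at sowing.
#' @export
soil_fixture <- function(name = c("melkassa", "miesso")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "sorghumsim")
  if (!nzchar(path)) abort(paste("bundled profile not found:", name), "input_error")
  read_soil_profile(path, site = name)
}
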