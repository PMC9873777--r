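# shared builders for tests; everything is generated in code

# constant-temperature weather covering n days (no rain unless given)
constant_weather <- function(n, tmax = 27, tmin = 27, radn = 20, rain = 0,
                             start = as.Date("2010-01-01")) {
  weather_series(data.frame(
    date = start + seq_len(n) - 1L,
    radn = rep_len(radn, n), tmax = rep_len(tmax, n),
    tmin = rep_len(tmin, n), rain = rep_len(rain, n)))
}

# a small two-layer profile with easy numbers
two_layer_profile <- function(sw = c(0.20, 0.20)) {
  soil_profile(top_cm = c(0, 20), bottom_cm = c(20, 40),
               bd = c(1.2, 1.2), dul = c(0.30, 0.30), cll = c(0.10, 0.10),
               sw = sw, kl = c(0.08, 0.08), site = "toy")
}

# random valid profile for property tests
random_profile <- function(n_layers = sample(2:6, 1)) {
  bottoms <- cumsum(sample(c(15, 20, 30), n_layers, replace = TRUE))
  tops <- c(0, bottoms[-n_layers])
  cll <- runif(n_layers, 0.05, 0.2)
  dul <- cll + runif(n_layers, 0.05, 0.25)
  soil_profile(tops, bottoms, bd = runif(n_layers, 0.9, 1.4),
               dul = dul, cll = cll,
               sw = cll + runif(n_layers) * (dul - cll))
}

# synthetic leaf measurements drawn exactly from a known profile family
synthetic_plants <- function(tlns, x0_slope = 0.80, y0_slope = 30,
                             y0_intercept = 0, noise_sd = 0) {
  rows <- lapply(seq_along(tlns), function(i) {
    tln <- tlns[i]
    prof <- leaf_size_profile(tln, y0 = y0_slope * tln + y0_intercept,
                              x0 = x0_slope * tln)
    area <- leaf_area_at(1:tln, prof)
    if (noise_sd > 0) area <- area * (1 + rnorm(tln, 0, noise_sd))
    data.frame(plant_id = paste0("p", i), tln = tln, leaf_no = 1:tln,
               area_cm2 = area)
  })
  do.call(rbind, rows)
}
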