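## Shared fixtures, all built in code.

frost_row <- function(species = "Abies alba", organ = "branch", method = "EL",
                      value = -25, date = "2020-01-15", lat = 45, rate = 2,
                      age = "adult") {
  data.frame(species = species, organ = organ, method = method,
             value_C = value, date = date, lat = lat, rate_C_per_h = rate,
             age_class = age, stringsAsFactors = FALSE)
}

drought_row <- function(species = "Abies alba", organ = "stem",
                        technique = "centrifuge", shape = "sigmoid",
                        p50 = -4, tlp = NA_real_) {
  data.frame(species = species, organ = organ, technique = technique,
             curve_shape = shape, p50_MPa = p50, psi_tlp_MPa = tlp,
             stringsAsFactors = FALSE)
}

## brute-force minimal-window HDI oracle
hdi_oracle <- function(draws, mass = 0.95) {
  s <- sort(draws)
  n <- length(s)
  k <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1)) {
    if (s[i + k - 1] - s[i] < best[2] - best[1]) best <- c(s[i], s[i + k - 1])
  }
  best
}

## linear-interpolation percentile oracle (independent of stats::quantile)
percentile_oracle <- function(v, q) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

## haversine great-circle distance in km (independent of geosphere)
hav_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}
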