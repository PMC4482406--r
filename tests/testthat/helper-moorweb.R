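# Shared fixtures, computed lazily and cached for the whole test run.

.moorweb_cache <- new.env(parent = emptyenv())

cached_signatures <- function() {
  if (is.null(.moorweb_cache$sig))
    .moorweb_cache$sig <- signature_table()
  .moorweb_cache$sig
}

# the synthetic four-year M2 stand-in, generated and processed once
cached_m2 <- function() {
  if (is.null(.moorweb_cache$m2)) {
    sig <- cached_signatures()
    bundles <- synthetic_m2_dataset(seed = 1, sig)
    .moorweb_cache$m2 <- list(bundles = bundles,
                              processed = process_m2_dataset(bundles, sig))
  }
  .moorweb_cache$m2
}

cached_m2_covariance <- function(year) {
  key <- paste0("cov", year)
  if (is.null(.moorweb_cache[[key]]))
    .moorweb_cache[[key]] <-
      year_covariance_summary(cached_m2()$processed[[year]]$daily,
                              include_dsigma = year != "2010")
  .moorweb_cache[[key]]
}

# hourly raw series over n days starting at the given Julian day
make_hourly_series <- function(values, start_day = 60, year = 2009,
                               variable = "temperature", depth = "shallow") {
  origin <- as.POSIXct(paste0(year, "-01-01"), tz = "UTC")
  times <- origin + ((start_day - 1) * 24 + seq_along(values) - 1) * 3600
  raw_series(times, values, variable, depth)
}

# independent DWBA oracle: fine-grid numerical quadrature of the continuous
# straight-cylinder line integral (closed geometry, no shared code with the
# package's segment sum)
oracle_straight_ts <- function(length_mm, g, h, freq_khz, tilt_deg,
                               length_radius_ratio = 16, sound_speed = 1456) {
  L <- length_mm / 1000
  a <- L / length_radius_ratio
  k1 <- 2 * pi * freq_khz * 1000 / sound_speed
  k2 <- k1 / h
  gam <- (1 - g * h^2) / (g * h^2) - (g - 1) / g
  th <- tilt_deg * pi / 180
  cosb <- cos(th)
  re <- stats::integrate(function(s) cos(2 * k1 * sin(th) * s),
                         -L / 2, L / 2, rel.tol = 1e-10)$value
  im <- stats::integrate(function(s) sin(2 * k1 * sin(th) * s),
                         -L / 2, L / 2, rel.tol = 1e-10)$value
  amp <- (k1 / 4) * gam * a * besselJ(2 * k2 * a * cosb, 1) / cosb *
    complex(real = re, imaginary = im)
  10 * log10(Mod(amp)^2)
}
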