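test_that("density anomaly matches the equation-of-state check values", {
  # independent published check values for the seawater EOS
  expect_equal(density_anomaly(5, 0, 0), -0.03325, tolerance = 1e-3)
  expect_equal(density_anomaly(5, 35, 0), 27.67547, tolerance = 1e-4)
  expect_equal(density_anomaly(25, 35, 10000), 62.53817, tolerance = 1e-4)
  expect_equal(density_anomaly(0, 35, 0), 28.1, tolerance = 0.02)
})

test_that("density anomaly has the physical monotonicities", {
  S <- seq(20, 36, by = 2)
  expect_true(all(diff(density_anomaly(5, S, 0)) > 0))   # haline contraction
  T <- seq(5, 20, by = 1)
  expect_true(all(diff(density_anomaly(T, 33, 0)) < 0))  # thermal expansion
  expect_error(density_anomaly(40, 33, 0), "temperature")
  expect_error(density_anomaly(5, 60, 0), "salinity")
})

test_that("stratification is the deep-minus-shallow density difference", {
  sh <- daily_series(2012, 60:70, rep(24, 11))
  dp <- daily_series(2012, 60:70, rep(25, 11))
  st <- stratification(sh, dp)
  expect_equal(st$delta_sigma, rep(1, 11))
  expect_equal(stratification(sh, sh)$delta_sigma, rep(0, 11))
  # alignment on the common day grid only
  dp2 <- daily_series(2012, 65:80, rep(25, 16))
  expect_equal(stratification(sh, dp2)$julian_day, 65:70)
})

test_that("stratification onset requires a sustained threshold crossing", {
  days <- 60:243
  ramp <- pmax(0, (days - 110) * 0.05)          # crosses 0.8 on day 127
  st <- data.frame(julian_day = days, delta_sigma = ramp)
  expect_equal(stratification_onset(st), 127L)

  zero <- data.frame(julian_day = days, delta_sigma = rep(0, length(days)))
  o <- stratification_onset(zero)
  expect_true(is.na(o) && isTRUE(attr(o, "undefined")))

  spike <- rep(0.1, length(days))
  spike[days == 100] <- 1.2
  spike[days >= 150] <- 1.0
  st2 <- data.frame(julian_day = days, delta_sigma = spike)
  expect_equal(stratification_onset(st2), 150L)
})

test_that("ice retreat day is the final drop below 15% cover", {
  days <- 60:243
  ext <- ifelse(days < 140, 80, 10)
  ice <- data.frame(julian_day = days, extent = ext, thickness = 0)
  expect_equal(ice_retreat_day(ice), 140L)

  none <- data.frame(julian_day = days, extent = 0, thickness = 0)
  r <- ice_retreat_day(none)
  expect_true(is.na(r) && isTRUE(attr(r, "undefined")))

  # a mid-season dip does not count: "last time" semantics
  ext2 <- rep(60, length(days))
  ext2[days >= 120 & days < 130] <- 10
  ext2[days >= 184] <- 8
  ice2 <- data.frame(julian_day = days, extent = ext2, thickness = 0)
  expect_equal(ice_retreat_day(ice2), 184L)

  # brute-force scan oracle over random step series
  set.seed(7)
  for (i in 1:20) {
    e <- pmax(0, pmin(100, cumsum(rnorm(184, -0.5, 8)) + 50))
    icex <- data.frame(julian_day = days, extent = e, thickness = 0)
    got <- ice_retreat_day(icex)
    hi <- which(e > 15)
    want <- if (!length(hi) || max(hi) == length(e)) NA_integer_ else
      days[max(hi) + 1L]
    expect_equal(as.integer(got), want)
  }
})

test_that("thin-ice day is the final drop below 50 cm", {
  days <- 60:243
  th <- ifelse(days < 119, 90, 30)
  ice <- data.frame(julian_day = days, extent = 50, thickness = th)
  expect_equal(thin_ice_day(ice), 119L)

  thin <- data.frame(julian_day = days, extent = 50, thickness = 20)
  r <- thin_ice_day(thin)
  expect_true(is.na(r) && isTRUE(attr(r, "undefined")))

  osc <- 50 + 30 * sin((days - 60) / 8) - (days - 60) * 0.45
  ice2 <- data.frame(julian_day = days, extent = 50, thickness = pmax(osc, 0))
  got <- thin_ice_day(ice2)
  hi <- which(pmax(osc, 0) >= 50)
  expect_equal(as.integer(got), days[max(hi) + 1L])
})

test_that("phenology dates are invariant to unit rescaling with scaled cutoffs", {
  days <- 60:243
  set.seed(3)
  e <- pmax(0, pmin(100, 80 - (days - 60) * 0.6 + rnorm(length(days), 0, 4)))
  ice <- data.frame(julian_day = days, extent = e, thickness = 0)
  d_pct <- ice_retreat_day(ice, cutoff = 15)
  ice_frac <- transform(ice, extent = extent / 100)
  d_frac <- ice_retreat_day(ice_frac, cutoff = 0.15)
  expect_equal(as.integer(d_pct), as.integer(d_frac))
})

test_that("environmental summary takes window max/mean and honors a truncated hydro window", {
  days <- 60:243
  ice <- data.frame(julian_day = days, extent = rep(40, 184),
                    thickness = rep(20, 184))
  tt <- daily_series(2010, days, rep(3, 184))
  ss <- daily_series(2010, days, rep(31.6, 184))
  env <- summarize_environment(ice, tt, ss, year = 2010)
  expect_equal(env$max_ice_pct, 40)
  expect_equal(env$mean_ice_pct, 40)
  expect_true(all(c(env$max_shtemp, env$mean_shtemp) == 3))

  # truncated sensor availability for temperature/salinity only
  tt2 <- daily_series(2010, days, ifelse(days < 120, 10, 3))
  env2 <- summarize_environment(ice, tt2, ss, year = 2010,
                                hydro_window = c(120, 217))
  expect_equal(env2$max_shtemp, 3)
  expect_equal(env2$mean_ice_pct, 40)  # ice still over the full window
  expect_true(env2$max_shtemp >= env2$mean_shtemp)
})
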