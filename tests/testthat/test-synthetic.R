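test_that("the generator is fully deterministic under a fixed seed", {
  sig <- cached_signatures()
  cfg <- synthetic_year_config(seed = 31)
  b1 <- generate_year(cfg, sig)
  b2 <- generate_year(cfg, sig)
  expect_identical(b1$raw$shallow_temperature$value,
                   b2$raw$shallow_temperature$value)
  expect_identical(b1$echo, b2$echo)
  expect_identical(b1$truth, b2$truth)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_year_config(ice = list(retreat_day = 20)), "window")
  expect_error(synthetic_year_config(ice = list(base_extent = 10)), "cutoff")
  expect_error(synthetic_year_config(ice = list(max_thickness = 30)), "50 cm")
  expect_error(synthetic_year_config(
    chl = list(shallow_pulses = data.frame(center = 100, peak = 5,
                                           width = -1))), "width")
})

test_that("planted phenology is recovered exactly through the pipeline", {
  sig <- cached_signatures()
  cfg <- synthetic_year_config(seed = 32,
                               ice = list(retreat_day = 151,
                                          thin_ice_day = 125))
  b <- generate_year(cfg, sig)
  expect_equal(b$truth$retreat_day, 151L)
  expect_equal(b$truth$thin_ice_day, 125L)
  p <- process_year(b, sig)
  expect_equal(p$phenology$ice_retreat_day, 151L)
  expect_equal(p$phenology$thin_ice_day, 125L)
  expect_lte(abs(p$phenology$stratification_day -
                   b$truth$stratification_day), 1)
})

test_that("planted composition survives forward-model noise within 5 points", {
  sig <- cached_signatures()
  classes <- data.frame(
    category = c("SmCrust", "MdCrust", "LgCrust", "WkReson", "StReson",
                 "Unclass"),
    center = c(100, 150, 190, 100, 100, 100),
    width = c(10, 40, 20, 10, 10, 10),
    peak = c(0, 0.6, 0.4, 0, 0, 0))
  cfg <- synthetic_year_config(seed = 33,
                               acoustics = list(classes = classes,
                                                floor_weight = 0,
                                                noise_db = 0.5))
  b <- generate_year(cfg, sig)
  comp <- composition_series(b$echo, sig)
  mm <- merge(comp, b$truth$composition, by = "julian_day",
              suffixes = c("", ".t"))
  # MdCrust is acoustically well separated, so its share holds per day;
  # LgCrust sits 3 dB from WkReson in signature space, so at 0.5 dB noise
  # occasional bins flip between those two — their combined share is the
  # acoustically resolvable quantity and holds per day
  err_md <- abs(mm$MdCrust - mm$MdCrust.t)
  err_lgwk <- abs((mm$LgCrust + mm$WkReson) -
                    (mm$LgCrust.t + mm$WkReson.t))
  expect_lt(max(err_md), 5)
  expect_lt(max(err_lgwk), 5)
  expect_lt(mean(abs(mm$LgCrust - mm$LgCrust.t)), 2)
})

test_that("planted bloom-consumer lags are recovered by the covariance stage", {
  sig <- cached_signatures()
  cfg <- synthetic_year_config(
    seed = 34,
    chl = list(shallow_pulses = data.frame(center = 150, peak = 8,
                                           width = 8)),
    acoustics = list(classes = data.frame(
      category = c("SmCrust", "MdCrust", "LgCrust", "WkReson", "StReson",
                   "Unclass"),
      center = c(160, 176, 120, 125, 205, 150),
      width = c(8, 25, 30, 30, 20, 60),
      peak = c(0.6, 0.3, 0.35, 0.3, 0.15, 0.05))))
  b <- generate_year(cfg, sig)
  p <- process_year(b, sig)
  cp <- xcov_normalized(p$daily$ShChl, p$daily$SmCrust)
  expect_lte(abs(cp$lag - 10), 1)
  expect_gt(cp$cov, 0.7)
})

test_that("cold and warm cohorts differ as constructed and separate end to end", {
  sig <- cached_signatures()
  hits <- 0
  for (s in 1:3) {
    cold <- generate_cohort(3, "cold", seed = 100 + s, sig)
    warm <- generate_cohort(3, "warm", seed = 200 + s, sig)
    r_cold <- vapply(cold, function(b) b$truth$retreat_day, integer(1))
    r_warm <- vapply(warm, function(b) b$truth$retreat_day, integer(1))
    expect_true(all(r_warm < min(r_cold)))
    feats <- do.call(rbind, lapply(c(cold, warm), function(b)
      process_year(b, sig)$environment[, -1]))
    rownames(feats) <- paste0("y", 1:6)
    r <- hcluster_simprof(normalize_features(feats), n_perm = 199, seed = s)
    k2 <- stats::cutree(r$hclust, 2)
    if (r$nodes$p_value[1] < 0.05 && length(unique(k2[1:3])) == 1 &&
        length(unique(k2[4:6])) == 1 && k2[1] != k2[4]) hits <- hits + 1
  }
  expect_gte(hits, 2)
  c1 <- generate_cohort(2, "cold", seed = 5, sig)
  c2 <- generate_cohort(2, "cold", seed = 5, sig)
  expect_identical(c1[[1]]$echo, c2[[1]]$echo)
})

test_that("the M2 stand-in carries its published study conditions", {
  m2 <- cached_m2()
  pr <- m2$processed
  tab <- m2_environment_table(features_only = FALSE)
  for (y in c("2009", "2010", "2011", "2012")) {
    expect_equal(pr[[y]]$phenology$ice_retreat_day, tab[y, "ice_retreat_day"])
    expect_equal(pr[[y]]$phenology$thin_ice_day, tab[y, "thin_ice_day"])
    expect_equal(pr[[y]]$environment$mean_ice_pct, tab[y, "mean_ice_pct"],
                 tolerance = 0.01)
    expect_equal(pr[[y]]$environment$mean_shtemp, tab[y, "mean_shtemp"],
                 tolerance = 0.05)
  }
  expect_true(pr[["2010"]]$phenology$stratification_undefined)
  expect_true(all(is.na(pr[["2010"]]$daily$SmCrust)))  # no 460-kHz channel
  # the August 2009 chlorophyll gap is filled by the trend extrapolation
  expect_false(anyNA(pr[["2009"]]$daily$ShChl))
})
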