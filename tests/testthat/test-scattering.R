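test_that("zero material contrast yields the no-scattering sentinel", {
  m <- scatterer_model("LgCrust", c(15, 30), g = 1, h = 1)
  expect_identical(dwba_backscatter(m, 200, 20), -Inf)
})

test_that("segment sum agrees with an independent quadrature oracle on straight cylinders", {
  m <- scatterer_model("LgCrust", c(15, 30), bend_ratio = Inf)
  for (case in list(c(20, 125, 0), c(20, 460, 0), c(30, 200, 10),
                    c(10, 460, 25))) {
    got <- dwba_backscatter(m, case[2], case[1], tilt_deg = case[3],
                            n_segments = 2000)
    want <- oracle_straight_ts(case[1], m$g, m$h, case[2], case[3])
    expect_equal(got, want, tolerance = 0.1 / abs(want))
  }
})

test_that("Rayleigh-regime frequency doubling raises TS by about 12 dB", {
  m <- scatterer_model("SmCrust", c(1, 5))
  ts1 <- dwba_backscatter(m, 10, 1)   # ka << 1 at 10/20 kHz for a 1-mm body
  ts2 <- dwba_backscatter(m, 20, 1)
  expect_equal(ts2 - ts1, 12, tolerance = 0.05)
})

test_that("stochastic mode is reproducible, convergent, and fills deep nulls", {
  m <- scatterer_model("LgCrust", c(15, 30))
  a <- dwba_backscatter(m, 460, 25, stochastic = TRUE, n_draws = 200,
                        seed = 42)
  b <- dwba_backscatter(m, 460, 25, stochastic = TRUE, n_draws = 200,
                        seed = 42)
  expect_identical(a, b)
  c2 <- dwba_backscatter(m, 460, 25, stochastic = TRUE, n_draws = 1000,
                         seed = 1)
  c3 <- dwba_backscatter(m, 460, 25, stochastic = TRUE, n_draws = 1000,
                         seed = 2)
  expect_lt(abs(c2 - c3), 0.5)
  # deterministic deep null: scan tilts, phase jitter must lift the minimum
  tilts <- seq(0, 40, by = 1)
  det <- vapply(tilts, function(th) dwba_backscatter(m, 460, 25,
                                                     tilt_deg = th),
                numeric(1))
  null_tilt <- tilts[which.min(det)]
  sto <- dwba_backscatter(m, 460, 25, tilt_deg = null_tilt,
                          stochastic = TRUE, n_draws = 500, seed = 9)
  expect_gt(sto, min(det))
})

test_that("class spectra are finite, size classes separate, and length scaling is monotone", {
  models <- default_scatterer_models()
  sp_sm <- class_spectrum(models$SmCrust)
  sp_lg <- class_spectrum(models$LgCrust)
  expect_true(all(is.finite(sp_sm$ts_db)) && all(is.finite(sp_lg$ts_db)))
  sep <- abs(spectrum_signature(sp_sm) - spectrum_signature(sp_lg))
  expect_gt(max(sep), 3)
  # doubling all lengths raises the expected TS at every frequency
  m2x <- scatterer_model("LgCrust", c(30, 60))
  sp2x <- class_spectrum(m2x)
  expect_true(all(sp2x$ts_db > sp_lg$ts_db))
  expect_error(class_spectrum(models$WkReson), "resonant")
})

test_that("resonant spectra carry the 200-kHz elevation signature", {
  wk <- spectrum_signature(resonant_spectrum("weak"))
  st <- spectrum_signature(resonant_spectrum("strong"))
  expect_equal(unname(wk), c(2, 0, -2))
  expect_equal(unname(st), c(25, 0, -25))
  expect_equal(wk[["d460_125"]], wk[["d200_125"]] + wk[["d460_200"]])
  expect_equal(st[["d460_125"]], st[["d200_125"]] + st[["d460_200"]])
})

test_that("the signature table has five consistent rows and is deterministic", {
  sig <- cached_signatures()
  expect_equal(nrow(sig), 5)
  expect_equal(sig$category, c("SmCrust", "MdCrust", "LgCrust", "WkReson",
                               "StReson"))
  expect_equal(sig$d460_125, sig$d200_125 + sig$d460_200, tolerance = 1e-12)
  expect_identical(signature_table(), signature_table())
  tf <- withr::local_tempfile(fileext = ".csv")
  write_signatures(sig, tf)
  back <- read_signatures(tf)
  expect_equal(back$d200_125, sig$d200_125, tolerance = 1e-10)
})

test_that("signatures are invariant to a constant offset across frequencies", {
  sig <- cached_signatures()
  sp <- structure(list(frequencies_khz = c(125, 200, 460),
                       ts_db = c(-80, -76, -70), category = "x"),
                  class = "scattering_spectrum")
  sp_off <- sp; sp_off$ts_db <- sp$ts_db + 13.7
  expect_equal(spectrum_signature(sp), spectrum_signature(sp_off))
})
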