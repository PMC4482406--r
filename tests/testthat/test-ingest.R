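test_that("read_mooring_table reads mapped columns and drops bad timestamps", {
  tf <- withr::local_tempfile(fileext = ".csv")
  ts <- format(as.POSIXct("2012-03-01", tz = "UTC") + 0:9 * 3600,
               "%Y-%m-%d %H:%M")
  ts[4] <- "not a time"
  write.csv(data.frame(t = ts, sh_temp = rnorm(10), ice = runif(10, 0, 100)),
            tf, row.names = FALSE)
  ser <- read_mooring_table(tf, list(
    timestamp = "t",
    shallow_temperature = list(column = "sh_temp", depth = "shallow"),
    ice_extent = "ice"))
  expect_named(ser, c("shallow_temperature", "ice_extent"))
  expect_equal(nrow(ser$shallow_temperature), 9)
  expect_equal(attr(ser, "dropped_rows"), 1)
  expect_equal(attr(ser$shallow_temperature, "depth"), "shallow")
  expect_error(read_mooring_table(tf, list(timestamp = "t", x = "nope")),
               "nope")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("t,v", empty)
  expect_error(read_mooring_table(empty, list(timestamp = "t", v = "v")),
               "empty")
})

test_that("Lanczos-squared filter has unit DC gain and the stated band edges", {
  w <- lanczos_weights(35)
  expect_equal(sum(w), 1)
  expect_equal(w, rev(w))
  # frequency-response oracle: direct evaluation of H(f) from the weights
  k <- seq(-(length(w) - 1) / 2, (length(w) - 1) / 2)
  H <- function(f) sum(w * cos(2 * pi * f * k))
  expect_equal(H(1 / 35)^2, 0.5, tolerance = 1e-8)
  expect_lt(abs(H(1 / 12)), 0.1)     # 12-h tide band strongly attenuated
  expect_gt(H(1 / 480), 0.95)        # 20-day band passes
  # response decreases monotonically through the transition band
  # (stopband sidelobes ring, so the sweep spans pass edge to stop edge)
  fs <- 1 / (35 * 2^seq(-1, 3, by = 0.25))
  expect_true(all(diff(vapply(sort(fs), H, numeric(1))) <= 1e-6))
})

test_that("filtering preserves constants and masks incomplete windows", {
  x <- make_hourly_series(rep(3.5, 200))
  f <- lanczos_lowpass(x)
  expect_equal(f$value[36:165], rep(3.5, 130))
  expect_true(all(is.na(f$value[1:35])))
  expect_true(all(is.na(f$value[166:200])))
  # attenuation of a 12-h sinusoid, passage of a 20-day one
  n <- 24 * 60
  tide <- make_hourly_series(sin(2 * pi * (1:n) / 12))
  slow <- make_hourly_series(sin(2 * pi * (1:n) / 480))
  expect_lt(max(abs(lanczos_lowpass(tide)$value), na.rm = TRUE), 0.1)
  expect_gt(max(abs(lanczos_lowpass(slow)$value), na.rm = TRUE), 0.95)
  expect_error(lanczos_lowpass(make_hourly_series(rnorm(20))), "shorter")
})

test_that("block averaging takes per-block means and handles empty blocks", {
  x <- make_hourly_series(1:6)
  expect_equal(block_average(x)$value, 3.5)
  y <- make_hourly_series(rep(c(0, 1), 6))
  expect_equal(block_average(y)$value, rep(0.5, 2))
  z <- make_hourly_series(c(rep(NA, 6), 1:6))
  expect_equal(block_average(z)$value, c(NA, 3.5))
})

test_that("daily binning averages within calendar days and flags gaps", {
  x <- make_hourly_series(rep(1:4, each = 6))  # one day of 6-h means 1..4
  d <- daily_bin(x)
  expect_equal(d$value, 2.5)
  expect_equal(d$mask, "observed")
  # two observed days separated by an empty day
  v <- c(rep(1, 24), rep(NA, 24), rep(5, 24))
  d3 <- daily_bin(make_hourly_series(v))
  expect_equal(d3$value, c(1, NA, 5))
  expect_equal(d3$mask, c("observed", "missing", "observed"))
})

test_that("gap filling interpolates short internal gaps only", {
  s <- daily_series(2009, 100:102, c(1, NA, 3))
  f <- fill_gaps(s)
  expect_equal(f$value[2], 2)
  expect_equal(f$mask[2], "linear_interp")

  s2 <- daily_series(2009, 100:104, c(0, NA, NA, NA, 8))
  expect_equal(fill_gaps(s2)$value, c(0, 2, 4, 6, 8))

  long <- daily_series(2009, 1:30, c(1, rep(NA, 20), rep(2, 9)))
  expect_true(all(is.na(fill_gaps(long)$value[2:21])))

  # observed values are never altered by the fill
  set.seed(1)
  v <- rnorm(50); v[sample(2:49, 10)] <- NA
  s3 <- daily_series(2009, 1:50, v)
  f3 <- fill_gaps(s3)
  expect_identical(f3$value[f3$mask == "observed"], v[!is.na(v)])
})

test_that("trailing gaps are extrapolated only on request", {
  s <- daily_series(2009, 1:20, c(seq(1, 10, length.out = 10), rep(NA, 10)))
  expect_true(all(is.na(fill_gaps(s)$value[11:20])))
  f <- fill_gaps(s, extrapolate_tail = TRUE)
  expect_equal(f$value[11:20], seq(11, 20), tolerance = 1e-8)
  expect_true(all(f$mask[11:20] == "extrapolated"))
})

test_that("ice conditioning zero-fills ice-free gaps and nearest-neighbor fills the rest", {
  ice <- data.frame(julian_day = c(150, 152), extent = c(0, 0),
                    thickness = c(0, 0))
  out <- condition_ice(ice)
  expect_equal(out$extent, c(0, 0, 0))
  expect_equal(out$mask[2], "zero_filled")

  ice2 <- data.frame(julian_day = 101:103, extent = c(80, NA, 60),
                     thickness = c(60, NA, 40))
  out2 <- condition_ice(ice2)
  expect_equal(out2$extent[2], 80)  # tie resolves to the earlier neighbor

  ice3 <- data.frame(julian_day = 101:105,
                     extent = c(80, NA, NA, NA, 60),
                     thickness = c(60, NA, NA, NA, 40))
  out3 <- condition_ice(ice3)
  expect_equal(out3$extent[2:4], c(80, 80, 60))

  # complete daily grid between first and last observation
  ice4 <- data.frame(julian_day = c(100, 103, 107, 110),
                     extent = c(80, 70, 20, 10),
                     thickness = c(90, 60, 10, 0))
  out4 <- condition_ice(ice4)
  expect_equal(out4$julian_day, 100:110)
  expect_false(anyNA(out4$extent))
  expect_error(condition_ice(data.frame(julian_day = 1, extent = 130,
                                        thickness = 0)), "extent")
})
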