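#' Seawater density anomaly (EOS-80)
#'
#' In-situ density minus 1000 kg m^-3 from the International Equation of State
#' of Seawater (EOS-80, UNESCO 1983): the one-atmosphere density polynomial
#' plus the secant bulk modulus for pressure dependence. Agrees with the
#' published check values to 1e-5 kg m^-3; the EOS-80 vs TEOS-10 divergence is
#' below 0.02 kg m^-3 over shelf conditions.
#'
#' @param temperature in-situ temperature, deg C (ITS; -2 to 35).
#' @param salinity practical salinity (0 to 42).
#' @param pressure sea pressure, dbar (default 0).
#' @return Density anomaly sigma = rho(S, T, P) - 1000, kg m^-3.
#' @examples
#' density_anomaly(0, 35, 0)   # ~28.106
#' @export
density_anomaly <- function(temperature, salinity, pressure = 0) {
  bad_t <- !is.na(temperature) & (temperature < -2 | temperature > 35)
  if (any(bad_t)) stop("temperature out of range [-2, 35] degC")
  bad_s <- !is.na(salinity) & (salinity < 0 | salinity > 42)
  if (any(bad_s)) stop("salinity out of range [0, 42]")
  bad_p <- !is.na(pressure) & pressure < 0
  if (any(bad_p)) stop("pressure must be non-negative (dbar)")
  T <- temperature; S <- salinity
  P <- pressure / 10 # dbar -> bar for the bulk-modulus polynomial

  rho_w <- 999.842594 + 6.793952e-2 * T - 9.095290e-3 * T^2 +
    1.001685e-4 * T^3 - 1.120083e-6 * T^4 + 6.536332e-9 * T^5
  rho0 <- rho_w +
    S * (0.824493 - 4.0899e-3 * T + 7.6438e-5 * T^2 -
           8.2467e-7 * T^3 + 5.3875e-9 * T^4) +
    S^1.5 * (-5.72466e-3 + 1.0227e-4 * T - 1.6546e-6 * T^2) +
    4.8314e-4 * S^2

  Kw <- 19652.21 + 148.4206 * T - 2.327105 * T^2 +
    1.360477e-2 * T^3 - 5.155288e-5 * T^4
  K0 <- Kw +
    S * (54.6746 - 0.603459 * T + 1.09987e-2 * T^2 - 6.1670e-5 * T^3) +
    S^1.5 * (7.944e-2 + 1.6483e-2 * T - 5.3009e-4 * T^2)
  Aw <- 3.239908 + 1.43713e-3 * T + 1.16092e-4 * T^2 - 5.77905e-7 * T^3
  A <- Aw + S * (2.2838e-3 - 1.0981e-5 * T - 1.6078e-6 * T^2) +
    1.91075e-4 * S^1.5
  Bw <- 8.50935e-5 - 6.12293e-6 * T + 5.2787e-8 * T^2
  B <- Bw + S * (-9.9348e-7 + 2.0816e-8 * T + 9.1697e-10 * T^2)
  K <- K0 + A * P + B * P^2

  rho0 / (1 - P / K) - 1000
}

#' Stratification series from shallow and deep density anomalies
#'
#' Aligns two daily density-anomaly series on their common Julian-day grid and
#' forms the stratification index delta-sigma = sigma(deep) - sigma(shallow),
#' positive for a stably stratified column.
#'
#' @param sigma_shallow,sigma_deep `daily_series` of density anomaly
#'   (kg m^-3) at the shallow and deep sensors.
#' @return A `data.frame` of class `"stratification_series"` with columns
#'   `year`, `julian_day`, `sigma_shallow`, `sigma_deep`, `delta_sigma`.
#' @export
stratification <- function(sigma_shallow, sigma_deep) {
  stopifnot(inherits(sigma_shallow, "daily_series"),
            inherits(sigma_deep, "daily_series"))
  key_s <- paste(sigma_shallow$year, sigma_shallow$julian_day)
  key_d <- paste(sigma_deep$year, sigma_deep$julian_day)
  common <- intersect(key_s, key_d)
  i <- match(common, key_s); j <- match(common, key_d)
  out <- data.frame(year = sigma_shallow$year[i],
                    julian_day = sigma_shallow$julian_day[i],
                    sigma_shallow = sigma_shallow$value[i],
                    sigma_deep = sigma_deep$value[j])
  out$delta_sigma <- out$sigma_deep - out$sigma_shallow
  out <- out[order(out$year, out$julian_day), ]
  rownames(out) <- NULL
  class(out) <- c("stratification_series", "data.frame")
  out
}

#' Stratification onset day
#'
#' First Julian day on which delta-sigma exceeds the threshold and stays above
#' it for `persistence_days` consecutive days, searched within the
#' March-August window. The persistence requirement operationalizes "generally
#' increasing": a single-day spike does not qualify. Returns `NA` with
#' attribute `undefined = TRUE` when the condition never holds.
#'
#' @param strat a `stratification_series` (or data frame with `julian_day`,
#'   `delta_sigma`).
#' @param threshold onset threshold for delta-sigma (kg m^-3), default 0.8.
#' @param persistence_days run length required above threshold, default 5.
#' @param window Julian-day search window, default days 60-243.
#' @return Integer Julian day, or `NA` (attribute `undefined`).
#' @export
stratification_onset <- function(strat, threshold = 0.8, persistence_days = 5,
                                 window = SPRING_WINDOW) {
  d <- strat[strat$julian_day >= window[1] & strat$julian_day <= window[2], ]
  d <- d[order(d$julian_day), ]
  above <- !is.na(d$delta_sigma) & d$delta_sigma > threshold
  n <- length(above)
  for (i in seq_len(n)) {
    j <- i + persistence_days - 1L
    if (j > n) break
    if (all(above[i:j]) &&
        all(diff(d$julian_day[i:j]) == 1L))
      return(d$julian_day[i])
  }
  structure(NA_integer_, undefined = TRUE)
}

# Shared "last downward crossing" scan: last day <= window end whose value is
# at-or-below (below) the cutoff immediately after the final day above
# (at-or-above) it. Guards against autumn freeze-up by ignoring days past the
# window end.
.last_crossing_day <- function(julian_day, value, above_fun, below_fun,
                               window) {
  keep <- julian_day >= min(julian_day) & julian_day <= window[2]
  jd <- julian_day[keep]; v <- value[keep]
  ok <- !is.na(v)
  jd <- jd[ok]; v <- v[ok]
  hi <- which(above_fun(v))
  if (!length(hi)) return(structure(NA_integer_, undefined = TRUE))
  last_hi <- max(hi)
  lo_after <- which(below_fun(v) & seq_along(v) > last_hi)
  if (!length(lo_after)) return(structure(NA_integer_, undefined = TRUE))
  jd[min(lo_after)]
}

#' Ice-retreat day
#'
#' The Julian day when ice extent is at or below `cutoff` percent for the last
#' time that spring: the first day at-or-below the cutoff after the final day
#' above it, with extent remaining at-or-below the cutoff through the end of
#' the window (31 August). Undefined when ice never exceeds the cutoff.
#'
#' @param ice an `ice_series` (daily `julian_day`, `extent`).
#' @param cutoff retreat threshold in percent cover, default 15.
#' @param window Julian-day window bounding the search, default days 60-243.
#' @return Integer Julian day, or `NA` (attribute `undefined`).
#' @export
ice_retreat_day <- function(ice, cutoff = 15, window = SPRING_WINDOW) {
  .last_crossing_day(ice$julian_day, ice$extent,
                     function(v) v > cutoff, function(v) v <= cutoff, window)
}

#' Thin-ice day
#'
#' The Julian day when ice thickness measures below `cutoff_cm` for the last
#' time: the first day below the cutoff after the final day at-or-above it.
#' The 50 cm default marks the thickness below which light attenuation through
#' sea ice drops sharply.
#'
#' @param ice an `ice_series` (daily `julian_day`, `thickness`).
#' @param cutoff_cm thickness threshold in cm, default 50.
#' @param window Julian-day window bounding the search.
#' @return Integer Julian day, or `NA` (attribute `undefined`).
#' @export
thin_ice_day <- function(ice, cutoff_cm = 50, window = SPRING_WINDOW) {
  .last_crossing_day(ice$julian_day, ice$thickness,
                     function(v) v >= cutoff_cm, function(v) v < cutoff_cm,
                     window)
}

#' Summarize spring-summer environmental conditions for one year
#'
#' Maximum and mean of ice extent, ice thickness, shallow temperature, and
#' shallow salinity over the March-August window (missing days excluded), the
#' feature set used for the between-year resemblance analysis.
#'
#' @param ice an `ice_series` for the year.
#' @param shallow_temperature,shallow_salinity `daily_series` at the shallow
#'   sensor.
#' @param year calendar year label.
#' @param window Julian-day window, default days 60-243.
#' @param hydro_window optional narrower Julian-day window applied to
#'   temperature and salinity only (e.g. a truncated sensor deployment).
#' @return A one-row `data.frame` with columns `year`, `max_ice_pct`,
#'   `mean_ice_pct`, `max_ice_cm`, `mean_ice_cm`, `max_shtemp`, `mean_shtemp`,
#'   `max_shsal`, `mean_shsal`.
#' @export
summarize_environment <- function(ice, shallow_temperature, shallow_salinity,
                                  year = NA_integer_, window = SPRING_WINDOW,
                                  hydro_window = window) {
  in_win <- function(df, w) df[df$julian_day >= w[1] & df$julian_day <= w[2], ]
  mx <- function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  mn <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  icw <- in_win(ice, window)
  tw <- in_win(shallow_temperature, hydro_window)
  sw <- in_win(shallow_salinity, hydro_window)
  data.frame(year = year,
             max_ice_pct = mx(icw$extent), mean_ice_pct = mn(icw$extent),
             max_ice_cm = mx(icw$thickness), mean_ice_cm = mn(icw$thickness),
             max_shtemp = mx(tw$value), mean_shtemp = mn(tw$value),
             max_shsal = mx(sw$value), mean_shsal = mn(sw$value))
}

#' Phenology dates for one year
#'
#' Bundles the three transition dates — ice retreat (extent <= 15% for the
#' last time), thin ice (thickness < 50 cm for the last time), and
#' stratification onset (delta-sigma > 0.8, sustained) — with undefined flags.
#'
#' @param ice an `ice_series`.
#' @param strat a `stratification_series`, or `NULL` when stratification was
#'   not computed (the onset is then flagged undefined).
#' @param year calendar year label.
#' @inheritParams stratification_onset
#' @return A one-row `data.frame`: `year`, `ice_retreat_day`, `thin_ice_day`,
#'   `stratification_day`, plus logical `*_undefined` flags.
#' @export
phenology_dates <- function(ice, strat = NULL, year = NA_integer_,
                            threshold = 0.8, persistence_days = 5,
                            window = SPRING_WINDOW) {
  rd <- ice_retreat_day(ice, window = window)
  td <- thin_ice_day(ice, window = window)
  sd <- if (is.null(strat)) structure(NA_integer_, undefined = TRUE) else
    stratification_onset(strat, threshold, persistence_days, window)
  undef <- function(x) isTRUE(attr(x, "undefined"))
  data.frame(year = year,
             ice_retreat_day = as.integer(rd),
             thin_ice_day = as.integer(td),
             stratification_day = as.integer(sd),
             ice_retreat_undefined = undef(rd),
             thin_ice_undefined = undef(td),
             stratification_undefined = undef(sd))
}
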