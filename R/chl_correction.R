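#' Fit rescaling parameters for a mis-scaled fluorometer period
#'
#' When a replacement fluorometer records with a wrong factory scale factor,
#' the affected period retains realistic relative variability but implausible
#' magnitudes. The correction normalizes the bad period by its own mean and
#' standard deviation and re-expresses it on the mean and standard deviation
#' of a trusted reference period from the same site. This fits those four
#' constants from observed values.
#'
#' @param series a `daily_series` of chlorophyll fluorescence with a `date`
#'   column, or columns `year` + `julian_day`.
#' @param bad_period,ref_period length-2 `Date` (or coercible) vectors giving
#'   inclusive start/end of the mis-scaled and reference periods.
#' @return A list of class `"rescale_params"` with `mu_bad`, `sd_bad`,
#'   `mu_ref`, `sd_ref`, and the period boundaries.
#' @export
fit_rescale_params <- function(series, bad_period, ref_period) {
  dates <- series_dates(series)
  bad_period <- as.Date(bad_period); ref_period <- as.Date(ref_period)
  pick <- function(p) {
    v <- series$value[dates >= p[1] & dates <= p[2] &
                        series$mask == "observed"]
    v[!is.na(v)]
  }
  vb <- pick(bad_period); vr <- pick(ref_period)
  if (length(vb) < 2 || length(vr) < 2)
    stop("both periods need at least 2 observed values")
  out <- list(mu_bad = mean(vb), sd_bad = sd(vb),
              mu_ref = mean(vr), sd_ref = sd(vr),
              bad_period = bad_period, ref_period = ref_period)
  if (out$sd_bad == 0 || out$sd_ref == 0)
    stop("degenerate (zero) standard deviation in a fitting period")
  class(out) <- "rescale_params"
  out
}

# Calendar dates of a daily series.
series_dates <- function(series) {
  if (!is.null(series$date)) return(as.Date(series$date))
  as.Date(series$julian_day - 1L,
          origin = as.Date(paste0(series$year, "-01-01")))
}

#' Rescale mis-scaled fluorescence values
#'
#' Affine transform `(value - mu_bad) / sd_bad * sd_ref + mu_ref`: the bad
#' period's z-scores are re-expressed on the reference period's scale. No
#' clipping is applied; values mapped below zero are flagged via the
#' `negative` attribute rather than floored.
#'
#' @param value numeric vector of mis-scaled values (ug L^-1).
#' @param params a [fit_rescale_params()] result (or list with the same
#'   elements).
#' @return Corrected values (ug L^-1) with attribute `negative` marking any
#'   below zero.
#' @examples
#' p <- list(mu_bad = 0.1, sd_bad = 0.1, mu_ref = 2.0, sd_ref = 2.6)
#' rescale(0.1, p)   # 2.0: a z-score of 0 maps to the reference mean
#' rescale(0.2, p)   # 4.6
#' @export
rescale <- function(value, params) {
  if (params$sd_bad <= 0 || params$sd_ref <= 0)
    stop("rescale parameters must have positive standard deviations")
  out <- (value - params$mu_bad) / params$sd_bad * params$sd_ref + params$mu_ref
  attr(out, "negative") <- which(!is.na(out) & out < 0)
  out
}

#' Apply the rescaling correction to a daily series
#'
#' Rescales all values inside the bad period and sets their provenance mask to
#' `"corrected"`; values outside the period are untouched.
#'
#' @param series a `daily_series` of chlorophyll fluorescence.
#' @param params a [fit_rescale_params()] result.
#' @return The corrected `daily_series`.
#' @export
apply_rescale <- function(series, params) {
  dates <- series_dates(series)
  sel <- dates >= params$bad_period[1] & dates <= params$bad_period[2] &
    !is.na(series$value)
  series$value[sel] <- as.numeric(rescale(series$value[sel], params))
  series$mask[sel] <- "corrected"
  series
}

#' Validation ratio between coincident CTD and mooring measurements
#'
#' Simple ratio used to judge whether a corrected mooring fluorescence record
#' is consistent with an independent CTD-mounted fluorometer profile taken at
#' the site (differences up to a factor of a few are attributable to
#' calibration and fine-scale variability).
#'
#' @param ctd_value CTD-derived concentration (> 0).
#' @param mooring_value mooring-derived concentration (> 0).
#' @return `ctd_value / mooring_value` (dimensionless).
#' @export
validation_ratio <- function(ctd_value, mooring_value) {
  if (any(ctd_value <= 0) || any(mooring_value <= 0))
    stop("both concentrations must be positive")
  ctd_value / mooring_value
}
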