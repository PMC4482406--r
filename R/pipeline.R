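#' Process one mooring year bundle onto the daily analysis grid
#'
#' Runs the full conditioning pipeline on a year's raw series: 35-h
#' Lanczos-squared low-pass, 6-h block averaging, daily binning, and
#' interpolation of sub-two-week gaps; conditions the ice series; computes
#' density anomaly at the shallow and deep sensors and the stratification
#' index; classifies the echo grid into the scatterer composition; and
#' assembles the wide daily table used by the covariance analysis, plus the
#' phenology dates and the environmental summary.
#'
#' @param bundle a list with elements `raw` (named list of [raw_series()]:
#'   `shallow_temperature`, `deep_temperature`, `shallow_salinity`,
#'   `deep_salinity`, `shallow_chl`, `mid_chl`), `ice` (observation table for
#'   [condition_ice()]), `echo` (grid for [composition_series()]), and
#'   optionally `config$year` — e.g. a [generate_year()] result.
#' @param signatures signature table for classification; default
#'   [signature_table()].
#' @param window Julian-day analysis window.
#' @param compute_strat compute the stratification series and onset? Set
#'   `FALSE` for discontinuous deployments.
#' @param extrapolate_chl_tail extend a trailing chlorophyll gap by linear
#'   trend (see [fill_gaps()]).
#' @param shallow_pressure,deep_pressure sensor pressures (dbar) for the
#'   density anomaly.
#' @param hydro_window optional Julian-day range restricting the
#'   temperature/salinity summary (truncated deployments).
#' @return A list of class `"mooring_year"`: `daily` (wide data frame:
#'   `julian_day`, `ShTemp`, `DpTemp`, `ShSal`, `DpSal`, `DeltaSigma`,
#'   `ShChl`, `MidChl`, `Sv` (dB of the column-integrated linear total),
#'   category percent columns, `IcePct`, `IceCm`), `phenology`,
#'   `environment`, `ice`, `strat`, `composition`.
#' @export
process_year <- function(bundle, signatures = NULL, window = SPRING_WINDOW,
                         compute_strat = TRUE, extrapolate_chl_tail = FALSE,
                         shallow_pressure = 11, deep_pressure = 55,
                         hydro_window = window) {
  if (is.null(signatures)) signatures <- signature_table()
  year <- if (!is.null(bundle$config$year)) bundle$config$year else
    NA_integer_

  cond <- function(rs, extrapolate = FALSE) {
    ds <- daily_bin(block_average(lanczos_lowpass(rs), 6))
    fill_gaps(ds, max_gap_days = 14, extrapolate_tail = extrapolate)
  }
  sh_t <- cond(bundle$raw$shallow_temperature)
  dp_t <- cond(bundle$raw$deep_temperature)
  sh_s <- cond(bundle$raw$shallow_salinity)
  dp_s <- cond(bundle$raw$deep_salinity)
  sh_c <- cond(bundle$raw$shallow_chl, extrapolate_chl_tail)
  md_c <- cond(bundle$raw$mid_chl, extrapolate_chl_tail)

  ice <- condition_ice(bundle$ice[c("julian_day", "extent", "thickness")])

  strat <- NULL
  if (compute_strat) {
    sig_sh <- sh_t
    both <- !is.na(sh_t$value) & !is.na(sh_s$value)
    sig_sh$value <- ifelse(both, density_anomaly(
      pmin(pmax(sh_t$value, -1.99), 34.99), pmin(pmax(sh_s$value, 0), 42),
      shallow_pressure), NA)
    sig_dp <- dp_t
    bothd <- !is.na(dp_t$value) & !is.na(dp_s$value)
    sig_dp$value <- ifelse(bothd, density_anomaly(
      pmin(pmax(dp_t$value, -1.99), 34.99), pmin(pmax(dp_s$value, 0), 42),
      deep_pressure), NA)
    strat <- stratification(sig_sh, sig_dp)
  }

  comp <- if (!is.null(bundle$echo) &&
                any(complete.cases(bundle$echo[c("sv125", "sv200", "sv460")])))
    composition_series(bundle$echo, signatures) else NULL

  days <- seq.int(window[1], window[2])
  pick <- function(ds) ds$value[match(days, ds$julian_day)]
  daily <- data.frame(
    julian_day = days,
    ShTemp = pick(sh_t), DpTemp = pick(dp_t),
    ShSal = pick(sh_s), DpSal = pick(dp_s),
    DeltaSigma = if (is.null(strat)) NA_real_ else
      strat$delta_sigma[match(days, strat$julian_day)],
    ShChl = pick(sh_c), MidChl = pick(md_c))
  # total scattering straight from the 200-kHz channel (no 460 needed)
  if (!is.null(bundle$echo)) {
    lin <- tapply(10^(bundle$echo$sv200 / 10), bundle$echo$julian_day,
                  sum, na.rm = TRUE)
    daily$Sv <- 10 * log10(as.numeric(lin[match(days, as.numeric(names(lin)))]))
  } else daily$Sv <- NA_real_
  cats <- c(SCATTERER_CATEGORIES, "Unclass")
  for (cc in cats)
    daily[[cc]] <- if (is.null(comp)) NA_real_ else
      comp[[cc]][match(days, comp$julian_day)]
  daily$IcePct <- ice$extent[match(days, ice$julian_day)]
  daily$IceCm <- ice$thickness[match(days, ice$julian_day)]

  phen <- phenology_dates(ice, strat, year = year, window = window)
  env <- summarize_environment(ice, sh_t, sh_s, year = year, window = window,
                               hydro_window = hydro_window)
  structure(list(daily = daily, phenology = phen, environment = env,
                 ice = ice, strat = strat, composition = comp, year = year),
            class = "mooring_year")
}

# Initial variables of the covariance analysis, in table order.
COVARIANCE_INITIAL_VARS <- c("ShTemp", "DpTemp", "ShSal", "DpSal",
                             "DeltaSigma", "ShChl", "MidChl", "Sv",
                             "SmCrust", "MdCrust", "LgCrust", "WkReson",
                             "StReson", "Unclass")

#' Year covariance summary (top-2 covariates per initial variable)
#'
#' Runs [xcov_matrix()] over the 14 initial variables of the processed daily
#' table (ice extent and thickness enter as comparison-only variables) and
#' keeps the top two |cov| pairs per initial variable — 28 values per year
#' when all variables are available.
#'
#' @param daily the wide `daily` table from [process_year()].
#' @param include_dsigma include the stratification index among the initial
#'   variables (drop it for years where stratification was not computed)?
#' @param max_lag lag bound in days, default 150.
#' @return A list: `pairs` (all pairs), `top` (top-2 per initial variable),
#'   `cov_values` (the |cov| vector), `mean_abs_cov`.
#' @export
year_covariance_summary <- function(daily, include_dsigma = TRUE,
                                    max_lag = 150) {
  vars <- COVARIANCE_INITIAL_VARS
  if (!include_dsigma) vars <- setdiff(vars, "DeltaSigma")
  avail <- vars[vapply(vars, function(v)
    sum(!is.na(daily[[v]])) >= 30 && sd(daily[[v]], na.rm = TRUE) > 0,
    logical(1))]
  comparison <- c(avail, "IcePct", "IceCm")
  pairs <- xcov_matrix(daily[c(avail, "IcePct", "IceCm")], avail,
                       comparison, max_lag = max_lag)
  top <- top_covariates(pairs, k = 2)
  list(pairs = pairs, top = top, cov_values = abs(top$cov),
       mean_abs_cov = mean(abs(top$cov)))
}
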