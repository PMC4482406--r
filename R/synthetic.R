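#' Configuration for one synthetic mooring year
#'
#' Defines the planted physics of a synthetic spring-summer transition:
#' a seasonal ice cycle (plateau + melt decay crossing 15% on the retreat day,
#' and a thickness pulse whose right flank crosses 50 cm on the thin-ice day),
#' a two-layer temperature/salinity structure whose density-anomaly difference
#' crosses the stratification threshold, depth-specific Gaussian chlorophyll
#' bloom pulses, and per-category seasonal scatterer abundance curves that are
#' forward-modelled to three-frequency backscatter through the theoretical
#' signature table.
#'
#' @param year calendar year label.
#' @param seed RNG seed for all of the year's noise.
#' @param window Julian-day analysis window (default days 60-243); hourly
#'   series carry a 3-day margin on each side so low-pass edge masking does
#'   not eat into the window.
#' @param ice list: `retreat_day`, `thin_ice_day`, `base_extent` (%; plateau
#'   level), `max_extent` (%; brief peak), `extent_bump_day`,
#'   `extent_bump_width`, `extent_decay_width` (d), `base_thickness` (cm),
#'   `max_thickness` (cm), `thickness_pulse_width` (d), `obs_interval` (d).
#' @param temp list: `winter_shallow`, `max_shallow` (deg C at the window
#'   end), `warming_mid` (day; `NULL` = retreat + 25), `warming_width`,
#'   `winter_deep`, `max_deep`, `deep_warming_mid` (`NULL` = retreat + 50),
#'   `deep_warming_width`.
#' @param sal list: `shallow_base`, `freshening_amp`, `freshening_day`
#'   (`NULL` = retreat day), `freshening_width`, `deep_base`.
#' @param chl list: `baseline` (ug L^-1), `shallow_pulses` and `mid_pulses`
#'   (data frames with `center`, `peak`, `width` in days/ug L^-1), `gap_days`
#'   (optional Julian days dropped from both fluorometers).
#' @param acoustics list: `classes` (data frame `category`, `center`, `width`,
#'   `peak` — relative linear-s_v weight curves), `floor_weight`, `n_bins`,
#'   `sv_scale` (linear m^2 m^-3 per unit weight), `noise_db`,
#'   `unclass_signature` (dB-difference triple planted for unclassifiable
#'   scatter).
#' @param noise list of hourly noise SDs: `temp` (deg C), `sal`, `chl`
#'   (ug L^-1).
#' @param hydro_days optional Julian-day range restricting hydrographic
#'   availability (truncated deployments).
#' @param shallow_temp_curve optional data frame (`julian_day`, `value`)
#'   overriding the logistic shallow-temperature curve.
#' @return A validated list of class `"synthetic_year_config"`.
#' @export
synthetic_year_config <- function(year = 2009, seed = 1,
                                  window = SPRING_WINDOW,
                                  ice = list(), temp = list(), sal = list(),
                                  chl = list(), acoustics = list(),
                                  noise = list(), hydro_days = NULL,
                                  shallow_temp_curve = NULL) {
  merge_defaults <- function(user, def) {
    def[names(user)] <- user
    def
  }
  ice <- merge_defaults(ice, list(
    retreat_day = 140, thin_ice_day = 119, base_extent = 30, max_extent = 85,
    extent_bump_day = 90, extent_bump_width = 4, extent_decay_width = 4,
    base_thickness = 8, max_thickness = 100, thickness_pulse_width = 8,
    obs_interval = 1))
  temp <- merge_defaults(temp, list(
    winter_shallow = -1.7, max_shallow = 10, warming_mid = NULL,
    warming_width = 15, winter_deep = -1.7, max_deep = 1.5,
    deep_warming_mid = NULL, deep_warming_width = 25))
  sal <- merge_defaults(sal, list(
    shallow_base = 31.9, freshening_amp = 0.8, freshening_day = NULL,
    freshening_width = 8, deep_base = 31.85))
  chl <- merge_defaults(chl, list(
    baseline = 0.4,
    shallow_pulses = data.frame(center = 156, peak = 9, width = 5),
    mid_pulses = data.frame(center = 154, peak = 14.7, width = 5),
    gap_days = NULL))
  acoustics <- merge_defaults(acoustics, list(
    classes = data.frame(
      category = c("SmCrust", "MdCrust", "LgCrust", "WkReson", "StReson",
                   "Unclass"),
      center = c(170, 176, 120, 125, 205, 150),
      width = c(20, 25, 30, 30, 20, 60),
      peak = c(0.5, 0.3, 0.35, 0.3, 0.15, 0.05)),
    floor_weight = 0.02, n_bins = 12, sv_scale = 1e-7, noise_db = 0.5,
    unclass_signature = c(-25, -25, 0)))
  noise <- merge_defaults(noise, list(temp = 0.05, sal = 0.01, chl = 0.08))

  if (ice$retreat_day < window[1] || ice$retreat_day > window[2])
    stop("retreat_day must lie inside the analysis window")
  if (ice$base_extent <= 15)
    stop("base_extent must exceed the 15% retreat cutoff")
  if (ice$max_thickness <= 50)
    stop("max_thickness must exceed the 50 cm benchmark")
  if (any(chl$shallow_pulses$width <= 0) || any(chl$mid_pulses$width <= 0))
    stop("bloom pulse widths must be positive")
  if (any(acoustics$classes$peak < 0) || any(acoustics$classes$width <= 0))
    stop("class abundance curves must be non-negative with positive widths")
  if (any(vapply(noise, function(x) x < 0, logical(1))))
    stop("noise SDs must be non-negative")
  structure(list(year = year, seed = seed, window = window, margin = 3,
                 ice = ice, temp = temp, sal = sal, chl = chl,
                 acoustics = acoustics, noise = noise,
                 hydro_days = hydro_days,
                 shallow_temp_curve = shallow_temp_curve),
            class = "synthetic_year_config")
}

.gauss <- function(t, center, width) exp(-((t - center) / width)^2 / 2)
.plog <- function(t, mid, width) stats::plogis((t - mid) / width)

# Noise-free continuous ice curves; t in fractional Julian days.
.ice_extent_curve <- function(cfg, t) {
  ic <- cfg$ice
  r0 <- ic$retreat_day - 0.5
  base_curve <- function(t50) {
    function(t) {
      decay <- stats::plogis(-(t - t50) / ic$extent_decay_width)
      bump <- (ic$max_extent - ic$base_extent) *
        .gauss(t, ic$extent_bump_day, ic$extent_bump_width)
      pmin((ic$base_extent + bump) * decay, 100)
    }
  }
  t50 <- uniroot(function(s) base_curve(s)(r0) - 15,
                 lower = r0 - 80, upper = r0 + 80, tol = 1e-10)$root
  base_curve(t50)(t)
}

.ice_thickness_curve <- function(cfg, t) {
  ic <- cfg$ice
  th0 <- cfg$ice$thin_ice_day - 0.5
  decay <- function(t) stats::plogis(-(t - (ic$retreat_day - 2)) / 3)
  curve_for <- function(tc) {
    function(t) (ic$base_thickness +
                   (ic$max_thickness - ic$base_thickness) *
                   .gauss(t, tc, ic$thickness_pulse_width)) * decay(t)
  }
  tc <- uniroot(function(s) curve_for(s)(th0) - 50,
                lower = th0 - 6 * ic$thickness_pulse_width, upper = th0,
                tol = 1e-10)$root
  v <- curve_for(tc)(t)
  ext <- .ice_extent_curve(cfg, t)
  v[ext < 0.5] <- 0
  v
}

.shallow_temp_curve <- function(cfg, t) {
  if (!is.null(cfg$shallow_temp_curve)) {
    sc <- cfg$shallow_temp_curve
    return(approx(sc$julian_day, sc$value, xout = t, rule = 2)$y)
  }
  tp <- cfg$temp
  mid <- if (is.null(tp$warming_mid)) cfg$ice$retreat_day + 25 else
    tp$warming_mid
  end_day <- if (is.null(tp$max_day)) cfg$window[2] else tp$max_day
  # asymptote chosen so the curve reaches max_shallow at the series end
  A <- tp$winter_shallow + (tp$max_shallow - tp$winter_shallow) /
    stats::plogis((end_day - mid) / tp$warming_width)
  tp$winter_shallow + (A - tp$winter_shallow) *
    stats::plogis((t - mid) / tp$warming_width)
}

.deep_temp_curve <- function(cfg, t) {
  tp <- cfg$temp
  mid <- if (is.null(tp$deep_warming_mid)) cfg$ice$retreat_day + 50 else
    tp$deep_warming_mid
  tp$winter_deep + (tp$max_deep - tp$winter_deep) *
    stats::plogis((t - mid) / tp$deep_warming_width)
}

.shallow_sal_curve <- function(cfg, t) {
  sl <- cfg$sal
  day <- if (is.null(sl$freshening_day)) cfg$ice$retreat_day else
    sl$freshening_day
  sl$shallow_base - sl$freshening_amp * stats::plogis((t - day) /
                                                        sl$freshening_width)
}

.deep_sal_curve <- function(cfg, t) rep(cfg$sal$deep_base, length(t))

.chl_curve <- function(pulses, baseline, t) {
  v <- rep(baseline, length(t))
  for (i in seq_len(nrow(pulses)))
    v <- v + (pulses$peak[i] - baseline) *
      .gauss(t, pulses$center[i], pulses$width[i])
  v
}

# Largest-remainder allocation of n_bins bins to class shares.
.allocate_bins <- function(shares, n_bins) {
  quota <- shares * n_bins
  base <- floor(quota)
  rem <- n_bins - sum(base)
  if (rem > 0) {
    o <- order(quota - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1L
  }
  base
}

#' Generate one synthetic mooring year
#'
#' Builds the full bundle for one spring-summer transition: hourly raw
#' hydrographic series (shallow/deep temperature and salinity, shallow/mid
#' chlorophyll) with Gaussian sensor noise, a daily ice series, an echo grid
#' forward-modelled from planted per-class linear backscatter through the
#' theoretical signature table with dB-domain noise, and a truth record of
#' every planted quantity (phenology days derived by applying the extraction
#' rules to the noise-free curves, bloom peaks, realized daily composition,
#' window means). Fully deterministic under the config seed.
#'
#' @param config a [synthetic_year_config()].
#' @param signatures signature table used by the forward model; default
#'   [signature_table()] on [default_scatterer_models()].
#' @return A list of class `"synthetic_year"`: `config`, `raw` (named list of
#'   [raw_series()]), `ice` (observation table), `echo` (grid data frame),
#'   `truth`.
#' @export
generate_year <- function(config, signatures = NULL) {
  stopifnot(inherits(config, "synthetic_year_config"))
  if (is.null(signatures)) signatures <- signature_table()
  set.seed(config$seed)
  w <- config$window
  d0 <- w[1] - config$margin; d1 <- w[2] + config$margin
  hyd_rng <- if (is.null(config$hydro_days)) c(d0, d1) else
    c(max(d0, config$hydro_days[1] - config$margin),
      min(d1, config$hydro_days[2] + config$margin))
  tt <- seq(hyd_rng[1], hyd_rng[2] + 23 / 24, by = 1 / 24)
  origin <- as.POSIXct(paste0(config$year, "-01-01 00:00:00"), tz = "UTC")
  times <- origin + (tt - 1) * 86400

  mk <- function(values, sd_noise, variable, depth) {
    raw_series(times, values + rnorm(length(values), 0, sd_noise),
               variable, depth)
  }
  raw <- list(
    shallow_temperature = mk(.shallow_temp_curve(config, tt),
                             config$noise$temp, "temperature", "shallow"),
    deep_temperature = mk(.deep_temp_curve(config, tt),
                          config$noise$temp, "temperature", "deep"),
    shallow_salinity = mk(.shallow_sal_curve(config, tt),
                          config$noise$sal, "salinity", "shallow"),
    deep_salinity = mk(.deep_sal_curve(config, tt),
                       config$noise$sal, "salinity", "deep"),
    shallow_chl = mk(pmax(.chl_curve(config$chl$shallow_pulses,
                                     config$chl$baseline, tt), 0.02),
                     config$noise$chl, "chlorophyll", "shallow"),
    mid_chl = mk(pmax(.chl_curve(config$chl$mid_pulses,
                                 config$chl$baseline, tt), 0.02),
                 config$noise$chl, "chlorophyll", "mid"))
  raw$shallow_chl$value <- pmax(raw$shallow_chl$value, 0.01)
  raw$mid_chl$value <- pmax(raw$mid_chl$value, 0.01)
  if (!is.null(config$chl$gap_days)) {
    gap <- floor(tt) %in% config$chl$gap_days
    raw$shallow_chl$value[gap] <- NA
    raw$mid_chl$value[gap] <- NA
  }

  ice_days <- seq(d0, d1, by = config$ice$obs_interval)
  ice <- data.frame(julian_day = as.integer(ice_days),
                    extent = .ice_extent_curve(config, ice_days),
                    thickness = .ice_thickness_curve(config, ice_days),
                    year = config$year)

  # echo grid: daily class weights -> bin allocation -> forward model
  days <- seq.int(w[1], w[2])
  cls_tab <- config$acoustics$classes
  weights <- vapply(seq_len(nrow(cls_tab)), function(i)
    config$acoustics$floor_weight +
      cls_tab$peak[i] * .gauss(days, cls_tab$center[i], cls_tab$width[i]),
    numeric(length(days)))
  colnames(weights) <- cls_tab$category
  n_bins <- config$acoustics$n_bins
  sig_map <- signatures[match(SCATTERER_CATEGORIES, signatures$category), ]
  u_sig <- config$acoustics$unclass_signature
  # planted Unclass triple must really be unclassifiable
  u_dist <- sqrt((sig_map$d200_125 - u_sig[1])^2 +
                   (sig_map$d460_125 - u_sig[2])^2 +
                   (sig_map$d460_200 - u_sig[3])^2)
  if (any(u_dist <= 12))
    stop("unclass_signature lies within 12 dB of a category signature")

  grid_rows <- vector("list", length(days))
  comp_truth <- matrix(0, length(days), ncol(weights),
                       dimnames = list(NULL, colnames(weights)))
  for (di in seq_along(days)) {
    shares <- weights[di, ] / sum(weights[di, ])
    nb <- .allocate_bins(shares, n_bins)
    comp_truth[di, ] <- 100 * nb / n_bins
    cls_of_bin <- rep(colnames(weights), nb)
    lin_per_bin <- rep(config$acoustics$sv_scale * sum(weights[di, ]) / n_bins,
                      n_bins)
    sv200 <- 10 * log10(lin_per_bin)
    d200_125 <- d460_200 <- numeric(n_bins)
    for (b in seq_len(n_bins)) {
      cc <- cls_of_bin[b]
      if (cc == "Unclass") {
        d200_125[b] <- u_sig[1]; d460_200[b] <- u_sig[3]
      } else {
        j <- match(cc, sig_map$category)
        d200_125[b] <- sig_map$d200_125[j]; d460_200[b] <- sig_map$d460_200[j]
      }
    }
    sv125 <- sv200 - d200_125
    sv460 <- sv200 + d460_200
    nz <- config$acoustics$noise_db
    grid_rows[[di]] <- data.frame(
      julian_day = days[di],
      bin_top_m = 2 + 5 * (seq_len(n_bins) - 1),
      sv125 = sv125 + rnorm(n_bins, 0, nz),
      sv200 = sv200 + rnorm(n_bins, 0, nz),
      sv460 = sv460 + rnorm(n_bins, 0, nz))
  }
  echo <- do.call(rbind, grid_rows)

  # truth record from the noise-free curves
  ice_nf <- condition_ice(ice[c("julian_day", "extent", "thickness")])
  strat_nf <- data.frame(
    julian_day = days,
    delta_sigma = density_anomaly(.deep_temp_curve(config, days),
                                  .deep_sal_curve(config, days), 55) -
      density_anomaly(.shallow_temp_curve(config, days),
                      .shallow_sal_curve(config, days), 11))
  win_days <- days
  truth <- list(
    retreat_day = as.integer(ice_retreat_day(ice_nf, window = w)),
    thin_ice_day = as.integer(thin_ice_day(ice_nf, window = w)),
    stratification_day = as.integer(stratification_onset(strat_nf,
                                                         window = w)),
    shallow_chl_peak = max(.chl_curve(config$chl$shallow_pulses,
                                      config$chl$baseline, win_days)),
    mid_chl_peak = max(.chl_curve(config$chl$mid_pulses,
                                  config$chl$baseline, win_days)),
    mean_ice_extent = mean(.ice_extent_curve(config, win_days)),
    mean_ice_thickness = mean(.ice_thickness_curve(config, win_days)),
    mean_shallow_temp = mean(.shallow_temp_curve(config, win_days)),
    max_shallow_temp = max(.shallow_temp_curve(config, win_days)),
    composition = cbind(data.frame(julian_day = days),
                        as.data.frame(comp_truth)),
    class_weights = weights)
  structure(list(config = config, raw = raw, ice = ice, echo = echo,
                 truth = truth),
            class = "synthetic_year")
}

#' Generate a cohort of synthetic years under a climate scenario
#'
#' The `cold` scenario mimics a heavy-ice year (retreat shifted +45 days,
#' doubled ice thickness, shallow-temperature mean lowered by about 0.7 deg C
#' via a matching delay of the warming); `warm` uses the defaults. Year-to-year
#' variation comes from small seeded jitters of the retreat day and
#' temperature.
#'
#' @param n_years number of years.
#' @param scenario `"cold"` or `"warm"`.
#' @param seed base RNG seed; year i uses `seed + i`.
#' @param signatures signature table for the forward model (computed once).
#' @return List of `synthetic_year` bundles.
#' @export
generate_cohort <- function(n_years, scenario = c("warm", "cold"), seed = 1,
                            signatures = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(signatures)) signatures <- signature_table()
  set.seed(seed)
  jit_retreat <- round(rnorm(n_years, 0, 3))
  jit_temp <- rnorm(n_years, 0, 0.3)
  lapply(seq_len(n_years), function(i) {
    shift <- if (scenario == "cold") 45 else 0
    retreat <- 139 + shift + jit_retreat[i]
    cfg <- synthetic_year_config(
      year = 2000 + i, seed = seed + i,
      ice = list(retreat_day = retreat,
                 thin_ice_day = retreat - 21,
                 base_extent = if (scenario == "cold") 50 else 30,
                 base_thickness = if (scenario == "cold") 16 else 8,
                 max_thickness = if (scenario == "cold") 120 else 60),
      temp = list(max_shallow = (if (scenario == "cold") 8.5 else 10) +
                    jit_temp[i],
                  warming_mid = retreat + (if (scenario == "cold") 32 else 25)))
    generate_year(cfg, signatures)
  })
}
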