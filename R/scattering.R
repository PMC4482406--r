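#' Define a scatterer category model
#'
#' Parameters for the fluid-like weakly-scattering body model (distorted-wave
#' Born approximation over a uniformly bent cylinder) used to generate
#' theoretical multifrequency scattering signatures. The crustacean size
#' classes are SmCrust (copepods, 1-5 mm), MdCrust (juvenile krill,
#' chaetognaths, amphipods, 5-15 mm) and LgCrust (adult euphausiids,
#' 15-30 mm); WkReson and StReson are gas-bearing resonant scatterers defined
#' by their 200-kHz elevation rather than by body physics.
#'
#' @param category one of `"SmCrust"`, `"MdCrust"`, `"LgCrust"`, `"WkReson"`,
#'   `"StReson"`.
#' @param length_range_mm body length range (mm), ordered.
#' @param g,h density and sound-speed contrasts of body tissue relative to
#'   seawater (near 1 for fluid-like bodies).
#' @param length_radius_ratio body length divided by cylinder radius.
#' @param bend_ratio radius of curvature divided by body length (`Inf` for a
#'   straight cylinder).
#' @param tilt_mean,tilt_sd mean and SD (degrees) of the normal orientation
#'   distribution, 0 = broadside incidence.
#' @param phase_sd per-segment phase-jitter SD (radians) for stochastic mode.
#' @param elevation_200_db for resonant categories, the S_v elevation at
#'   200 kHz (dB) relative to the flat 125/460 baseline.
#' @return A list of class `"scatterer_model"`.
#' @export
scatterer_model <- function(category,
                            length_range_mm = NULL,
                            g = 1.016, h = 1.020,
                            length_radius_ratio = 16,
                            bend_ratio = 3,
                            tilt_mean = 0, tilt_sd = 30,
                            phase_sd = sqrt(2) / 2,
                            elevation_200_db = NA_real_) {
  if (!category %in% c(SCATTERER_CATEGORIES))
    stop("unknown category: ", category)
  if (!is.null(length_range_mm)) {
    if (length(length_range_mm) != 2 || any(length_range_mm <= 0) ||
        diff(length_range_mm) < 0)
      stop("length_range_mm must be a positive ordered pair")
  }
  if (g < 0.95 || g > 1.10 || h < 0.95 || h > 1.10)
    stop("g and h must stay within [0.95, 1.10] (weak-scattering regime)")
  structure(list(category = category, length_range_mm = length_range_mm,
                 g = g, h = h, length_radius_ratio = length_radius_ratio,
                 bend_ratio = bend_ratio, tilt_mean = tilt_mean,
                 tilt_sd = tilt_sd, phase_sd = phase_sd,
                 elevation_200_db = elevation_200_db),
            class = "scatterer_model")
}

#' Default models for the five scatterer categories
#'
#' @param g,h,length_radius_ratio,bend_ratio,tilt_sd,phase_sd shared shape and
#'   material parameters for the crustacean classes (see [scatterer_model()]).
#' @param weak_elevation_db,strong_elevation_db representative 200-kHz
#'   elevations for the resonant classes, chosen inside the defining bands
#'   (weak: < 3 dB; strong: > 20 dB).
#' @return Named list of five `scatterer_model` objects in tie-break order.
#' @export
default_scatterer_models <- function(g = 1.016, h = 1.020,
                                     length_radius_ratio = 16, bend_ratio = 3,
                                     tilt_sd = 30, phase_sd = sqrt(2) / 2,
                                     weak_elevation_db = 2,
                                     strong_elevation_db = 25) {
  crust <- function(cat, range) {
    scatterer_model(cat, range, g = g, h = h,
                    length_radius_ratio = length_radius_ratio,
                    bend_ratio = bend_ratio, tilt_sd = tilt_sd,
                    phase_sd = phase_sd)
  }
  list(SmCrust = crust("SmCrust", c(1, 5)),
       MdCrust = crust("MdCrust", c(5, 15)),
       LgCrust = crust("LgCrust", c(15, 30)),
       WkReson = scatterer_model("WkReson",
                                 elevation_200_db = weak_elevation_db),
       StReson = scatterer_model("StReson",
                                 elevation_200_db = strong_elevation_db))
}

# Complex DWBA scattering amplitude (m) for a uniformly bent fluid cylinder,
# discretized into n_segments along the body axis. phase_jitter, when given,
# is one extra phase (rad) per segment (stochastic mode).
.dwba_amplitude <- function(length_m, radius_m, g, h, bend_ratio,
                            k1, tilt_deg, n_segments, phase_jitter = NULL) {
  gamma_kappa <- (1 - g * h^2) / (g * h^2)
  gamma_rho <- (g - 1) / g
  contrast <- gamma_kappa - gamma_rho
  if (contrast == 0) return(0 + 0i)
  k2 <- k1 / h
  th <- tilt_deg * pi / 180
  khat <- c(sin(th), cos(th))           # incidence, broadside = +z
  if (is.finite(bend_ratio)) {
    rho_c <- bend_ratio * length_m
    a0 <- length_m / (2 * rho_c)
    ds <- length_m / n_segments
    alpha <- seq(-a0 + a0 / n_segments, a0 - a0 / n_segments,
                 length.out = n_segments)
    pos_x <- rho_c * sin(alpha); pos_z <- rho_c * cos(alpha)
    tan_x <- cos(alpha); tan_z <- -sin(alpha)
  } else {
    ds <- length_m / n_segments
    s <- seq(-length_m / 2 + ds / 2, length_m / 2 - ds / 2,
             length.out = n_segments)
    pos_x <- s; pos_z <- rep(0, n_segments)
    tan_x <- rep(1, n_segments); tan_z <- rep(0, n_segments)
  }
  dot_kt <- khat[1] * tan_x + khat[2] * tan_z
  cos_beta <- pmax(sqrt(pmax(1 - dot_kt^2, 0)), 1e-10)
  bess <- besselJ(2 * k2 * radius_m * cos_beta, 1)
  phase <- 2 * k1 * (khat[1] * pos_x + khat[2] * pos_z)
  if (!is.null(phase_jitter)) phase <- phase + phase_jitter
  (k1 / 4) * contrast *
    sum(radius_m * bess / cos_beta * exp(1i * phase)) * ds
}

#' Target strength of a fluid-like scatterer (DWBA / SDWBA)
#'
#' Backscattering cross-section from the distorted-wave Born approximation
#' line integral along a uniformly bent fluid cylinder, discretized into
#' `n_segments` segments: each segment contributes its material-contrast term
#' weighted by a Bessel directivity factor and the two-way propagation phase.
#' In stochastic mode, independent zero-mean Gaussian phase jitter (SD
#' `phase_sd`) is added per segment and the cross-section is averaged over
#' `n_draws` Monte-Carlo draws and over the model's tilt distribution.
#'
#' @param model a [scatterer_model()] (crustacean category).
#' @param frequency_khz acoustic frequency, kHz.
#' @param length_mm body length, mm.
#' @param tilt_deg incidence tilt (degrees from broadside); default the
#'   model's mean tilt. Ignored in stochastic mode, which draws tilts.
#' @param stochastic use Monte-Carlo phase jitter + tilt averaging?
#' @param n_segments number of discretization segments (>= 100).
#' @param n_draws Monte-Carlo draws in stochastic mode.
#' @param seed RNG seed for stochastic mode.
#' @param sound_speed ambient sound speed, m s^-1.
#' @return Target strength, dB re 1 m^2. `-Inf` (the "no scattering"
#'   sentinel) when `g = h = 1`, since the Born amplitude is identically zero.
#' @export
dwba_backscatter <- function(model, frequency_khz, length_mm,
                             tilt_deg = model$tilt_mean, stochastic = FALSE,
                             n_segments = 200, n_draws = 100, seed = NULL,
                             sound_speed = 1456) {
  stopifnot(inherits(model, "scatterer_model"))
  if (n_segments < 100) stop("n_segments must be at least 100")
  L <- length_mm / 1000
  a <- L / model$length_radius_ratio
  k1 <- 2 * pi * frequency_khz * 1000 / sound_speed
  if (model$g == 1 && model$h == 1) return(-Inf)
  if (!stochastic) {
    f <- .dwba_amplitude(L, a, model$g, model$h, model$bend_ratio, k1,
                         tilt_deg, n_segments)
    return(10 * log10(Mod(f)^2))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                       .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  sig <- vapply(seq_len(n_draws), function(i) {
    th <- rnorm(1, model$tilt_mean, model$tilt_sd)
    jit <- rnorm(n_segments, 0, model$phase_sd)
    Mod(.dwba_amplitude(L, a, model$g, model$h, model$bend_ratio, k1,
                        th, n_segments, jit))^2
  }, numeric(1))
  10 * log10(mean(sig))
}

#' Expected three-frequency scattering spectrum for a crustacean category
#'
#' Backscattering cross-section averaged (in the linear domain) over a uniform
#' grid of body lengths spanning the category's size band and over the
#' category's tilt distribution (normal-weighted quadrature), reported as
#' target strength at the three mooring frequencies. Resonant categories are
#' signature-defined and must use [resonant_spectrum()].
#'
#' @param model a crustacean [scatterer_model()].
#' @param frequencies_khz acoustic frequencies, default `c(125, 200, 460)`.
#' @param n_lengths points of the uniform length grid.
#' @param tilt_step tilt quadrature step, degrees.
#' @param n_segments DWBA discretization segments.
#' @param sound_speed ambient sound speed, m s^-1.
#' @return A list of class `"scattering_spectrum"`: `frequencies_khz`,
#'   `ts_db`, `category`.
#' @export
class_spectrum <- function(model, frequencies_khz = c(125, 200, 460),
                           n_lengths = 15, tilt_step = 5, n_segments = 200,
                           sound_speed = 1456) {
  stopifnot(inherits(model, "scatterer_model"))
  if (model$category %in% c("WkReson", "StReson"))
    stop("resonant categories are signature-defined; use resonant_spectrum()")
  lens <- seq(model$length_range_mm[1], model$length_range_mm[2],
              length.out = n_lengths)
  tilts <- seq(-90, 90, by = tilt_step)
  wts <- dnorm(tilts, model$tilt_mean, model$tilt_sd)
  wts <- wts / sum(wts)
  ts <- vapply(frequencies_khz, function(f) {
    k1 <- 2 * pi * f * 1000 / sound_speed
    sig <- 0
    for (L_mm in lens) {
      L <- L_mm / 1000
      a <- L / model$length_radius_ratio
      s_tilt <- vapply(tilts, function(th)
        Mod(.dwba_amplitude(L, a, model$g, model$h, model$bend_ratio,
                            k1, th, n_segments))^2, numeric(1))
      sig <- sig + sum(wts * s_tilt) / length(lens)
    }
    10 * log10(sig)
  }, numeric(1))
  structure(list(frequencies_khz = frequencies_khz, ts_db = ts,
                 category = model$category),
            class = "scattering_spectrum")
}

#' Spectrum of a resonant scatterer category
#'
#' Resonant (gas-bearing) scatterers are defined by their backscatter
#' elevation at 200 kHz relative to a flat 125/460-kHz baseline: weak
#' resonators show a < 3 dB increase, strong resonators a > 20 dB increase.
#' Representative elevations (+2 and +25 dB) inside those bands define the
#' class spectra; the baseline level is arbitrary because classification uses
#' dB differences only.
#'
#' @param kind `"weak"` or `"strong"`.
#' @param baseline_db baseline target strength at 125 and 460 kHz (dB).
#' @param weak_elevation_db,strong_elevation_db 200-kHz elevations (dB).
#' @param frequencies_khz acoustic frequencies, default `c(125, 200, 460)`.
#' @return A `"scattering_spectrum"` list.
#' @export
resonant_spectrum <- function(kind = c("weak", "strong"), baseline_db = -75,
                              weak_elevation_db = 2, strong_elevation_db = 25,
                              frequencies_khz = c(125, 200, 460)) {
  kind <- match.arg(kind)
  elev <- if (kind == "weak") weak_elevation_db else strong_elevation_db
  ts <- rep(baseline_db, length(frequencies_khz))
  ts[frequencies_khz == 200] <- baseline_db + elev
  structure(list(frequencies_khz = frequencies_khz, ts_db = ts,
                 category = if (kind == "weak") "WkReson" else "StReson"),
            class = "scattering_spectrum")
}

#' dB-difference signature of a scattering spectrum
#'
#' The coordinate triple (S_v(200) - S_v(125), S_v(460) - S_v(125),
#' S_v(460) - S_v(200)); by construction the second equals the sum of the
#' other two, and any constant additive offset across frequencies (numerical
#' density) cancels.
#'
#' @param spectrum a `"scattering_spectrum"`.
#' @return Named numeric vector `d200_125`, `d460_125`, `d460_200`.
#' @export
spectrum_signature <- function(spectrum) {
  f <- spectrum$frequencies_khz
  ts <- spectrum$ts_db
  c(d200_125 = ts[f == 200] - ts[f == 125],
    d460_125 = ts[f == 460] - ts[f == 125],
    d460_200 = ts[f == 460] - ts[f == 200])
}

#' Theoretical dB-difference signature table for all five categories
#'
#' Computes each crustacean category's spectrum with [class_spectrum()] and
#' each resonant category's with [resonant_spectrum()], and collects the
#' dB-difference triples (plus the per-frequency levels used by the forward
#' model) into one table. Fully deterministic for fixed inputs.
#'
#' @param models list of five [scatterer_model()]s, as from
#'   [default_scatterer_models()].
#' @param ... passed to [class_spectrum()].
#' @return A `data.frame` with columns `category`, `d200_125`, `d460_125`,
#'   `d460_200`, `ts125`, `ts200`, `ts460`, one row per category in tie-break
#'   order.
#' @export
signature_table <- function(models = default_scatterer_models(), ...) {
  stopifnot(all(SCATTERER_CATEGORIES %in% names(models)))
  rows <- lapply(SCATTERER_CATEGORIES, function(cat) {
    m <- models[[cat]]
    sp <- if (cat %in% c("WkReson", "StReson"))
      resonant_spectrum(if (cat == "WkReson") "weak" else "strong",
                        weak_elevation_db = if (!is.na(m$elevation_200_db) &&
                                                cat == "WkReson")
                          m$elevation_200_db else 2,
                        strong_elevation_db = if (!is.na(m$elevation_200_db) &&
                                                  cat == "StReson")
                          m$elevation_200_db else 25)
    else class_spectrum(m, ...)
    sig <- spectrum_signature(sp)
    data.frame(category = cat, d200_125 = sig[["d200_125"]],
               d460_125 = sig[["d460_125"]], d460_200 = sig[["d460_200"]],
               ts125 = sp$ts_db[1], ts200 = sp$ts_db[2], ts460 = sp$ts_db[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a signature table
#'
#' Persists the signature table as CSV so classification runs can pin a
#' versioned signature set.
#'
#' @param sig a [signature_table()] result.
#' @param path CSV path.
#' @return `read_signatures` returns the signature `data.frame`.
#' @export
write_signatures <- function(sig, path) {
  write.csv(sig, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  sig <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("category", "d200_125", "d460_125", "d460_200")
  if (!all(need %in% names(sig)))
    stop("signature file lacks column(s): ",
         paste(setdiff(need, names(sig)), collapse = ", "))
  sig
}
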