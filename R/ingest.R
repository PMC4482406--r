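#' Construct a raw mooring series
#'
#' A raw series is the direct product of one mooring sensor: a strictly
#' increasing timestamp vector (at least hourly in deployed practice) with one
#' physical value per timestamp, tagged with the variable name and the depth
#' label of the sensor (shallow < 20 m, mid 20-40 m, deep > 40 m).
#'
#' @param time `POSIXct` timestamps, strictly increasing.
#' @param value numeric values in the variable's physical units.
#' @param variable variable name, e.g. `"temperature"`.
#' @param depth one of `"shallow"`, `"mid"`, `"deep"`, or `NA` for variables
#'   without a depth (e.g. ice).
#' @return A `data.frame` of class `"raw_series"` with columns `time`, `value`
#'   and attributes `variable`, `depth`.
#' @export
raw_series <- function(time, value, variable, depth = NA_character_) {
  if (!inherits(time, "POSIXct")) time <- as.POSIXct(time, tz = "UTC")
  if (length(time) != length(value))
    stop("`time` and `value` must have equal length")
  if (any(diff(as.numeric(time)) <= 0))
    stop("timestamps must be strictly increasing")
  if (!is.na(depth) && !depth %in% DEPTH_LABELS)
    stop("`depth` must be one of: ", paste(DEPTH_LABELS, collapse = ", "))
  out <- data.frame(time = time, value = as.numeric(value))
  attr(out, "variable") <- variable
  attr(out, "depth") <- depth
  class(out) <- c("raw_series", "data.frame")
  out
}

#' Read a mooring data table into raw series
#'
#' Reads a delimited text file (or, when `readxl` is installed, an XLS/XLSX
#' workbook) with one timestamp column and one column per measured variable,
#' returning one [raw_series()] per mapped variable column. Rows whose
#' timestamp cannot be parsed are dropped and counted.
#'
#' @param path path to a CSV/TSV file or an Excel workbook with a header row.
#' @param column_map named list: `timestamp` gives the timestamp column name;
#'   every other entry maps an output variable name to either a column name or
#'   a list with elements `column` and optional `depth`.
#' @param tz timezone for parsing timestamps.
#' @return A named list of `raw_series`, with attribute `dropped_rows` giving
#'   the number of rows removed for unparseable timestamps.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(t = c("2012-03-01 00:00", "2012-03-01 01:00"),
#'                      sh_temp = c(-1.5, -1.4)), tf, row.names = FALSE)
#' ser <- read_mooring_table(tf, list(timestamp = "t",
#'   shallow_temperature = list(column = "sh_temp", depth = "shallow")))
#' nrow(ser$shallow_temperature)
#' @export
read_mooring_table <- function(path, column_map, tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading Excel workbooks requires the 'readxl' package")
    tab <- as.data.frame(readxl::read_excel(path))
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    tab <- read.csv(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  if (nrow(tab) == 0) stop("empty table: ", path)
  if (is.null(column_map$timestamp))
    stop("column_map must name a `timestamp` column")
  needed <- vapply(column_map, function(m)
    if (is.list(m)) m$column else m, character(1))
  missing_cols <- setdiff(unname(needed), names(tab))
  if (length(missing_cols))
    stop("mapped column(s) not in table: ", paste(missing_cols, collapse = ", "))

  ts_raw <- tab[[column_map$timestamp]]
  if (inherits(ts_raw, "POSIXct")) {
    ts <- ts_raw
  } else {
    # per-row fallback across formats so one bad row does not void the column
    fmts <- c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
              "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M",
              "%Y-%m-%d", "%m/%d/%Y %H:%M", "%m/%d/%Y")
    x <- as.character(ts_raw)
    ts <- .POSIXct(rep(NA_real_, length(x)), tz = tz)
    for (f in fmts) {
      idx <- which(is.na(ts))
      if (!length(idx)) break
      ts[idx] <- as.POSIXct(strptime(x[idx], format = f, tz = tz))
    }
  }
  keep <- !is.na(ts)
  dropped <- sum(!keep)
  if (!any(keep)) stop("no parseable timestamps in ", path)

  vars <- column_map[setdiff(names(column_map), "timestamp")]
  out <- lapply(names(vars), function(v) {
    m <- vars[[v]]
    col <- if (is.list(m)) m$column else m
    depth <- if (is.list(m) && !is.null(m$depth)) m$depth else NA_character_
    raw_series(ts[keep], as.numeric(tab[[col]][keep]), v, depth)
  })
  names(out) <- names(vars)
  attr(out, "dropped_rows") <- dropped
  out
}

#' Lanczos-squared low-pass filter weights
#'
#' Symmetric cosine-Lanczos (squared Lanczos) taper whose amplitude response
#' has its half-power point (|H|^2 = 1/2) at the requested period. The cutoff
#' frequency of the underlying ideal low-pass kernel is solved numerically so
#' that the truncated, tapered filter hits the half-power condition exactly.
#' Weights sum to one, so the DC gain is exactly 1.
#'
#' @param half_power_hours period (h) of the half-power point; default 35.
#' @param half_width half-width of the window in samples; the full window has
#'   `2 * half_width + 1` points. Default equals `half_power_hours` at hourly
#'   cadence (shortest window supporting the stated half-power point).
#' @param dt_hours sampling interval in hours.
#' @return Numeric weight vector of length `2 * half_width + 1`.
#' @export
lanczos_weights <- function(half_power_hours = 35, half_width = NULL,
                            dt_hours = 1) {
  if (is.null(half_width))
    half_width <- ceiling(half_power_hours / dt_hours)
  k <- seq(-half_width, half_width)
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  make_w <- function(fc) { # fc in cycles per sample
    w <- 2 * fc * sinc(2 * fc * k) * sinc(k / (half_width + 1))^2
    w / sum(w)
  }
  resp <- function(w, f) sum(w * cos(2 * pi * f * k))
  f_half <- dt_hours / half_power_hours   # target frequency, cycles per sample
  fc <- uniroot(function(fc) resp(make_w(fc), f_half)^2 - 0.5,
                lower = 0.2 * f_half, upper = min(0.499, 5 * f_half),
                tol = 1e-12)$root
  make_w(fc)
}

#' Apply the Lanczos-squared low-pass filter to a raw series
#'
#' Filters a regularly sampled series with the [lanczos_weights()] taper.
#' Positions where the window is incomplete (series edges, or windows touching
#' an internal `NA`) are set to `NA` rather than filtered with a shrunken
#' window, avoiding phase and amplitude distortion at the ends.
#'
#' @param series a [raw_series()] sampled at a constant, at most hourly cadence.
#' @param half_power_hours half-power period in hours (default 35).
#' @return The filtered `raw_series` on the original time base.
#' @export
lanczos_lowpass <- function(series, half_power_hours = 35) {
  stopifnot(inherits(series, "raw_series"))
  dt <- diff(as.numeric(series$time)) / 3600
  if (max(abs(dt - dt[1])) > 1e-6)
    stop("series must be regularly sampled")
  dt <- dt[1]
  if (dt > 1 + 1e-9) stop("cadence must be at most hourly")
  w <- lanczos_weights(half_power_hours, dt_hours = dt)
  hw <- (length(w) - 1L) / 2L
  n <- nrow(series)
  if (n < length(w)) stop("series shorter than the filter window")
  # centered convolution; windows touching the edges or an NA yield NA
  out <- as.numeric(stats::filter(series$value, w, method = "convolution",
                                  sides = 2))
  res <- series
  res$value <- out
  attr(res, "filtered") <- sprintf("lanczos2_%gh", half_power_hours)
  res
}

#' Block-average a raw series
#'
#' Averages a regularly sampled series over consecutive fixed-length blocks
#' (default 6 h), ignoring missing values; an all-missing block yields `NA`.
#' Each block is stamped with its start time.
#'
#' @param series a [raw_series()].
#' @param hours block length in hours; must be a multiple of the cadence.
#' @return A `raw_series` with one value per block.
#' @export
block_average <- function(series, hours = 6) {
  stopifnot(inherits(series, "raw_series"))
  t0 <- as.numeric(series$time[1])
  rel <- (as.numeric(series$time) - t0) / 3600
  blk <- floor(rel / hours)
  means <- tapply(series$value, blk, function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  times <- as.POSIXct(t0 + as.numeric(names(means)) * hours * 3600,
                      origin = "1970-01-01", tz = "UTC")
  out <- data.frame(time = times, value = as.numeric(means))
  attr(out, "variable") <- attr(series, "variable")
  attr(out, "depth") <- attr(series, "depth")
  class(out) <- c("raw_series", "data.frame")
  out
}

#' Bin a raw series into daily means
#'
#' Computes per-calendar-day (UTC) means and returns a daily series on the
#' Julian-day grid spanning the observed record. Days with at least one
#' contributing datum are masked `observed`; empty days are `missing`.
#'
#' @param series a [raw_series()] at any sub-daily cadence.
#' @return A `data.frame` of class `"daily_series"` with columns `year`,
#'   `julian_day`, `value`, `mask`.
#' @export
daily_bin <- function(series) {
  stopifnot(inherits(series, "raw_series"))
  day <- as.Date(series$time, tz = "UTC")
  means <- tapply(series$value, day, function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  obs_days <- as.Date(names(means))
  grid <- seq(min(obs_days), max(obs_days), by = "day")
  value <- as.numeric(means[match(as.character(grid), names(means))])
  out <- data.frame(
    year = as.integer(format(grid, "%Y")),
    julian_day = as.integer(format(grid, "%j")),
    value = value,
    mask = ifelse(is.na(value), "missing", "observed"),
    stringsAsFactors = FALSE)
  attr(out, "variable") <- attr(series, "variable")
  attr(out, "depth") <- attr(series, "depth")
  class(out) <- c("daily_series", "data.frame")
  out
}

#' Build a daily series directly from values
#'
#' Convenience constructor for a `daily_series` on an explicit Julian-day grid
#' (used by the synthetic generator and in tests).
#'
#' @param year calendar year (scalar or vector).
#' @param julian_day integer day-of-year vector.
#' @param value numeric values; `NA` marks missing days.
#' @param variable,depth metadata tags.
#' @return A `daily_series` data frame.
#' @export
daily_series <- function(year, julian_day, value, variable = NA_character_,
                         depth = NA_character_) {
  out <- data.frame(
    year = as.integer(rep_len(year, length(julian_day))),
    julian_day = as.integer(julian_day),
    value = as.numeric(value),
    mask = ifelse(is.na(value), "missing", "observed"),
    stringsAsFactors = FALSE)
  attr(out, "variable") <- variable
  attr(out, "depth") <- depth
  class(out) <- c("daily_series", "data.frame")
  out
}

#' Interpolate short gaps in a daily series
#'
#' Fills internal gaps strictly shorter than `max_gap_days` by linear
#' interpolation between the flanking observed values (mask `linear_interp`);
#' longer gaps are left missing. A terminal (trailing) gap is only filled when
#' `extrapolate_tail = TRUE`, in which case a linear trend fitted to the last
#' `trend_days` observed values is extended (mask `extrapolated`) — the
#' treatment applied to the month-long August 2009 chlorophyll gap.
#'
#' @param series a `daily_series`.
#' @param max_gap_days gaps of this length or longer stay missing (default 14,
#'   i.e. "< 2 weeks" are filled).
#' @param extrapolate_tail fill a trailing gap by linear trend? Default `FALSE`.
#' @param trend_days number of final observed days used for the tail trend.
#' @return The `daily_series` with gaps filled and masks updated.
#' @export
fill_gaps <- function(series, max_gap_days = 14, extrapolate_tail = FALSE,
                      trend_days = 14) {
  stopifnot(inherits(series, "daily_series"))
  v <- series$value
  obs <- which(!is.na(v))
  if (length(obs) >= 2) {
    r <- rle(is.na(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) next
      s <- starts[j]; e <- ends[j]
      if (s == 1L || e == length(v)) next            # leading/trailing gap
      if (r$lengths[j] >= max_gap_days) next
      x0 <- s - 1L; x1 <- e + 1L
      f <- (seq.int(s, e) - x0) / (x1 - x0)
      v[s:e] <- v[x0] + f * (v[x1] - v[x0])
      series$mask[s:e] <- "linear_interp"
    }
  }
  if (extrapolate_tail && length(obs) >= 2 && max(obs) < length(v)) {
    last <- max(obs)
    idx <- obs[obs > last - trend_days]
    if (length(idx) >= 2) {
      fit <- stats::lm.fit(cbind(1, idx), v[idx])
      tail_idx <- seq.int(last + 1L, length(v))
      v[tail_idx] <- fit$coefficients[1] + fit$coefficients[2] * tail_idx
      series$mask[tail_idx] <- "extrapolated"
    }
  }
  series$value <- v
  series
}

#' Condition an ice series onto a daily grid
#'
#' Ice charts report extent (% area) and thickness (cm) only every 2-3 days.
#' This places the observations on a complete daily grid between the first and
#' last observation; gaps of at most `zero_gap_days` days flanked by zero-ice
#' observations on both sides are set to zero (ice-free conditions), all other
#' gaps are filled by nearest-neighbor interpolation with ties resolved toward
#' the earlier observation.
#'
#' @param ice a `data.frame` with columns `julian_day`, `extent`, `thickness`
#'   (and optionally `year`).
#' @param zero_gap_days longest gap set to zero under ice-free context.
#' @return A `data.frame` of class `"ice_series"` with columns `julian_day`,
#'   `extent`, `thickness`, `mask`, on a complete daily grid.
#' @export
condition_ice <- function(ice, zero_gap_days = 2) {
  stopifnot(all(c("julian_day", "extent", "thickness") %in% names(ice)))
  if (any(ice$extent < 0 | ice$extent > 100, na.rm = TRUE))
    stop("ice extent must lie in [0, 100]")
  if (any(ice$thickness < 0, na.rm = TRUE))
    stop("ice thickness must be non-negative")
  ice <- ice[order(ice$julian_day), ]
  grid <- seq.int(min(ice$julian_day), max(ice$julian_day))
  idx <- match(grid, ice$julian_day)
  out <- data.frame(julian_day = grid,
                    extent = ice$extent[idx],
                    thickness = ice$thickness[idx],
                    mask = ifelse(is.na(idx), "missing", "observed"),
                    stringsAsFactors = FALSE)

  fill_col <- function(v) {
    how <- rep(NA_character_, length(v))
    obs <- which(!is.na(v))
    r <- rle(is.na(v))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      if (!r$values[j]) next
      s <- starts[j]; e <- ends[j]
      left <- if (s > 1L) v[s - 1L] else NA
      right <- if (e < length(v)) v[e + 1L] else NA
      if (!is.na(left) && !is.na(right) && left == 0 && right == 0 &&
          r$lengths[j] <= zero_gap_days) {
        v[s:e] <- 0
        how[s:e] <- "zero_filled"
      } else {
        for (i in seq.int(s, e)) {
          nn <- obs[which.min(abs(obs - i))] # first match: earlier on tie
          v[i] <- v[nn]
          how[i] <- "linear_interp"          # nearest-neighbor fill
        }
      }
    }
    list(v = v, how = how)
  }
  fe <- fill_col(out$extent)
  ft <- fill_col(out$thickness)
  out$extent <- fe$v
  out$thickness <- ft$v
  filled <- out$mask == "missing"
  out$mask[filled] <- ifelse(
    !is.na(fe$how[filled]) & fe$how[filled] == "zero_filled" &
      !is.na(ft$how[filled]) & ft$how[filled] == "zero_filled",
    "zero_filled", "linear_interp")
  # physical consistency: no thickness without ice
  out$thickness[out$extent == 0] <- 0
  if (!is.null(ice$year)) out$year <- ice$year[1]
  class(out) <- c("ice_series", "data.frame")
  out
}
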