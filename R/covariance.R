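#' Normalized lagged cross-covariance of two daily series
#'
#' Mean-removed cross-covariance with coefficient scaling: every lag is
#' normalized by the fixed lag-0 denominator `sqrt(sum(x'^2) * sum(y'^2))`, so
#' a series against itself gives exactly 1 at lag 0, all values lie in
#' [-1, 1], and large-lag values taper naturally with the shrinking overlap
#' (the zero-padded behavior of the standard signal-processing routine).
#' The lag convention is `cov(m) ~ corr(x_t, y_(t+m))`: a positive reported
#' lag means the first series leads the second. Missing days are excluded
#' pairwise from the numerator sum. The reported `(cov, lag)` maximizes
#' |cov(m)| over |m| < `max_lag`; ties resolve toward the smaller |lag|, then
#' toward the positive lag.
#'
#' @param x,y numeric vectors on a common daily grid (e.g. the March-August
#'   window of one year), `NA` allowed; or `daily_series` objects, which are
#'   aligned on their common days.
#' @param max_lag exclusive lag bound in days; lags `-(max_lag-1)` to
#'   `max_lag-1` are searched. Default 150 ("< 150 d").
#' @param min_overlap smallest number of complete pairs for which a lag is
#'   evaluated.
#' @return A list of class `"covariance_pair"`: `cov`, `lag`, and `trace`
#'   (data frame `lag`, `cov`).
#' @export
xcov_normalized <- function(x, y, max_lag = 150, min_overlap = 10) {
  if (inherits(x, "daily_series")) x <- x$value
  if (inherits(y, "daily_series")) y <- y$value
  if (length(x) != length(y))
    stop("series must share one daily grid (equal length)")
  if (sd(x, na.rm = TRUE) == 0 || sd(y, na.rm = TRUE) == 0 ||
      all(is.na(x)) || all(is.na(y)))
    stop("zero-variance or empty series")
  xc <- x - mean(x, na.rm = TRUE)
  yc <- y - mean(y, na.rm = TRUE)
  n <- length(xc)
  den <- sqrt(sum(xc^2, na.rm = TRUE) * sum(yc^2, na.rm = TRUE))
  lags <- seq.int(-(max_lag - 1L), max_lag - 1L)
  lags <- lags[abs(lags) < n]
  cv <- vapply(lags, function(m) {
    if (m >= 0) { xi <- seq_len(n - m); yi <- xi + m }
    else { yi <- seq_len(n + m); xi <- yi - m }
    ok <- !is.na(xc[xi]) & !is.na(yc[yi])
    if (sum(ok) < min_overlap) return(NA_real_)
    sum(xc[xi][ok] * yc[yi][ok]) / den
  }, numeric(1))
  ok <- which(!is.na(cv))
  if (!length(ok)) stop("no lag had sufficient overlap")
  # max |cov|; ties -> smaller |lag|, then positive lag
  o <- ok[order(-abs(cv[ok]), abs(lags[ok]), -sign(lags[ok]))]
  best <- o[1]
  structure(list(cov = cv[best], lag = as.integer(lags[best]),
                 trace = data.frame(lag = lags, cov = cv)),
            class = "covariance_pair")
}

#' All pairwise cross-covariances for one year
#'
#' Computes [xcov_normalized()] for every (initial variable, comparison
#' variable) pair. Initial variables form the rows of the summary; the
#' comparison pool for each initial variable is every other variable,
#' including comparison-only variables (ice extent/thickness) that are never
#' initial themselves.
#'
#' @param data a `data.frame` of aligned daily values, one column per
#'   variable (March-August window, already processed/mean-removable).
#' @param initial_vars character vector of initial-variable column names.
#' @param comparison_vars comparison pool; default all columns.
#' @param max_lag lag bound, days.
#' @return A `data.frame` with columns `var1`, `var2`, `cov`, `lag`.
#' @export
xcov_matrix <- function(data, initial_vars,
                        comparison_vars = names(data), max_lag = 150) {
  stopifnot(all(initial_vars %in% names(data)),
            all(comparison_vars %in% names(data)))
  rows <- list()
  for (v1 in initial_vars) for (v2 in setdiff(comparison_vars, v1)) {
    cp <- tryCatch(xcov_normalized(data[[v1]], data[[v2]], max_lag),
                   error = function(e) NULL)
    if (is.null(cp)) next
    rows[[length(rows) + 1L]] <- data.frame(var1 = v1, var2 = v2,
                                            cov = cp$cov, lag = cp$lag)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top covariates for each initial variable
#'
#' For each initial variable, the `k` comparison pairs with the largest
#' absolute covariance. Ties resolve toward the smaller |lag|, then the
#' alphabetically earlier comparison variable.
#'
#' @param pairs a [xcov_matrix()] result (columns `var1`, `var2`, `cov`,
#'   `lag`).
#' @param k pairs retained per initial variable, default 2.
#' @return The subset of `pairs`, ordered by `var1` then rank, with a `rank`
#'   column.
#' @export
top_covariates <- function(pairs, k = 2) {
  out <- lapply(split(pairs, pairs$var1), function(p) {
    p <- p[order(-abs(p$cov), abs(p$lag), p$var2), ]
    p <- head(p, k)
    p$rank <- seq_len(nrow(p))
    p
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compare covariance strength between two years
#'
#' Tests whether the mean top-|cov| differs between two years. Each input is
#' the vector of top-k absolute covariances (n = 28 for 14 initial variables
#' and k = 2). Both vectors are screened with Shapiro-Wilk normality at
#' `alpha`; if both pass, a pooled two-sample t-test is used (df = n1+n2-2),
#' otherwise a Mann-Whitney rank-sum test.
#'
#' @param cov_a,cov_b numeric vectors of |cov| values.
#' @param alpha normality screening level, default 0.05.
#' @return A list: `test` ("t-test" or "mann-whitney"), `statistic`, `df`
#'   (`NA` for the rank test), `p_value`, `mean_a`, `mean_b`.
#' @export
compare_years <- function(cov_a, cov_b, alpha = 0.05) {
  cov_a <- abs(cov_a[!is.na(cov_a)])
  cov_b <- abs(cov_b[!is.na(cov_b)])
  norm_a <- shapiro.test(cov_a)$p.value
  norm_b <- shapiro.test(cov_b)$p.value
  if (norm_a > alpha && norm_b > alpha) {
    tt <- t.test(cov_a, cov_b, var.equal = TRUE)
    list(test = "t-test", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         mean_a = mean(cov_a), mean_b = mean(cov_b))
  } else {
    wt <- suppressWarnings(wilcox.test(cov_a, cov_b))
    list(test = "mann-whitney", statistic = unname(wt$statistic),
         df = NA_real_, p_value = wt$p.value,
         mean_a = mean(cov_a), mean_b = mean(cov_b))
  }
}
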