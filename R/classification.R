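#' dB differences between the three mooring frequencies
#'
#' @param sv125,sv200,sv460 mean volume backscattering strength (dB re 1 m^-1)
#'   at 125, 200 and 460 kHz; vectors recycle.
#' @return A matrix with columns `d200_125`, `d460_125`, `d460_200` (one row
#'   per input element).
#' @export
db_differences <- function(sv125, sv200, sv460) {
  cbind(d200_125 = sv200 - sv125,
        d460_125 = sv460 - sv125,
        d460_200 = sv460 - sv200)
}

#' Classify one aggregation by its dB-difference triple
#'
#' Euclidean distance in the three-coordinate dB-difference space between the
#' observed triple and each category signature; the closest category wins
#' unless the closest distance exceeds `unknown_threshold` dB, in which case
#' the aggregation is `"Unclass"`. Exact distance ties resolve toward the
#' smaller size class (the signature table's row order). A non-finite triple
#' yields `NA`.
#'
#' @param triple numeric length-3 vector `(d200_125, d460_125, d460_200)`.
#' @param signatures a [signature_table()] (or [read_signatures()]) table.
#' @param unknown_threshold distance (dB) beyond which the aggregation is
#'   unclassifiable; default 12.
#' @return Category name (character scalar), `"Unclass"`, or `NA`.
#' @export
classify_aggregation <- function(triple, signatures, unknown_threshold = 12) {
  if (any(!is.finite(triple))) return(NA_character_)
  d <- sqrt((signatures$d200_125 - triple[1])^2 +
              (signatures$d460_125 - triple[2])^2 +
              (signatures$d460_200 - triple[3])^2)
  i <- which.min(d) # first minimum = smaller size class on ties
  if (d[i] > unknown_threshold) "Unclass" else signatures$category[i]
}

#' Daily composition and total scattering from a classified echo grid
#'
#' Classifies every day x 5-m-bin cell of the grid by its dB-difference triple
#' and aggregates, per day, each category's share of the column's total linear
#' backscatter (percent) plus the column-integrated total. Averaging and
#' summation are done on linear s_v (m^2 m^-3); decibels are used only for
#' differencing. The 200-kHz channel provides the energy weighting and the
#' total.
#'
#' @param grid `data.frame` with columns `julian_day`, `bin_top_m`, `sv125`,
#'   `sv200`, `sv460` (dB re 1 m^-1; `NA` = missing cell).
#' @param signatures a signature table.
#' @param unknown_threshold passed to [classify_aggregation()].
#' @return A `data.frame` of class `"composition_series"`: `julian_day`, one
#'   percent column per category plus `Unclass`, and `total_sv` (linear,
#'   m^2 m^-3). Days with no finite cells are dropped.
#' @export
composition_series <- function(grid, signatures, unknown_threshold = 12) {
  need <- c("julian_day", "sv125", "sv200", "sv460")
  stopifnot(all(need %in% names(grid)))
  cats <- c(SCATTERER_CATEGORIES, "Unclass")
  triples <- db_differences(grid$sv125, grid$sv200, grid$sv460)
  cls <- vapply(seq_len(nrow(grid)), function(i)
    classify_aggregation(triples[i, ], signatures, unknown_threshold),
    character(1))
  lin <- 10^(grid$sv200 / 10)
  days <- sort(unique(grid$julian_day))
  rows <- lapply(days, function(d) {
    sel <- grid$julian_day == d & !is.na(cls) & is.finite(lin)
    if (!any(sel)) return(NULL)
    tot <- sum(lin[sel])
    shares <- vapply(cats, function(cc)
      100 * sum(lin[sel][cls[sel] == cc]) / tot, numeric(1))
    cbind(data.frame(julian_day = d), as.data.frame(as.list(shares)),
          data.frame(total_sv = tot))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("composition_series", "data.frame")
  out
}
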