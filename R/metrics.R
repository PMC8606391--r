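# Summary analytics over pressure-volume tables and strain tables: volume
# tables across bougie sizes, cross-size strain means, ratio and
# group-difference statistics with explicit rounding conventions, and the
# computational band (pointwise envelope of a pressure-volume curve family)
# with observation coverage.

#' Volume table from a family of inflation results
#'
#' @param results Named list of [inflate()] results, names = bougie sizes
#'   in Fr.
#' @param pressures Pressures (mmHg) to extract; must be present in every
#'   result.
#' @return data.frame `bougie_fr`, `pressure_mmhg`, `volume_ml`.
#' @export
volume_table <- function(results, pressures = NULL) {
  stopifnot(is.list(results), length(results) > 0, !is.null(names(results)))
  if (is.null(pressures)) pressures <- results[[1]]$pressures_mmhg
  rows <- lapply(names(results), function(nm) {
    res <- results[[nm]]
    stopifnot(inherits(res, "inflation_result"))
    i <- match(pressures, res$pressures_mmhg)
    if (anyNA(i)) {
      stop(sprintf("pressure(s) missing from the %s Fr result: %s", nm,
                   paste(pressures[is.na(i)], collapse = ", ")))
    }
    data.frame(
      bougie_fr = as.numeric(nm),
      pressure_mmhg = pressures,
      volume_ml = res$volumes_ml[i]
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$bougie_fr, out$pressure_mmhg), ]
}

#' Cross-size mean of a strain table grouping
#'
#' Arithmetic mean of the per-size strain means for one grouping at one
#' pressure, i.e. the statistic printed in the reference table's Mean rows.
#' Requires the cell for every bougie size present in the table.
#'
#' @param table Strain table as from [read_table2()] (columns `bougie_fr`,
#'   `pressure_mmhg`, `grouping`, `mean_percent`).
#' @param grouping One of whole/antrum/corpus/mucosa/muscularis.
#' @param pressure_mmhg Pressure of the cells to average.
#' @return Mean percent (unrounded).
#' @export
mean_over_sizes <- function(table, grouping, pressure_mmhg) {
  stopifnot(is.data.frame(table))
  if (!grouping %in% table$grouping) stop("unknown grouping: ", grouping)
  sizes <- sort(unique(table$bougie_fr))
  sub <- table[table$grouping == grouping &
                 table$pressure_mmhg == pressure_mmhg, ]
  if (!setequal(sub$bougie_fr, sizes) || nrow(sub) != length(sizes)) {
    stop("incomplete size set for the requested grouping/pressure")
  }
  mean(sub$mean_percent)
}

.round_half_up <- function(x) floor(x + 0.5)

#' Volume ratio between two bougie sizes at one pressure
#'
#' @param table Pressure-volume table (see [validate_pv_table()]).
#' @param pressure_mmhg Pressure of the two cells.
#' @param numerator_fr,denominator_fr Bougie sizes of numerator and
#'   denominator.
#' @param rounding `"none"`, `"integer"` (nearest integer) or `"half"`
#'   (nearest 0.5), matching how such ratios are quoted in prose.
#' @return The (possibly rounded) ratio.
#' @export
size_ratio <- function(table, pressure_mmhg, numerator_fr, denominator_fr,
                       rounding = c("none", "integer", "half")) {
  validate_pv_table(table)
  rounding <- match.arg(rounding)
  cell <- function(fr) {
    v <- table$volume_ml[table$bougie_fr == fr &
                           table$pressure_mmhg == pressure_mmhg]
    if (length(v) != 1) {
      stop(sprintf("missing cell: %g Fr at %g mmHg", fr, pressure_mmhg))
    }
    v
  }
  r <- cell(numerator_fr) / cell(denominator_fr)
  switch(rounding,
    none = r,
    integer = .round_half_up(r),
    half = .round_half_up(r * 2) / 2
  )
}

#' Difference of cross-size mean strains between two groupings
#'
#' `mean_over_sizes(group_a) - mean_over_sizes(group_b)` in percentage
#' points, with the rounding conventions used when such differences are
#' quoted in prose: `"round"` is round-half-up to an integer, `"truncate"`
#' drops the fractional part.
#'
#' @param table Strain table as from [read_table2()].
#' @param pressure_mmhg Pressure at which to compare.
#' @param group_a,group_b Grouping labels.
#' @param rounding `"none"`, `"round"` or `"truncate"`.
#' @return Difference in percentage points.
#' @export
group_difference <- function(table, pressure_mmhg, group_a, group_b,
                             rounding = c("none", "round", "truncate")) {
  rounding <- match.arg(rounding)
  d <- mean_over_sizes(table, group_a, pressure_mmhg) -
    mean_over_sizes(table, group_b, pressure_mmhg)
  switch(rounding,
    none = d,
    round = .round_half_up(d),
    truncate = trunc(d)
  )
}

#' Pointwise envelope of a family of pressure-volume curves
#'
#' @param curves data.frame with columns `curve_id`, `pressure_mmhg`,
#'   `volume_ml`; every curve must share the same pressure grid.
#' @return An object of class `pv_band`: data.frame `pressure_mmhg`,
#'   `volume_min_ml`, `volume_max_ml`.
#' @export
band_envelope <- function(curves) {
  need <- c("curve_id", "pressure_mmhg", "volume_ml")
  stopifnot(is.data.frame(curves), all(need %in% names(curves)))
  ids <- unique(curves$curve_id)
  if (length(ids) < 2) stop("need at least two curves for an envelope")
  grid <- sort(unique(curves$pressure_mmhg))
  for (id in ids) {
    g <- sort(curves$pressure_mmhg[curves$curve_id == id])
    if (!isTRUE(all.equal(g, grid))) {
      stop("curves do not share a common pressure grid")
    }
  }
  agg_min <- stats::aggregate(volume_ml ~ pressure_mmhg, curves, min)
  agg_max <- stats::aggregate(volume_ml ~ pressure_mmhg, curves, max)
  out <- data.frame(
    pressure_mmhg = agg_min$pressure_mmhg,
    volume_min_ml = agg_min$volume_ml,
    volume_max_ml = agg_max$volume_ml
  )
  structure(out[order(out$pressure_mmhg), ], class = c("pv_band", "data.frame"))
}

#' Fraction of observation points inside a pressure-volume band
#'
#' Band edges are interpolated linearly in volume between grid pressures;
#' points on an edge count as inside.
#'
#' @param band A [band_envelope()] band.
#' @param observations data.frame with columns `pressure_mmhg`, `volume_ml`.
#' @return Fraction in `[0, 1]`.
#' @export
band_coverage <- function(band, observations) {
  stopifnot(inherits(band, "pv_band"))
  need <- c("pressure_mmhg", "volume_ml")
  stopifnot(is.data.frame(observations), all(need %in% names(observations)))
  if (nrow(observations) == 0) stop("empty observation set")
  rng <- range(band$pressure_mmhg)
  p <- observations$pressure_mmhg
  if (any(p < rng[1] | p > rng[2])) {
    stop("observation pressures outside the band's pressure range")
  }
  lo <- stats::approx(band$pressure_mmhg, band$volume_min_ml, xout = p)$y
  hi <- stats::approx(band$pressure_mmhg, band$volume_max_ml, xout = p)$y
  mean(observations$volume_ml >= lo & observations$volume_ml <= hi)
}

#' Plot a pressure-volume band with optional observations
#'
#' @param x A `pv_band`.
#' @param observations Optional data.frame of observation points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pv_band <- function(x, observations = NULL, ...) {
  graphics::plot(
    NA, xlim = range(c(x$volume_min_ml, x$volume_max_ml)),
    ylim = range(x$pressure_mmhg),
    xlab = "Volume (ml)", ylab = "Intragastric pressure (mmHg)", ...
  )
  graphics::polygon(
    c(x$volume_min_ml, rev(x$volume_max_ml)),
    c(x$pressure_mmhg, rev(x$pressure_mmhg)),
    col = grDevices::adjustcolor("steelblue", 0.3), border = NA
  )
  graphics::lines(x$volume_min_ml, x$pressure_mmhg, col = "steelblue")
  graphics::lines(x$volume_max_ml, x$pressure_mmhg, col = "steelblue")
  if (!is.null(observations)) {
    graphics::points(observations$volume_ml, observations$pressure_mmhg,
                     pch = 19, cex = 0.6)
  }
  invisible(x)
}
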