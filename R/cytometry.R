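# Per-sample flow-cytometry preprocessing: two-stage FSC/SSC gating,
# saturation correction of the FITC-A channel from its correlated PE-A
# signal, pseudo-log expression summaries, event-rate cell densities and
# Malthusian growth rates.

#' Two-stage scatter gate
#'
#' First keeps events inside the per-axis central `rect_quantile` box in
#' FSC x SSC (e.g. 0.95 trims 2.5\% from each tail of each axis), then keeps
#' the `1 - centroid_exclusion` fraction of those events nearest the densest
#' point of the standardized FSC/SSC plane (the mode of a `grid` x `grid`
#' 2-D histogram).
#'
#' @param events event table with `FSC` and `SSC` columns.
#' @param rect_quantile proportion in `(0, 1]`.
#' @param centroid_exclusion proportion in `[0, 1)` of rectangle-gated
#'   events to exclude as outlying.
#' @param grid side of the 2-D histogram used to locate the density mode.
#' @param min_events below this many retained events the sample is flagged
#'   censored (attribute `censored`), not dropped.
#' @return the gated event table; attributes `n_input`, `n_gated`,
#'   `censored`.
#' @export
gate_events <- function(events, rect_quantile = 0.95, centroid_exclusion = 0.40,
                        grid = 64L, min_events = 100L) {
  if (nrow(events) == 0) stopf("gate_events: empty event table")
  if (rect_quantile <= 0 || rect_quantile > 1) stopf("rect_quantile must be in (0, 1]")
  if (centroid_exclusion < 0 || centroid_exclusion >= 1) {
    stopf("centroid_exclusion must be in [0, 1)")
  }
  n0 <- nrow(events)
  tail <- (1 - rect_quantile) / 2
  fsc <- events$FSC; ssc <- events$SSC
  idx <- seq_len(n0)
  if (rect_quantile < 1) {
    qf <- stats::quantile(fsc, c(tail, 1 - tail), names = FALSE, type = 7)
    qs <- stats::quantile(ssc, c(tail, 1 - tail), names = FALSE, type = 7)
    idx <- which(fsc >= qf[1] & fsc <= qf[2] & ssc >= qs[1] & ssc <= qs[2])
  }
  if (centroid_exclusion > 0 && length(idx) > 1) {
    zf <- standardize(fsc[idx])
    zs <- standardize(ssc[idx])
    ctr <- density_mode_2d(zf, zs, grid)
    d2 <- (zf - ctr[1])^2 + (zs - ctr[2])^2
    n_keep <- ceiling((1 - centroid_exclusion) * length(idx))
    # boundary ties are kept: with all-identical events everything survives
    thr <- sort.int(d2, partial = n_keep)[n_keep]
    idx <- idx[d2 <= thr]                    # preserves acquisition order
  }
  out <- events[idx, , drop = FALSE]
  attr(out, "sampling_rate") <- attr(events, "sampling_rate")
  attr(out, "sample_id") <- attr(events, "sample_id")
  attr(out, "n_input") <- n0
  attr(out, "n_gated") <- nrow(out)
  attr(out, "censored") <- nrow(out) < min_events
  out
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# mode (cell center) of a 2-D histogram over standardized axes
density_mode_2d <- function(x, y, grid) {
  rx <- range(x); ry <- range(y)
  if (rx[1] == rx[2] || ry[1] == ry[2]) return(c(mean(rx), mean(ry)))
  ix <- pmin(grid, pmax(1L, ceiling((x - rx[1]) / (rx[2] - rx[1]) * grid)))
  iy <- pmin(grid, pmax(1L, ceiling((y - ry[1]) / (ry[2] - ry[1]) * grid)))
  counts <- tabulate(ix + (iy - 1L) * grid, nbins = grid * grid)
  m <- which.max(counts) - 1L
  mx <- (m %% grid) + 1L
  my <- (m %/% grid) + 1L
  c(rx[1] + (mx - 0.5) / grid * (rx[2] - rx[1]),
    ry[1] + (my - 0.5) / grid * (ry[2] - ry[1]))
}

#' Replace saturated FITC-A readings by their PE-A prediction
#'
#' Fits ordinary least squares of `log(FITC)` on `log(PE)` over
#' non-saturated events with positive signal in both channels, then replaces
#' the FITC-A value of events at or above the ceiling with the fit's
#' prediction from their PE-A.  All other events are untouched.
#'
#' @param events event table with `FITC` and `PE` columns.
#' @param ceiling machine maximum (A.U.); readings `>= ceiling` are treated
#'   as saturated.
#' @param min_fit_events minimum usable events for the regression.
#' @return the corrected event table; attributes `n_saturated` and
#'   `saturation_flagged` (TRUE when a needed fit was impossible or
#'   degenerate and saturated values were left at the ceiling).
#' @export
correct_saturation <- function(events, ceiling = 2^18 - 1, min_fit_events = 30L) {
  sat <- events$FITC >= ceiling
  attr(events, "n_saturated") <- sum(sat)
  attr(events, "saturation_flagged") <- FALSE
  if (!any(sat)) return(events)
  ok <- !sat & events$FITC > 0 & events$PE > 0
  if (sum(ok) < min_fit_events) {
    stopf("correct_saturation: only %d usable non-saturated events (need %d)",
          sum(ok), min_fit_events)
  }
  lx <- log(events$PE[ok])
  ly <- log(events$FITC[ok])
  b <- ols_slope(lx, ly)
  if (!is.finite(b)) {
    attr(events, "saturation_flagged") <- TRUE
    return(events)
  }
  a <- mean(ly) - b * mean(lx)
  pred <- exp(a + b * log(pmax(events$PE[sat], .Machine$double.eps)))
  events$FITC[sat] <- pred
  events
}

#' Equally spaced pseudo-log bin edges
#' @param n number of bins.
#' @param range pseudo-log range covered.
#' @return numeric vector of `n + 1` edges.
#' @export
bin_edges <- function(n = 60L, range = c(-0.5, 3.5)) {
  seq(range[1], range[2], length.out = n + 1L)
}

#' Summarize a gated, saturation-corrected sample
#'
#' Computes the fraction of cells above the ON cutoff, the mean pseudo-log
#' and raw FITC-A signal, a normalized density histogram over the pseudo-log
#' bin grid (events outside the grid are counted in the edge bins so the
#' densities integrate to 1), and the cell density as the OLS slope of
#' cumulative event count against time (events/ms) scaled by the sampling
#' rate.
#'
#' @param events gated event table (with `time_ms` and a `sampling_rate`
#'   attribute, ul/s).
#' @param on_cutoff ON threshold, pseudo-log A.U.
#' @param edges bin edges from [bin_edges()].
#' @param sampling_rate overrides the attribute if given.
#' @return one-row data frame: `n_gated`, `fracON`, `mean_yfp` (pseudo-log),
#'   `mean_raw`, `density` (cells/ul), `censored`, plus the density vector
#'   as an attribute `density_vector`.
#' @export
summarize_sample <- function(events, on_cutoff = 0.25, edges = bin_edges(),
                             sampling_rate = NULL) {
  sampling_rate <- sampling_rate %||% attr(events, "sampling_rate")
  n <- nrow(events)
  nb <- length(edges) - 1L
  if (n == 0) {
    out <- data.frame(n_gated = 0L, fracON = NA_real_, mean_yfp = NA_real_,
                      mean_raw = NA_real_, density = NA_real_, censored = TRUE)
    attr(out, "density_vector") <- rep(NA_real_, nb)
    return(out)
  }
  pl <- pseudolog(events$FITC)
  idx <- findInterval(pl, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nb)          # clamp out-of-range into edge bins
  binwidth <- (edges[length(edges)] - edges[1]) / nb
  dens <- tabulate(idx, nbins = nb) / (n * binwidth)
  # events/ms as the slope of cumulative count ~ time, then cells/ul
  slope <- ols_slope(events$time_ms, seq_len(n))
  density <- if (is.null(sampling_rate) || !is.finite(slope)) NA_real_ else {
    (1000 * slope) / sampling_rate
  }
  out <- data.frame(n_gated = n,
                    fracON = mean(pl > on_cutoff),
                    mean_yfp = mean(pl),
                    mean_raw = mean(events$FITC),
                    density = density,
                    censored = isTRUE(attr(events, "censored")))
  attr(out, "density_vector") <- dens
  out
}

#' ON cutoff from autofluorescent controls
#'
#' The empirical ON threshold is a high quantile (default 99.9\%) of the
#' pooled autofluorescent-control signal on the pseudo-log scale.
#'
#' @param control_events list of event tables (or one table) from reporter-free
#'   controls.
#' @param quantile quantile of the pooled distribution.
#' @return pseudo-log cutoff.
#' @export
on_cutoff_from_controls <- function(control_events, quantile = 0.999) {
  if (is.data.frame(control_events)) control_events <- list(control_events)
  pooled <- unlist(lapply(control_events, function(e) pseudolog(e$FITC)))
  stats::quantile(pooled, quantile, names = FALSE)
}

#' Malthusian growth rate from paired culture densities
#'
#' The galactose culture was inoculated from the glucose culture at a
#' dilution of 9/150, so the inoculum density is the measured glucose
#' density times the dilution factor, and
#' `mu = ln(density_gal / inoculum) / hours`;
#' `generations = log2(density_gal / inoculum)`.
#'
#' @param density_glu measured glucose culture density (cells/ul).
#' @param density_gal measured galactose culture density after growth.
#' @param dilution glucose -> galactose inoculum dilution factor.
#' @param hours growth duration.
#' @return data frame `mu` (per hour), `generations`, `flagged`.
#' @export
growth_rate <- function(density_glu, density_gal, dilution = 9 / 150, hours = 12) {
  bad <- !is.finite(density_glu) | !is.finite(density_gal) |
         density_glu <= 0 | density_gal <= 0
  ratio <- ifelse(bad, NA_real_, density_gal / (density_glu * dilution))
  mu <- log(ratio) / hours
  gen <- log2(ratio)
  data.frame(mu = mu, generations = gen, flagged = bad)
}

#' Gate, correct and summarize one event table
#'
#' Convenience wrapper chaining [gate_events()], [correct_saturation()] and
#' [summarize_sample()] under one configuration.
#'
#' @param events raw event table.
#' @param on_cutoff pseudo-log ON threshold.
#' @param config a [galcomb_config()] list.
#' @return as [summarize_sample()].
#' @export
process_sample <- function(events, on_cutoff, config = galcomb_config()) {
  g <- config$gating
  ev <- gate_events(events, g$rect_quantile, g$centroid_exclusion,
                    g$grid, g$min_events)
  ev <- correct_saturation(ev, config$events$saturation_ceiling)
  edges <- bin_edges(config$bins$n, config$bins$range)
  summarize_sample(ev, on_cutoff = on_cutoff, edges = edges)
}
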