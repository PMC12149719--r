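#' Dose threshold specification for the PBS dose-rate metric
#'
#' The PBS dose rate at a point measures the dose-rate over the time
#' window during which the point's cumulative dose rises from a small
#' threshold \eqn{\hat d} to the total dose minus \eqn{\hat d}. The
#' threshold can be given in percent of the local total dose at the
#' evaluated point (the default, 1%), or as an absolute dose in Gy.
#'
#' @param percent Threshold as percent of the local total dose.
#' @param gy Absolute threshold in Gy (overrides `percent` if given).
#' @return An object of class `dose_threshold`.
#' @export
dose_threshold <- function(percent = 1, gy = NULL) {
  if (!is.null(gy)) {
    if (gy < 0) stop("threshold must be >= 0", call. = FALSE)
    return(structure(list(mode = "absolute", value = as.numeric(gy)),
                     class = "dose_threshold"))
  }
  if (percent < 0 || percent >= 50)
    stop("percent threshold must be in [0, 50)", call. = FALSE)
  structure(list(mode = "percent", value = as.numeric(percent)),
            class = "dose_threshold")
}

resolve_threshold <- function(threshold, total_dose) {
  if (!inherits(threshold, "dose_threshold"))
    threshold <- dose_threshold(percent = threshold)
  if (threshold$mode == "percent") threshold$value / 100 * total_dose
  else threshold$value
}

# Crossing times on the piecewise-linear cumulative-dose curve of a point.
# contrib: per-event dose (Gy), aligned with timeline$events.
#   t_rise(target): earliest t with c(t) >= target.
#   t_onset(target): sup{t : c(t) <= target}, the moment accrual exceeds the
#     target (ties resolved forward so pre-event dead time is excluded).
crossing_times <- function(events, contrib, target, side = c("rise", "onset")) {
  side <- match.arg(side)
  csum <- cumsum(contrib)
  before <- c(0, csum[-length(csum)])
  dur <- events$t_end_ms - events$t_start_ms
  if (side == "rise") {
    if (target <= 0) return(0)
    # the slack tolerates mass removed by the negligible-contribution floor;
    # the interpolation below still uses the exact target, clamped into the
    # selected event
    i <- which(csum >= target * (1 - 1e-9))[1]
    if (is.na(i)) return(NA_real_)
  } else {
    i <- which(csum > target)[1]
    if (is.na(i)) return(events$t_end_ms[length(dur)])
  }
  if (dur[i] == 0 || contrib[i] == 0) return(events$t_start_ms[i])
  frac <- (target - before[i]) / contrib[i]
  events$t_start_ms[i] + dur[i] * min(max(frac, 0), 1)
}

#' PBS dose rate at a point of interest
#'
#' Computes the threshold-based PBS dose rate at one point: with `c(t)`
#' the cumulative dose at the point, \eqn{\hat d} the resolved threshold,
#' and `D` the total dose, the metric is
#' \deqn{\dot D_{PBS} = \frac{D - 2\hat d}{t_1 - t_0}}
#' where `t0` is the time at which the cumulative dose rises above
#' \eqn{\hat d} and `t1` the earliest time it reaches \eqn{D - \hat d},
#' both located by linear interpolation inside events. At \eqn{\hat d = 0}
#' the window spans the first to the last non-zero deposition at the
#' point, so dead time before and after delivery never dilutes the rate.
#'
#' @param timeline A [build_timeline()] result.
#' @param spot_maps The spot map(s) the timeline was built from.
#' @param beam A [beam_model()].
#' @param x,y The evaluation point (mm).
#' @param threshold A [dose_threshold()], or a number interpreted as a
#'   percent-of-local-dose threshold. Default 1%.
#' @return The PBS dose rate in Gy/s (scalar).
#' @examples
#' sm <- spot_map(0, 0, 1)
#' tl <- build_timeline(sm, timing_model(t_spot_fixed = 10, t_spot_per_gy = 90))
#' pbs_dose_rate_at_point(tl, sm, beam_model(3), 0, 0, dose_threshold(0))
#' @export
pbs_dose_rate_at_point <- function(timeline, spot_maps, beam, x, y,
                                   threshold = dose_threshold(1)) {
  stopifnot(inherits(timeline, "timeline"), inherits(beam, "beam_model"))
  if (timeline$total_time_ms <= 0)
    stop("undefined dose rate: timeline has zero total duration",
         call. = FALSE)
  contrib <- event_contributions(timeline, spot_maps, beam, x, y)
  D <- sum(contrib)
  dhat <- resolve_threshold(threshold, D)
  if (D <= 2 * dhat)
    stop(sprintf(
      "point (%g, %g) below threshold: total dose %.3g Gy <= 2 x %.3g Gy",
      x, y, D, dhat), call. = FALSE)
  # Contributions below double-precision relevance (1e-12 of the local
  # total) are treated as zero when locating the window: without a floor
  # the untruncated Gaussian tails would start every point's window at the
  # first event of the whole plan.
  contrib[contrib < 1e-12 * D] <- 0
  ev <- timeline$events
  t0 <- crossing_times(ev, contrib, dhat, side = "onset")
  t1 <- crossing_times(ev, contrib, D - dhat, side = "rise")
  if (!is.finite(t1) || t1 <= t0) {
    if (isTRUE(all.equal(t1, t0)) || t1 == t0)
      stop("undefined dose rate: dose delivered instantaneously at the point",
           call. = FALSE)
    stop("could not bracket the dose-rate window", call. = FALSE)
  }
  (D - 2 * dhat) / ((t1 - t0) / 1000)
}

#' PBS dose rate of all spots and mean PBS dose rate
#'
#' Evaluates [pbs_dose_rate_at_point()] at every spot center. Spots whose
#' center dose does not exceed twice the resolved threshold are excluded
#' from the mean and flagged, not reported as zero.
#'
#' @inheritParams pbs_dose_rate_at_point
#' @return A list of class `pbs_dose_rate`: `per_spot` (data frame with
#'   `field`, `spot`, `x`, `y`, `dose_gy`, `dose_rate_gy_s`, `excluded`),
#'   `mean` (arithmetic mean over included spots), `threshold`.
#' @export
pbs_dose_rate_per_spot <- function(timeline, spot_maps, beam,
                                   threshold = dose_threshold(1)) {
  if (inherits(spot_maps, "spot_map")) spot_maps <- list(spot_maps)
  rows <- list()
  for (f in seq_along(spot_maps)) {
    map <- spot_maps[[f]]
    for (s in seq_len(nrow(map))) {
      D <- dose_at_point(map_union(spot_maps), beam, map$x[s], map$y[s])
      val <- tryCatch(
        pbs_dose_rate_at_point(timeline, spot_maps, beam,
                               map$x[s], map$y[s], threshold),
        error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <-
        data.frame(field = f, spot = s, x = map$x[s], y = map$y[s],
                   dose_gy = D, dose_rate_gy_s = val, excluded = is.na(val))
    }
  }
  per_spot <- do.call(rbind, rows)
  if (all(per_spot$excluded))
    stop("all spot centers are below the PBS dose-rate threshold",
         call. = FALSE)
  structure(list(per_spot = per_spot,
                 mean = mean(per_spot$dose_rate_gy_s[!per_spot$excluded]),
                 threshold = threshold),
            class = "pbs_dose_rate")
}

#' @export
print.pbs_dose_rate <- function(x, ...) {
  n_ex <- sum(x$per_spot$excluded)
  cat(sprintf("<pbs_dose_rate> %d spots (%d excluded), mean %.4g Gy/s\n",
              nrow(x$per_spot), n_ex, x$mean))
  invisible(x)
}

# union of several spot maps into one (for static dose evaluation)
map_union <- function(spot_maps) {
  if (inherits(spot_maps, "spot_map")) return(spot_maps)
  if (length(spot_maps) == 1L) return(spot_maps[[1L]])
  spot_map(unlist(lapply(spot_maps, `[[`, "x")),
           unlist(lapply(spot_maps, `[[`, "y")),
           unlist(lapply(spot_maps, `[[`, "weight")))
}

#' Field average dose rate
#'
#' Delivered dose divided by irradiation time: the mean dose over the
#' `level_percent` isodose region of the dose map (95% of the maximum by
#' default, the convention used for cross-study comparability), divided
#' by the total treatment time.
#'
#' @param grid A [dose_grid()].
#' @param timeline A [build_timeline()] result with positive total time.
#' @param level_percent Isodose level defining the field region (default 95).
#' @param reference,prescribed_gy Passed to [isodose_mask()].
#' @param numerator `"mask_mean"` (default: mean dose inside the region) or
#'   `"prescribed"` (use `prescribed_gy` as the delivered dose).
#' @return Field average dose rate in Gy/s.
#' @export
field_average_dose_rate <- function(grid, timeline, level_percent = 95,
                                    reference = c("max", "prescribed"),
                                    prescribed_gy = NULL,
                                    numerator = c("mask_mean", "prescribed")) {
  stopifnot(inherits(grid, "dose_grid"), inherits(timeline, "timeline"))
  numerator <- match.arg(numerator)
  if (timeline$total_time_ms <= 0)
    stop("undefined dose rate: timeline has zero total duration",
         call. = FALSE)
  mask <- isodose_mask(grid, level_percent, reference, prescribed_gy)
  if (!any(mask)) stop("empty isodose mask", call. = FALSE)
  dose <- if (numerator == "mask_mean") mean(grid$values[mask]) else {
    if (is.null(prescribed_gy))
      stop("numerator = \"prescribed\" requires prescribed_gy", call. = FALSE)
    prescribed_gy
  }
  dose / total_time_s(timeline)
}

#' Dose-rate-volume histogram
#'
#' Bins per-cell (or per-spot) dose-rate values into user-supplied bins.
#' Bins are left-closed, `[e_i, e_{i+1})`, with the last bin closed on
#' both sides; values outside the edges are collected into flagged
#' underflow/overflow counts. Fractions are taken over all supplied
#' (masked) values, so they sum to 1 including under/overflow.
#'
#' @param values Numeric vector or matrix of dose rates (Gy/s).
#' @param bin_edges Strictly increasing numeric vector of bin edges.
#' @param mask Optional logical vector/matrix selecting values.
#' @return A list of class `drv_histogram`: `bin_edges`, `counts`,
#'   `fractions`, `underflow`, `overflow`, `n`.
#' @examples
#' dose_rate_volume_histogram(c(1, 5, 9), bin_edges = c(0, 4, 8, 12))
#' @export
dose_rate_volume_histogram <- function(values, bin_edges, mask = NULL) {
  stopifnot(is.numeric(values), is.numeric(bin_edges))
  if (length(bin_edges) < 2L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing with >= 2 edges",
         call. = FALSE)
  v <- as.numeric(values)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), length(mask) == length(v))
    v <- v[mask]
  }
  v <- v[!is.na(v)]
  if (!length(v)) stop("no values to bin", call. = FALSE)
  idx <- findInterval(v, bin_edges, rightmost.closed = TRUE)
  under <- sum(idx == 0L)
  over <- sum(idx == length(bin_edges))
  counts <- tabulate(idx[idx >= 1L & idx < length(bin_edges)],
                     nbins = length(bin_edges) - 1L)
  if (under > 0 || over > 0)
    warning(sprintf("%d value(s) below and %d above the bin range",
                    under, over), call. = FALSE)
  structure(list(bin_edges = bin_edges, counts = counts,
                 fractions = c(counts, under, over) / length(v),
                 underflow = under, overflow = over, n = length(v)),
            class = "drv_histogram")
}

#' @export
print.drv_histogram <- function(x, ...) {
  cat(sprintf("<drv_histogram> %d values in %d bins", x$n,
              length(x$counts)))
  if (x$underflow || x$overflow)
    cat(sprintf(" (+%d underflow, +%d overflow)", x$underflow, x$overflow))
  cat("\n")
  lo <- x$bin_edges[-length(x$bin_edges)]
  hi <- x$bin_edges[-1]
  for (i in seq_along(x$counts))
    cat(sprintf("  [%g, %g%s : %d\n", lo[i], hi[i],
                if (i == length(x$counts)) "]" else ")", x$counts[i]))
  invisible(x)
}

#' @export
plot.drv_histogram <- function(x, xlab = "dose rate (Gy/s)",
                               ylab = "fraction", ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::barplot(x$counts / x$n, names.arg = signif(mids, 3),
                    xlab = xlab, ylab = ylab, ...)
  invisible(x)
}
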