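#' Build a delivery timeline for one or more spot maps
#'
#' Turns spot maps plus a [timing_model()] into the ordered sequence of
#' beam-on events realizing the delivery. Within a painting, spots are
#' visited row by row starting at the minimum-`y` row; `"serpentine"`
#' (boustrophedon, the default) reverses the x-direction on alternate
#' rows, `"raster"` always scans in increasing x with the fly-back
#' counted as part of the single `tau_y` row change. Each painting
#' delivers `weight / n_repaint` of every spot; paintings repeat the full
#' map in the same order, separated by `tau_repaint`; fields are
#' delivered sequentially, separated by `tau_field`.
#'
#' Per spot and painting the beam-on time is
#' `t_spot_fixed + t_spot_per_gy * (weight / n_repaint)`; consecutive
#' spots in a row are separated by `tau_x`, consecutive rows by `tau_y`.
#' Zero-weight spots with `t_spot_fixed = 0` produce zero-length events,
#' which deliver their (zero) dose instantaneously.
#'
#' @param spot_maps A [spot_map()] or a list of them (one per field).
#' @param timing A [timing_model()].
#' @param scan_order `"serpentine"` (default) or `"raster"`.
#' @param reverse_start Logical; start the first row scanning in
#'   decreasing x. Useful for symmetry checks.
#' @return An object of class `timeline`: a list with `events` (a data
#'   frame with columns `field`, `repaint`, `spot`, `t_start_ms`,
#'   `t_end_ms`, `dose_fraction`, sorted and non-overlapping) and
#'   `total_time_ms`.
#' @examples
#' sm <- generate_spot_map(2, 2, 5, 5, w_center = 1)
#' tm <- timing_model(t_spot_fixed = 50, tau_x = 2, tau_y = 10)
#' build_timeline(sm, tm)
#' @export
build_timeline <- function(spot_maps, timing,
                           scan_order = c("serpentine", "raster"),
                           reverse_start = FALSE) {
  scan_order <- match.arg(scan_order)
  stopifnot(inherits(timing, "timing_model"))
  if (inherits(spot_maps, "spot_map")) spot_maps <- list(spot_maps)
  if (!length(spot_maps) || !all(vapply(spot_maps, inherits, TRUE, "spot_map")))
    stop("spot_maps must be a spot_map or a list of spot_map objects",
         call. = FALSE)
  if (any(vapply(spot_maps, nrow, 0L) == 0L))
    stop("every spot map must be non-empty", call. = FALSE)

  ev <- vector("list", length(spot_maps))
  t_cur <- 0
  for (f in seq_along(spot_maps)) {
    map <- spot_maps[[f]]
    if (f > 1L) t_cur <- t_cur + timing$tau_field
    ord <- scan_order_indices(map, scan_order, reverse_start)
    rows <- ord$row_of[ord$idx]
    w_paint <- map$weight / timing$n_repaint
    t_on <- timing$t_spot_fixed + timing$t_spot_per_gy * w_paint
    gaps <- c(0, ifelse(diff(rows) != 0, timing$tau_y, timing$tau_x))
    fev <- vector("list", timing$n_repaint)
    for (r in seq_len(timing$n_repaint)) {
      if (r > 1L) t_cur <- t_cur + timing$tau_repaint
      starts <- numeric(length(ord$idx))
      ends <- numeric(length(ord$idx))
      for (k in seq_along(ord$idx)) {
        t_cur <- t_cur + gaps[k]
        starts[k] <- t_cur
        t_cur <- t_cur + t_on[ord$idx[k]]
        ends[k] <- t_cur
      }
      fev[[r]] <- data.frame(field = f, repaint = r, spot = ord$idx,
                             t_start_ms = starts, t_end_ms = ends,
                             dose_fraction = 1 / timing$n_repaint)
    }
    ev[[f]] <- do.call(rbind, fev)
  }
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  structure(list(events = events, total_time_ms = t_cur,
                 n_fields = length(spot_maps), timing = timing,
                 scan_order = scan_order),
            class = "timeline")
}

# Visit order for one painting: spots sorted into rows by y, row-major from
# minimum y; serpentine flips x-direction on alternate rows.
scan_order_indices <- function(map, scan_order, reverse_start = FALSE) {
  ys <- sort(unique(map$y))
  row_of <- match(map$y, ys)
  idx <- integer(0)
  for (r in seq_along(ys)) {
    in_row <- which(row_of == r)
    decreasing <- reverse_start
    if (scan_order == "serpentine" && (r %% 2L) == 0L)
      decreasing <- !decreasing
    idx <- c(idx, in_row[order(map$x[in_row], decreasing = decreasing)])
  }
  list(idx = idx, row_of = row_of)
}

#' @export
print.timeline <- function(x, ...) {
  cat(sprintf("<timeline> %d events, %d field(s), %s scan, total %g ms (%g s)\n",
              nrow(x$events), x$n_fields, x$scan_order,
              x$total_time_ms, x$total_time_ms / 1000))
  print(utils::head(x$events, 6L))
  if (nrow(x$events) > 6L)
    cat(sprintf("  ... %d more events\n", nrow(x$events) - 6L))
  invisible(x)
}

#' Total treatment time in seconds
#' @param timeline A [build_timeline()] result.
#' @return Total delivery time in seconds.
#' @export
total_time_s <- function(timeline) {
  stopifnot(inherits(timeline, "timeline"))
  timeline$total_time_ms / 1000
}

# Per-event dose contributions (Gy) at a point, aligned with timeline$events.
# spot_maps must be the same map(s) the timeline was built from.
event_contributions <- function(timeline, spot_maps, beam, x, y) {
  if (inherits(spot_maps, "spot_map")) spot_maps <- list(spot_maps)
  ev <- timeline$events
  per_spot <- lapply(spot_maps, function(m) dose_at_point_per_spot(m, beam, x, y))
  vapply(seq_len(nrow(ev)), function(i)
    per_spot[[ev$field[i]]][ev$spot[i]] * ev$dose_fraction[i], 0)
}

# dose contribution of each spot of one map at a single point
dose_at_point_per_spot <- function(map, beam, x, y) {
  if (nrow(map) == 0L) return(numeric(0))
  map$weight * exp(-(x - map$x)^2 / (2 * beam$sigma_x^2)
                   - (y - map$y)^2 / (2 * beam$sigma_y^2))
}

#' Time-resolved cumulative dose at a point
#'
#' Evaluates the cumulative dose delivered to a point by time `t`:
#' within an event the event's contribution accrues linearly (constant
#' instantaneous rate); zero-length events deposit at their start time.
#' The result is piecewise linear and non-decreasing in `t`, and at
#' `t >= total_time_ms` equals the static [dose_at_point()] value.
#'
#' @param timeline A [build_timeline()] result.
#' @param spot_maps The spot map (or list, one per field) the timeline was
#'   built from.
#' @param beam A [beam_model()].
#' @param x,y A single evaluation point (mm).
#' @param t Numeric vector of times (ms, `>= 0`).
#' @return Numeric vector of cumulative doses (Gy), one per time.
#' @export
cumulative_dose <- function(timeline, spot_maps, beam, x, y, t) {
  stopifnot(inherits(timeline, "timeline"), is.numeric(t), all(t >= 0))
  contrib <- event_contributions(timeline, spot_maps, beam, x, y)
  ev <- timeline$events
  dur <- ev$t_end_ms - ev$t_start_ms
  vapply(t, function(tt) {
    frac <- ifelse(dur > 0,
                   pmin(pmax((tt - ev$t_start_ms) / ifelse(dur > 0, dur, 1), 0), 1),
                   as.numeric(tt >= ev$t_start_ms))
    sum(contrib * frac)
  }, 0)
}

#' Export a timeline's events as CSV
#' @param timeline A [build_timeline()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeline <- function(timeline, path) {
  stopifnot(inherits(timeline, "timeline"))
  utils::write.csv(timeline$events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
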