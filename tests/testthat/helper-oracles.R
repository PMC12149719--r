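# Independent oracles used across the suite. These deliberately avoid the
# package's event-indexed crossing search and grid code paths.

# Brute-force PBS dose rate at a point: sample the cumulative-dose curve on a
# fine time grid (dt ms), locate the threshold crossings by scanning the
# samples, and interpolate between neighbouring samples only.
oracle_pbs_dose_rate <- function(timeline, maps, beam, x, y,
                                 threshold_pct = 1, dt = 0.01) {
  if (inherits(maps, "spot_map")) maps <- list(maps)
  ev <- timeline$events
  contrib <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    m <- maps[[ev$field[i]]]
    s <- ev$spot[i]
    contrib[i] <- m$weight[s] * ev$dose_fraction[i] *
      exp(-(x - m$x[s])^2 / (2 * beam$sigma_x^2) -
          (y - m$y[s])^2 / (2 * beam$sigma_y^2))
  }
  tk <- seq(0, timeline$total_time_ms, by = dt)
  if (tk[length(tk)] < timeline$total_time_ms)
    tk <- c(tk, timeline$total_time_ms)
  dur <- ev$t_end_ms - ev$t_start_ms
  frac <- outer(tk, ev$t_start_ms, "-")
  frac <- sweep(frac, 2L, ifelse(dur > 0, dur, 1), "/")
  frac <- pmin(pmax(frac, 0), 1)
  zero <- which(dur == 0)
  for (j in zero) frac[, j] <- as.numeric(tk >= ev$t_start_ms[j])
  cume <- as.numeric(frac %*% contrib)
  D <- cume[length(cume)]
  dhat <- threshold_pct / 100 * D
  if (D <= 2 * dhat) return(NA_real_)
  interp <- function(i0, target) {
    if (cume[i0 + 1L] == cume[i0]) return(tk[i0 + 1L])
    tk[i0] + dt * (target - cume[i0]) / (cume[i0 + 1L] - cume[i0])
  }
  i0 <- max(which(cume <= dhat))
  t0 <- if (i0 == length(cume)) tk[i0] else interp(i0, dhat)
  i1 <- min(which(cume >= (D - dhat) * (1 - 1e-12)))
  t1 <- if (i1 == 1L) tk[1L] else interp(i1 - 1L, D - dhat)
  (D - 2 * dhat) / ((t1 - t0) / 1000)
}

# Closed-form mean dose of a single circular Gaussian spot over its p% isodose
# disk: with a = -log(p/100), mean = w * (1 - p/100) / a.
oracle_gaussian_mask_mean <- function(w, level_percent) {
  p <- level_percent / 100
  w * (1 - p) / (-log(p))
}

# Reference 5x5 random plan shared by dose-rate tests and the acceptance
# suite: weights U[0.5, 2] Gy on a 5 mm pitch grid, sigma 3 mm,
# beam-on 1 ms + 10 ms/Gy, tau_x 2 ms, tau_y 10 ms.
random_plan <- function(seed) {
  fx <- generate_fixture_spotmaps(seed, n_maps = 1)
  list(map = fx$maps[[1]], timing = fx$timing,
       beam = beam_model(3),
       timeline = build_timeline(fx$maps[[1]], fx$timing))
}
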