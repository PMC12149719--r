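test_that("single-spot PBS dose rate at zero threshold is dose over beam-on time", {
  b <- beam_model(3)
  for (w in c(0.5, 1, 4)) {
    sm <- spot_map(0, 0, w)
    tm <- timing_model(t_spot_fixed = 10, t_spot_per_gy = 90)
    tl <- build_timeline(sm, tm)
    t_on <- (10 + 90 * w) / 1000
    expect_equal(pbs_dose_rate_at_point(tl, sm, b, 0, 0, dose_threshold(0)),
                 w / t_on, tolerance = 1e-12)
  }
})

test_that("dead time outside the local deposition window never dilutes the rate", {
  # two spots >= 10 sigma apart: each spot center sees only its own event
  b <- beam_model(3)
  sm <- spot_map(c(0, 40), c(0, 0), c(1, 1))
  tm <- timing_model(t_spot_fixed = 100, tau_x = 500)
  tl <- build_timeline(sm, tm)
  r <- pbs_dose_rate_at_point(tl, sm, b, 0, 0, dose_threshold(0))
  D <- dose_at_point(sm, b, 0, 0)
  # window is the first event alone: [0, 100] ms, not [0, 700]
  expect_equal(r, D / 0.1, tolerance = 1e-9)
  # the second spot's center window is its own event [600, 700]
  r2 <- pbs_dose_rate_at_point(tl, sm, b, 40, 0, dose_threshold(0))
  expect_equal(r2, dose_at_point(sm, b, 40, 0) / 0.1, tolerance = 1e-9)
})

test_that("single-event points give exactly the event's instantaneous rate", {
  b <- beam_model(3)
  sm <- spot_map(0, 0, 1.5)
  tm <- timing_model(t_spot_fixed = 7, t_spot_per_gy = 31)
  tl <- build_timeline(sm, tm)
  ev <- tl$events
  inst <- 1.5 / ((ev$t_end_ms - ev$t_start_ms) / 1000)
  expect_identical(pbs_dose_rate_at_point(tl, sm, b, 0, 0, dose_threshold(0)),
                   inst)
})

test_that("event-based PBS dose rate matches the fine-time-step oracle", {
  for (seed in c(101, 202, 303)) {
    pl <- random_plan(seed)
    for (s in c(1L, 7L, 13L, 25L)) {
      got <- pbs_dose_rate_at_point(pl$timeline, pl$map, pl$beam,
                                    pl$map$x[s], pl$map$y[s],
                                    dose_threshold(1))
      want <- oracle_pbs_dose_rate(pl$timeline, pl$map, pl$beam,
                                   pl$map$x[s], pl$map$y[s],
                                   threshold_pct = 1)
      expect_equal(got, want, tolerance = 1e-4)
    }
  }
})

test_that("per-spot PBS dose rates are mirror-symmetric after direction averaging", {
  pl <- list(map = generate_spot_map(4, 3, 5, 5, w_center = 1, w_rim = 0.7,
                                     w_corner = 0.9),
             beam = beam_model(3),
             timing = timing_model(t_spot_fixed = 2, t_spot_per_gy = 20,
                                   tau_x = 2, tau_y = 10))
  fwd <- build_timeline(pl$map, pl$timing, reverse_start = FALSE)
  rev_ <- build_timeline(pl$map, pl$timing, reverse_start = TRUE)
  vf <- pbs_dose_rate_per_spot(fwd, pl$map, pl$beam, dose_threshold(1))$per_spot
  vr <- pbs_dose_rate_per_spot(rev_, pl$map, pl$beam, dose_threshold(1))$per_spot
  avg <- (vf$dose_rate_gy_s + vr$dose_rate_gy_s) / 2
  # pair each spot with its x-mirror image
  mirror <- match(paste(-vf$x, vf$y), paste(vf$x, vf$y))
  expect_equal(avg, avg[mirror], tolerance = 1e-9)
})

test_that("per-spot summary equals the point metric and excludes cold spots", {
  b <- beam_model(3)
  sm <- spot_map(0, 0, 1)
  tl <- build_timeline(sm, timing_model(t_spot_fixed = 10, t_spot_per_gy = 90))
  ps <- pbs_dose_rate_per_spot(tl, sm, b, dose_threshold(0))
  expect_equal(ps$per_spot$dose_rate_gy_s,
               pbs_dose_rate_at_point(tl, sm, b, 0, 0, dose_threshold(0)))
  expect_equal(ps$mean, ps$per_spot$dose_rate_gy_s)
  # an absolute threshold larger than half a spot's dose excludes that spot
  sm2 <- spot_map(c(0, 40), c(0, 0), c(1, 0.1))
  tl2 <- build_timeline(sm2, timing_model(t_spot_fixed = 10, tau_x = 2))
  ps2 <- pbs_dose_rate_per_spot(tl2, sm2, b, dose_threshold(gy = 0.2))
  expect_identical(ps2$per_spot$excluded, c(FALSE, TRUE))
  expect_error(pbs_dose_rate_per_spot(tl2, sm2, b, dose_threshold(gy = 2)),
               "all spot centers")
})

test_that("below-threshold points and degenerate timelines raise errors", {
  b <- beam_model(3)
  sm <- spot_map(0, 0, 1)
  tl <- build_timeline(sm, timing_model(t_spot_fixed = 10))
  expect_error(
    pbs_dose_rate_at_point(tl, sm, b, 50, 0, dose_threshold(gy = 0.5)),
    "below threshold")
  # an all-zero timing model means instantaneous delivery: undefined rate
  tz <- build_timeline(sm, timing_model())
  expect_error(pbs_dose_rate_at_point(tz, sm, b, 0, 0, dose_threshold(0)),
               "undefined dose rate")
})

test_that("dose-rate metrics scale with weights and inversely with time", {
  pl <- random_plan(7)
  b <- pl$beam
  tm0 <- timing_model(t_spot_fixed = 5, t_spot_per_gy = 0, tau_x = 2,
                      tau_y = 10)
  tl0 <- build_timeline(pl$map, tm0)
  scaled <- spot_map(pl$map$x, pl$map$y, 3 * pl$map$weight)
  tls <- build_timeline(scaled, tm0)
  r1 <- pbs_dose_rate_at_point(tl0, pl$map, b, 0, 0, dose_threshold(1))
  r3 <- pbs_dose_rate_at_point(tls, scaled, b, 0, 0, dose_threshold(1))
  expect_equal(r3, 3 * r1, tolerance = 1e-12)
  # multiplying every timing parameter by c divides the rate by c
  tmc <- timing_model(t_spot_fixed = 10, t_spot_per_gy = 0, tau_x = 4,
                      tau_y = 20)
  tlc <- build_timeline(pl$map, tmc)
  rc <- pbs_dose_rate_at_point(tlc, pl$map, b, 0, 0, dose_threshold(1))
  expect_equal(rc, r1 / 2, tolerance = 1e-12)
  # field average dose rate scales the same way
  dg <- compute_dose_map(pl$map, b)
  dgs <- compute_dose_map(scaled, b)
  f1 <- field_average_dose_rate(dg, tl0)
  expect_equal(field_average_dose_rate(dgs, tls), 3 * f1, tolerance = 1e-12)
  expect_equal(field_average_dose_rate(dg, tlc), f1 / 2, tolerance = 1e-12)
})

test_that("field average dose rate is mean mask dose over treatment time", {
  # synthetic uniform field: 10 Gy everywhere, delivered in 0.5 s
  g <- dose_grid(matrix(10, 20, 20), c(0, 0), 1)
  sm <- spot_map(0, 0, 1)
  tl <- build_timeline(sm, timing_model(t_spot_fixed = 500))
  expect_equal(field_average_dose_rate(g, tl, 95), 20)
  # single circular Gaussian spot: closed-form mean over the p% isodose disk
  b <- beam_model(3)
  s1 <- spot_map(0, 0, 2)
  dg <- compute_dose_map(s1, b, xlim = c(-12, 12), ylim = c(-12, 12),
                         spacing = 0.05)
  tl1 <- build_timeline(s1, timing_model(t_spot_fixed = 1000))
  for (lev in c(95, 50)) {
    got <- field_average_dose_rate(dg, tl1, lev)
    expect_equal(got, oracle_gaussian_mask_mean(2, lev), tolerance = 0.01)
  }
  expect_error(field_average_dose_rate(g, build_timeline(sm, timing_model()),
                                       95), "zero total duration")
})

test_that("dose-rate-volume histograms bin, normalize and flag overflow", {
  h <- dose_rate_volume_histogram(c(1, 5, 9), bin_edges = c(0, 4, 8, 12))
  expect_identical(h$counts, c(1L, 1L, 1L))
  expect_equal(sum(h$fractions), 1)
  # uniform field: all mass in one bin
  hu <- dose_rate_volume_histogram(rep(40, 50), bin_edges = c(0, 30, 60, 90))
  expect_identical(hu$counts, c(0L, 50L, 0L))
  # values outside the edges land in flagged under/overflow bins
  expect_warning(
    ho <- dose_rate_volume_histogram(c(-1, 5, 100), bin_edges = c(0, 4, 8, 12)),
    "below and")
  expect_identical(ho$underflow, 1L)
  expect_identical(ho$overflow, 1L)
  expect_equal(sum(ho$fractions), 1)
  # a mask restricts the binned population; edges must increase
  hm <- dose_rate_volume_histogram(1:10, bin_edges = c(0, 5, 10),
                                   mask = 1:10 > 5)
  expect_equal(hm$n, 5L)
  expect_error(dose_rate_volume_histogram(1:3, bin_edges = c(1, 1, 2)),
               "strictly increasing")
})

test_that("PBS dose rate exceeds the field average when transits add dead time", {
  pl <- random_plan(31)
  dg <- compute_dose_map(pl$map, pl$beam)
  favg <- field_average_dose_rate(dg, pl$timeline, 95)
  ps <- pbs_dose_rate_per_spot(pl$timeline, pl$map, pl$beam, dose_threshold(1))
  expect_gt(ps$mean, favg)
})
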