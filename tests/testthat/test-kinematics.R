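test_that("population speed summarises per-trajectory means", {
  tracks <- rbind(make_const_track(10, id = 1), make_const_track(20, id = 2),
                  make_const_track(30, id = 3))
  s <- population_speed(tracks, "whole")
  expect_equal(s$mean_um_s, 20)
  expect_equal(s$sem_um_s, 10 / sqrt(3))
  expect_equal(s$n, 3)
  one <- population_speed(make_const_track(15), "whole")
  expect_true(is.na(one$sem_um_s))
  expect_equal(one$n, 1)
  expect_error(population_speed(tracks[0, ], "whole"), "no trajectories")
})

test_that("speed dialects agree exactly on all-run trajectories", {
  set.seed(12)
  # wiggly but everywhere fast: everything is one run episode
  tr <- make_const_track(25, duration = 3)
  tr$y_um <- tr$y_um + cumsum(rnorm(nrow(tr), 0, 0.01))
  w <- population_speed(tr, "whole")
  r <- population_speed(tr, "runs")
  expect_equal(r$mean_um_s, w$mean_um_s, tolerance = 1e-12)
})

test_that("a slow erratic population is far slower than a fast one through the same summary", {
  bulk <- environment_profile("bulk")
  wt_pop <- simulate_population(40, strain_profile("WT"), bulk, 8,
                                seed = 41)
  ab_pop <- simulate_population(40, strain_profile("dmotAB"), bulk, 8,
                                seed = 42)
  cols <- c("track_id", "t_s", "x_um", "y_um")
  s_wt <- population_speed(as.data.frame(wt_pop)[, cols], "whole")
  s_ab <- population_speed(as.data.frame(ab_pop)[, cols], "whole")
  expect_lt(s_ab$mean_um_s, s_wt$mean_um_s / 4)
})

test_that("MSD matches closed forms", {
  still <- make_const_track(0, duration = 3)
  m0 <- compute_msd(still, max_lag = 1)
  expect_true(all(m0$msd_um2 == 0))
  ball <- make_const_track(12, duration = 3)
  m1 <- compute_msd(ball, max_lag = 1)
  expect_equal(m1$msd_um2, (12 * m1$lag_s)^2, tolerance = 1e-9)
  expect_equal(m1$msd_um2[m1$lag_s == 0], 0)
  expect_true(all(diff(m1$n_pairs[m1$lag_s > 0]) <= 0))
  # units: doubling coordinates quadruples the MSD
  sc <- ball
  sc$x_um <- 2 * sc$x_um
  sc$y_um <- 2 * sc$y_um
  m2 <- compute_msd(sc, max_lag = 1)
  expect_equal(m2$msd_um2, 4 * m1$msd_um2, tolerance = 1e-9)
  expect_error(compute_msd(ball, max_lag = 0.01), "below one frame")
})

test_that("diffusivity is recovered from simulated random walks", {
  set.seed(19)
  D <- 0.5
  dt <- 0.1
  n_steps <- 100
  walks <- do.call(rbind, lapply(1:300, function(i) {
    data.frame(track_id = i, t_s = (0:n_steps) * dt,
               x_um = cumsum(c(0, rnorm(n_steps, 0, sqrt(2 * D * dt)))),
               y_um = cumsum(c(0, rnorm(n_steps, 0, sqrt(2 * D * dt)))))
  }))
  msd <- compute_msd(walks, max_lag = 2)
  est <- estimate_diffusivity(msd, fit_range = c(0, 2))
  expect_equal(est$D_um2_s, D, tolerance = 0.1)
  expect_false(est$superdiffusive)
})

test_that("diffusivity fit flags ballistic curves and exact lines", {
  lag <- seq(0, 2, by = 0.1)
  line <- structure(data.frame(lag_s = lag, msd_um2 = 4 * 1 * lag,
                               n_pairs = 100),
                    class = c("msd_curve", "data.frame"))
  est <- estimate_diffusivity(line, c(0, 2))
  expect_equal(est$D_um2_s, 1.0, tolerance = 1e-12)
  ball <- compute_msd(make_const_track(10, duration = 5), max_lag = 2)
  expect_warning(est2 <- estimate_diffusivity(ball, c(0, 2)),
                 "superdiffusive")
  expect_true(est2$superdiffusive)
  expect_gt(est2$loglog_slope, 1.5)
  expect_error(estimate_diffusivity(line[1, ], c(0, 0)), "2 lags")
})

test_that("a slower population has a pointwise lower MSD curve", {
  bulk <- environment_profile("bulk")
  cols <- c("track_id", "t_s", "x_um", "y_um")
  fast <- as.data.frame(simulate_population(30, strain_profile("WT"),
                                            bulk, 8, seed = 51))[, cols]
  slow <- as.data.frame(simulate_population(30, strain_profile("dmotAB"),
                                            bulk, 8, seed = 52))[, cols]
  mf <- compute_msd(fast, max_lag = 2)
  ms <- compute_msd(slow, max_lag = 2)
  expect_true(all(ms$msd_um2 <= mf$msd_um2))
})
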