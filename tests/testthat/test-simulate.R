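wt <- strain_profile("WT")
bulk <- environment_profile("bulk")
agar <- environment_profile("agar0.25")

test_that("identical seeds give identical generator output", {
  a <- simulate_swimmer(wt, bulk, 5, 0.05, seed = 7)
  b <- simulate_swimmer(wt, bulk, 5, 0.05, seed = 7)
  expect_identical(a, b)
  pa <- simulate_population(10, wt, agar, 3, 0.05, seed = 3)
  pb <- simulate_population(10, wt, agar, 3, 0.05, seed = 3)
  expect_identical(pa, pb)
  pc <- simulate_population(10, wt, agar, 3, 0.05, seed = 4)
  expect_false(identical(pa, pc))
})

test_that("the nonmotile double mutant does not translate in any medium", {
  dm <- strain_profile("dmotABCD")
  for (env in list(bulk, agar, environment_profile("ficoll20"))) {
    p <- simulate_swimmer(dm, env, 5, 0.05, seed = 1)
    expect_equal(path_length(p), 0)
  }
})

test_that("degenerate durations and steps are handled", {
  p <- simulate_swimmer(wt, bulk, 0, 0.05, seed = 1)
  expect_length(p$times, 1)
  expect_equal(c(p$x, p$y), c(0, 0))
  expect_error(simulate_swimmer(wt, bulk, 1, dt = 2, seed = 1), "dt")
  expect_error(simulate_swimmer(wt, bulk, -1, 0.05), "duration")
  expect_error(simulate_swimmer(wt, bulk, 1, dt = 0), "dt")
  expect_length(simulate_population(0, wt, bulk, 1, 0.05, seed = 1), 0)
})

test_that("mode occupancy follows the stationary distribution of the switch chain", {
  # end states of independent paths are iid draws from the stationary law
  pop <- simulate_population(500, wt, bulk, 2, 0.05, seed = 11)
  final <- vapply(unclass(pop), function(p) p$mode[length(p$mode)],
                  character(1))
  obs <- table(factor(final, levels = c("push", "pull", "wrapped", "stop")))
  exp_occ <- expected_mode_occupancy(wt, bulk)
  ct <- suppressWarnings(stats::chisq.test(obs, p = exp_occ))
  expect_gt(ct$p.value, 1e-3)
  # long-run time fractions converge to the same law
  p1 <- simulate_swimmer(wt, bulk, 2000, 0.05, seed = 12)
  frac <- table(factor(p1$mode, levels = names(exp_occ))) / length(p1$mode)
  expect_equal(as.numeric(frac), unname(exp_occ), tolerance = 0.15)
})

test_that("stop and trap timepoints do not translate; runs do", {
  p <- simulate_swimmer(wt, agar, 30, 0.05, seed = 5)
  step <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  # step k is governed by the state at timepoint k
  idx <- which(p$mode[-length(p$mode)] == "stop" |
               p$phase[-length(p$phase)] == "trap")
  expect_true(all(step[idx] == 0))
  moving <- which(p$mode[-length(p$mode)] != "stop" &
                  p$phase[-length(p$phase)] != "trap")
  expect_true(all(step[moving] > 0))
})

test_that("grand mean run speed of a bulk population matches the mixture mean", {
  n <- 200
  pop <- simulate_population(n, wt, bulk, 10, 0.05, seed = 21)
  per_path <- vapply(unclass(pop), function(p) {
    step_v <- sqrt(diff(p$x)^2 + diff(p$y)^2) / 0.05
    run <- p$mode[-length(p$mode)] != "stop"
    mean(step_v[run])
  }, numeric(1))
  mc_sem <- sd(per_path) / sqrt(n)
  expect_lt(abs(mean(per_path) - expected_run_speed(wt, bulk)), 2 * mc_sem)
})

test_that("wrapped-mode steps are slower than push steps in generated paths", {
  pop <- simulate_population(30, wt, environment_profile("ficoll10"),
                             10, 0.05, seed = 9)
  for (p in unclass(pop)) {
    step_v <- sqrt(diff(p$x)^2 + diff(p$y)^2) / 0.05
    m <- p$mode[-length(p$mode)]
    ok <- p$phase[-length(p$phase)] == "run"
    if (any(m == "wrapped" & ok) && any(m == "push" & ok))
      expect_lt(max(step_v[m == "wrapped" & ok]),
                min(step_v[m == "push" & ok]) + 1e-9)
  }
})

test_that("trapping happens in agar, never in bulk, and more in finer meshes", {
  pop_b <- simulate_population(50, wt, bulk, 10, 0.05, seed = 13)
  pop_a <- simulate_population(50, wt, agar, 10, 0.05, seed = 13)
  expect_equal(sum(trap_fraction(pop_b)), 0)
  expect_gt(mean(trap_fraction(pop_a)), 0)
  fine <- environment_profile("agar0.25")
  fine$pore_range <- c(300, 1500)   # finer mesh, same trap parameters
  pop_f <- simulate_population(50, wt, fine, 10, 0.05, seed = 13)
  expect_gt(mean(trap_fraction(pop_f)), mean(trap_fraction(pop_a)))
})

test_that("rendered detections reproduce truth under ideal settings", {
  pop <- simulate_population(5, wt, bulk, 2, 0.05, seed = 2)
  det <- render_detections(pop, sigma_loc = 0, p_detect = 1,
                           fp_per_frame = 0, fov = c(-1e4, 1e4, -1e4, 1e4),
                           seed = 1)
  truth <- as.data.frame(pop)
  expect_equal(nrow(det), nrow(truth))
  det_o <- det[order(det$frame, det$x_um), ]
  tr_o <- truth[order(truth$frame, truth$x_um), ]
  expect_equal(det_o$x_um, tr_o$x_um)
  expect_equal(det_o$y_um, tr_o$y_um)
})

test_that("localisation noise has the configured RMS radius", {
  pop <- simulate_population(10, wt, bulk, 50, 0.05, seed = 31)
  err2 <- numeric(0)
  for (i in seq_along(pop)) {
    p <- unclass(pop)[[i]]
    det <- render_detections(list(p), sigma_loc = 0.1, p_detect = 1,
                             fp_per_frame = 0,
                             fov = c(-1e4, 1e4, -1e4, 1e4), seed = 100 + i)
    # exactly one detection per frame, in frame order
    err2 <- c(err2, (det$x_um - p$x)^2 + (det$y_um - p$y)^2)
  }
  expect_gt(length(err2), 5000)
  # isotropic 2-D Gaussian: RMS radial deviation is sigma * sqrt(2)
  expect_equal(sqrt(mean(err2)), 0.1 * sqrt(2), tolerance = 0.05)
})

test_that("detection probability zero leaves only false positives", {
  pop <- simulate_population(5, wt, bulk, 2, 0.05, seed = 2)
  det <- render_detections(pop, p_detect = 0, fp_per_frame = 2,
                           fov = c(0, 10, 0, 10), seed = 3)
  expect_true(all(det$x_um >= 0 & det$x_um <= 10))
  expect_gt(nrow(det), 0)
  expect_error(render_detections(pop, fov = c(1, 1, 0, 1)), "fov")
})

test_that("division outcomes control cluster formation", {
  cd <- strain_profile("dmotCD")
  agar3 <- environment_profile("agar0.3")
  # all daughters motile -> clusters never form
  allmot <- cd
  allmot$p_motile_daughter <- list("agar0.3" = 1)
  sim <- simulate_division_clusters(allmot, agar3, n0 = 5, duration = 6,
                                    seed = 1)
  expect_length(sim$cluster_sizes, 0)
  # no motile daughters: branching process, E[size] = 2^(t / doubling time)
  nomot <- cd
  nomot$p_motile_daughter <- list("agar0.3" = 0)
  tdouble <- log(2) / nomot$division_rate
  sizes <- vapply(1:250, function(s) {
    sim <- simulate_division_clusters(nomot, agar3, n0 = 1,
                                      duration = 3 * tdouble, seed = s)
    sum(sim$cluster_sizes) + sim$series$n_motile[nrow(sim$series)]
  }, numeric(1))
  expect_equal(mean(sizes), 8, tolerance = 0.2)
  # dmotCD keeps fewer motile cells than dmotAB in 0.3% agar
  ab <- strain_profile("dmotAB")
  mot_frac <- function(strain, seed) {
    sim <- simulate_division_clusters(strain, agar3, n0 = 40, duration = 6,
                                      seed = seed)
    last <- sim$series[nrow(sim$series), ]
    last$n_motile / (last$n_motile + last$n_sessile)
  }
  expect_lt(mot_frac(cd, 5), mot_frac(ab, 5))
})

test_that("spreading series obey the Fisher front closed form", {
  dm <- strain_profile("dmotABCD")
  sp0 <- simulate_spreading(dm, agar, 24)
  expect_true(all(sp0$diameter_mm == sp0$diameter_mm[1]))
  # front speed scales as sqrt(D * g): doubling g scales c by sqrt(2)
  wt2 <- wt
  wt2$division_rate <- 2 * wt$division_rate
  expect_equal(spreading_front_speed(wt2, agar),
               sqrt(2) * spreading_front_speed(wt, agar),
               tolerance = 1e-12)
  # fitted diameter slope of a noiseless series = 2 * front speed within 1%
  sp <- simulate_spreading(wt, agar, 24)
  fit <- fit_spreading(sp)
  expect_equal(fit$slope_mm_h, 2 * spreading_front_speed(wt, agar),
               tolerance = 0.01)
  # spreading slope is monotone non-decreasing in p_motile_daughter
  slopes <- vapply(c(0.1, 0.4, 0.9), function(p) {
    s <- wt
    s$p_motile_daughter <- list("agar0.25" = p)
    spreading_front_speed(s, agar)
  }, numeric(1))
  expect_true(all(diff(slopes) >= 0))
  expect_error(simulate_spreading(wt, agar, 0), "duration")
})
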