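test_that("a static detection repeated over frames yields one track", {
  det <- data.frame(frame = 0:9, x_um = 1, y_um = 2)
  tr <- link_detections(det, link_config())
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)
  expect_equal(tr$t_s, tr$frame / 20)
})

test_that("detections beyond the gate are never cross-linked", {
  det <- data.frame(frame = rep(0:9, each = 2),
                    x_um = rep(c(0, 50), 10), y_um = 0)
  tr <- link_detections(det, link_config(max_disp = 5))
  expect_equal(length(unique(tr$track_id)), 2)
  expect_true(all(table(tr$track_id) == 10))
  for (id in unique(tr$track_id)) {
    expect_equal(length(unique(tr$x_um[tr$track_id == id])), 1)
  }
})

test_that("no link ever exceeds max_disp", {
  set.seed(14)
  for (rep in 1:10) {
    det <- make_random_instance(k = 6, nf = 8, max_step = 3)
    cfg <- link_config(max_disp = 2.5, memory = 1)
    tr <- link_detections(det, cfg)
    for (id in unique(tr$track_id)) {
      t1 <- tr[tr$track_id == id, ]
      if (nrow(t1) < 2) next
      d <- sqrt(diff(t1$x_um)^2 + diff(t1$y_um)^2)
      expect_true(all(d <= cfg$max_disp + 1e-12))
    }
  }
})

test_that("linking equals the exhaustive assignment oracle on small instances", {
  set.seed(5)
  cfg <- link_config(max_disp = 3, memory = 1)
  for (rep in 1:30) {
    k <- sample(3:5, 1)
    det <- make_random_instance(k, nf = 6, max_step = 2.5)
    # drop a few detections so births/deaths and memory are exercised
    det <- det[runif(nrow(det)) > 0.1, ]
    det <- det[order(det$frame), ]
    got <- canonical_tracks(link_detections(det, cfg))
    want <- canonical_track_list(oracle_link(det, cfg))
    expect_identical(got, want)
  }
})

test_that("within-frame detection order does not change the links", {
  set.seed(8)
  det <- make_random_instance(5, nf = 6, max_step = 2)
  cfg <- link_config(max_disp = 3, memory = 0)
  base <- canonical_tracks(link_detections(det, cfg))
  for (rep in 1:5) {
    perm <- do.call(rbind, lapply(split(det, det$frame),
                                  function(d) d[sample(nrow(d)), ]))
    perm <- perm[order(perm$frame), ]
    expect_identical(canonical_tracks(link_detections(perm, cfg)), base)
  }
})

test_that("track memory bridges short gaps and terminates long ones", {
  det <- data.frame(frame = c(0, 1, 3, 4), x_um = 0, y_um = 0)
  tr2 <- link_detections(det, link_config(memory = 2))
  expect_equal(length(unique(tr2$track_id)), 1)
  tr0 <- link_detections(det, link_config(memory = 0))
  expect_equal(length(unique(tr0$track_id)), 2)
  expect_error(link_detections(det[c(3, 1, 2, 4), ], link_config()),
               "ordered")
})

test_that("track recovery score is 1 on truth and low on swapped links", {
  wt <- strain_profile("WT")
  bulk <- environment_profile("bulk")
  pop <- simulate_population(4, wt, bulk, 3, 0.05, seed = 17)
  # separate the paths in space so nearest-truth lookup is unambiguous
  for (i in seq_along(pop)) pop[[i]]$x <- pop[[i]]$x + 500 * i
  truth_df <- as.data.frame(pop)
  expect_equal(track_recovery_score(truth_df, pop), 1.0)
  # interleave two static, well-separated cells and swap their links
  a <- data.frame(track_id = 1, frame = 0:9, t_s = (0:9) / 20,
                  x_um = 0, y_um = 0)
  b <- data.frame(track_id = 2, frame = 0:9, t_s = (0:9) / 20,
                  x_um = 100, y_um = 0)
  static_pop <- structure(list(
    structure(list(id = 1, times = a$t_s, x = a$x_um, y = a$y_um),
              class = "swimmer_path"),
    structure(list(id = 2, times = b$t_s, x = b$x_um, y = b$y_um),
              class = "swimmer_path")), class = "swimmer_population")
  swapped <- rbind(a, b)
  swapped$x_um <- ifelse(swapped$frame %% 2 == 0, swapped$x_um,
                         100 - swapped$x_um)
  expect_equal(track_recovery_score(swapped, static_pop), 0)
  expect_error(track_recovery_score(truth_df[0, ], pop), "empty")
})

test_that("well-separated swimmers are recovered nearly perfectly", {
  wt <- strain_profile("WT")
  bulk <- environment_profile("bulk")
  pop <- simulate_population(9, wt, bulk, 5, 0.05, seed = 23)
  off <- bactrack:::.grid_offsets(9, 2000)  # spacing >> per-frame step
  det <- render_detections(pop, sigma_loc = 0.05, p_detect = 1,
                           fp_per_frame = 0, fov = c(-1, 1, -1, 1) * 5000,
                           seed = 2, offsets = off)
  tr <- link_detections(det[order(det$frame), ], link_config())
  expect_gte(track_recovery_score(tr, pop, offsets = off), 0.99)
})
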