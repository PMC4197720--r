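test_that("path length, velocity and persistence match hand arithmetic", {
  tri <- data.frame(t_min = c(0, 10), x_um = c(0, 3), y_um = c(0, 4))
  expect_equal(path_length(tri), 5)          # 3-4-5 triangle
  expect_equal(velocity(tri), 0.5)
  two_seg <- data.frame(t_min = c(0, 10, 20), x_um = c(0, 0, 0),
                        y_um = c(0, 5, 10))
  expect_equal(path_length(two_seg), 10)
  expect_equal(persistence(two_seg), 1)      # straight line
  bend <- data.frame(t_min = c(0, 7, 19), x_um = c(0, 3, 3), y_um = c(0, 0, 4))
  expect_equal(persistence(bend), 5 / 7)
  square <- data.frame(t_min = 0:4 * 10, x_um = c(0, 1, 1, 0, 0),
                       y_um = c(0, 0, 1, 1, 0))
  expect_equal(persistence(square), 0)       # loop back to start
})

test_that("velocity is homogeneous of degree one in the coordinates", {
  set.seed(2)
  tr <- random_track(12)
  scaled <- tr
  scaled$x_um <- 2 * tr$x_um
  scaled$y_um <- 2 * tr$y_um
  expect_equal(velocity(scaled), 2 * velocity(tr), tolerance = 1e-12)
  expect_equal(persistence(scaled), persistence(tr), tolerance = 1e-12)
})

test_that("degenerate tracks are rejected or flagged", {
  expect_error(path_length(data.frame(t_min = 0, x_um = 0, y_um = 0)), "2")
  expect_error(velocity(data.frame(t_min = c(0, 0), x_um = c(0, 1),
                                   y_um = c(0, 0))), "increasing")
  still <- data.frame(t_min = c(0, 10, 20), x_um = c(1, 1, 1), y_um = c(2, 2, 2))
  expect_true(is.na(persistence(still)))     # stationary cell: undefined
})

test_that("deviation angles follow the signed triple-wise convention", {
  coll <- data.frame(t_min = 0:3 * 10, x_um = 0:3, y_um = rep(0, 4))
  expect_equal(as.numeric(deviation_angles(coll)), c(0, 0))
  left <- data.frame(t_min = 0:2 * 10, x_um = c(0, 1, 1), y_um = c(0, 0, 1))
  expect_equal(as.numeric(deviation_angles(left)), 90)
  rev <- data.frame(t_min = 0:2 * 10, x_um = c(0, 1, 0), y_um = c(0, 0, 0))
  expect_equal(as.numeric(deviation_angles(rev)), 180)
  short <- data.frame(t_min = c(0, 10), x_um = c(0, 1), y_um = c(0, 0))
  expect_length(deviation_angles(short), 0)
})

test_that("zero-length displacements are skipped and counted", {
  tr <- data.frame(t_min = 0:3 * 10, x_um = c(0, 1, 1, 2), y_um = rep(0, 4))
  ang <- deviation_angles(tr)   # middle step is stationary: both triples bad
  expect_length(ang, 0)
  expect_equal(attr(ang, "n_skipped"), 2L)
})

test_that("deviation angles equal the segment-heading differencing oracle", {
  set.seed(31)
  for (i in 1:200) {
    tr <- random_track(20)
    expect_equal(as.numeric(deviation_angles(tr)),
                 oracle_deviation_angles(tr), tolerance = 1e-9)
  }
})

test_that("metrics are invariant under rigid motions of the field of view", {
  set.seed(17)
  for (i in 1:50) {
    tr <- random_track()
    moved <- rigid_transform(tr, runif(1, -180, 180), rnorm(1, 0, 100),
                             rnorm(1, 0, 100))
    expect_equal(velocity(moved), velocity(tr), tolerance = 1e-9)
    expect_equal(persistence(moved), persistence(tr), tolerance = 1e-9)
    expect_equal(abs(as.numeric(deviation_angles(moved))),
                 abs(as.numeric(deviation_angles(tr))), tolerance = 1e-9)
  }
})

test_that("the complete-track filter keeps exactly window-spanning tracks", {
  full <- data.frame(track_id = "a", group = "g",
                     t_min = seq(0, 360, 10), x_um = 0, y_um = seq(0, 36, 1))
  short <- data.frame(track_id = "b", group = "g",
                      t_min = seq(0, 200, 10), x_um = 0, y_um = seq(0, 20, 1))
  both <- rbind(full, short)
  kept <- filter_complete_tracks(both, 0, 360)
  expect_equal(unique(kept$track_id), "a")
  expect_equal(attr(kept, "n_dropped"), 1L)
  # a track with an internal gap over 1.5x the nominal interval is dropped
  gappy <- full[full$t_min != 180 & full$t_min != 190, ]
  expect_equal(nrow(filter_complete_tracks(rbind(gappy), 0, 360)), 0L)
  # retained tracks are cropped to the window
  long <- data.frame(track_id = "c", group = "g", t_min = seq(-20, 400, 10),
                     x_um = 0, y_um = seq_along(seq(-20, 400, 10)))
  cropped <- filter_complete_tracks(long, 0, 360)
  expect_equal(range(cropped$t_min), c(0, 360))
  expect_equal(nrow(filter_complete_tracks(full[0, ], 0, 360)), 0L)
})

test_that("filter retention equals a direct span-recount on simulated dropout", {
  cfg <- simulation_config("wt", n_cells = 100, dropout_prob = 0.3, seed = 6)
  tr <- simulate_tracks(cfg)
  kept <- filter_complete_tracks(tr, 0, 360)
  spans_ok <- tapply(tr$t_min, tr$track_id, function(t) {
    min(t) <= 0 && max(t) >= 360
  })
  expect_equal(length(unique(kept$track_id)), sum(spans_ok))
})

test_that("angle histograms bin on the (lo, hi] convention and conserve counts", {
  h <- bin_angles(rep(0, 12), n_bins = 8)
  expect_equal(sum(h$counts), 12L)
  expect_equal(h$counts[4], 12L)  # 0 closes the (-45, 0] bin
  expect_equal(sum(h$counts > 0), 1L)
  set.seed(8)
  a <- runif(500, -179.9, 180)
  expect_equal(sum(bin_angles(a, 12)$counts), 500L)
  # boundary values: 180 belongs to the top bin, -180 is out of range
  expect_equal(which(bin_angles(180, 8)$counts == 1L), 8L)
  expect_error(bin_angles(-180, 8), "\\(-180, 180\\]")
  expect_error(bin_angles(c(0, 200), 8), "180")
  expect_error(bin_angles(0, 7), "n_bins")
  # absolute mode folds signs together
  expect_equal(bin_angles(c(-90, 90), 4, absolute = TRUE)$counts,
               c(0L, 2L, 0L, 0L))
})

test_that("uniform angles pass a chi-square uniformity calibration", {
  # binned counts of uniform draws should rarely look non-uniform
  stat_ok <- vapply(1:50, function(i) {
    set.seed(400 + i)
    h <- bin_angles(runif(10000, -180, 180), 8)
    e <- sum(h$counts) / 8
    sum((h$counts - e)^2 / e) < qchisq(0.999, df = 7)
  }, logical(1))
  expect_gte(mean(stat_ok), 0.98)
})

test_that("group summaries match a two-pass mean/sd oracle", {
  m <- data.frame(track_id = c("a", "b", "c", "d", "e"),
                  group = c("g1", "g1", "g1", "g2", "g2"),
                  velocity_um_per_min = c(0.2, 0.3, 0.4, 0.5, 0.7),
                  persistence = c(1, 1, 1, 0, 1))
  s <- summarize_group_metrics(m)
  g1p <- s[s$group == "g1" & s$metric == "persistence", ]
  expect_equal(g1p$mean, 1)
  expect_equal(g1p$sem, 0)
  g2p <- s[s$group == "g2" & s$metric == "persistence", ]
  expect_equal(g2p$mean, 0.5)
  expect_equal(g2p$sem, 0.5)
  g1v <- s[s$group == "g1" & s$metric == "velocity", ]
  v <- c(0.2, 0.3, 0.4)
  two_pass_sd <- sqrt(sum((v - sum(v) / 3)^2) / 2)
  expect_equal(g1v$mean, sum(v) / 3)
  expect_equal(g1v$sem, two_pass_sd / sqrt(3))
  # undefined persistence values are excluded and counted
  m$persistence[1] <- NA
  s2 <- summarize_group_metrics(m)
  expect_equal(attr(s2, "n_persistence_excluded"), 1L)
  expect_equal(s2[s2$group == "g1" & s2$metric == "persistence", "n"], 2L)
})

test_that("binned counts conserve the per-track valid step totals", {
  cfg <- simulation_config("wt", n_cells = 20, dropout_prob = 0.2, seed = 15)
  kept <- filter_complete_tracks(simulate_tracks(cfg), 0, 360)
  metrics <- track_metrics(kept)
  pooled <- deviation_angle_table(kept)
  h <- bin_angles(pooled$angle_deg, 8)
  expect_equal(sum(h$counts), sum(metrics$n_valid_steps))
})
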