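test_that("segment_runs applies the run rule and its arithmetic", {
  expect_equal(nrow(segment_runs(make_track(rep(5, 20)))), 0)

  # 10 frames falling 1 um per frame: one retrograde run
  tr <- make_track(seq(20, 11, by = -1))
  runs <- segment_runs(tr, segmentation_params(min_step_um = 0.2))
  expect_equal(nrow(runs), 1)
  expect_equal(runs$direction, "retrograde")
  expect_equal(runs$start_frame, 0)
  expect_equal(runs$end_frame, 9)
  expect_equal(runs$length_um, 9)
  expect_equal(runs$duration_s, 4.5)
  expect_equal(runs$speed_um_per_s, 2.0)

  # duration invariant: (end - start) * dt, and runs are ordered and disjoint
  zig <- make_track(50 + cumsum(c(0, 1, 1, 1, 0, -1, -1, -1, -1, 0, 1, 1)))
  rz <- segment_runs(zig, segmentation_params(min_step_um = 0.5))
  expect_equal(rz$duration_s, (rz$end_frame - rz$start_frame) * 0.5)
  expect_true(all(diff(rz$start_frame) > 0))
  expect_true(all(rz$start_frame[-1] >= head(rz$end_frame, -1)))

  # fewer samples than min_run_frames is an empty result, not an error
  expect_equal(nrow(segment_runs(make_track(c(1, 2)))), 0)
  expect_error(track("x", "g", c(1, NA, 3)), "finite")
})

test_that("segmentation matches the exhaustive block-scan oracle (3^6 sequences)", {
  grids <- expand.grid(rep(list(c(-1L, 0L, 1L)), 6))
  params <- segmentation_params(min_step_um = 0.5)
  for (i in seq_len(nrow(grids))) {
    signs <- as.integer(grids[i, ])
    tr <- make_track(positions_from_signs(signs))
    runs <- segment_runs(tr, params)
    orc <- oracle_blocks(signs, min_steps = 2L)
    expect_equal(nrow(runs), nrow(orc))
    if (nrow(orc)) {
      expect_equal(runs$start_frame, unname(orc[, "start_step"]) - 1L)
      expect_equal(runs$end_frame, unname(orc[, "end_step"]))
      expect_equal(ifelse(runs$direction == "anterograde", 1L, -1L),
                   unname(orc[, "sign"]))
    }
  }
})

test_that("time reversal swaps run directions and preserves magnitudes", {
  set.seed(42)
  for (rep in 1:25) {
    signs <- sample(c(-1L, 0L, 1L), 30, replace = TRUE)
    tr <- make_track(positions_from_signs(signs))
    rv <- make_track(rev(tr$positions))
    p <- segmentation_params(min_step_um = 0.5)
    a <- segment_runs(tr, p); b <- segment_runs(rv, p)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a)) {
      b <- b[order(-b$start_frame), ]
      swap <- c(anterograde = "retrograde", retrograde = "anterograde")
      expect_equal(unname(swap[a$direction]), b$direction)
      expect_equal(a$length_um, b$length_um)
      expect_equal(a$duration_s, b$duration_s)
      expect_equal(a$speed_um_per_s, b$speed_um_per_s)
    }
  }
})

test_that("runs, classes and metrics are invariant to position translation", {
  set.seed(7)
  signs <- sample(c(-1L, 0L, 1L), 200, replace = TRUE)
  tr <- make_track(positions_from_signs(signs, x0 = 300))
  sh <- make_track(tr$positions + 57.3)
  p <- segmentation_params(min_step_um = 0.5)
  r1 <- segment_runs(tr, p); r2 <- segment_runs(sh, p)
  r2$track_id <- r1$track_id
  expect_equal(r1, r2)
  expect_equal(classify_track(r1), classify_track(r2))
  m1 <- retrograde_metrics(tr, r1, p); m2 <- retrograde_metrics(sh, r2, p)
  expect_equal(m1$total_retro_distance_um, m2$total_retro_distance_um)
})

test_that("classification matches the truth table over all small run lists", {
  expect_equal(classify_track(segment_runs(make_track(rep(1, 10)))), "immobile")
  dirs <- c("anterograde", "retrograde")
  combos <- c(list(character(0)),
              lapply(dirs, identity),
              apply(expand.grid(dirs, dirs), 1, as.character, simplify = FALSE),
              apply(expand.grid(dirs, dirs, dirs), 1, as.character,
                    simplify = FALSE))
  for (cmb in combos) {
    runs <- data.frame(track_id = rep("t", length(cmb)), direction = cmb,
                       stringsAsFactors = FALSE)
    expect_equal(classify_track(runs), oracle_classify(cmb))
  }
  mixed <- data.frame(track_id = c("a", "b"),
                      direction = c("anterograde", "retrograde"))
  expect_error(classify_track(mixed), "more than one track")
})

test_that("retrograde metrics implement the eligibility rule and arithmetic", {
  p <- segmentation_params(min_step_um = 0.2)
  short <- make_track(seq(30, 15.5, by = -0.25))  # 59 frames = 29 s
  m <- retrograde_metrics(short, segment_runs(short, p), p)
  expect_false(m$eligible)
  expect_true(is.na(m$mean_retro_speed_um_per_s))

  # 180 s track: retro 2 um at 1 um/s, pause, retro 4 um at 2 um/s
  pos <- c(seq(50, 48, by = -0.5), rep(48, 200), seq(47, 44, by = -1),
           rep(44, 152))
  long <- make_track(pos)
  expect_equal(track_duration_s(long), 180)
  runs <- segment_runs(long, p)
  m2 <- retrograde_metrics(long, runs, p)
  expect_true(m2$eligible)
  expect_equal(m2$mean_retro_speed_um_per_s, 1.5)
  expect_equal(m2$total_retro_distance_um,
               sum(m2$retro_run_lengths_um))
  expect_equal(m2$total_retro_distance_um, 6)

  # duration-weighted speed switch: (2 + 4) / (2 + 2) = 1.5 vs run mean 1.5;
  # make them differ by changing the slow run to 3 um at 0.5 um/s
  pos2 <- c(seq(50, 47, by = -0.25), rep(47, 200), seq(46, 43, by = -1),
            rep(43, 148))
  tr2 <- make_track(pos2)
  r2 <- segment_runs(tr2, p)
  w <- retrograde_metrics(tr2, r2, segmentation_params(
    min_step_um = 0.2, speed_weighting = "duration_weighted"))
  u <- retrograde_metrics(tr2, r2, p)
  expect_equal(u$mean_retro_speed_um_per_s, mean(c(0.5, 2)))
  expect_equal(w$mean_retro_speed_um_per_s, (3 + 4) / (6 + 2))
})

test_that("eligibility can be gated on cumulative retrograde time", {
  # 180 s track with only 4.5 s of retrograde movement
  pos <- c(seq(50, 41, by = -1), rep(41, 351))
  tr <- make_track(pos)
  p_total <- segmentation_params(min_step_um = 0.2)
  p_retro <- segmentation_params(min_step_um = 0.2,
                                 eligibility = "retrograde_time")
  runs <- segment_runs(tr, p_total)
  expect_true(retrograde_metrics(tr, runs, p_total)$eligible)
  expect_false(retrograde_metrics(tr, runs, p_retro)$eligible)
})

test_that("movement table conserves counts and ignores track order", {
  cls <- data.frame(
    track_id = sprintf("t%d", 1:7),
    group = c("a", "a", "a", "b", "b", "b", "b"),
    class = c("anterograde", "retrograde", "immobile", "bidirectional",
              "retrograde", "retrograde", "immobile"),
    stringsAsFactors = FALSE)
  tab <- movement_class_table(cls, groups = c("a", "b"))
  expect_equal(sum(tab), 7)
  expect_equal(unname(rowSums(tab)), c(3, 4))
  shuffled <- cls[sample(nrow(cls)), ]
  expect_identical(movement_class_table(shuffled, groups = c("a", "b")), tab)

  single <- movement_class_table(cls[1, ], groups = "a")
  expect_equal(sum(single), 1)
  expect_equal(single["a", "anterograde"], 1)

  expect_error(movement_class_table(cls, groups = "a"), "unknown group")
})

test_that("identical groups give a zero chi-square and a complete report", {
  sim <- simulate_tracks(track_sim_config(n_tracks_per_group = 12,
                                          immobile_fraction = 0.4, seed = 13))
  ctrl <- sim$tracks[vapply(sim$tracks, function(t) t$group, character(1)) ==
                       "control"]
  copy <- lapply(ctrl, function(t)
    track(paste0(t$track_id, "_copy"), "mutant", t$positions,
          t$frame_interval_s, t$pixel_size_um))
  rep <- compare_trafficking(c(ctrl, copy))
  expect_true(rep$class_test$computable)
  expect_equal(unname(rep$class_test$statistic), 0)
  expect_equal(sum(rep$movement_table), 24)
  expect_equal(unname(rep$run_length_test$p_value), 1, tolerance = 1e-12)
})

test_that("a group without eligible tracks is flagged, not an error", {
  sim <- simulate_tracks(track_sim_config(n_tracks_per_group = 5,
                                          immobile_fraction = 0, seed = 4))
  mut <- sim$tracks[vapply(sim$tracks, function(t) t$group, character(1)) ==
                      "mutant"]
  still <- lapply(seq_along(mut), function(i)
    track(sprintf("still_%d", i), "control", rep(40, 361), 0.5, 0.1))
  rep <- compare_trafficking(c(still, mut))
  expect_false(rep$run_length_test$computable)
  expect_false(rep$speed_test$computable)
})

test_that("detected retrograde distance agrees with the simulation ground truth", {
  cfg <- track_sim_config(n_tracks_per_group = 15, position_noise_um = 0,
                          immobile_fraction = 0, seed = 77)
  sim <- simulate_tracks(cfg)
  params <- segmentation_params()
  dt <- cfg$frame_interval_s
  total_detected <- 0; total_inner <- 0; total_outer <- 0
  for (id in names(sim$tracks)) {
    tr <- sim$tracks[[id]]
    runs <- segment_runs(tr, params)
    m <- retrograde_metrics(tr, runs, params)
    gt <- sim$truth[sim$truth$track_id == id &
                      sim$truth$direction == "retrograde", ]
    det <- if (is.na(m$total_retro_distance_um)) 0 else m$total_retro_distance_um
    total_detected <- total_detected + det
    # inner truth: displacement over the frames fully inside each run with
    # >= 3 sampled frames; outer truth: frames bracketing each run
    inner <- gt[gt$n_frames >= 3, ]
    total_inner <- total_inner + sum(abs(inner$grid_displacement_um))
    n <- length(tr$positions)
    sf_o <- pmax(0L, floor(gt$start_s / dt))
    ef_o <- pmin(n - 1L, ceiling(gt$end_s / dt))
    total_outer <- total_outer +
      sum(abs(tr$positions[ef_o + 1L] - tr$positions[sf_o + 1L]))
  }
  # run-edge frames are partially traversed, so the detected distance must
  # land between the interior-grid and bracketing-grid ground truth
  expect_gte(total_detected, total_inner * 0.999)
  expect_lte(total_detected, total_outer * 1.001)
  expect_lt(abs(total_detected - total_inner) / total_inner, 0.25)
})
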