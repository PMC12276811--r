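test_that("length filter keeps exactly the trajectories of >= min_frames", {
  both <- rbind(still_track(89, traj_id = "short"),
                still_track(90, traj_id = "long"))
  kept <- filter_trajectories(both)
  expect_equal(unique(kept$traj_id), "long")

  expect_equal(filter_trajectories(both, min_frames = 1), both)

  tr <- random_tracks(100, len_range = c(50, 130), seed = 21)
  kept <- filter_trajectories(tr, 90)
  # brute-force oracle: tabulate lengths, list comprehension over ids
  lens <- table(tr$traj_id)
  expect_setequal(unique(kept$traj_id), names(lens)[lens >= 90])
})

test_that("dwell time counts in-period in-volume samples at 1/frame_rate", {
  vol <- test_vol()
  outside <- still_track(100, at = c(50, 20, 30))
  expect_equal(time_in_volume(outside, vol), 0)

  inside <- still_track(60, at = c(vol$center_x, vol$center_y, 2))
  expect_equal(time_in_volume(inside, vol), 1.0)  # 60 frames at 60 Hz

  # period window is half-open
  expect_equal(time_in_volume(inside, vol, t_start = 0, t_end = 0.5), 0.5)
  expect_equal(time_in_volume(inside, vol, t_start = 0.5, t_end = 10),
               0.5)  # frames 30..59: t_start inclusive, t_end exclusive
})

test_that("dwell time matches a per-point brute-force count on random tracks", {
  tr <- random_tracks(30, len_range = c(20, 200), seed = 8)
  vol <- response_volume(-20, 5, diameter = 40, height = 30)
  for (id in unique(tr$traj_id)[1:10]) {
    one <- tr[tr$traj_id == id, ]
    expect_equal(time_in_volume(one, vol),
                 sum(brute_in_volume(one, vol)) / 60)
  }
})

test_that("preference index follows its dwell-time definition", {
  tv <- test_vol(); cv <- control_vol()
  # 30 test frames then 10 control frames
  tr <- rbind(
    still_track(30, at = c(tv$center_x, tv$center_y, 2), traj_id = "m"),
    still_track(10, at = c(cv$center_x, cv$center_y, 2), traj_id = "m",
                frame0 = 30L))
  rec <- preference_records(tr, tv, cv)
  expect_equal(rec$pi, (30 - 10) / 40)
  expect_equal(rec$weight, 40 / 60)
  expect_equal(rec$n_test, 30)
  expect_equal(rec$n_trials, 40)

  only_test <- still_track(30, at = c(tv$center_x, tv$center_y, 2))
  expect_equal(preference_records(only_test, tv, cv)$pi, 1)

  neither <- still_track(30, at = c(50, 0, 30))
  rec0 <- preference_records(neither, tv, cv)
  expect_true(is.na(rec0$pi))     # undefined, never coerced to 0
  expect_equal(rec0$weight, 0)

  expect_error(preference_records(tr, tv, response_volume(-56, -14)),
               "overlap")
})

test_that("preference index is antisymmetric under label swap", {
  set.seed(31)
  tv <- test_vol(); cv <- control_vol()
  runs <- simulate_run(fast_cfg(), seed = 77)
  sc <- suppressWarnings(score_run(runs))
  p <- sc$preferences[sc$preferences$n_trials > 0, ]
  swapped <- purrr::pmap_dfr(runs$schedule, function(...) {
    per <- list(...)
    preference_records(filter_trajectories(runs$trajectories),
                       response_volume(per$control_x, per$control_y),
                       response_volume(per$test_x, per$test_y),
                       period_id = per$period_id,
                       t_start = per$t_start, t_end = per$t_end)
  })
  swapped <- swapped[swapped$n_trials > 0, ]
  m <- dplyr::inner_join(p, swapped, by = c("run_id", "traj_id", "period_id"))
  expect_gt(nrow(m), 0)
  expect_equal(m$pi.x, -m$pi.y)
  expect_equal(m$weight.x, m$weight.y)
  expect_true(all(abs(m$pi.x) <= 1, na.rm = TRUE))
  # invariant: pi * weight = t_test - t_control
  expect_equal(p$pi * p$weight, p$t_test - p$t_control, tolerance = 1e-12)
})

test_that("activation and recruitment match a brute-force double loop", {
  tv <- test_vol(); cv <- control_vol()
  # 50 trajectories, 3 placed inside a volume
  far <- purrr::map_dfr(1:47, ~ still_track(95, at = c(60, 10, 30),
                                            traj_id = sprintf("w%02d", .x)))
  near <- purrr::map_dfr(1:3, ~ still_track(
    95, at = c(tv$center_x, tv$center_y, 2), traj_id = sprintf("h%02d", .x)))
  s <- summarize_period(rbind(far, near), tv, cv)
  expect_equal(s$n_trajectories, 50)
  expect_equal(s$n_recruited, 3)
  expect_equal(s$recruitment, 0.06)

  empty <- summarize_period(far[0, ], tv, cv)
  expect_equal(empty$n_trajectories, 0)
  expect_true(is.na(empty$recruitment))

  tr <- random_tracks(40, len_range = c(10, 60), seed = 5)
  big_tv <- response_volume(-20, -8, diameter = 35, height = 25)
  big_cv <- response_volume(30, 8, diameter = 35, height = 25)
  s <- summarize_period(tr, big_tv, big_cv, t_start = 0.2, t_end = 0.7)
  hits <- 0; act <- 0
  for (id in unique(tr$traj_id)) {
    one <- tr[tr$traj_id == id & tr$t >= 0.2 & tr$t < 0.7, ]
    if (nrow(one) == 0) next
    act <- act + 1
    if (any(brute_in_volume(one, big_tv) | brute_in_volume(one, big_cv))) {
      hits <- hits + 1
    }
  }
  expect_equal(s$n_trajectories, act)
  expect_equal(s$n_recruited, hits)
})

test_that("occupancy maps normalize to 100% and match a 2D histogram", {
  one_spot <- still_track(25, at = c(10, 3, 12))
  m <- occupancy_map(one_spot, "top")
  expect_equal(max(m$pct), 100)
  expect_equal(sum(m$pct), 100, tolerance = 1e-9)

  none <- occupancy_map(one_spot[0, ], "top")
  expect_true(attr(none, "empty"))
  expect_equal(sum(none$pct), 0)

  tr <- random_tracks(20, len_range = c(30, 80), seed = 13)
  for (view in c("top", "side")) {
    m <- occupancy_map(tr, view, bin_area = 25)
    expect_equal(sum(m$pct), 100, tolerance = 1e-9)
    expect_true(all(m$pct >= 0))
    # brute-force: count points per bin directly
    bin <- attr(m, "bin_size")
    v <- if (view == "top") tr$y else tr$z
    vlo <- if (view == "top") -61 / 2 else 0
    hs <- sort(unique(m$h))
    for (k in sample(nrow(m), 25)) {
      hits <- sum(tr$x >= m$h[k] - bin / 2 - 1e-12 &
                    tr$x < m$h[k] + bin / 2 - 1e-12 &
                    v >= m$v[k] - bin / 2 - 1e-12 &
                    v < m$v[k] + bin / 2 - 1e-12)
      expect_equal(m$pct[k], 100 * hits / nrow(tr), tolerance = 1e-9)
    }
  }
})

test_that("occupancy matrix writer produces a dense readable grid", {
  tr <- random_tracks(5, seed = 2)
  m <- occupancy_map(tr, "top", bin_area = 100)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_occupancy_matrix(m, f)
  back <- as.matrix(utils::read.table(f, sep = "\t", row.names = 1,
                                      header = TRUE, check.names = FALSE))
  expect_equal(sum(back), 100, tolerance = 1e-9)
  expect_equal(dim(back), dim(occupancy_matrix(m)))
})

test_that("metrics on concatenated runs equal per-run metrics", {
  r1 <- simulate_run(fast_cfg(), seed = 5, run_id = "runA")
  r2 <- simulate_run(fast_cfg(), seed = 6, run_id = "runB")
  sep <- suppressWarnings(score_cohort(list(r1, r2)))
  joint_traj <- rbind(r1$trajectories, r2$trajectories)
  joint <- suppressWarnings(score_run(
    list(run_id = "both", trajectories = joint_traj,
         schedule = r1$schedule, geometry = r1$geometry)))
  agg <- dplyr::summarise(
    dplyr::group_by(sep$summaries, period_id),
    n = sum(n_trajectories), r = sum(n_recruited))
  agg2 <- joint$summaries[match(agg$period_id, joint$summaries$period_id), ]
  expect_equal(agg$n, agg2$n_trajectories)
  expect_equal(agg$r, agg2$n_recruited)
})
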