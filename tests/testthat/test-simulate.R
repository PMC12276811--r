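test_that("simulation is deterministic in (config, seed) and varies in seed", {
  r1 <- simulate_run(fast_cfg(), seed = 10)
  r2 <- simulate_run(fast_cfg(), seed = 10)
  expect_identical(r1$trajectories, r2$trajectories)
  expect_identical(attr(r1, "truth"), attr(r2, "truth"))
  r3 <- simulate_run(fast_cfg(), seed = 11)
  expect_false(identical(r1$trajectories, r3$trajectories))
})

test_that("generated trajectories satisfy the data-model invariants", {
  run <- simulate_run(fast_cfg(), seed = 3)
  expect_silent(validate_trajectories(run$trajectories, run$geometry,
                                      strict = TRUE))
  lens <- dplyr::count(run$trajectories, traj_id)
  truth <- attr(run, "truth")
  long_ids <- truth$traj_id[!truth$short]
  expect_true(all(lens$n[lens$traj_id %in% long_ids] >= 90))
  expect_true(any(lens$n < 90))  # censored fragments exercise the filter
  expect_equal(sum(run$schedule$phase == "main"), 17)
})

test_that("step lengths respect the configured flight speed", {
  cfg <- fast_cfg()
  ds <- cfg$speed / cfg$geometry$frame_rate
  for (mode in c("wander", "approach_test")) {
    set.seed(5)
    tr <- simulate_trajectory(cfg, mode, n_frames = 400, dwell_frames = 60)
    st <- sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)
    # reflections and maneuvers shorten a step, never lengthen it
    expect_lte(max(st), ds * (1 + 1e-9))
    expect_equal(median(st), ds, tolerance = 1e-9)
  }
})

test_that("pure wandering dwells in the volumes at about chance level", {
  cfg <- fast_cfg()
  set.seed(99)
  n_tracks <- 300
  frames <- 0
  hits <- 0
  tv <- test_vol(); cv <- control_vol()
  for (i in seq_len(n_tracks)) {
    tr <- simulate_trajectory(cfg, "wander", n_frames = 200)
    frames <- frames + nrow(tr)
    hits <- hits + sum(brute_in_volume(tr, tv)) + sum(brute_in_volume(tr, cv))
  }
  geom_frac <- 2 * (pi * 7^2 * 4) / (222 * 59 * 59.5)  # two cylinders /
  # wander box volume
  rate <- hits / frames
  # chance passage: same order of magnitude as the geometric fraction
  expect_lt(rate, 10 * geom_frac)
  expect_lt(abs(rate - geom_frac), 5 * sqrt(geom_frac / frames) + geom_frac)
})

test_that("approach modes realize the requested dwell split", {
  cfg <- fast_cfg()
  tv <- test_vol(); cv <- control_vol()
  set.seed(42)
  for (i in 1:10) {
    tr <- simulate_trajectory(cfg, "approach_test", n_frames = 300,
                              dwell_frames = 60, dwell_split = 1)
    rec <- preference_records(tr, tv, cv)
    expect_equal(rec$pi, 1)          # split 1 -> all dwell in the test volume
    expect_equal(rec$n_trials, 60)
  }
  tr <- simulate_trajectory(cfg, "approach_control", n_frames = 300,
                            dwell_frames = 60, dwell_split = 1)
  expect_equal(preference_records(tr, tv, cv)$pi, -1)
})

test_that("metrics recover the injected per-trajectory dwell counts", {
  run <- simulate_run(fast_cfg(), seed = 29)
  sc <- suppressWarnings(score_run(run))
  truth <- attr(run, "truth")
  rec <- dplyr::inner_join(
    truth[truth$recruited, c("traj_id", "n_test", "n_total")],
    sc$preferences, by = "traj_id")
  expect_gt(nrow(rec), 0)
  expect_equal(rec$n_test.y, rec$n_test.x)
  expect_equal(rec$n_trials, rec$n_total)
})

test_that("without CO2 gating almost no trajectories are recruited", {
  runs <- simulate_cohort(fast_cfg(co2_percent = 0), 12, seed = 60)
  sc <- suppressWarnings(score_cohort(runs))
  main <- sc$summaries[sc$summaries$phase == "main", ]
  rate <- sum(main$n_recruited) / sum(main$n_trajectories)
  expect_lt(rate, 0.01)
  with_co2 <- simulate_cohort(fast_cfg(), 12, seed = 61)
  sc2 <- suppressWarnings(score_cohort(with_co2))
  main2 <- sc2$summaries[sc2$summaries$phase == "main", ]
  rate2 <- sum(main2$n_recruited) / sum(main2$n_trajectories)
  expect_gt(rate2, 0.02)      # CO2 gates recruitment up by several-fold
  expect_gt(rate2 / rate, 3)
})

test_that("dispersion-free counts show only binomial variation", {
  d <- simulate_betabinom_records(60, 8, mu = 0.55, phi = Inf, sigma = 0,
                                  seed = 8, trials_mean = 50)
  p_hat <- sum(d$successes) / sum(d$trials)
  # Pearson dispersion statistic ~ chi-square under pure binomial sampling
  X2 <- sum((d$successes - d$trials * p_hat)^2 /
              (d$trials * p_hat * (1 - p_hat)))
  df <- nrow(d) - 1
  expect_gt(pchisq(X2, df, lower.tail = FALSE), 0.01)

  over <- simulate_betabinom_records(60, 8, mu = 0.55, phi = 3, sigma = 0,
                                     seed = 8, trials_mean = 50)
  p2 <- sum(over$successes) / sum(over$trials)
  X2o <- sum((over$successes - over$trials * p2)^2 /
               (over$trials * p2 * (1 - p2)))
  expect_lt(pchisq(X2o, df, lower.tail = FALSE), 1e-6)
})

test_that("cohorts are independent and written runs round-trip", {
  runs <- simulate_cohort(fast_cfg(), 3, seed = 5)
  man <- attr(runs, "manifest")
  expect_equal(man$n_runs, 3)
  expect_equal(length(unique(man$run_seeds)), 3)

  dir <- withr::local_tempdir()
  write_run(runs[[1]], dir)
  back <- suppressMessages(suppressWarnings(read_run(dir, runs[[1]]$run_id)))
  expect_equal(as.data.frame(back$trajectories),
               as.data.frame(runs[[1]]$trajectories))
  expect_equal(back$schedule$test_channel, runs[[1]]$schedule$test_channel)
  expect_equal(back$seed, runs[[1]]$seed)
})

test_that("configured preference surface has the documented shape", {
  cfg <- fast_cfg()
  wl <- led_channel_wavelengths()
  base <- sapply(wl, function(w) pref_logit_surface(cfg, w, 1, "none"))
  expect_equal(wl[which.min(base)], 527)  # trough in the green band
  expect_gt(base[wl == 390], base[wl == 527])
  expect_gt(base[wl == 743], base[wl == 527])
  # floral odor boosts only the green band
  shift <- sapply(wl, function(w) pref_logit_surface(cfg, w, 1, "floral")) - base
  expect_equal(shift[wl >= 475 & wl <= 575],
               rep(cfg$green_boost_floral, 5))
  expect_equal(shift[wl < 475 | wl > 575], rep(0, 12))
  # host odor boosts uniformly
  host <- sapply(wl, function(w) pref_logit_surface(cfg, w, 1, "host")) - base
  expect_equal(host, rep(cfg$host_uniform_boost, length(wl)))
})
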