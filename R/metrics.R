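#' Filter trajectories by minimum length
#'
#' Analyses are restricted to trajectories of at least `min_frames` tracked
#' samples (90 frames = 1.5 s at 60 Hz by default); shorter fragments carry
#' too little information to score an approach.
#'
#' @param trajectories Track-point tibble.
#' @param min_frames Minimum number of samples to retain a trajectory.
#' @return The track-point tibble restricted to retained trajectories,
#'   original order preserved.
#' @export
filter_trajectories <- function(trajectories, min_frames = 90) {
  stopifnot(min_frames >= 1)
  trajectories %>%
    group_by(.data$run_id, .data$traj_id) %>%
    filter(n() >= min_frames) %>%
    ungroup()
}

#' Dwell time of one trajectory in a response volume
#'
#' Counts the trajectory's samples that fall inside the cylinder during the
#' half-open period `[t_start, t_end)` and converts to seconds at the
#' tracking frame rate. No sub-frame interpolation is applied: dwell time is
#' resolved at the tracker's native 1/frame_rate granularity.
#'
#' @param trajectory Track points of a single trajectory.
#' @param volume A [response_volume()].
#' @param t_start,t_end Period window in seconds (half-open).
#' @param frame_rate Tracking rate, Hz.
#' @return Dwell time in seconds.
#' @export
time_in_volume <- function(trajectory, volume, t_start = -Inf, t_end = Inf,
                           frame_rate = 60) {
  inside <- with(trajectory,
                 t >= t_start & t < t_end & in_volume(x, y, z, volume))
  sum(inside) / frame_rate
}

#' Per-trajectory preference records for one period
#'
#' For each trajectory overlapping a stimulus period, computes the time
#' spent in the test and control response volumes and the preference index
#' `pi = (t_test - t_control) / (t_test + t_control)`. The total dwell time
#' `weight = t_test + t_control` is kept alongside: trajectories that enter
#' neither volume have an undefined index (`NA`, never coerced to 0) and
#' carry no weight in inference. Frame counts (`n_test`, `n_trials`) are
#' retained as the integer successes/trials used by the beta-binomial
#' models.
#'
#' @param trajectories Filtered track-point tibble (may span many
#'   trajectories and runs).
#' @param test_volume,control_volume Disjoint [response_volume()]s.
#' @param period_id Label copied into the output.
#' @param t_start,t_end Period window in seconds (half-open).
#' @param frame_rate Tracking rate, Hz.
#' @return A tibble with one row per trajectory that has at least one frame
#'   in the period: `run_id, traj_id, period_id, t_test, t_control, weight,
#'   pi, n_test, n_trials`.
#' @export
preference_records <- function(trajectories, test_volume, control_volume,
                               period_id = "p01", t_start = -Inf,
                               t_end = Inf, frame_rate = 60) {
  check_disjoint(test_volume, control_volume)
  recs <- trajectories %>%
    filter(.data$t >= t_start, .data$t < t_end) %>%
    group_by(.data$run_id, .data$traj_id) %>%
    summarise(
      n_test = sum(in_volume(.data$x, .data$y, .data$z, test_volume)),
      n_control = sum(in_volume(.data$x, .data$y, .data$z, control_volume)),
      .groups = "drop"
    ) %>%
    mutate(
      period_id = period_id,
      t_test = .data$n_test / frame_rate,
      t_control = .data$n_control / frame_rate,
      weight = .data$t_test + .data$t_control,
      pi = ifelse(.data$weight > 0,
                  (.data$t_test - .data$t_control) / .data$weight,
                  NA_real_),
      n_trials = .data$n_test + .data$n_control
    ) %>%
    select(all_of(c("run_id", "traj_id", "period_id", "t_test", "t_control",
                    "weight", "pi", "n_test", "n_trials")))
  recs
}

#' Period-level activation and recruitment
#'
#' Activation is the number of (filtered) trajectories recorded during a
#' period — a proxy for the propensity to fly. Recruitment is the
#' proportion of those trajectories with at least one sample inside either
#' response volume. A period with no trajectories has undefined recruitment
#' (`NA`).
#'
#' @inheritParams preference_records
#' @return One-row tibble: `period_id, n_trajectories, n_recruited,
#'   recruitment`.
#' @export
summarize_period <- function(trajectories, test_volume, control_volume,
                             period_id = "p01", t_start = -Inf, t_end = Inf) {
  check_disjoint(test_volume, control_volume)
  per <- trajectories %>%
    filter(.data$t >= t_start, .data$t < t_end) %>%
    group_by(.data$run_id, .data$traj_id) %>%
    summarise(
      hit = any(in_volume(.data$x, .data$y, .data$z, test_volume) |
                  in_volume(.data$x, .data$y, .data$z, control_volume)),
      .groups = "drop"
    )
  tibble(
    period_id = period_id,
    n_trajectories = nrow(per),
    n_recruited = sum(per$hit),
    recruitment = if (nrow(per) > 0) sum(per$hit) / nrow(per) else NA_real_
  )
}

period_volumes <- function(period) {
  list(
    test = response_volume(period$test_x, period$test_y),
    control = response_volume(period$control_x, period$control_y)
  )
}

#' Score every period of a run
#'
#' Applies the length filter, then computes period summaries (activation,
#' recruitment) and per-trajectory preference records for each scheduled
#' period of a run, using the response-volume positions carried by the
#' schedule.
#'
#' @param run A `tv_run` (see [simulate_run()]) or a list with elements
#'   `run_id`, `trajectories` (track-point tibble), `schedule` (period
#'   tibble) and `geometry`.
#' @param min_frames Trajectory length filter; see [filter_trajectories()].
#' @return A list with tibbles `summaries` (one row per period, stimulus
#'   metadata attached) and `preferences` (one row per trajectory x period).
#' @export
score_run <- function(run, min_frames = 90) {
  traj <- filter_trajectories(run$trajectories, min_frames)
  fr <- run$geometry$frame_rate
  res <- purrr::pmap(run$schedule, function(...) {
    p <- list(...)
    vols <- period_volumes(p)
    s <- summarize_period(traj, vols$test, vols$control,
                          period_id = p$period_id,
                          t_start = p$t_start, t_end = p$t_end)
    pr <- preference_records(traj, vols$test, vols$control,
                             period_id = p$period_id,
                             t_start = p$t_start, t_end = p$t_end,
                             frame_rate = fr)
    list(summary = s, preferences = pr)
  })
  meta <- select(run$schedule, all_of(c(
    "period_id", "phase", "test_channel", "test_intensity",
    "control_channel", "control_intensity", "co2_percent", "odor")))
  summaries <- bind_rows(purrr::map(res, "summary")) %>%
    mutate(run_id = run$run_id, .before = 1) %>%
    left_join(meta, by = "period_id")
  preferences <- bind_rows(purrr::map(res, "preferences")) %>%
    left_join(meta, by = "period_id")
  list(summaries = summaries, preferences = preferences)
}

#' Score a cohort of runs
#'
#' @param runs List of runs (see [score_run()]).
#' @param min_frames Trajectory length filter.
#' @return A list of stacked tibbles `summaries` and `preferences`.
#' @export
score_cohort <- function(runs, min_frames = 90) {
  scored <- purrr::map(runs, score_run, min_frames = min_frames)
  list(
    summaries = bind_rows(purrr::map(scored, "summaries")),
    preferences = bind_rows(purrr::map(scored, "preferences"))
  )
}

#' Occupancy map of trajectory samples
#'
#' Bins all sample positions into squares on a top (x, y) or side (x, z)
#' projection of the working section and normalizes counts to percent
#' residency: each bin holds the percentage of all samples that fell in it.
#' The bin is specified by its area (0.3 cm^2 by default, i.e. side
#' ~0.548 cm); the choice only rescales the map.
#'
#' @param trajectories Track-point tibble.
#' @param view `"top"` (x-y) or `"side"` (x-z).
#' @param bin_area Bin area in cm^2.
#' @param geometry [tunnel_geometry()] supplying the binned region.
#' @return A tibble of class `tv_occupancy` with bin centres (`h`, `v`, cm)
#'   and `pct`; attributes `view`, `bin_size` (side length, cm) and `empty`.
#' @export
occupancy_map <- function(trajectories, view = c("top", "side"),
                          bin_area = 0.3, geometry = tunnel_geometry()) {
  view <- arg_match(view)
  stopifnot(bin_area > 0)
  bin <- sqrt(bin_area)
  b <- geometry_bounds(geometry)
  hlim <- b$x
  vlim <- if (view == "top") b$y else b$z
  hbreaks <- seq(hlim[1], hlim[2] + bin, by = bin)
  vbreaks <- seq(vlim[1], vlim[2] + bin, by = bin)
  h <- trajectories$x
  v <- if (view == "top") trajectories$y else trajectories$z
  keep <- h >= hlim[1] & h <= hlim[2] & v >= vlim[1] & v <= vlim[2]
  h <- h[keep]; v <- v[keep]
  hi <- pmin(findInterval(h, hbreaks), length(hbreaks) - 1)
  vi <- pmin(findInterval(v, vbreaks), length(vbreaks) - 1)
  counts <- matrix(0, nrow = length(hbreaks) - 1, ncol = length(vbreaks) - 1)
  if (length(h) > 0) {
    tab <- table(factor(hi, levels = seq_len(nrow(counts))),
                 factor(vi, levels = seq_len(ncol(counts))))
    counts <- matrix(as.numeric(tab), nrow = nrow(counts))
  }
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else counts
  grid <- tidyr::expand_grid(
    hi = seq_len(nrow(counts)), vi = seq_len(ncol(counts))) %>%
    mutate(h = hbreaks[.data$hi] + bin / 2,
           v = vbreaks[.data$vi] + bin / 2,
           pct = pct[cbind(.data$hi, .data$vi)]) %>%
    select(all_of(c("h", "v", "pct")))
  structure(grid,
            class = c("tv_occupancy", class(grid)),
            view = view, bin_size = bin, empty = total == 0)
}

#' Convert an occupancy map to a dense matrix
#'
#' @param map A `tv_occupancy` tibble.
#' @return Numeric matrix of percentages, rows = downwind (x) bins,
#'   columns = cross-wind or vertical bins.
#' @export
occupancy_matrix <- function(map) {
  hs <- sort(unique(map$h)); vs <- sort(unique(map$v))
  m <- matrix(0, length(hs), length(vs), dimnames = list(
    sprintf("%.3f", hs), sprintf("%.3f", vs)))
  m[cbind(match(map$h, hs), match(map$v, vs))] <- map$pct
  m
}

#' Write an occupancy map as a dense matrix text file
#'
#' @param map A `tv_occupancy` tibble.
#' @param path Output path (tab-delimited, row/column names are bin-centre
#'   coordinates in cm).
#' @return `path`, invisibly.
#' @export
write_occupancy_matrix <- function(map, path) {
  utils::write.table(occupancy_matrix(map), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
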