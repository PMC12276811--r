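#' Read a 3D trajectory table
#'
#' Reads comma-delimited trajectory exports with one row per tracked sample
#' and columns `run_id, traj_id, frame, x, y, z` (a `t` column is optional
#' and is reconstructed as `frame / frame_rate` when absent). Rows are
#' grouped by trajectory and sorted by frame.
#'
#' @param path Path to a CSV file.
#' @param geometry A [tunnel_geometry()]; supplies the frame rate and, when
#'   `strict = TRUE`, the bounds used for validation.
#' @param strict If `TRUE`, out-of-bounds points raise an error; otherwise
#'   they produce a warning (tracking jitter near walls is common).
#' @return A tibble of track points with columns
#'   `run_id, traj_id, frame, t, x, y, z`, ordered by (run_id, traj_id,
#'   frame).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("run_id,traj_id,frame,x,y,z", "r1,a,0,0,0,10", "r1,a,1,1,0,10"), f)
#' read_trajectories(f)
#' @export
read_trajectories <- function(path, geometry = tunnel_geometry(),
                              strict = FALSE) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("run_id", "traj_id", "frame", "x", "y", "z")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("trajectory file %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  pts <- raw %>%
    mutate(run_id = as.character(.data$run_id),
           traj_id = as.character(.data$traj_id),
           frame = as.integer(.data$frame)) %>%
    arrange(.data$run_id, .data$traj_id, .data$frame)
  if (!"t" %in% names(pts)) {
    pts <- mutate(pts, t = .data$frame / geometry$frame_rate)
  }
  pts <- select(pts, all_of(c("run_id", "traj_id", "frame", "t", "x", "y", "z")))
  validate_trajectories(pts, geometry, strict = strict)
  n_traj <- nrow(distinct(pts, .data$run_id, .data$traj_id))
  inform(sprintf("read %d track points in %d trajectories from %s",
                 nrow(pts), n_traj, path))
  pts
}

#' Validate a trajectory table
#'
#' Checks the track-point invariants: finite coordinates, non-negative
#' frames, strictly increasing frames within each trajectory, and (by
#' warning, or by error under `strict`) containment in the working section.
#'
#' @inheritParams read_trajectories
#' @param trajectories A track-point tibble as returned by
#'   [read_trajectories()].
#' @return The input, invisibly; raises on violation.
#' @export
validate_trajectories <- function(trajectories, geometry = tunnel_geometry(),
                                  strict = FALSE) {
  if (nrow(trajectories) == 0) return(invisible(trajectories))
  with(trajectories, {
    if (any(!is.finite(x) | !is.finite(y) | !is.finite(z))) {
      abort("trajectory coordinates must be finite")
    }
    if (any(frame < 0)) abort("frame indices must be >= 0")
  })
  bad <- trajectories %>%
    group_by(.data$run_id, .data$traj_id) %>%
    summarise(mono = all(diff(.data$frame) > 0), .groups = "drop") %>%
    filter(!.data$mono)
  if (nrow(bad) > 0) {
    abort(sprintf("non-monotone frames within trajectory id(s): %s",
                  paste(bad$traj_id, collapse = ", ")))
  }
  b <- geometry_bounds(geometry)
  out <- with(trajectories,
              x < b$x[1] | x > b$x[2] | y < b$y[1] | y > b$y[2] |
                z < b$z[1] | z > b$z[2])
  if (any(out)) {
    msg <- sprintf("%d track point(s) fall outside the working section", sum(out))
    if (strict) abort(msg) else warn(msg)
  }
  invisible(trajectories)
}

#' Write a trajectory table
#'
#' @param trajectories Track-point tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  readr::write_csv(trajectories, path, progress = FALSE)
  invisible(path)
}

schedule_columns <- c("period_id", "phase", "t_start", "t_end",
                      "test_channel", "test_intensity",
                      "control_channel", "control_intensity",
                      "co2_percent", "odor",
                      "test_x", "test_y", "control_x", "control_y")

#' Read a run schedule
#'
#' A run schedule describes the ordered stimulus periods of one bioassay
#' release: for each period, the test and control stimuli (LED channel or
#' symbolic achromatic stimulus, plus relative intensity), the odor
#' condition, and the period's time window. Schedules are YAML (or JSON)
#' with an optional `geometry` block and a `periods` list; see
#' [write_run_schedule()] for the layout.
#'
#' @param path Path to a YAML/JSON schedule file.
#' @return A tibble of periods, time-ordered, with attribute `"geometry"`.
#' @export
read_run_schedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$periods)) abort(sprintf("schedule %s has no 'periods' list", path))
  geometry <- if (!is.null(cfg$geometry)) {
    do.call(tunnel_geometry, cfg$geometry)
  } else {
    tunnel_geometry()
  }
  pos <- default_stimulus_positions()
  periods <- purrr::map_dfr(cfg$periods, function(p) {
    tibble(
      period_id = as.character(p$period_id %||% NA_character_),
      phase = p$phase %||% "main",
      t_start = as.numeric(p$t_start), t_end = as.numeric(p$t_end),
      test_channel = as.character(p$test$channel %||% p$test_channel),
      test_intensity = as.numeric(p$test$intensity %||% p$test_intensity %||% 1),
      control_channel = as.character(p$control$channel %||% p$control_channel %||% "gray"),
      control_intensity = as.numeric(p$control$intensity %||% p$control_intensity %||% 0.5),
      co2_percent = as.numeric(p$co2_percent %||% 0),
      odor = as.character(p$odor %||% "none"),
      test_x = as.numeric(p$test_x %||% pos$test[["x"]]),
      test_y = as.numeric(p$test_y %||% pos$test[["y"]]),
      control_x = as.numeric(p$control_x %||% pos$control[["x"]]),
      control_y = as.numeric(p$control_y %||% pos$control[["y"]])
    )
  })
  if (any(is.na(periods$period_id))) {
    periods$period_id <- ifelse(is.na(periods$period_id),
                                sprintf("p%02d", seq_len(nrow(periods))),
                                periods$period_id)
  }
  validate_schedule(periods)
  attr(periods, "geometry") <- geometry
  periods
}

validate_schedule <- function(periods) {
  stopifnot(is.data.frame(periods))
  if (any(!(periods$t_start < periods$t_end))) {
    abort("every period must satisfy t_start < t_end")
  }
  validate_channel(periods$test_channel)
  validate_channel(periods$control_channel)
  if (!all(periods$phase %in% c("pre_clean_air", "main", "post_clean_air"))) {
    abort("phase must be one of pre_clean_air, main, post_clean_air")
  }
  ord <- order(periods$t_start)
  s <- periods$t_start[ord]; e <- periods$t_end[ord]
  if (any(utils::head(e, -1) > utils::tail(s, -1) + 1e-9)) {
    abort("stimulus periods overlap")
  }
  if (any(periods$test_intensity < 0 | periods$test_intensity > 3 |
            periods$control_intensity < 0 | periods$control_intensity > 3)) {
    abort("relative intensities must lie in [0, 3]")
  }
  invisible(periods)
}

#' Write a run schedule
#'
#' Serializes a period tibble (plus geometry) to YAML in the layout
#' [read_run_schedule()] consumes.
#'
#' @param periods Period tibble.
#' @param path Output path.
#' @param geometry Geometry to embed; defaults to the tibble's
#'   `"geometry"` attribute.
#' @return `path`, invisibly.
#' @export
write_run_schedule <- function(periods, path,
                               geometry = attr(periods, "geometry")) {
  geometry <- geometry %||% tunnel_geometry()
  cfg <- list(
    geometry = geometry[c("length", "width", "height", "wind_speed", "frame_rate")],
    periods = purrr::pmap(periods, function(...) {
      p <- list(...)
      list(period_id = p$period_id, phase = p$phase,
           t_start = p$t_start, t_end = p$t_end,
           test = list(channel = p$test_channel, intensity = p$test_intensity),
           control = list(channel = p$control_channel, intensity = p$control_intensity),
           co2_percent = p$co2_percent, odor = p$odor,
           test_x = p$test_x, test_y = p$test_y,
           control_x = p$control_x, control_y = p$control_y)
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write and read result tables
#'
#' All result records (preference records, period summaries, QC reports,
#' contrast tables, fitted-curve evaluations) are plain delimited text.
#' Undefined values (for example the preference index of a trajectory that
#' entered neither volume) serialize as the explicit token `NA` and
#' round-trip losslessly.
#'
#' @param records A data frame of result records.
#' @param path Output CSV path.
#' @return For `write_table()`, `path` invisibly; for `read_table()`, a
#'   tibble.
#' @export
write_table <- function(records, path) {
  readr::write_csv(records, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  readr::read_csv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
}
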