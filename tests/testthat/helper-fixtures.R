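# shared fixtures: all built in code at test time

toy_geometry <- function() tunnel_geometry()

# a trajectory table from explicit coordinates
pts_tbl <- function(x, y, z, frame = seq_along(x) - 1L, run_id = "r1",
                    traj_id = "t1", frame_rate = 60) {
  tibble::tibble(run_id = run_id, traj_id = traj_id, frame = as.integer(frame),
                 t = frame / frame_rate, x = x, y = y, z = z)
}

# a straight-line trajectory of n frames at a fixed point (degenerate but
# legal for metric tests)
still_track <- function(n, at = c(0, 0, 10), run_id = "r1", traj_id = "t1",
                        frame0 = 0L) {
  pts_tbl(rep(at[1], n), rep(at[2], n), rep(at[3], n),
          frame = frame0 + seq_len(n) - 1L, run_id = run_id,
          traj_id = traj_id)
}

# random trajectory table within the working section
random_tracks <- function(n_traj, len_range = c(5, 120), seed = 1) {
  set.seed(seed)
  g <- geometry_bounds(tunnel_geometry())
  purrr::map_dfr(seq_len(n_traj), function(i) {
    n <- sample(len_range[1]:len_range[2], 1)
    pts_tbl(runif(n, g$x[1], g$x[2]), runif(n, g$y[1], g$y[2]),
            runif(n, g$z[1], g$z[2]), traj_id = sprintf("t%03d", i))
  })
}

test_vol <- function() response_volume(-56, -15.25)
control_vol <- function() response_volume(-56, 15.25)

# independent brute-force membership check (loop, no package internals)
brute_in_volume <- function(df, vol) {
  out <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    dx <- df$x[i] - vol$center_x
    dy <- df$y[i] - vol$center_y
    out[i] <- sqrt(dx^2 + dy^2) <= vol$diameter / 2 &&
      df$z[i] >= vol$z_base && df$z[i] <= vol$z_base + vol$height
  }
  out
}

# minimal hand-rolled fit container for pure-arithmetic LRT checks
fake_fit <- function(logLik, df, n_obs = 100) {
  structure(list(logLik = logLik, df = df, n_obs = n_obs, converged = TRUE),
            class = "tv_bbfit")
}

fast_cfg <- function(...) {
  sim_config(...)
}
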