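# Agent-based generator of wind-tunnel runs. Flight is a fixed-speed
# correlated random walk with reflecting walls; responses (activation,
# recruitment, dwell split between the two response volumes) are drawn
# from the same logistic/beta-binomial structure the analysis assumes, so
# metrics computed on simulated runs recover the configured surfaces.

#' Simulation configuration
#'
#' Bundles the tunnel geometry, stimulus schedule template and behavioral
#' parameters of the generator. Defaults emulate the study conditions of
#' the wind-tunnel bioassays: releases of 50 mosquitos tracked at 60 Hz,
#' pre/post clean-air periods around a main series (a 17-channel spectral
#' sweep at isoquantal intensity 1.0, or an intensity ramp spanning nominal
#' 0-3), CO2-gated recruitment to two circular floor targets, a spectral
#' preference curve lowest in the 475-575 nm green band, achromatic and
#' ramp preferences following a four-parameter log-logistic in relative
#' intensity, per-run random intercepts and beta-binomial overdispersion.
#'
#' @param geometry [tunnel_geometry()].
#' @param template `"spectral_sweep"` or `"intensity_ramp"`.
#' @param channels Peak wavelengths for the sweep (nm).
#' @param ramp_channel Channel for the intensity ramp (a wavelength or
#'   `"gray"`).
#' @param ramp_intensities Nominal intensities of the ramp (0-3, relative
#'   to the isoquantal level).
#' @param n_mosquitos Mosquitos released per run.
#' @param period_s,clean_air_s Durations (s) of main and clean-air periods.
#' @param co2_percent CO2 concentration of the plume in the main periods
#'   (0 disables gating).
#' @param odor Odor paired with the CO2 plume: `"none"`, `"floral"`,
#'   `"host"`, `"oviposition"` or `"humidity"`.
#' @param activation_base Expected trajectories per period in clean air.
#' @param activation_co2_gain Multiplier on activation when CO2 is present.
#' @param recruit_base Per-trajectory recruitment probability without CO2.
#' @param recruit_co2_logit_gain Logit-scale recruitment gain from CO2.
#' @param recruit_spectral_depth,recruit_intensity_slope Mild
#'   wavelength/intensity dependence of recruitment (logit scale).
#' @param pref_ceiling,pref_green_depth,pref_center,pref_width Spectral
#'   preference curve on the logit scale: an inverted Gaussian,
#'   `ceiling - depth * exp(-(lambda - center)^2 / (2 width^2))`.
#' @param green_band Wavelength band (nm) receiving odor-specific boosts.
#' @param green_boost_floral,green_boost_oviposition Logit boost applied
#'   inside the green band by floral / oviposition odors.
#' @param host_uniform_boost Logit boost applied at all wavelengths by host
#'   odor.
#' @param intensity_curve LL4 parameters (list `b, c, d, e` on the
#'   preference-index scale) governing achromatic stimuli and intensity
#'   ramps; per-channel overrides via `intensity_curves`.
#' @param intensity_curves Named list of per-channel LL4 overrides.
#' @param ambient_rel_intensity Relative intensity of the unilluminated
#'   tulle target due to ambient light (keeps ramp intensities strictly
#'   positive).
#' @param sigma_run SD of the per-run x stimulus-pair preference intercept.
#' @param sigma_run_recruit SD of the single per-run recruitment intercept.
#' @param phi Beta-binomial precision of the dwell split.
#' @param dwell_mean_s,dwell_min_frames Mean total dwell (s) and minimum
#'   dwell (frames) of a recruited trajectory.
#' @param speed Flight speed, cm/s.
#' @param turn_sd SD of the per-frame heading increment (rad).
#' @param short_track_fraction Fraction of tracks shorter than 90 frames,
#'   exercising the length filter.
#' @return A list of class `tv_sim_config`.
#' @export
sim_config <- function(geometry = tunnel_geometry(),
                       template = c("spectral_sweep", "intensity_ramp"),
                       channels = led_channel_wavelengths(),
                       ramp_channel = 527,
                       ramp_intensities = c(0, 0.125, 0.25, 0.5, 1, 2, 3),
                       n_mosquitos = 50,
                       period_s = 90, clean_air_s = 120,
                       co2_percent = 10, odor = "none",
                       activation_base = 10, activation_co2_gain = 2.5,
                       recruit_base = 0.004, recruit_co2_logit_gain = 2.6,
                       recruit_spectral_depth = 0.4,
                       recruit_intensity_slope = 0.25,
                       pref_ceiling = 0.85, pref_green_depth = 1.25,
                       pref_center = 525, pref_width = 60,
                       green_band = c(475, 575),
                       green_boost_floral = 0.8,
                       green_boost_oviposition = 0.6,
                       host_uniform_boost = 0.4,
                       intensity_curve = list(b = 2, c = -0.6, d = 0.5, e = 0.8),
                       intensity_curves = list(),
                       ambient_rel_intensity = 0.08,
                       sigma_run = 0.5, sigma_run_recruit = 0.4,
                       phi = 8,
                       dwell_mean_s = 1.5, dwell_min_frames = 30,
                       speed = 50, turn_sd = 0.35,
                       short_track_fraction = 0.15) {
  template <- arg_match(template)
  cfg <- as.list(environment())
  stopifnot(cfg$n_mosquitos >= 1, cfg$phi > 0, cfg$sigma_run >= 0,
            cfg$sigma_run_recruit >= 0, cfg$recruit_base > 0,
            cfg$recruit_base < 1, cfg$speed > 0,
            cfg$short_track_fraction >= 0, cfg$short_track_fraction <= 1)
  structure(cfg, class = "tv_sim_config")
}

#' Build the stimulus schedule for a simulated run
#'
#' Pre clean-air period, then the main series (one period per sweep
#' channel, or per ramp intensity), then post clean-air. Clean-air periods
#' present an unilluminated black tulle target against the mid-gray
#' control, the most attractive pairing, so odor contamination is readily
#' detected by QC.
#'
#' @param config A [sim_config()].
#' @return Period tibble (see [read_run_schedule()]) with geometry
#'   attribute.
#' @export
build_schedule <- function(config) {
  pos <- default_stimulus_positions()
  mk <- function(phase, channel, intensity, co2, t0, dur) {
    tibble(period_id = NA_character_, phase = phase,
           t_start = t0, t_end = t0 + dur,
           test_channel = as.character(channel), test_intensity = intensity,
           control_channel = "gray", control_intensity = 0.5,
           co2_percent = co2, odor = if (co2 > 0) config$odor else "none",
           test_x = pos$test[["x"]], test_y = pos$test[["y"]],
           control_x = pos$control[["x"]], control_y = pos$control[["y"]])
  }
  t0 <- 0
  rows <- list(mk("pre_clean_air", "black_tulle", 0, 0, t0, config$clean_air_s))
  t0 <- config$clean_air_s
  if (config$template == "spectral_sweep") {
    for (ch in config$channels) {
      rows <- c(rows, list(mk("main", ch, 1.0, config$co2_percent, t0,
                              config$period_s)))
      t0 <- t0 + config$period_s
    }
  } else {
    for (x in config$ramp_intensities) {
      rows <- c(rows, list(mk("main", config$ramp_channel, x,
                              config$co2_percent, t0, config$period_s)))
      t0 <- t0 + config$period_s
    }
  }
  rows <- c(rows, list(mk("post_clean_air", "black_tulle", 0, 0, t0,
                          config$clean_air_s)))
  sched <- bind_rows(rows)
  sched$period_id <- sprintf("p%02d", seq_len(nrow(sched)))
  attr(sched, "geometry") <- config$geometry
  sched
}

ll4_params_for <- function(config, channel) {
  over <- config$intensity_curves[[as.character(channel)]]
  if (is.null(over)) config$intensity_curve else
    modifyList(config$intensity_curve, over)
}

is_achromatic <- function(channel) {
  is.na(suppressWarnings(as.numeric(as.character(channel))))
}

#' Configured preference surface on the logit scale
#'
#' The expected dwell-split probability of a recruited trajectory, before
#' the run random effect: achromatic stimuli and intensity ramps follow
#' the configured four-parameter log-logistic in intensity relative to the
#' tulle target; spectral-sweep channels follow the inverted-Gaussian
#' spectral curve plus the odor shift (green-band boost for
#' floral/oviposition odors, uniform boost for host odor).
#'
#' @param config A [sim_config()].
#' @param channel Stimulus channel (wavelength or symbolic).
#' @param intensity Nominal relative intensity (0-3).
#' @param odor Odor condition.
#' @return `logit(p)` where `E[pi] = 2p - 1`.
#' @export
pref_logit_surface <- function(config, channel, intensity, odor = "none") {
  wl <- suppressWarnings(as.numeric(as.character(channel)))
  ramp_like <- is.na(wl) || config$template == "intensity_ramp"
  base <- if (ramp_like) {
    p <- ll4_params_for(config, channel)
    x <- intensity + config$ambient_rel_intensity
    pi_mean <- ll4(x, p$b, p$c, p$d, p$e)
    qlogis(pmin(pmax((pi_mean + 1) / 2, 1e-6), 1 - 1e-6))
  } else {
    config$pref_ceiling - config$pref_green_depth *
      exp(-(wl - config$pref_center)^2 / (2 * config$pref_width^2))
  }
  base + odor_shift(config, wl, odor)
}

odor_shift <- function(config, wl, odor) {
  in_band <- !is.na(wl) & wl >= config$green_band[1] & wl <= config$green_band[2]
  switch(odor,
         floral = config$green_boost_floral * in_band,
         oviposition = config$green_boost_oviposition * in_band,
         host = config$host_uniform_boost,
         0)
}

recruit_logit_surface <- function(config, channel, intensity, co2) {
  wl <- suppressWarnings(as.numeric(as.character(channel)))
  eff <- if (is.na(wl)) {
    -config$recruit_intensity_slope *
      (intensity + config$ambient_rel_intensity - 1)
  } else {
    -config$recruit_spectral_depth *
      exp(-(wl - config$pref_center)^2 / (2 * config$pref_width^2))
  }
  qlogis(config$recruit_base) + config$recruit_co2_logit_gain * (co2 > 0) + eff
}

# triangle-wave fold of an unbounded coordinate into [lo, hi]: a
# reflecting-wall path with chord lengths <= the free-flight step
fold_into <- function(v, lo, hi) {
  w <- hi - lo
  u <- (v - lo) %% (2 * w)
  lo + pmin(u, 2 * w - u)
}

# correlated random walk at fixed speed, vectorized; returns n x 3 matrix
crw_path <- function(n, p0, ds, turn_sd, bounds, az0 = runif(1, 0, 2 * pi)) {
  if (n <= 0) return(matrix(numeric(0), 0, 3))
  az <- cumsum(c(az0, rnorm(n - 1, 0, turn_sd)))
  # mean-reverting pitch keeps flight roughly level
  pitch <- as.numeric(stats::filter(rnorm(n, 0, 0.08), 0.95,
                                    method = "recursive"))
  pitch <- pmin(pmax(pitch, -0.6), 0.6)
  x <- p0[1] + cumsum(ds * cos(pitch) * cos(az))
  y <- p0[2] + cumsum(ds * cos(pitch) * sin(az))
  z <- p0[3] + cumsum(ds * sin(pitch))
  cbind(fold_into(x, bounds$x[1], bounds$x[2]),
        fold_into(y, bounds$y[1], bounds$y[2]),
        fold_into(z, bounds$z[1], bounds$z[2]))
}

# straight transit from p (exclusive) toward q at step ds
line_path <- function(p, q, ds) {
  d <- sqrt(sum((q - p)^2))
  k <- max(1L, ceiling(d / ds))
  f <- seq_len(k) / k
  cbind(p[1] + f * (q[1] - p[1]), p[2] + f * (q[2] - p[2]),
        p[3] + f * (q[3] - p[3]))
}

# CRW dwell inside a box inscribed in the response cylinder
dwell_path <- function(n, p0, ds, turn_sd, volume) {
  half <- volume$diameter / 2 / sqrt(2) * 0.99
  bounds <- list(x = volume$center_x + c(-half, half),
                 y = volume$center_y + c(-half, half),
                 z = c(volume$z_base + 0.12 * volume$height,
                       volume$z_base + volume$height - 0.2 * ds))
  p0 <- c(fold_into(p0[1], bounds$x[1], bounds$x[2]),
          fold_into(p0[2], bounds$y[1], bounds$y[2]),
          fold_into(p0[3], bounds$z[1], bounds$z[2]))
  crw_path(n, p0, ds, turn_sd, bounds)
}

# One volume visit realizing exactly n in-volume frames: entry by
# vertical descent from the transit altitude (the frame just below the
# cylinder top is the first counted frame), a CRW dwell inside the
# cylinder, and a vertical exit ascent whose five below-top frames
# complete the count. All transit between visits happens above the
# cylinders, so no stray in-volume frames arise from recruited tracks.
visit_volume <- function(cur, n, volume, ds, turn_sd, alt) {
  ztop <- volume$z_base + volume$height
  half <- volume$diameter / 2 * 0.55
  ex <- volume$center_x + runif(1, -half, half)
  ey <- volume$center_y + runif(1, -half, half)
  cruise <- line_path(cur, c(ex, ey, alt), ds)
  desc_zs <- c(seq(alt - ds, ztop + 0.3 * ds, by = -ds), ztop + 0.3 * ds)
  desc_zs <- desc_zs[desc_zs > ztop + 0.25 * ds]
  if (n <= 6) {
    # shallow dip at half speed: a vertical V with exactly n frames below
    # the cylinder top, re-emerging clear of the (inclusive) boundary
    k1 <- ceiling(n / 2); k2 <- n - k1
    zs <- c(ztop - 0.5 * ds * seq_len(k1),
            if (k2 > 0) ztop - 0.5 * ds * rev(seq_len(k2)) + 0.25 * ds
            else numeric(0))
    up <- seq(ztop + 0.5 * ds, alt, by = ds)
    dip <- cbind(ex, ey, c(desc_zs, zs, up))
    return(rbind(cruise, dip))
  }
  entry <- c(ex, ey, ztop - 0.2 * ds)
  # n - 6 CRW dwell frames, then a five-frame sub-top ascent: in-volume
  # count = 1 (entry) + (n - 6) + 5 = n exactly
  m <- n - 6
  dwell <- dwell_path(m, entry, ds, turn_sd, volume)
  dend <- dwell[m, ]
  span <- (ztop - 0.05 * ds) - dend[3]
  rise_in <- dend[3] + span * seq_len(5) / 5
  rise_out <- seq(ztop + 0.95 * ds, alt, by = ds)
  ascent <- cbind(dend[1], dend[2], c(rise_in, rise_out))
  rbind(cruise, cbind(ex, ey, desc_zs), matrix(entry, 1, 3), dwell, ascent)
}

# assemble one trajectory's position matrix; dwell counts are injected
# exactly so downstream metrics recover them (up to rare chance passages
# of the free-flight segments)
build_track <- function(config, n_frames, n_test = 0, n_control = 0,
                        test_volume = NULL, control_volume = NULL,
                        zfloor = NULL) {
  ds <- config$speed / config$geometry$frame_rate
  b <- geometry_bounds(config$geometry)
  recruited <- n_test + n_control > 0
  # tracks not engaged with a target cruise above the response cylinders:
  # within a run this keeps non-responding flight out of the scoring
  # volumes (approach there is what the recruitment process models), and
  # for recruited tracks it keeps the injected dwell counts exact
  if (is.null(zfloor)) zfloor <- if (recruited) 5 else 4.5
  bounds <- list(x = b$x + c(1, -1), y = b$y + c(1, -1),
                 z = c(zfloor, b$z[2] - 1))
  p0 <- c(runif(1, bounds$x[1], bounds$x[2]),
          runif(1, bounds$y[1], bounds$y[2]),
          runif(1, bounds$z[1], bounds$z[2]))
  if (!recruited) {
    return(crw_path(n_frames, p0, ds, config$turn_sd, bounds))
  }
  alt <- 8  # transit altitude, above the cylinder tops
  w1 <- max(10L, floor(0.1 * n_frames))
  parts <- list(crw_path(w1, p0, ds, config$turn_sd, bounds))
  visits <- list(list(vol = test_volume, n = n_test),
                 list(vol = control_volume, n = n_control))
  if (runif(1) < 0.5) visits <- rev(visits)
  for (v in visits) {
    if (v$n <= 0) next
    cur <- parts[[length(parts)]]
    cur <- cur[nrow(cur), ]
    parts <- c(parts,
               list(visit_volume(cur, v$n, v$vol, ds, config$turn_sd * 2, alt)))
  }
  used <- sum(vapply(parts, nrow, integer(1)))
  pad <- n_frames - used
  if (pad > 0) {
    cur <- parts[[length(parts)]]
    cur <- cur[nrow(cur), ]
    parts <- c(parts, list(crw_path(pad, cur, ds, config$turn_sd, bounds)))
  }
  do.call(rbind, parts)
}

#' Simulate a single flight trajectory
#'
#' Generates one correlated-random-walk trajectory at the configured speed
#' and frame rate inside the working section (reflecting walls). Approach
#' modes steer to the requested response volume and dwell there;
#' `dwell_split` sets the expected fraction of dwell frames spent in the
#' approached (test) volume versus the other.
#'
#' @param config A [sim_config()].
#' @param mode `"wander"`, `"approach_test"` or `"approach_control"`.
#' @param n_frames Track length in frames (>= 90 unless simulating a
#'   censored fragment).
#' @param dwell_frames Total dwell frames for approach modes.
#' @param dwell_split Binomial probability that a dwell frame falls in the
#'   test volume (approach_test) or control volume (approach_control).
#' @param t0 Start time (s).
#' @param run_id,traj_id Identifiers.
#' @param test_volume,control_volume Response volumes; default placement.
#' @return Track-point tibble.
#' @export
simulate_trajectory <- function(config = sim_config(),
                                mode = c("wander", "approach_test",
                                         "approach_control"),
                                n_frames = 300, dwell_frames = 90,
                                dwell_split = 1, t0 = 0,
                                run_id = "sim", traj_id = "t0001",
                                test_volume = NULL, control_volume = NULL) {
  mode <- arg_match(mode)
  pos <- default_stimulus_positions()
  test_volume <- test_volume %||%
    response_volume(pos$test[["x"]], pos$test[["y"]])
  control_volume <- control_volume %||%
    response_volume(pos$control[["x"]], pos$control[["y"]])
  if (mode == "wander") {
    # the free-wander primitive may explore the full section height,
    # including chance passes through the response volumes
    m <- build_track(config, n_frames, zfloor = 1)
  } else {
    n_pref <- rbinom(1, dwell_frames, dwell_split)
    nt <- if (mode == "approach_test") n_pref else dwell_frames - n_pref
    m <- build_track(config, n_frames, n_test = nt,
                     n_control = dwell_frames - nt,
                     test_volume = test_volume,
                     control_volume = control_volume)
  }
  fr <- config$geometry$frame_rate
  frame0 <- round(t0 * fr)
  tibble(run_id = run_id, traj_id = traj_id,
         frame = frame0 + seq_len(nrow(m)) - 1L,
         t = (frame0 + seq_len(nrow(m)) - 1L) / fr,
         x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Simulate one bioassay run
#'
#' Draws, per scheduled period, an activation count (Poisson, CO2-gated
#' rate), per-trajectory recruitment (logistic, with a single per-run
#' random intercept), and for recruited trajectories a beta-binomial dwell
#' split between the test and control volumes whose expectation follows
#' the configured spectral/intensity/odor preference surface with a per-run
#' x stimulus-pair random intercept. Trajectories are then laid down as
#' correlated random walks that realize those dwell counts exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the run is bit-reproducible given
#'   (config, seed).
#' @param run_id Identifier.
#' @param cohort Cohort label.
#' @return A `tv_run`: list with `run_id`, `cohort`, `schedule`,
#'   `trajectories`, `geometry`, `seed`; attribute `"truth"` holds the
#'   per-trajectory generative record for recovery testing.
#' @export
simulate_run <- function(config = sim_config(), seed = 1L, run_id = "run001",
                         cohort = "cohort1") {
  set.seed(seed)
  sched <- build_schedule(config)
  fr <- config$geometry$frame_rate
  pair_ids <- unique(paste(sched$test_channel, sched$test_intensity))
  u_pref <- setNames(rnorm(length(pair_ids), 0, config$sigma_run), pair_ids)
  u_recruit <- rnorm(1, 0, config$sigma_run_recruit)

  mats <- list()
  ids <- list()
  frame0s <- integer(0)
  truth <- list()
  truth_meta <- list()
  for (i in seq_len(nrow(sched))) {
    p <- sched[i, ]
    vols <- period_volumes(p)
    rate <- config$activation_base *
      if (p$co2_percent > 0) config$activation_co2_gain else 1
    n_traj <- rpois(1, rate)
    if (n_traj == 0) next
    pair <- paste(p$test_channel, p$test_intensity)
    logit_r <- recruit_logit_surface(config, p$test_channel,
                                     p$test_intensity, p$co2_percent) +
      u_recruit
    logit_p <- pref_logit_surface(config, p$test_channel, p$test_intensity,
                                  p$odor) + u_pref[[pair]]
    short <- runif(n_traj) < config$short_track_fraction
    len <- ifelse(short, sample(20:89, n_traj, replace = TRUE),
                  90 + rpois(n_traj, 120))
    recruited <- !short & rbinom(n_traj, 1, plogis(logit_r)) == 1
    dur <- p$t_end - p$t_start
    for (j in seq_len(n_traj)) {
      nf <- min(len[j], floor(dur * fr) - 1)
      nt <- 0L; ntot <- 0L
      if (recruited[j]) {
        ntot <- config$dwell_min_frames +
          rpois(1, max(config$dwell_mean_s * fr - config$dwell_min_frames, 1))
        pr <- rbeta(1, plogis(logit_p) * config$phi,
                    (1 - plogis(logit_p)) * config$phi)
        nt <- rbinom(1, ntot, pr)
        nf <- max(nf, 90)
        m <- build_track(config, nf, n_test = nt, n_control = ntot - nt,
                         test_volume = vols$test,
                         control_volume = vols$control)
      } else {
        m <- build_track(config, nf)
      }
      t0 <- runif(1, p$t_start, max(p$t_start, p$t_end - nrow(m) / fr - 1 / fr))
      id <- sprintf("%s_%s_t%03d", run_id, p$period_id, j)
      mats[[length(mats) + 1]] <- m
      ids[[length(ids) + 1]] <- id
      frame0s <- c(frame0s, as.integer(round(t0 * fr)))
      truth[[length(truth) + 1]] <- c(nt, ntot)
    }
    truth_meta[[length(truth_meta) + 1]] <- tibble(
      run_id = run_id, period_id = p$period_id,
      short = short, recruited = recruited,
      p_recruit = plogis(logit_r), p_pref = plogis(logit_p))
  }
  lens <- vapply(mats, nrow, integer(1))
  frames <- unlist(purrr::map2(frame0s, lens, function(f0, k)
    f0 + seq_len(k) - 1L))
  pts <- if (length(mats) > 0) {
    m <- do.call(rbind, mats)
    tibble(run_id = run_id,
           traj_id = rep(unlist(ids), lens),
           frame = frames, t = frames / fr,
           x = m[, 1], y = m[, 2], z = m[, 3])
  } else {
    tibble(run_id = character(0), traj_id = character(0),
           frame = integer(0), t = numeric(0),
           x = numeric(0), y = numeric(0), z = numeric(0))
  }
  run <- structure(list(
    run_id = run_id, cohort = cohort, schedule = sched,
    trajectories = pts, geometry = config$geometry,
    seed = seed), class = "tv_run")
  counts <- if (length(truth) > 0) do.call(rbind, truth) else
    matrix(integer(0), 0, 2)
  tr <- bind_rows(truth_meta)
  tr$traj_id <- unlist(ids) %||% character(0)
  tr$n_test <- counts[, 1]
  tr$n_total <- counts[, 2]
  attr(run, "truth") <- tr
  run
}

#' @export
print.tv_run <- function(x, ...) {
  cat(sprintf("<wind-tunnel run %s> %d periods, %d trajectories, %d points (seed %d)\n",
              x$run_id, nrow(x$schedule),
              nrow(distinct(x$trajectories, .data$traj_id)),
              nrow(x$trajectories), x$seed))
  invisible(x)
}

#' Simulate a cohort of replicate runs
#'
#' Independent runs with independent random intercepts; run seeds are
#' derived deterministically from the cohort seed.
#'
#' @param config A [sim_config()].
#' @param n_runs Number of replicate bioassay runs.
#' @param seed Cohort seed.
#' @param cohort Cohort label.
#' @return List of `tv_run` objects, with attribute `"manifest"` recording
#'   the per-run seeds and key parameters.
#' @export
simulate_cohort <- function(config = sim_config(), n_runs = 10, seed = 1L,
                            cohort = "cohort1") {
  stopifnot(n_runs >= 1)
  seeds <- (as.integer(seed) + 7919L * seq_len(n_runs)) %% 2147483647L
  runs <- purrr::map(seq_len(n_runs), function(i) {
    simulate_run(config, seed = seeds[i],
                 run_id = sprintf("%s_run%03d", cohort, i), cohort = cohort)
  })
  attr(runs, "manifest") <- list(
    cohort = cohort, n_runs = n_runs, seed = seed, run_seeds = seeds,
    template = config$template, odor = config$odor,
    co2_percent = config$co2_percent,
    parameters = unclass(config)[!vapply(config, is.list, logical(1)) &
                                   names(config) != "geometry"])
  runs
}

#' Record-level beta-binomial generator
#'
#' Draws (successes, trials) records directly from the beta-binomial mixed
#' model — the distributional core of the full simulator without the
#' flight layer — for parameter-recovery and calibration studies.
#'
#' @param n_clusters Number of clusters (runs).
#' @param obs_per_cluster Records per cluster.
#' @param mu Marginal mean on the probability scale (scalar, or one value
#'   per cluster).
#' @param phi Beta-binomial precision.
#' @param sigma SD of the cluster random intercept (logit scale).
#' @param trials_mean Mean trials per record (Poisson, shifted to >= 10).
#' @param seed Integer seed.
#' @param cluster_prefix Prefix for cluster ids.
#' @return Tibble `cluster, successes, trials` with attribute `"u"` (the
#'   drawn intercepts).
#' @export
simulate_betabinom_records <- function(n_clusters, obs_per_cluster, mu,
                                       phi = 8, sigma = 0.5,
                                       trials_mean = 60, seed = 1L,
                                       cluster_prefix = "run") {
  set.seed(seed)
  mu <- rep_len(mu, n_clusters)
  u <- rnorm(n_clusters, 0, sigma)
  recs <- purrr::map_dfr(seq_len(n_clusters), function(j) {
    n <- 10 + rpois(obs_per_cluster, max(trials_mean - 10, 1))
    p <- plogis(qlogis(mu[j]) + u[j])
    pr <- if (is.infinite(phi)) rep(p, obs_per_cluster) else
      rbeta(obs_per_cluster, p * phi, (1 - p) * phi)
    tibble(cluster = sprintf("%s%04d", cluster_prefix, j),
           successes = rbinom(obs_per_cluster, n, pr), trials = n)
  })
  attr(recs, "u") <- u
  recs
}

#' Write a simulated run to disk
#'
#' Emits the exact external interfaces the readers consume: the trajectory
#' CSV, the schedule YAML and a JSON manifest with the seed and parameters.
#'
#' @param run A `tv_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectories(run$trajectories,
                     file.path(dir, paste0(run$run_id, "_trajectories.csv")))
  write_run_schedule(run$schedule,
                     file.path(dir, paste0(run$run_id, "_schedule.yaml")),
                     geometry = run$geometry)
  jsonlite::write_json(
    list(run_id = run$run_id, cohort = run$cohort, seed = run$seed),
    file.path(dir, paste0(run$run_id, "_manifest.json")),
    auto_unbox = TRUE)
  invisible(dir)
}

#' Read a run back from disk
#'
#' @param dir Directory written by [write_run()].
#' @param run_id Run identifier.
#' @return A `tv_run` (without the generative truth attribute).
#' @export
read_run <- function(dir, run_id) {
  sched <- read_run_schedule(file.path(dir, paste0(run_id, "_schedule.yaml")))
  geometry <- attr(sched, "geometry")
  traj <- read_trajectories(file.path(dir, paste0(run_id, "_trajectories.csv")),
                            geometry = geometry)
  man <- jsonlite::read_json(file.path(dir, paste0(run_id, "_manifest.json")))
  structure(list(run_id = run_id, cohort = man$cohort %||% NA_character_,
                 schedule = sched, trajectories = traj, geometry = geometry,
                 seed = man$seed %||% NA_integer_),
            class = "tv_run")
}
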