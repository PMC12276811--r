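#' Prepare preference records for model fitting
#'
#' Restricts to main-phase records with non-zero dwell, attaches the
#' stimulus-pair and cluster labels (run x stimulus pair — the unit that
#' receives a preference random intercept), parses numeric wavelengths and
#' flags the green band.
#'
#' @param preferences Preference records with schedule metadata, as from
#'   [score_cohort()].
#' @param green_band Wavelength band (nm) flagged as `band = "green"`.
#' @return Modeling tibble with columns `successes`, `trials`, `cluster`,
#'   `pair`, `wavelength`, `band` added.
#' @export
prepare_preference_data <- function(preferences, green_band = c(475, 575)) {
  preferences %>%
    filter(.data$phase == "main", .data$n_trials > 0) %>%
    mutate(
      successes = .data$n_test,
      trials = .data$n_trials,
      pair = paste(.data$test_channel, .data$test_intensity),
      cluster = paste(.data$run_id, .data$pair),
      wavelength = suppressWarnings(as.numeric(.data$test_channel)),
      band = factor(
        ifelse(!is.na(.data$wavelength) &
                 .data$wavelength >= green_band[1] &
                 .data$wavelength <= green_band[2],
               "green", "out"),
        levels = c("out", "green"))
    )
}

#' Prepare period summaries for recruitment models
#'
#' Period-level records: successes = recruited trajectories, trials =
#' activation, a single random intercept per run.
#'
#' @param summaries Period summaries from [score_cohort()].
#' @return Modeling tibble (main phase only).
#' @export
prepare_recruitment_data <- function(summaries) {
  summaries %>%
    filter(.data$phase == "main", .data$n_trajectories > 0) %>%
    mutate(successes = .data$n_recruited, trials = .data$n_trajectories,
           cluster = .data$run_id,
           wavelength = suppressWarnings(as.numeric(.data$test_channel)))
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  writeLines(line, con)
  inform(line)
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate -> QC -> metrics -> inference (-> dose-response
#' for intensity ramps) -> report, writing every intermediate as plain
#' delimited text so any stage can be re-entered from the previous stage's
#' outputs. Re-running with the same config and seed reproduces the output
#' tables bit-for-bit.
#'
#' @param output_dir Output directory (created).
#' @param config A [sim_config()] describing the cohort to simulate.
#' @param n_runs Number of replicate runs.
#' @param seed Cohort seed.
#' @param runs Optional pre-built list of `tv_run` objects (skips
#'   simulation).
#' @param thresholds QC thresholds, see [qc_thresholds()].
#' @param min_frames Trajectory length filter.
#' @param stages Character subset of
#'   `c("simulate", "qc", "metrics", "infer", "doseresponse", "report")`.
#'   Later stages read intermediates from `output_dir` when earlier stages
#'   are skipped.
#' @return `output_dir`, invisibly. On stage failure the partial outputs
#'   are retained next to a `FAILED` marker naming the stage.
#' @export
run_pipeline <- function(output_dir, config = sim_config(), n_runs = 5,
                         seed = 1L, runs = NULL,
                         thresholds = qc_thresholds(), min_frames = 90,
                         stages = c("simulate", "qc", "metrics", "infer",
                                    "doseresponse", "report")) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(output_dir, "pipeline.log")
  con <- file(logfile, open = "a")
  on.exit(close(con), add = TRUE)
  current <- "setup"
  result <- tryCatch({
    scored <- NULL

    if ("simulate" %in% stages) {
      current <- "simulate"
      if (is.null(runs)) {
        runs <- simulate_cohort(config, n_runs = n_runs, seed = seed)
      }
      pipeline_log(con, current, sprintf("%d runs available", length(runs)))
    }

    if (any(c("qc", "metrics") %in% stages)) {
      current <- "metrics"
      if (is.null(runs)) abort("metrics stage needs runs (enable 'simulate')")
      scored <- score_cohort(runs, min_frames = min_frames)
      write_table(scored$summaries, file.path(output_dir, "period_summaries.csv"))
      write_table(scored$preferences, file.path(output_dir, "preference_records.csv"))
      pipeline_log(con, current, sprintf(
        "%d period summaries, %d preference records",
        nrow(scored$summaries), nrow(scored$preferences)))
      traj_all <- bind_rows(purrr::map(runs, "trajectories")) %>%
        filter_trajectories(min_frames)
      for (view in c("top", "side")) {
        om <- occupancy_map(traj_all, view = view,
                            geometry = config$geometry)
        write_occupancy_matrix(om, file.path(
          output_dir, sprintf("occupancy_%s.tsv", view)))
      }
    }

    if ("qc" %in% stages) {
      current <- "qc"
      qc <- qc_cohort(scored$summaries, thresholds)
      write_table(qc, file.path(output_dir, "qc_report.csv"))
      writeLines(qc$run_id[qc$excluded],
                 file.path(output_dir, "excluded_runs.txt"))
      keep <- qc$run_id[!qc$excluded]
      if (length(keep) == 0) abort("no runs remain after quality control")
      scored$summaries <- filter(scored$summaries, .data$run_id %in% keep)
      scored$preferences <- filter(scored$preferences, .data$run_id %in% keep)
      pipeline_log(con, current, sprintf("%d/%d runs retained",
                                         length(keep), nrow(qc)))
    }

    fits <- NULL
    if ("infer" %in% stages) {
      current <- "infer"
      if (is.null(scored)) {
        scored <- list(
          summaries = read_table(file.path(output_dir, "period_summaries.csv")),
          preferences = read_table(file.path(output_dir, "preference_records.csv")))
      }
      pd <- prepare_preference_data(scored$preferences)
      if (nrow(pd) == 0) abort("no preference records with positive dwell")
      fixed <- if (config$template == "spectral_sweep") ~test_channel else
        ~factor(test_intensity)
      fit <- fit_betabinom_mixed(pd, fixed = fixed, cluster = "cluster")
      null_fit <- fit_betabinom_mixed(pd, fixed = ~1, cluster = "cluster")
      lrt <- likelihood_ratio_test(fit, null_fit)
      grouping <- if (config$template == "spectral_sweep") "test_channel" else
        "test_intensity"
      means <- estimate_group_means(fit, grouping, scale = "preference")
      preds <- predict_run_effects(fit)
      write_table(tidy(fit), file.path(output_dir, "preference_fit.csv"))
      write_table(glance(fit), file.path(output_dir, "preference_fit_glance.csv"))
      write_table(lrt, file.path(output_dir, "stimulus_lrt.csv"))
      write_table(means, file.path(output_dir, "preference_means.csv"))
      write_table(preds, file.path(output_dir, "run_predictions.csv"))

      rd <- prepare_recruitment_data(scored$summaries)
      rfit <- fit_betabinom_mixed(rd, fixed = ~1, cluster = "cluster")
      write_table(glance(rfit), file.path(output_dir, "recruitment_fit_glance.csv"))
      write_table(estimate_group_means(rfit, "phase", scale = "proportion"),
                  file.path(output_dir, "recruitment_mean.csv"))
      pipeline_log(con, current, sprintf(
        "stimulus LRT chi2=%.2f df=%d p=%.3g", lrt$chi2, lrt$df, lrt$p.value))
      fits <- list(preference = fit, means = means, predictions = preds)
    }

    if ("doseresponse" %in% stages && config$template == "intensity_ramp") {
      current <- "doseresponse"
      if (is.null(fits)) abort("dose-response stage needs the 'infer' stage")
      # stage 2: run-level predictions against relative intensity
      xy <- fits$predictions %>%
        mutate(x = as.numeric(sub("^.* ", "", .data$cluster)) +
                 config$ambient_rel_intensity,
               y = .data$fitted_pi,
               run_id = sub(" .*$", "", .data$cluster))
      gray_fit <- fit_asymptotes_from_gray(xy)
      ll4fit <- fit_ll4_fixed_cd(xy, c = gray_fit$c, d = gray_fit$d,
                                 group = paste(config$ramp_channel, config$odor))
      write_table(tidy(gray_fit), file.path(output_dir, "asymptote_fit.csv"))
      write_table(tidy(ll4fit), file.path(output_dir, "ll4_fit.csv"))
      write_table(ll4_curve(ll4fit), file.path(output_dir, "ll4_curve.csv"))
      pipeline_log(con, current, sprintf(
        "LL4: b=%.3f e=%.3f (c=%.3f d=%.3f frozen)",
        ll4fit$b, ll4fit$e, ll4fit$c, ll4fit$d))
    }

    if ("report" %in% stages) {
      current <- "report"
      echo <- list(seed = seed, n_runs = n_runs, min_frames = min_frames,
                   thresholds = thresholds, template = config$template,
                   odor = config$odor, co2_percent = config$co2_percent,
                   stages = stages)
      jsonlite::write_json(echo, file.path(output_dir, "config_echo.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      pipeline_log(con, current, "pipeline complete")
    }
    output_dir
  }, error = function(e) {
    writeLines(sprintf("stage %s failed: %s", current, conditionMessage(e)),
               file.path(output_dir, "FAILED"))
    abort(sprintf("pipeline stage '%s' failed: %s", current,
                  conditionMessage(e)), parent = e)
  })
  invisible(result)
}
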