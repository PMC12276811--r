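#' Run-level quality-control thresholds
#'
#' Runs are excluded wholesale on three independent criteria: (1) strong
#' responses to the visual stimuli during the clean-air-only periods
#' (suggesting odor contamination), (2) generally low visual responses
#' throughout the run (CO2 delivery or animal problems), and (3) much lower
#' responses in one half of the stimulus series than the other (the run
#' fell outside the activity peak). The criteria are qualitative in origin;
#' these numeric commitments make them reproducible and are recorded in the
#' QC report.
#'
#' @param clean_air_max_recruitment Flag 1 threshold: maximum tolerated
#'   recruitment proportion in the pre/post clean-air periods (default 2%).
#' @param min_recruited Flag 2 threshold: minimum total recruited
#'   trajectories across main periods (default 5).
#' @param max_half_ratio Flag 3 threshold: maximum tolerated ratio of
#'   recruited counts between the two halves of the main series
#'   (default 3).
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(clean_air_max_recruitment = 0.02,
                          min_recruited = 5,
                          max_half_ratio = 3) {
  list(clean_air_max_recruitment = clean_air_max_recruitment,
       min_recruited = min_recruited,
       max_half_ratio = max_half_ratio)
}

#' Quality-control report for one run
#'
#' Evaluates the three run-exclusion criteria from the run's period
#' summaries. The clean-air criterion needs pre/post clean-air periods in
#' the schedule; without them it is reported as not evaluable (`NA`), never
#' as a silent pass. The half-imbalance ratio is computed as
#' `(larger + 1) / (smaller + 1)` over recruited counts in the first and
#' second halves of the main series, so runs with empty halves remain
#' comparable.
#'
#' @param summaries Period summaries of a single run, as produced by
#'   [score_run()] (must include the clean-air phases).
#' @param thresholds See [qc_thresholds()].
#' @return One-row tibble: run id, the three flags with their backing
#'   metrics, `excluded` (the OR of the flags, treating a non-evaluable
#'   clean-air flag as FALSE but reporting it), and the thresholds used.
#' @export
qc_run <- function(summaries, thresholds = qc_thresholds()) {
  stopifnot(length(unique(summaries$run_id)) == 1)
  clean <- filter(summaries, .data$phase %in% c("pre_clean_air", "post_clean_air"))
  main <- filter(summaries, .data$phase == "main")
  if (nrow(main) == 0) abort("run has no main stimulus periods")

  if (nrow(clean) == 0) {
    clean_air_recruitment <- NA_real_
    flag_clean_air <- NA
  } else {
    n_act <- sum(clean$n_trajectories)
    clean_air_recruitment <- if (n_act > 0) sum(clean$n_recruited) / n_act else 0
    flag_clean_air <- clean_air_recruitment > thresholds$clean_air_max_recruitment
  }

  total_recruited <- sum(main$n_recruited)
  flag_low <- total_recruited < thresholds$min_recruited

  k <- nrow(main)
  first <- sum(main$n_recruited[seq_len(ceiling(k / 2))])
  second <- total_recruited - first
  half_ratio <- (max(first, second) + 1) / (min(first, second) + 1)
  flag_half <- half_ratio > thresholds$max_half_ratio

  tibble(
    run_id = summaries$run_id[1],
    clean_air_recruitment = clean_air_recruitment,
    flag_clean_air_response = flag_clean_air,
    total_recruited = total_recruited,
    flag_low_response = flag_low,
    half_ratio = half_ratio,
    flag_half_imbalance = flag_half,
    excluded = isTRUE(flag_clean_air) | flag_low | flag_half,
    thr_clean_air = thresholds$clean_air_max_recruitment,
    thr_min_recruited = thresholds$min_recruited,
    thr_half_ratio = thresholds$max_half_ratio
  )
}

#' Quality control across a cohort
#'
#' @param summaries Stacked period summaries (many runs), as from
#'   [score_cohort()].
#' @inheritParams qc_run
#' @return A QC report tibble, one row per run.
#' @export
qc_cohort <- function(summaries, thresholds = qc_thresholds()) {
  summaries %>%
    group_by(.data$run_id) %>%
    dplyr::group_map(~ qc_run(.x %>% mutate(run_id = .y$run_id), thresholds)) %>%
    bind_rows()
}
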