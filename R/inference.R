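#' Likelihood-ratio test between nested fits
#'
#' Tests the overall effect of a stimulus factor by comparing the marginal
#' likelihoods of the model with and without the factor.
#'
#' @param full,reduced `tv_bbfit` objects fitted to the same records, with
#'   the reduced model nested in the full one.
#' @return A one-row tibble: `chi2`, `df`, `p.value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (!inherits(full, "tv_bbfit") || !inherits(reduced, "tv_bbfit")) {
    abort("both arguments must be tv_bbfit objects")
  }
  if (full$n_obs != reduced$n_obs) {
    abort("models were fitted to different numbers of records; not nested")
  }
  df <- full$df - reduced$df
  if (df <= 0) abort("'full' has no more parameters than 'reduced'; not nested")
  chi2 <- max(0, 2 * (full$logLik - reduced$logLik))
  tibble(chi2 = chi2, df = df, p.value = pchisq(chi2, df, lower.tail = FALSE))
}

#' Sidak adjustment for a family of p-values
#'
#' `p_adj = 1 - (1 - p)^m` with `m` the family size (the set of post hoc
#' contrasts requested together). A priori contrasts bypass adjustment.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values, clipped to `[0, 1]`.
#' @examples
#' sidak_adjust(0.01, m = 10)
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(pmax(1 - (1 - p)^m, 0), 1)
}

# average model-matrix rows over observations within each grouping cell:
# proportional (data-frequency) weighting over the remaining factors,
# on the link scale
reference_rows <- function(fit, grouping) {
  dat <- fit$data
  missing <- setdiff(grouping, names(dat))
  if (length(missing) > 0) {
    abort(sprintf("grouping variable(s) not in the model data: %s",
                  paste(missing, collapse = ", ")))
  }
  key <- interaction(dat[grouping], drop = TRUE, lex.order = TRUE)
  G <- rowsum(fit$X, key, reorder = TRUE)
  cnt <- as.numeric(table(key))
  G <- G / cnt
  labels <- distinct(dat[grouping]) %>%
    mutate(.key = interaction(across(all_of(grouping)), drop = TRUE,
                              lex.order = TRUE)) %>%
    arrange(.data$.key) %>%
    select(-all_of(".key"))
  list(G = G, labels = labels)
}

#' Estimated group means with confidence intervals
#'
#' Computes response-scale means per grouping cell from a converged fit.
#' Cell predictors are the data-frequency (proportional) average of the
#' model-matrix rows in the cell; the Wald interval is formed on the logit
#' scale and back-transformed, so endpoints respect the response bounds.
#' For preference models the proportion scale is mapped to the preference
#' index via `pi = 2p - 1`.
#'
#' @param fit A converged `tv_bbfit`.
#' @param grouping Character vector of factor names in the model data (or a
#'   one-sided formula such as `~ test_channel`).
#' @param scale `"proportion"`, `"preference"` (pi = 2p - 1) or `"logit"`.
#' @param level Confidence level.
#' @return A tibble with the grouping columns plus `estimate`, `std.error`
#'   (link scale), `conf.low`, `conf.high` on the requested scale.
#' @export
estimate_group_means <- function(fit, grouping,
                                 scale = c("proportion", "preference", "logit"),
                                 level = 0.95) {
  stop_if_unconverged(fit)
  scale <- arg_match(scale)
  if (inherits(grouping, "formula")) grouping <- all.vars(grouping)
  rr <- reference_rows(fit, grouping)
  eta <- unname(as.numeric(rr$G %*% fit$coefficients))
  se <- unname(sqrt(pmax(rowSums((rr$G %*% fit$vcov) * rr$G), 0)))
  zq <- qnorm(1 - (1 - level) / 2)
  lo <- eta - zq * se; hi <- eta + zq * se
  tr <- switch(scale,
               logit = identity,
               proportion = plogis,
               preference = function(e) 2 * plogis(e) - 1)
  rr$labels %>%
    mutate(estimate = tr(eta), std.error = se,
           conf.low = tr(lo), conf.high = tr(hi))
}

#' Contrasts between group means
#'
#' Builds pairwise (or user-supplied) contrasts of the logit-scale group
#' means and tests them with Wald z statistics. Post hoc families are
#' Sidak-adjusted over the contrasts requested in the call; a priori
#' contrasts (`adjust = "none"`) are reported unadjusted.
#'
#' @inheritParams estimate_group_means
#' @param contrasts Optional numeric matrix (rows = contrasts, columns in
#'   the order of the grouping cells) overriding the pairwise set.
#' @param adjust `"sidak"` (post hoc) or `"none"` (a priori).
#' @return A tibble: `contrast`, `estimate` (logit scale), `std.error`,
#'   `statistic`, `p.value`, `p.adjusted`, `adjustment`.
#' @export
contrast_groups <- function(fit, grouping, contrasts = NULL,
                            adjust = c("sidak", "none")) {
  stop_if_unconverged(fit)
  adjust <- arg_match(adjust)
  if (inherits(grouping, "formula")) grouping <- all.vars(grouping)
  rr <- reference_rows(fit, grouping)
  cell_names <- apply(rr$labels, 1, paste, collapse = ":")
  k <- nrow(rr$G)
  if (is.null(contrasts)) {
    if (k < 2) abort("need at least two cells for pairwise contrasts")
    pairs <- utils::combn(k, 2)
    contrasts <- matrix(0, ncol(pairs), k)
    nm <- character(ncol(pairs))
    for (i in seq_len(ncol(pairs))) {
      contrasts[i, pairs[1, i]] <- 1
      contrasts[i, pairs[2, i]] <- -1
      nm[i] <- paste(cell_names[pairs[1, i]], "-", cell_names[pairs[2, i]])
    }
    rownames(contrasts) <- nm
  } else {
    contrasts <- as.matrix(contrasts)
    if (ncol(contrasts) != k) {
      abort(sprintf("contrast matrix must have %d columns (one per cell)", k))
    }
    if (is.null(rownames(contrasts))) {
      rownames(contrasts) <- sprintf("c%d", seq_len(nrow(contrasts)))
    }
  }
  L <- contrasts %*% rr$G           # map cell contrasts to coefficient space
  est <- as.numeric(L %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((L %*% fit$vcov) * L), 0))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  p_adj <- if (adjust == "sidak") sidak_adjust(p, m = length(p)) else p
  tibble(contrast = rownames(contrasts), estimate = est, std.error = se,
         statistic = z, p.value = p, p.adjusted = p_adj,
         adjustment = adjust)
}

#' Per-cluster empirical-Bayes predictions
#'
#' Combines each cluster's empirical-Bayes random-intercept mode with the
#' fixed effects of its design cell and returns response-scale predictions
#' — one per run (or run x stimulus-pair presentation), the per-replicate
#' points shown alongside group means in figures. The modes are exact
#' maximizers of each cluster's conditional posterior (Newton, tolerance
#' 1e-10).
#'
#' @param fit A converged `tv_bbfit`.
#' @return A tibble: `cluster`, `eta_fixed` (cell mean on the logit scale,
#'   averaged over the cluster's records), `u` (EB mode), `fitted_prop`,
#'   `fitted_pi`.
#' @export
predict_run_effects <- function(fit) {
  stop_if_unconverged(fit)
  eta0 <- as.numeric(fit$X %*% fit$coefficients)
  eta_cell <- as.numeric(rowsum(eta0, fit$cluster, reorder = TRUE)) /
    as.numeric(table(fit$cluster))
  u <- fit$eb_modes
  tibble(cluster = fit$cluster_levels,
         eta_fixed = eta_cell,
         u = u,
         fitted_prop = plogis(eta_cell + u),
         fitted_pi = 2 * plogis(eta_cell + u) - 1)
}
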