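# Four-parameter log-logistic intensity-preference curves.
#
# ll4(x) = c + (d - c) / (1 + exp(b * (log x - log e)))
# with c, d the lower/upper asymptotes on the preference-index scale,
# e the relative intensity at the inflection point (midway between the
# asymptotes) and b the relative steepness there. Intensities are measured
# relative to the unilluminated black tulle target and are strictly
# positive (ambient light).

#' Evaluate the four-parameter log-logistic curve
#'
#' @param x Relative intensity, strictly positive.
#' @param b,c,d,e Curve parameters: steepness, lower asymptote, upper
#'   asymptote, inflection intensity (`e > 0`).
#' @return Preference values; `ll4(e) = (c + d) / 2` by construction.
#' @examples
#' ll4(1, b = 2, c = -0.2, d = 0.6, e = 1)  # inflection: (c + d) / 2
#' @export
ll4 <- function(x, b, c, d, e) {
  if (any(x <= 0)) abort("relative intensity x must be > 0")
  if (e <= 0) abort("inflection intensity e must be > 0")
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

# SSE of the fixed-(c,d) curve in (b, log e) coordinates
ll4_sse <- function(par, x, y, c, d) {
  pred <- c + (d - c) / (1 + exp(par[1] * (log(x) - par[2])))
  sum((y - pred)^2)
}

# start values by logit-linearization of the scaled response, plus a
# multiplicative 5x5 grid around them
ll4_starts <- function(x, y, c, d) {
  z <- (y - c) / (d - c)
  z <- pmin(pmax(z, 0.02), 0.98)
  # logit(z) = -b (log x - log e): slope/intercept give (b, log e)
  f <- lm(qlogis(z) ~ log(x))
  b0 <- -unname(coef(f)[2])
  loge0 <- if (abs(b0) > 1e-8) unname(coef(f)[1]) / b0 else 0
  if (!is.finite(b0) || abs(b0) < 1e-3) b0 <- 1
  if (!is.finite(loge0)) loge0 <- 0
  grid <- tidyr::expand_grid(fb = c(0.25, 0.5, 1, 2, 4),
                             de = c(-1, -0.5, 0, 0.5, 1))
  cbind(b = b0 * grid$fb, loge = loge0 + grid$de)
}

ll4_optimize <- function(x, y, c, d, starts) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      optim(starts[i, ], ll4_sse, x = x, y = y, c = c, d = d,
            method = "BFGS",
            control = list(reltol = 1e-14, maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value - 1e-12)) best <- o
  }
  best
}

# numeric Jacobian of predictions wrt (b, log e); vcov = s2 (J'J)^-1
ll4_vcov <- function(par, x, c, d, sse, n_obs) {
  h <- 1e-6
  J <- matrix(0, length(x), 2)
  for (j in 1:2) {
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (c + (d - c) / (1 + exp(up[1] * (log(x) - up[2]))) -
                 (c + (d - c) / (1 + exp(dn[1] * (log(x) - dn[2]))))) / (2 * h)
  }
  dfree <- max(n_obs - 2, 1)
  s2 <- sse / dfree
  V <- tryCatch(s2 * solve(crossprod(J)), error = function(e)
    matrix(NA_real_, 2, 2))
  list(vcov = V, sigma = sqrt(s2))
}

new_ll4_fit <- function(b, c, d, e, vcov_blog_e, sigma, fixed, group,
                        converged, n_obs, flags = character(),
                        run_effects = NULL) {
  structure(list(
    b = unname(b), c = unname(c), d = unname(d), e = unname(e),
    vcov = vcov_blog_e,        # covariance of (b, log e)
    sigma = sigma, fixed = fixed, group = group,
    converged = converged, n_obs = n_obs, flags = flags,
    run_effects = run_effects
  ), class = "tv_ll4fit")
}

#' @export
print.tv_ll4fit <- function(x, ...) {
  cat(sprintf("<LL4 fit%s> b=%.4g c=%.4g d=%.4g e=%.4g (fixed: %s)%s\n",
              if (!is.null(x$group)) paste0(" ", x$group) else "",
              x$b, x$c, x$d, x$e,
              if (length(x$fixed)) paste(x$fixed, collapse = ",") else "none",
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Tidy an LL4 fit
#' @param x A `tv_ll4fit`.
#' @param ... Unused.
#' @return Tibble of parameters with standard errors (free parameters only
#'   carry uncertainties).
#' @exportS3Method generics::tidy
tidy.tv_ll4fit <- function(x, ...) {
  se_b <- sqrt(x$vcov[1, 1])
  se_loge <- sqrt(x$vcov[2, 2])
  tibble(term = c("b", "c", "d", "e"),
         estimate = c(x$b, x$c, x$d, x$e),
         std.error = c(se_b, NA, NA, x$e * se_loge),
         fixed = c("b", "c", "d", "e") %in% x$fixed)
}

#' @rdname tidy.tv_ll4fit
#' @exportS3Method generics::glance
glance.tv_ll4fit <- function(x, ...) {
  tibble(sigma = x$sigma, nobs = x$n_obs, converged = x$converged,
         flags = paste(x$flags, collapse = ";"))
}

#' Estimate the shared asymptotes from the gray intensity ramp
#'
#' The achromatic gray ramp spans the widest relative-intensity range, so
#' its full four-parameter fit pins the preference floor and ceiling; the
#' fitted `c` and `d` are then frozen for every wavelength x odor curve.
#'
#' @param data Data frame with columns `x` (relative intensity) and `y`
#'   (run-level preference predictions).
#' @param min_log_span Minimum required span of `log(x)` (default `log(5)`,
#'   i.e. a 5-fold intensity range); a narrower ramp cannot pin both
#'   asymptotes.
#' @return A `tv_ll4fit` with all four parameters free; `c`/`d` carry
#'   bootstrap-free least-squares SEs via the local quadratic
#'   approximation. Constant data yield a degenerate fit flagged
#'   `"degenerate_flat"` with `c = d`.
#' @export
fit_asymptotes_from_gray <- function(data, min_log_span = log(5)) {
  x <- data$x; y <- data$y
  stopifnot(length(x) == length(y), all(x > 0))
  if (diff(range(log(x))) < min_log_span) {
    abort(sprintf(
      "intensity span too narrow to pin both asymptotes (%.1f-fold < %.1f-fold); widen the ramp",
      exp(diff(range(log(x)))), exp(min_log_span)))
  }
  if (sd(y) < 1e-12) {
    return(new_ll4_fit(b = 0, c = y[1], d = y[1], e = exp(mean(log(x))),
                       vcov_blog_e = matrix(NA_real_, 2, 2), sigma = 0,
                       fixed = character(), group = "gray",
                       converged = FALSE, n_obs = length(y),
                       flags = "degenerate_flat"))
  }
  sse4 <- function(par) {
    # par = (b, log e, c, d)
    pred <- par[3] + (par[4] - par[3]) /
      (1 + exp(par[1] * (log(x) - par[2])))
    sum((y - pred)^2)
  }
  lo <- min(y); hi <- max(y); span <- hi - lo
  starts2 <- ll4_starts(x, y, lo - 0.05 * span, hi + 0.05 * span)
  best <- NULL
  for (i in seq_len(nrow(starts2))) {
    st <- c(starts2[i, ], lo - 0.02 * span, hi + 0.02 * span)
    o <- tryCatch(optim(st, sse4, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 5000)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value - 1e-12)) best <- o
  }
  if (is.null(best)) abort("gray-ramp asymptote fit failed from all starts")
  par <- best$par
  cc <- min(par[3], par[4]); dd <- max(par[3], par[4])
  b <- if (par[3] <= par[4]) par[1] else -par[1]
  # SEs for all four via the Gauss-Newton approximation H ~ 2 J'J, so
  # vcov ~ s2 * (H/2)^-1 with s2 the residual variance
  H <- tryCatch(optimHess(best$par, sse4), error = function(e) NULL)
  s2 <- best$value / max(length(y) - 4, 1)
  V4 <- if (!is.null(H)) tryCatch(s2 * solve(H / 2), error = function(e)
    matrix(NA_real_, 4, 4)) else matrix(NA_real_, 4, 4)
  fit <- new_ll4_fit(b = b, c = cc, d = dd, e = exp(par[2]),
                     vcov_blog_e = V4[1:2, 1:2, drop = FALSE],
                     sigma = sqrt(s2), fixed = character(), group = "gray",
                     converged = TRUE, n_obs = length(y))
  fit$vcov_cd <- V4[3:4, 3:4, drop = FALSE]
  fit
}

#' Fit the intensity-preference curve with frozen asymptotes
#'
#' Fits `b` (steepness) and `e` (inflection intensity) for one wavelength x
#' odor group by least squares on run-level preference predictions, with
#' the asymptotes `c`, `d` frozen from the gray ramp. Optimization runs in
#' `(b, log e)` from a logit-linearization start plus a 5x5 multistart
#' grid. With `random = "two_stage"`, per-run `(b, e)` fits are pooled by
#' inverse-variance weighting, a two-stage approximation to a nonlinear
#' mixed fit; the pooled estimates and the between-run spread are attached.
#'
#' @param data Data frame with columns `x`, `y` and (for the two-stage
#'   option) `run_id`.
#' @param c,d Frozen asymptotes (from [fit_asymptotes_from_gray()]).
#' @param group Label for the wavelength x odor combination.
#' @param random `"none"` or `"two_stage"`.
#' @return A `tv_ll4fit`. Flat data (fitted `|b|` below 0.05) are flagged
#'   `"e_unidentifiable"`.
#' @export
fit_ll4_fixed_cd <- function(data, c, d, group = NULL,
                             random = c("none", "two_stage")) {
  random <- arg_match(random)
  x <- data$x; y <- data$y
  stopifnot(all(x > 0), c <= d)
  if (length(unique(x)) < 4) {
    abort("need at least 4 distinct intensities to fit (b, e)")
  }
  starts <- ll4_starts(x, y, c, d)
  best <- ll4_optimize(x, y, c, d, starts)
  if (is.null(best)) {
    return(new_ll4_fit(NA_real_, c, d, NA_real_,
                       matrix(NA_real_, 2, 2), NA_real_, c("c", "d"),
                       group, FALSE, length(y), flags = "non_convergent"))
  }
  b <- best$par[1]; e <- exp(best$par[2])
  vc <- ll4_vcov(best$par, x, c, d, best$value, length(y))
  flags <- character()
  if (abs(b) < 0.05) flags <- c(flags, "e_unidentifiable")
  fit <- new_ll4_fit(b, c, d, e, vc$vcov, vc$sigma, fixed = c("c", "d"),
                     group = group, converged = TRUE, n_obs = length(y),
                     flags = flags)
  if (random == "two_stage" && "run_id" %in% names(data)) {
    per_run <- data %>%
      group_by(.data$run_id) %>%
      dplyr::group_map(function(dd, key) {
        if (length(unique(dd$x)) < 4) return(NULL)
        o <- ll4_optimize(dd$x, dd$y, c, d, starts)
        if (is.null(o)) return(NULL)
        v <- ll4_vcov(o$par, dd$x, c, d, o$value, nrow(dd))
        tibble(run_id = key$run_id, b = o$par[1], log_e = o$par[2],
               var_b = v$vcov[1, 1], var_loge = v$vcov[2, 2])
      }) %>% bind_rows()
    if (nrow(per_run) >= 2 &&
        all(is.finite(per_run$var_b)) && all(is.finite(per_run$var_loge))) {
      wb <- 1 / pmax(per_run$var_b, 1e-12)
      we <- 1 / pmax(per_run$var_loge, 1e-12)
      fit$run_effects <- per_run
      fit$pooled <- tibble(
        b = sum(wb * per_run$b) / sum(wb),
        log_e = sum(we * per_run$log_e) / sum(we),
        sd_b_between = sd(per_run$b),
        sd_loge_between = sd(per_run$log_e))
    }
  }
  fit
}

#' Compare two intensity curves by relative potency
#'
#' Tests whether two fitted curves (sharing frozen asymptotes) differ in
#' the relative intensity at their inflection points, via a delta-method z
#' test on `log(e1) - log(e2)`. The ratio `e1/e2` is the relative potency.
#'
#' @param fit1,fit2 Converged `tv_ll4fit` objects with the same frozen
#'   `c`, `d`.
#' @return One-row tibble: `ratio`, `se_log_ratio`, `statistic`, `p.value`.
#' @export
compare_potency <- function(fit1, fit2) {
  for (f in list(fit1, fit2)) {
    if (!isTRUE(f$converged) || "non_convergent" %in% f$flags) {
      abort("refusing to compare potency with a non-converged fit")
    }
  }
  if (abs(fit1$c - fit2$c) > 1e-8 || abs(fit1$d - fit2$d) > 1e-8) {
    abort("fits do not share frozen asymptotes; potency comparison undefined")
  }
  lr <- log(fit1$e) - log(fit2$e)
  se <- sqrt(fit1$vcov[2, 2] + fit2$vcov[2, 2])
  z <- if (abs(lr) < 1e-15) 0 else lr / se
  tibble(ratio = fit1$e / fit2$e, se_log_ratio = se, statistic = z,
         p.value = 2 * pnorm(-abs(z)))
}

#' Evaluate a fitted curve on an intensity grid
#'
#' @param fit A `tv_ll4fit`.
#' @param x Intensity grid (default 100 log-spaced points over a 0.05-3
#'   range).
#' @return Tibble `x`, `fitted`.
#' @export
ll4_curve <- function(fit, x = exp(seq(log(0.05), log(3), length.out = 100))) {
  tibble(x = x, fitted = ll4(x, fit$b, fit$c, fit$d, fit$e),
         group = fit$group %||% NA_character_)
}
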