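# Beta-binomial mixed model with a Gaussian random intercept per cluster,
# logit link, fitted by maximum marginal likelihood with adaptive
# Gauss-Hermite quadrature.
#
# Parameterization: successes y ~ BetaBinomial(n, mu, phi) with
# alpha = mu * phi, beta = (1 - mu) * phi, so phi is a precision: the
# binomial is recovered as phi -> Inf. logit(mu) = X b + u_j,
# u_j ~ N(0, sigma^2) with one intercept per cluster (a run, or a
# run x stimulus-pair presentation for preference models).

MU_EPS <- 1e-10

# log density; phi = Inf selects the plain binomial
bb_logdens <- function(y, n, mu, phi) {
  mu <- pmin(pmax(mu, MU_EPS), 1 - MU_EPS)
  if (is.infinite(phi)) return(dbinom(y, n, mu, log = TRUE))
  a <- mu * phi
  b <- (1 - mu) * phi
  lchoose(n, y) + lgamma(y + a) + lgamma(n - y + b) - lgamma(n + phi) -
    lgamma(a) - lgamma(b) + lgamma(phi)
}

# first/second derivatives of the per-observation log density wrt u where
# mu = plogis(eta0 + u); returns list(d1, d2) per observation
bb_derivs_u <- function(y, n, eta, phi) {
  mu <- pmin(pmax(plogis(eta), MU_EPS), 1 - MU_EPS)
  dmu <- mu * (1 - mu)
  if (is.infinite(phi)) {
    d1m <- y / mu - (n - y) / (1 - mu)
    d2m <- -y / mu^2 - (n - y) / (1 - mu)^2
  } else {
    a <- mu * phi; b <- (1 - mu) * phi
    d1m <- phi * (digamma(y + a) - digamma(a) - digamma(n - y + b) + digamma(b))
    d2m <- phi^2 * (trigamma(y + a) - trigamma(a) + trigamma(n - y + b) - trigamma(b))
  }
  list(d1 = d1m * dmu,
       d2 = d2m * dmu^2 + d1m * dmu * (1 - 2 * mu))
}

# joint log-likelihood contributions summed by cluster at offsets u (per
# cluster), excluding the Gaussian prior
cluster_cond_ll <- function(u, eta0, y, n, phi, cid, J) {
  ll <- bb_logdens(y, n, plogis(eta0 + u[cid]), phi)
  as.numeric(rowsum(ll, cid, reorder = TRUE))
}

# vectorized Newton ascent for the conditional posterior mode of each
# cluster's random intercept; returns modes and curvatures
find_modes <- function(eta0, y, n, phi, sigma, cid, J, u0 = NULL) {
  u <- if (is.null(u0)) numeric(J) else u0
  for (iter in 1:50) {
    d <- bb_derivs_u(y, n, eta0 + u[cid], phi)
    g <- as.numeric(rowsum(d$d1, cid, reorder = TRUE)) - u / sigma^2
    h <- as.numeric(rowsum(d$d2, cid, reorder = TRUE)) - 1 / sigma^2
    h <- pmin(h, -1e-10)
    step <- g / h
    step <- pmin(pmax(step, -2), 2)
    u <- u - step
    if (max(abs(step)) < 1e-10) break
  }
  d <- bb_derivs_u(y, n, eta0 + u[cid], phi)
  h <- as.numeric(rowsum(d$d2, cid, reorder = TRUE)) - 1 / sigma^2
  list(u = u, h = pmin(h, -1e-10))
}

# marginal log-likelihood by adaptive Gauss-Hermite quadrature
marginal_ll <- function(beta, log_phi, log_sigma, X, y, n, cid, J, gh,
                        env = NULL) {
  phi <- exp(log_phi)
  if (is.infinite(log_phi)) phi <- Inf
  sigma <- exp(log_sigma)
  eta0 <- as.numeric(X %*% beta)
  if (sigma < 1e-7) {
    ll <- sum(bb_logdens(y, n, plogis(eta0), phi))
    return(list(ll = ll, modes = numeric(J), scales = rep(0, J)))
  }
  u0 <- if (!is.null(env) && !is.null(env$u_warm)) env$u_warm else NULL
  m <- find_modes(eta0, y, n, phi, sigma, cid, J, u0 = u0)
  if (!is.null(env)) env$u_warm <- m$u
  s <- 1 / sqrt(-m$h)
  z <- gh$x; w <- gh$w
  K <- length(z)
  # log integrand at shifted nodes, clusters x nodes
  lf <- matrix(0, J, K)
  for (k in seq_len(K)) {
    uk <- m$u + sqrt(2) * s * z[k]
    lf[, k] <- cluster_cond_ll(uk, eta0, y, n, phi, cid, J) +
      dnorm(uk, 0, sigma, log = TRUE) + z[k]^2
  }
  mx <- apply(lf, 1, max)
  lint <- mx + log((exp(lf - mx) %*% w)[, 1]) + 0.5 * log(2) + log(s)
  list(ll = sum(lint), modes = m$u, scales = s)
}

#' Fit a beta-binomial mixed model
#'
#' Fits a logit-link beta-binomial regression with a Gaussian random
#' intercept per cluster by maximum marginal likelihood, integrating the
#' random effects with adaptive Gauss-Hermite quadrature. This is the
#' inferential engine for all three behavioral responses: per-trajectory
#' preference (successes = frames in the test volume, trials = frames in
#' either volume, clusters = run x stimulus-pair presentations, so the
#' integer frame counts weight each trajectory by its total dwell time) and
#' per-run recruitment/activation proportions (a single intercept per run).
#'
#' @param data A data frame of records.
#' @param fixed One-sided formula for the fixed effects
#'   (e.g. `~ test_channel * odor`).
#' @param successes,trials,cluster Names of the columns holding the integer
#'   successes, trials, and the cluster id for the random intercept.
#' @param nodes Number of Gauss-Hermite nodes (default 20; 1 gives the
#'   Laplace approximation).
#' @param fix_phi Optional fixed precision; `Inf` pins the model to a plain
#'   binomial likelihood.
#' @param fix_sigma Optional fixed random-intercept SD; `0` removes the
#'   random effect.
#' @return An object of class `tv_bbfit` with logit-scale coefficients and
#'   their covariance, the precision `phi`, the random-intercept SD
#'   `sigma`, the marginal log-likelihood, empirical-Bayes cluster modes,
#'   and convergence diagnostics. Records with zero trials are dropped
#'   (they carry no weight).
#' @seealso [likelihood_ratio_test()], [estimate_group_means()],
#'   [predict_run_effects()], [tidy.tv_bbfit()]
#' @export
fit_betabinom_mixed <- function(data, fixed = ~1, successes = "successes",
                                trials = "trials", cluster = "run_id",
                                nodes = 20, fix_phi = NULL, fix_sigma = NULL) {
  stopifnot(is.data.frame(data))
  data <- as_tibble(data)
  y <- data[[successes]]
  n <- data[[trials]]
  if (is.null(y) || is.null(n)) abort("successes/trials columns not found")
  keep <- !is.na(y) & !is.na(n) & n > 0
  if (!any(keep)) abort("all records have zero trials; nothing to fit")
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(y[keep]); n <- as.numeric(n[keep])
  if (any(y < 0 | y > n)) abort("successes must lie in [0, trials]")

  mf <- model.frame(fixed, data = data, na.action = na.omit)
  X <- model.matrix(fixed, mf)
  p <- ncol(X)
  cl <- factor(data[[cluster]])
  cid <- as.integer(cl)
  J <- nlevels(cl)
  gh <- pracma::gaussHermite(nodes)

  free_phi <- is.null(fix_phi)
  free_sigma <- is.null(fix_sigma)

  # starting values from an unclustered binomial GLM
  b0 <- tryCatch(
    coef(suppressWarnings(stats::glm.fit(X, cbind(y, n - y),
                                         family = stats::binomial()))),
    error = function(e) rep(0, p))
  b0[!is.finite(b0)] <- 0
  theta0 <- b0
  lower <- rep(-Inf, p); upper <- rep(Inf, p)
  if (free_phi) {
    theta0 <- c(theta0, log(10))
    lower <- c(lower, log(1e-3)); upper <- c(upper, log(1e6))
  }
  if (free_sigma) {
    theta0 <- c(theta0, log(0.3))
    lower <- c(lower, log(1e-6)); upper <- c(upper, log(50))
  }
  env <- new.env()

  unpack <- function(theta) {
    beta <- theta[seq_len(p)]
    k <- p
    if (free_phi) { log_phi <- theta[k + 1]; k <- k + 1 } else {
      log_phi <- if (is.infinite(fix_phi)) Inf else log(fix_phi)
    }
    log_sigma <- if (free_sigma) theta[k + 1] else log(max(fix_sigma, 0))
    if (!free_sigma && fix_sigma == 0) log_sigma <- -Inf
    list(beta = beta, log_phi = log_phi, log_sigma = log_sigma)
  }
  negll <- function(theta) {
    par <- unpack(theta)
    sig <- if (is.infinite(par$log_sigma)) 0 else exp(par$log_sigma)
    res <- marginal_ll(par$beta, par$log_phi, log(max(sig, 1e-300)),
                       X, y, n, cid, J, gh, env = env)
    if (!is.finite(res$ll)) 1e10 else -res$ll
  }

  opt <- nlminb(theta0, negll, lower = lower, upper = upper,
                control = list(rel.tol = 1e-10, iter.max = 500,
                               eval.max = 2000))
  # nlminb can report "false convergence" when a variance parameter drifts
  # to its boundary (e.g. phi -> Inf with no overdispersion); accept the
  # optimum if the scaled gradient is negligible in the interior directions
  converged <- opt$convergence == 0
  if (!converged) {
    g <- vapply(seq_along(opt$par), function(j) {
      h <- 1e-5 * max(1, abs(opt$par[j]))
      up <- opt$par; up[j] <- min(up[j] + h, upper[j])
      dn <- opt$par; dn[j] <- max(dn[j] - h, lower[j])
      if (up[j] == dn[j]) return(0)
      (negll(up) - negll(dn)) / (up[j] - dn[j])
    }, numeric(1))
    at_bound <- opt$par >= upper - 1e-6 | opt$par <= lower + 1e-6
    converged <- max(abs(g[!at_bound]), 0) <
      1e-3 * max(1, abs(opt$objective))
  }
  theta <- opt$par
  par <- unpack(theta)
  final <- marginal_ll(par$beta, par$log_phi,
                       if (is.infinite(par$log_sigma)) log(1e-300) else par$log_sigma,
                       X, y, n, cid, J, gh, env = env)

  H <- tryCatch(optimHess(theta, negll), error = function(e) NULL)
  V <- NULL
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) {
      s <- svd(H); tol <- max(s$d) * 1e-10
      dinv <- ifelse(s$d > tol, 1 / s$d, 0)
      s$v %*% (dinv * t(s$u))
    })
  }
  if (is.null(V)) V <- matrix(NA_real_, length(theta), length(theta))
  se_all <- sqrt(pmax(diag(V), 0))

  beta <- setNames(unname(par$beta), colnames(X))
  phi <- if (is.infinite(par$log_phi)) Inf else unname(exp(par$log_phi))
  sigma <- if (is.infinite(par$log_sigma)) 0 else unname(exp(par$log_sigma))

  fit <- structure(list(
    coefficients = beta,
    se = setNames(se_all[seq_len(p)], colnames(X)),
    vcov = V[seq_len(p), seq_len(p), drop = FALSE],
    vcov_all = V,
    phi = phi,
    sigma = sigma,
    sigma2 = sigma^2,
    logLik = final$ll,
    df = length(theta),
    n_obs = length(y),
    n_clusters = J,
    converged = converged,
    message = opt$message,
    nodes = nodes,
    fixed = fixed,
    terms = terms(mf),
    xlevels = stats::.getXlevels(terms(mf), mf),
    X = X, y = y, n = n,
    cluster_levels = levels(cl),
    cluster = cl,
    data = data,
    eb_modes = final$modes,
    free = c(phi = free_phi, sigma = free_sigma)
  ), class = "tv_bbfit")
  fit
}

#' @export
print.tv_bbfit <- function(x, ...) {
  cat(sprintf("<beta-binomial mixed fit> %d obs, %d clusters, %s\n",
              x$n_obs, x$n_clusters,
              if (x$converged) "converged" else "NOT CONVERGED"))
  cat(sprintf("  logLik %.3f (df %d), phi %.4g, sigma_run %.4g\n",
              x$logLik, x$df, x$phi, x$sigma))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
logLik.tv_bbfit <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' Tidy a beta-binomial mixed fit
#'
#' @param x A `tv_bbfit`.
#' @param ... Unused.
#' @return A tibble of logit-scale coefficients with Wald statistics.
#' @exportS3Method generics::tidy
tidy.tv_bbfit <- function(x, ...) {
  z <- x$coefficients / x$se
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se),
         statistic = unname(z),
         p.value = unname(2 * pnorm(-abs(z))))
}

#' @rdname tidy.tv_bbfit
#' @exportS3Method generics::glance
glance.tv_bbfit <- function(x, ...) {
  tibble(logLik = x$logLik, df = x$df, phi = x$phi, sigma_run = x$sigma,
         nobs = x$n_obs, n_clusters = x$n_clusters, converged = x$converged)
}

stop_if_unconverged <- function(fit) {
  if (!isTRUE(fit$converged)) {
    abort("fit did not converge; refusing to compute downstream summaries")
  }
  invisible(fit)
}
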