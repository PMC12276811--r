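test_that("pinned-variance fit reduces to the binomial closed form", {
  d <- tibble::tibble(successes = 400, trials = 1000, run_id = "r1")
  f <- fit_betabinom_mixed(d, ~1, fix_phi = Inf, fix_sigma = 0)
  expect_equal(unname(coef(f)), qlogis(0.4), tolerance = 1e-8)
})

test_that("zero run variance in the data drives the sigma estimate to ~0", {
  d <- simulate_betabinom_records(80, 10, mu = 0.55, phi = 50, sigma = 0,
                                  seed = 2, trials_mean = 100)
  f <- fit_betabinom_mixed(d, ~1, cluster = "cluster")
  expect_true(f$converged)
  expect_lt(f$sigma^2, 0.01)  # variance estimate pinned near its 0 bound
  expect_equal(plogis(unname(coef(f))), 0.55, tolerance = 0.05)
})

test_that("marginal likelihood agrees with an independent mixed-model fit", {
  d <- simulate_betabinom_records(25, 8, mu = c(rep(0.45, 12), rep(0.7, 13)),
                                  phi = 6, sigma = 0.4, seed = 7)
  d$grp <- rep(c("a", "b"), times = c(12 * 8, 13 * 8))
  f <- fit_betabinom_mixed(d, ~grp, cluster = "cluster")
  g <- glmmTMB::glmmTMB(cbind(successes, trials - successes) ~ grp +
                          (1 | cluster),
                        family = glmmTMB::betabinomial(), data = d)
  expect_equal(unname(coef(f)), unname(glmmTMB::fixef(g)$cond),
               tolerance = 5e-3)
  expect_equal(f$phi, glmmTMB::sigma(g), tolerance = 0.05)
  # adaptive quadrature should not undercut the Laplace fit's likelihood
  expect_gt(f$logLik, as.numeric(logLik(g)) - 0.5)
})

test_that("likelihood-ratio test computes the chi-square upper tail", {
  f <- fit_betabinom_mixed(
    simulate_betabinom_records(10, 5, 0.5, 8, 0.3, seed = 3),
    ~1, cluster = "cluster")
  same <- likelihood_ratio_test(fake_fit(f$logLik, f$df + 1, n_obs = f$n_obs), f)
  expect_equal(same$chi2, 0)
  expect_equal(same$p.value, 1)

  # tail arithmetic on a printed-scale statistic
  lrt <- likelihood_ratio_test(fake_fit(-100, 13), fake_fit(-100 - 12.55 / 2, 3))
  expect_equal(lrt$chi2, 12.55)
  expect_equal(lrt$df, 10)
  expect_equal(lrt$p.value, 0.25, tolerance = 0.005)

  expect_error(likelihood_ratio_test(fake_fit(-10, 3), fake_fit(-11, 3)),
               "nested")
  expect_error(likelihood_ratio_test(fake_fit(-10, 4, n_obs = 50),
                                     fake_fit(-11, 3, n_obs = 60)),
               "nested")
})

test_that("LRT is invariant to affine reparameterization of the design", {
  d <- simulate_betabinom_records(20, 6, mu = rep(c(0.4, 0.6), each = 10),
                                  phi = 8, sigma = 0.3, seed = 5)
  d$grp <- factor(rep(c("a", "b"), each = 60))
  f_trt <- fit_betabinom_mixed(d, ~grp, cluster = "cluster")
  d$grp2 <- stats::C(d$grp, stats::contr.sum)
  f_sum <- fit_betabinom_mixed(d, ~grp2, cluster = "cluster")
  f_null <- fit_betabinom_mixed(d, ~1, cluster = "cluster")
  expect_equal(f_trt$logLik, f_sum$logLik, tolerance = 1e-5)
  expect_equal(likelihood_ratio_test(f_trt, f_null)$chi2,
               likelihood_ratio_test(f_sum, f_null)$chi2, tolerance = 1e-4)
})

test_that("Sidak adjustment matches direct evaluation and its boundaries", {
  expect_equal(sidak_adjust(0.3, m = 1), 0.3)
  expect_equal(sidak_adjust(0.01, m = 10), 1 - 0.99^10)
  expect_equal(sidak_adjust(0, m = 7), 0)
  expect_equal(sidak_adjust(1, m = 7), 1)
  p <- c(0.001, 0.2, 0.8)
  expect_equal(sidak_adjust(p), 1 - (1 - p)^3)
  expect_true(all(sidak_adjust(p) >= p))
})

test_that("group means convert logit estimates to the preference scale", {
  d <- tibble::tibble(successes = c(2, 2), trials = c(4, 4),
                      run_id = "r1", grp = "a")
  f <- fit_betabinom_mixed(d, ~1, fix_phi = Inf, fix_sigma = 0)
  m <- estimate_group_means(f, "grp", scale = "preference")
  expect_equal(m$estimate, 0, tolerance = 1e-6)  # logit(0.5) -> pi = 0

  d2 <- tibble::tibble(successes = 300, trials = 400, run_id = "r1", grp = "a")
  f2 <- fit_betabinom_mixed(d2, ~1, fix_phi = Inf, fix_sigma = 0)
  m2 <- estimate_group_means(f2, "grp", scale = "preference")
  expect_equal(m2$estimate, 0.5, tolerance = 1e-6)  # logit(0.75) -> pi = 0.5

  expect_error(estimate_group_means(f2, "nonexistent"), "grouping")
})

test_that("interval endpoints match parametric-bootstrap quantiles", {
  d <- simulate_betabinom_records(15, 6, mu = 0.62, phi = 8, sigma = 0.4,
                                  seed = 9)
  d$grp <- "a"
  f <- fit_betabinom_mixed(d, ~1, cluster = "cluster")
  m <- estimate_group_means(f, "grp", scale = "preference")
  set.seed(404)
  draws <- rnorm(1e5, unname(coef(f)), f$se[[1]])
  q <- quantile(2 * plogis(draws) - 1, c(0.025, 0.975))
  expect_equal(m$conf.low, unname(q[1]), tolerance = 0.005)
  expect_equal(m$conf.high, unname(q[2]), tolerance = 0.005)
})

test_that("contrasts adjust post hoc families and bypass a priori ones", {
  d <- simulate_betabinom_records(30, 5, mu = rep(c(0.35, 0.5, 0.65), 10),
                                  phi = 8, sigma = 0.3, seed = 12)
  d$grp <- factor(rep(c("a", "b", "c"), 50))
  f <- fit_betabinom_mixed(d, ~grp, cluster = "cluster")
  ct <- contrast_groups(f, "grp")
  expect_equal(nrow(ct), 3)  # pairwise among 3 cells
  expect_equal(ct$p.adjusted, sidak_adjust(ct$p.value, m = 3))
  expect_true(all(ct$p.adjusted >= ct$p.value))
  expect_true(all(ct$p.adjusted <= 1 & ct$p.adjusted >= 0))

  apriori <- contrast_groups(f, "grp", contrasts = rbind(c(1, -2, 1) / 2),
                             adjust = "none")
  expect_equal(apriori$p.value, apriori$p.adjusted)
})

test_that("label swap negates every estimated preference", {
  d <- simulate_betabinom_records(20, 6, mu = 0.68, phi = 8, sigma = 0.4,
                                  seed = 33)
  d$grp <- "a"
  sw <- d
  sw$successes <- sw$trials - sw$successes
  f <- fit_betabinom_mixed(d, ~1, cluster = "cluster")
  fs <- fit_betabinom_mixed(sw, ~1, cluster = "cluster")
  expect_equal(unname(coef(f)), -unname(coef(fs)), tolerance = 1e-4)
  m <- estimate_group_means(f, "grp", scale = "preference")
  ms <- estimate_group_means(fs, "grp", scale = "preference")
  expect_equal(m$estimate, -ms$estimate, tolerance = 1e-4)
})

test_that("run predictions are exact conditional-posterior modes", {
  d <- simulate_betabinom_records(12, 5, mu = 0.6, phi = 6, sigma = 0.6,
                                  seed = 21)
  f <- fit_betabinom_mixed(d, ~1, cluster = "cluster")
  pr <- predict_run_effects(f)
  # oracle: maximize each cluster's conditional posterior with optimize()
  for (j in seq_len(nrow(pr))) {
    rows <- d[d$cluster == pr$cluster[j], ]
    obj <- function(u) {
      mu <- plogis(unname(coef(f)) + u)
      a <- mu * f$phi; b <- (1 - mu) * f$phi
      sum(lchoose(rows$trials, rows$successes) +
            lbeta(rows$successes + a, rows$trials - rows$successes + b) -
            lbeta(a, b)) + dnorm(u, 0, f$sigma, log = TRUE)
    }
    u_star <- optimize(obj, c(-4, 4), maximum = TRUE, tol = 1e-10)$maximum
    expect_equal(pr$u[j], u_star, tolerance = 1e-6)
  }
})

test_that("shrinkage limits of run predictions behave correctly", {
  d <- simulate_betabinom_records(10, 5, mu = 0.6, phi = 8, sigma = 0.5,
                                  seed = 55)
  f0 <- fit_betabinom_mixed(d, ~1, cluster = "cluster", fix_sigma = 0)
  pr0 <- predict_run_effects(f0)
  expect_equal(pr0$fitted_prop, rep(plogis(unname(coef(f0))), 10))

  # an extreme cluster's prediction lies between its raw proportion and
  # the group mean
  d2 <- d
  ext <- d2$cluster == d2$cluster[1]
  d2$successes[ext] <- d2$trials[ext]  # all successes
  f2 <- fit_betabinom_mixed(d2, ~1, cluster = "cluster")
  pr2 <- predict_run_effects(f2)
  grand <- plogis(unname(coef(f2)))
  raw <- 1
  pred <- pr2$fitted_prop[pr2$cluster == d2$cluster[1]]
  expect_gt(pred, grand)
  expect_lt(pred, raw)
})

test_that("degenerate inputs are rejected with clear errors", {
  d <- tibble::tibble(successes = c(0, 0), trials = c(0, 0), run_id = "r")
  expect_error(fit_betabinom_mixed(d, ~1), "zero trials")
  bad <- tibble::tibble(successes = 5, trials = 3, run_id = "r")
  expect_error(fit_betabinom_mixed(bad, ~1), "successes")
  f <- fit_betabinom_mixed(
    simulate_betabinom_records(8, 4, 0.5, 8, 0.3, seed = 1),
    ~1, cluster = "cluster")
  f$converged <- FALSE
  expect_error(estimate_group_means(f, "cluster"), "converge")
  expect_error(predict_run_effects(f), "converge")
})
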