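test_that("prior specification validates its parameters", {
  p <- prior_spec()
  expect_equal(p$mu_mean, 0)
  expect_equal(p$mu_sd, 2)
  expect_equal(p$tau_shape, 1)
  expect_equal(p$tau_scale, 0.15)
  expect_error(prior_spec(mu_sd = 0), "positive")
  expect_error(prior_spec(tau_scale = -1), "positive")
})

test_that("quadrature posterior has calibrated tails and sane moments", {
  y <- c(0.9, 0.6, 1.1, 0.8, 0.7)
  se <- c(0.3, 0.25, 0.4, 0.2, 0.35)
  fit <- fit_bayes_re(y, se)
  expect_s3_class(fit, "posterior_summary")
  expect_true(fit$cri_low <= fit$mu_mean && fit$mu_mean <= fit$cri_high)
  expect_gte(fit$tau2, 0)
  # exceedance at the credible limits recovers the tail masses
  p <- threshold_probabilities(fit, c(fit$cri_low, fit$cri_high))
  expect_close(p[1], 0.975, 0.005)
  expect_close(p[2], 0.025, 0.005)
})

test_that("with tau fixed at zero the data overwhelm the prior", {
  # conjugate limit: posterior mean ~ y, sd ~ se for a precise single study
  fit <- fit_bayes_re(0.8, 0.001, tau_fixed = 0)
  expect_close(fit$mu_mean, 0.8, 1e-5)
  expect_lt(fit$mu_sd, 0.01)
  # with a free heterogeneity prior one study cannot pin tau down, but the
  # posterior mean must still track the datum rather than the prior mean
  free <- fit_bayes_re(0.8, 0.001)
  expect_gt(free$mu_mean, 0.5)
})

test_that("wide-prior fixed-tau posterior converges to the fixed-effect estimate", {
  set.seed(5)
  y <- rnorm(6, 0.4, 0.3)
  se <- runif(6, 0.1, 0.4)
  fit <- fit_bayes_re(y, se, prior_spec(mu_sd = 1e6), tau_fixed = 0)
  w <- 1 / se^2
  expect_equal(fit$mu_mean, sum(w * y) / sum(w), tolerance = 1e-6)
  expect_equal(fit$mu_sd, 1 / sqrt(sum(w)), tolerance = 1e-6)
})

test_that("MCMC cross-check agrees with quadrature", {
  y <- c(0.9, 0.6, 1.1, 0.8, 0.7)
  se <- c(0.3, 0.25, 0.4, 0.2, 0.35)
  fq <- fit_bayes_re(y, se)
  fm <- fit_bayes_re(y, se, method = "mcmc", seed = 3,
                     n_iter = 60000, n_burn = 10000)
  expect_lt(abs(fq$mu_mean - fm$mu_mean), 0.01)
  expect_lt(abs(fq$mu_sd - fm$mu_sd), 0.01)
  expect_lt(abs(fq$tau_mean - fm$tau_mean), 0.02)
  # same seed, same draws
  fm2 <- fit_bayes_re(y, se, method = "mcmc", seed = 3,
                      n_iter = 60000, n_burn = 10000)
  expect_identical(fm$draws, fm2$draws)
})

test_that("credible intervals cover the true pooled effect", {
  # simulation oracle: nominal 95% interval, k = 10, mu = 0.8, tau = 0.2
  hits <- vapply(1:500, function(i) {
    set.seed(20000 + i)
    theta <- rnorm(10, 0.8, 0.2)
    y <- rnorm(10, theta, 0.3)
    fit <- fit_bayes_re(y, rep(0.3, 10), n_mu = 201L, n_tau = 151L)
    fit$cri_low <= 0.8 && 0.8 <= fit$cri_high
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("threshold probabilities reproduce the normal approximation and decrease in t", {
  p <- threshold_probabilities(mean = 0.858, sd = 0.217,
                               thresholds = c(a = 0.469, b = 0.858))
  expect_close(p[["a"]], 1 - pnorm((0.469 - 0.858) / 0.217), 1e-12)
  expect_equal(p[["b"]], 0.5)   # own mean: symmetry

  ts <- seq(-1, 2, by = 0.1)
  pm <- threshold_probabilities(mean = 0.5, sd = 0.3, thresholds = ts)
  expect_true(all(diff(pm) < 0))
  # grid-based probabilities are monotone too
  fit <- fit_bayes_re(c(0.4, 0.7, 0.5), c(0.2, 0.3, 0.25))
  pg <- threshold_probabilities(fit, ts)
  expect_true(all(diff(pg) <= 0))
  expect_error(threshold_probabilities(mean = 0, sd = 0, thresholds = 1),
               "positive")
})

test_that("Bayes factor routes agree with each other and the conjugate closed form", {
  # closed form: single y = 0, se = 1, mu-prior sd 2, tau = 0:
  # bf10 = N(0; 0, 5)/N(0; 0, 1) = sqrt(1/5)
  bf <- bayes_factor(0, 1, method = "marginal_likelihood", tau_fixed = 0)
  expect_equal(bf, sqrt(1 / 5), tolerance = 1e-9)

  # Savage-Dickey vs marginal likelihood within 5% on a battery
  battery <- list(
    list(y = c(0.9, 0.6, 1.1, 0.8, 0.7), se = c(0.3, 0.25, 0.4, 0.2, 0.35)),
    list(y = c(0.1, -0.2, 0.3), se = c(0.3, 0.3, 0.3)),
    list(y = c(0.5, 0.4, 0.6, 0.5), se = c(0.15, 0.2, 0.25, 0.2)),
    list(y = c(-0.4, -0.6), se = c(0.3, 0.35)))
  for (case in battery) {
    b_ml <- bayes_factor(case$y, case$se, method = "marginal_likelihood")
    b_sd <- bayes_factor(case$y, case$se, method = "savage_dickey")
    expect_gt(b_sd / b_ml, 0.95)
    expect_lt(b_sd / b_ml, 1.05)
  }

  # strong consistent signal: overwhelming evidence
  set.seed(1)
  y8 <- rnorm(8, 0.9, 0.05)
  expect_gt(bayes_factor(y8, rep(0.2, 8)), 30)

  # data consistent with the null and tiny k: no real evidence either way
  expect_lt(bayes_factor(c(0.02, -0.03), c(0.3, 0.3)), 1.5)
})

test_that("Bayes factor classification follows the published bins", {
  expect_equal(classify_bf(3)$evidence, "anecdotal")
  expect_equal(classify_bf(67)$evidence, "very_strong")
  expect_equal(classify_bf(1)$evidence, "no_evidence")
  expect_equal(classify_bf(5)$evidence, "moderate")
  expect_equal(classify_bf(10)$evidence, "moderate")
  expect_equal(classify_bf(30)$evidence, "strong")
  expect_equal(classify_bf(30.001)$evidence, "very_strong")
  r <- classify_bf(1 / 20)
  expect_equal(r$evidence, "strong")
  expect_equal(r$direction, "H0")
  expect_error(classify_bf(0), "positive")
  expect_error(classify_bf(-2), "positive")
})

test_that("definition comparison builds the symmetric threshold table", {
  a <- list(mu_mean = 0.858, mu_sd = 0.217, cri_low = 0.470, cri_high = 1.325)
  b <- list(mu_mean = 0.469, mu_sd = 0.170, cri_low = 0.134, cri_high = 0.834)
  tt <- compare_definitions(a, b, names = c("UDMI34", "SCAI"),
                            normal_approx = TRUE)
  expect_equal(nrow(tt), 7)
  expect_named(tt, c("threshold", "log_hr_threshold", "UDMI34", "SCAI"))
  # each definition sits at 50% against its own posterior mean
  expect_equal(tt$UDMI34[tt$log_hr_threshold == 0.858][1], 50)
  expect_equal(tt$SCAI[tt$log_hr_threshold == 0.469][1], 50)
})
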