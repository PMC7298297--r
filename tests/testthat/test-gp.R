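test_that("covariance kernels match their closed forms", {
  expect_equal(k_ou(0, ou_params(3, 1)), 1)
  expect_equal(k_ou(1 / 3, ou_params(3, 1)), exp(-1), tolerance = 1e-12)
  expect_lt(k_ou(100, ou_params(3, 1)), 1e-12)
  expect_equal(k_ou(-0.5, ou_params(3, 2)), k_ou(0.5, ou_params(3, 2)))

  p <- ouosc_params(1.2, 4, 1.7)
  expect_equal(k_ouosc(0, p), 1.7)
  expect_equal(k_ouosc(pi / 4, p), -1.7 * exp(-1.2 * pi / 4),
               tolerance = 1e-12)
  # beta = 0 collapses exactly onto the aperiodic kernel
  taus <- seq(0, 10, by = 0.1)
  expect_equal(k_ouosc(taus, ouosc_params(2, 0, 1.3)),
               k_ou(taus, ou_params(2, 1.3)), tolerance = 1e-14)
})

test_that("the smooth-box prior has its stated shape", {
  pr <- smoothbox_prior()        # l = 1, L = 2, eta = 5
  expect_lt(smoothbox1(-5, pr), 1e-10)
  expect_lt(smoothbox1(10, pr), 1e-10)
  # centre value: S(2.5)^2 with S the logistic
  s25 <- 1 / (1 + exp(-2.5))
  expect_equal(smoothbox1(1.5, pr), s25^2, tolerance = 1e-10)
  for (d in c(0.1, 0.4, 0.9))
    expect_equal(smoothbox1(1.5 + d, pr), smoothbox1(1.5 - d, pr),
                 tolerance = 1e-12)
  expect_error(smoothbox_prior(l = 2, L = 1), "smaller")
})

test_that("log marginal likelihood agrees with a dense LU oracle", {
  # one-point closed form: y = 0, K(0) = 1, no noise
  expect_equal(log_marginal_likelihood(0, 0, ou_params(1, 1)),
               -0.5 * log(2 * pi), tolerance = 1e-12)
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    # alternate uniform and irregular grids to exercise both kernel paths
    tt <- if (i %% 2 == 0) sort(runif(n, 0, 12)) else 0.1 * (0:(n - 1))
    y <- rnorm(n)
    nv <- runif(1, 0, 0.5)
    if (i %% 3 == 0) {
      par <- ou_params(runif(1, 0.1, 20), runif(1, 0.5, 2))
      kf <- function(D) k_ou(D, par)
    } else {
      par <- ouosc_params(runif(1, 0.1, 5), runif(1, 0.5, 10),
                          runif(1, 0.5, 2))
      kf <- function(D) k_ouosc(D, par)
    }
    expect_equal(log_marginal_likelihood(y, tt, par, noise_model(nv)),
                 dense_lml_oracle(y, tt, kf, nv), tolerance = 1e-8)
  }
})

test_that("in the diagonal limit the likelihood follows the closed form", {
  # alpha so large that K is effectively sigma2 * I
  tt <- 0.1 * (0:19)
  y <- numeric(20)
  for (nv in c(0.1, 0.5, 2)) {
    got <- log_marginal_likelihood(y, tt, ou_params(1e6, 1),
                                   noise_model(nv))
    expect_equal(got, -0.5 * sum(log(rep(1 + nv, 20))) - 10 * log(2 * pi),
                 tolerance = 1e-6)
  }
})

test_that("the aperiodic lengthscale is recovered from simulated traces", {
  g <- time_grid(0, 0.1, 120)
  est <- vapply(1:20, function(i) {
    tr <- sample_ou_trace(ou_params(2, 1), g, seed = i)
    fit_ou(zscore(tr$values), times = tr$times)$params$alpha_ou
  }, numeric(1))
  expect_lt(abs(stats::median(est) - 2) / 2, 0.2)
  # faster-decorrelating population is clearly separated
  est15 <- vapply(1:20, function(i) {
    tr <- sample_ou_trace(ou_params(15, 1), g, seed = 100 + i)
    fit_ou(zscore(tr$values), times = tr$times)$params$alpha_ou
  }, numeric(1))
  expect_gt(stats::median(est15), 3 * stats::median(est))
})

test_that("white-noise traces pin the lengthscale at its upper bound", {
  set.seed(9)
  y <- zscore(rnorm(120))
  expect_warning(f <- fit_ou(y, times = 0.1 * (0:119)), "upper bound")
  expect_gt(f$params$alpha_ou, 900)
})

test_that("the oscillator period is recovered within 10%", {
  g <- time_grid(0, 0.1, 120)
  per <- vapply(1:10, function(i) {
    tr <- sample_ouosc_trace(ouosc_params(1, 2 * pi / 1.5, 1), g,
                             seed = 40 + i)
    2 * pi / fit_ouosc(zscore(tr$values), times = tr$times)$params$beta
  }, numeric(1))
  expect_lt(abs(stats::median(per) - 1.5) / 1.5, 0.10)
})

test_that("the prior suppresses periodic lengthscales far beyond its box", {
  g <- time_grid(0, 0.1, 120)
  pr <- smoothbox_prior()
  a_hat <- vapply(1:20, function(i) {
    tr <- sample_ou_trace(ou_params(2, 1), g, seed = 300 + i)
    y <- zscore(tr$values)
    suppressWarnings(
      fit_ouosc(y, prior = pr, times = tr$times)$params$alpha_ouosc)
  }, numeric(1))
  expect_gte(mean(a_hat <= pr$L + 3 / pr$eta), 0.95)
})

test_that("the LLR statistic behaves as a model-comparison score", {
  g <- time_grid(0, 0.1, 120)
  tr <- sample_ouosc_trace(ouosc_params(0.5, 2 * pi / 1.5, 1), g, seed = 1)
  res <- llr_test(tr)
  expect_equal(res$llr,
               2 * (res$fit_ouosc$log_marginal_likelihood -
                      res$fit_ou$log_marginal_likelihood))
  expect_equal(res$period_h, 2 * pi / res$fit_ouosc$params$beta)
  # a clean strong oscillation is overwhelmingly favoured
  tt <- grid_times(g)
  clean <- zscore(sin(2 * pi * tt / 1.5) + 0.05 * rnorm(120))
  expect_gt(suppressWarnings(llr_test(clean, times = tt))$llr, 10)
})

test_that("fits are invariant to time translation", {
  g <- time_grid(0, 0.1, 100)
  tr <- sample_ouosc_trace(ouosc_params(1, 2 * pi / 1.5, 1), g, seed = 6)
  y <- zscore(tr$values)
  f1 <- fit_ouosc(y, times = tr$times)
  f2 <- fit_ouosc(y, times = tr$times + 5)
  expect_equal(f1$params$alpha_ouosc, f2$params$alpha_ouosc,
               tolerance = 1e-8)
  expect_equal(f1$params$beta, f2$params$beta, tolerance = 1e-8)
})

test_that("lengthscale bias shrinks as traces grow longer", {
  bias_at <- function(n) {
    est <- vapply(1:12, function(i) {
      tr <- sample_ou_trace(ou_params(2, 1), time_grid(0, 0.1, n),
                            seed = 700 + i)
      fit_ou(zscore(tr$values), times = tr$times)$params$alpha_ou
    }, numeric(1))
    abs(stats::median(est) - 2)
  }
  expect_lte(bias_at(240), bias_at(60))
})
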