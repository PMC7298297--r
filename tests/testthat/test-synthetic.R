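test_that("OU sampler matches the closed-form autocovariance", {
  g <- time_grid(0, 0.1, 10000)
  tr <- sample_ou_trace(ou_params(2, 1.7), g, seed = 11)
  y <- tr$values
  # lag-1 autocorrelation: exp(-alpha * dt), tolerance 3 Monte-Carlo SEs
  r1 <- stats::cor(y[-1], y[-length(y)])
  rho <- exp(-2 * 0.1)
  se <- sqrt((1 - rho^2) / length(y))
  expect_lt(abs(r1 - rho), 3 * se + 0.01)
  # variance close to the configured 1.7 (autocorrelated draws inflate
  # the Monte-Carlo error of the sample variance; 10% is generous)
  expect_lt(abs(stats::var(y) - 1.7) / 1.7, 0.10)
  # white-noise limit: huge alpha decorrelates successive samples
  tw <- sample_ou_trace(ou_params(1000, 1), time_grid(0, 0.1, 5000),
                        seed = 2)
  expect_lt(abs(stats::cor(tw$values[-1], tw$values[-5000])), 0.05)
})

test_that("OU lag-k autocorrelation converges to exp(-alpha k dt)", {
  g <- time_grid(0, 0.1, 10000)
  tr <- sample_ou_trace(ou_params(3, 1), g, seed = 5)
  y <- tr$values
  for (k in c(1L, 3L, 7L)) {
    rk <- stats::cor(y[-(1:k)], y[seq_len(length(y) - k)])
    rho <- exp(-3 * k * 0.1)
    se <- sqrt((1 - rho^2) / (length(y) - k))
    expect_lt(abs(rk - rho), 3 * se + 0.01)
  }
})

test_that("OUosc sampler reproduces the damped-cosine covariance matrix", {
  g <- time_grid(0, 0.25, 20)
  p <- ouosc_params(1, 2 * pi / 1.5, 1)
  reps <- 2000L
  Y <- vapply(seq_len(reps), function(r)
    sample_ouosc_trace(p, g, seed = r)$values, numeric(20L))
  S <- tcrossprod(Y) / reps           # zero-mean process: raw second moment
  tt <- grid_times(g)
  K <- k_ouosc(outer(tt, tt, "-"), p)
  se <- sqrt((outer(diag(K), diag(K)) + K^2) / reps)
  expect_lt(max(abs(S - K) / se), 5)
})

test_that("at beta = 0 the dense-covariance sampler is an OU sampler", {
  g <- time_grid(0, 0.25, 20)
  reps <- 1500L
  Y <- vapply(seq_len(reps), function(r)
    sample_ouosc_trace(ouosc_params(2, 0, 1), g, seed = 3000 + r)$values,
    numeric(20L))
  S <- tcrossprod(Y) / reps
  tt <- grid_times(g)
  K <- k_ou(outer(tt, tt, "-"), ou_params(2, 1))
  se <- sqrt((outer(diag(K), diag(K)) + K^2) / reps)
  expect_lt(max(abs(S - K) / se), 5)
  # empirical autocovariance at half a period is the negated decayed
  # variance: K(pi/beta) = -sigma2 * exp(-alpha * pi / beta)
  p <- ouosc_params(1, 2 * pi / 1.5, 1)
  expect_equal(k_ouosc(pi / p$beta, p),
               -exp(-1 * pi / p$beta), tolerance = 1e-12)
})

test_that("OU recursion and dense Cholesky sampling agree in distribution", {
  # KS needs independent draws: take two well-separated points per
  # trace (lag 10 * 0.25 h at alpha = 2: correlation e^-5), giving
  # 5000 effectively independent marginals per sampler
  g <- time_grid(0, 0.25, 20)
  n_tr <- 2500L
  rec_m <- vapply(seq_len(n_tr), function(r)
    sample_ou_trace(ou_params(2, 1), g, seed = r)$values[c(5L, 15L)],
    numeric(2L))
  den_m <- vapply(seq_len(n_tr), function(r)
    sample_ouosc_trace(ouosc_params(2, 0, 1), g,
                       seed = 5000 + r)$values[c(5L, 15L)], numeric(2L))
  expect_gt(suppressWarnings(
    stats::ks.test(as.numeric(rec_m), as.numeric(den_m)))$p.value, 0.01)
  # lag-1 joint structure: distribution of successive-sample sums,
  # one pair per trace
  rec_p <- vapply(seq_len(n_tr), function(r) {
    v <- sample_ou_trace(ou_params(2, 1), g, seed = 40000 + r)$values
    v[10L] + v[11L]
  }, numeric(1L))
  den_p <- vapply(seq_len(n_tr), function(r) {
    v <- sample_ouosc_trace(ouosc_params(2, 0, 1), g,
                            seed = 60000 + r)$values
    v[10L] + v[11L]
  }, numeric(1L))
  expect_gt(suppressWarnings(stats::ks.test(rec_p, den_p))$p.value, 0.01)
})

test_that("technical noise is additive, seeded, and vanishes at sd 0", {
  g <- time_grid(0, 0.1, 2000)
  base <- trace("c", "venus", grid_times(g), numeric(2000))
  expect_identical(add_technical_noise(base, 0), base)
  noisy <- add_technical_noise(base, 3, seed = 4)
  expect_lt(abs(stats::sd(noisy$values) - 3) / 3, 0.05)
  sig <- sample_ou_trace(ou_params(2, 1), g, seed = 9)
  out <- add_technical_noise(sig, 0.5, seed = 10)
  expect_lt(abs(stats::var(out$values) -
                  (stats::var(sig$values) + 0.25)) / 1.25, 0.08)
  expect_error(add_technical_noise(base, -1), "non-negative")
  expect_identical(add_technical_noise(base, 2, seed = 1)$values,
                   add_technical_noise(base, 2, seed = 1)$values)
})

test_that("trend and bleach compose multiplicatively on the baseline", {
  g <- time_grid(0, 0.1, 121)
  sig <- trace("c", "venus", grid_times(g), numeric(121))
  # no bleach, no trend: affine shift to the baseline
  out <- add_trend_and_bleach(sig, 0, 6, 0, baseline = 50)
  expect_equal(out$values, rep(50, 121))
  # bleach to extinction is rejected
  expect_error(add_trend_and_bleach(sig, 0, 6, bleach_slope = 0.1,
                                    baseline = 1),
               "decay factor")
  expect_error(add_trend_and_bleach(sig, 0.1, 2, 0, baseline = 1),
               "cutoff")
})

test_that("injected bleaching and trends are recovered downstream", {
  g <- time_grid(0, 0.1, 121)
  traces <- lapply(1:30, function(i) {
    sig <- sample_ou_trace(ou_params(2, 0.01), g, seed = i, cell_id = i)
    add_trend_and_bleach(sig, 0, 6, bleach_slope = 0.02, baseline = 100)
  })
  expect_lt(abs(estimate_bleach_slope(traces) - 0.02) / 0.02, 0.05)
  # a 6 h trend sits in the detrending band and is mostly removed
  flat <- trace("c", "ratio", grid_times(g), numeric(121))
  trended <- add_trend_and_bleach(flat, 0.2, 6, 0, baseline = 1,
                                  trend_phase = 0.7)
  pre <- detrend(trended)
  resid_var <- stats::var(pre$detrended$values * pre$scale)
  expect_lt(resid_var / stats::var(trended$values), 0.10)
})

test_that("embryo datasets are deterministic and honestly labelled", {
  cfg <- synthetic_dataset_config(n_cells = 6, frac_oscillatory = 0.5,
                                  seed = 3, grid = time_grid(0, 0.1, 41))
  d1 <- make_embryo_dataset(cfg)
  d2 <- make_embryo_dataset(cfg)
  expect_identical(d1, d2)
  expect_equal(sum(d1$labels$label == "oscillatory"), 3)
  expect_equal(length(d1$backgrounds$venus), 2L)
  d0 <- make_embryo_dataset(synthetic_dataset_config(
    n_cells = 5, frac_oscillatory = 0, seed = 3,
    grid = time_grid(0, 0.1, 41)))
  expect_true(all(d0$labels$label == "aperiodic"))
  expect_error(synthetic_dataset_config(n_background = 1), "minimum")
})
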