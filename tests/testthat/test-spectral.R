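test_that("an on-grid cosine concentrates in a single bin", {
  n <- 64; fs <- 10
  tt <- (0:(n - 1)) / fs
  f0 <- 8 * fs / n                      # exact DFT frequency
  x <- cos(2 * pi * f0 * tt)
  sp <- periodogram(x, times = tt)
  peak_bin <- which.max(sp$power)
  expect_equal(sp$freqs[peak_bin], f0)
  expect_lt(max(sp$power[-peak_bin]) / sp$power[peak_bin], 1e-10)
})

test_that("the periodogram satisfies Parseval's identity", {
  set.seed(3)
  for (win in c("rectangular", "hamming")) {
    for (n in c(64, 101)) {
      tt <- (0:(n - 1)) * 0.1
      x <- rnorm(n)
      sp <- periodogram(x, window = win, times = tt)
      w <- if (win == "hamming")
        0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)) else rep(1, n)
      # rectangle-rule integral of the folded spectrum = mean square
      expect_equal(sum(sp$power) * sp$fs / n, mean((x * w)^2),
                   tolerance = 1e-8)
    }
  }
})

test_that("white noise yields a flat spectrum on average", {
  set.seed(11)
  n <- 128; reps <- 500
  tt <- (0:(n - 1)) * 0.1
  P <- vapply(seq_len(reps), function(r)
    periodogram(rnorm(n), times = tt)$power, numeric(n / 2 + 1))
  keep <- 2:(n / 2)                    # interior bins (DC and Nyquist are
  m <- rowMeans(P)[keep]               # unfolded, hence half the power)
  se <- apply(P, 1, stats::sd)[keep] / sqrt(reps)
  grand <- mean(m)
  expect_gte(mean(abs(m - grand) <= 3 * se), 0.95)
  expect_true(all(abs(m - grand) <= 5 * se))
})

test_that("psd normalisation integrates to one", {
  set.seed(5)
  tt <- (0:199) * 0.1
  sp <- periodogram(rnorm(200), normalization = "psd", times = tt)
  expect_lt(abs(oracle_trapz(sp$freqs, sp$power) - 1), 1e-6)
})

test_that("aggregation is a per-bin mean with grid checking", {
  set.seed(6)
  tt <- (0:99) * 0.1
  s1 <- periodogram(rnorm(100), times = tt)
  expect_equal(aggregate_spectrum(list(s1))$power, s1$power)
  expect_equal(aggregate_spectrum(list(s1, s1))$power, s1$power)
  s2 <- periodogram(rnorm(100), times = tt)
  expect_equal(aggregate_spectrum(list(s1, s2))$power,
               (s1$power + s2$power) / 2)
  # delta-like spectra at distinct bins average to equal peaks
  d1 <- s1; d1$power <- replace(numeric(51), 11, 1)
  d2 <- s1; d2$power <- replace(numeric(51), 31, 1)
  agg <- aggregate_spectrum(list(d1, d2))
  expect_equal(agg$power[11], 0.5)
  expect_equal(agg$power[31], 0.5)
  s3 <- periodogram(rnorm(120), times = (0:119) * 0.1)
  expect_error(aggregate_spectrum(list(s1, s3)), "different frequency")
})

test_that("coherence concentrates to 100% for a one-bin spectrum", {
  freqs <- seq(0, 5, by = 0.05)
  power <- rep(1e-9, length(freqs))
  power[freqs == 4] <- 100
  sp <- structure(list(freqs = freqs, power = power,
                       normalization = "power", window = "rectangular",
                       fs = 10, n = 200), class = "spectrum")
  expect_gt(as.numeric(coherence(sp)), 95)
})

test_that("coherence matches an independent integration oracle", {
  freqs <- seq(0, 5, by = 0.025)
  power <- 1 + 0.5 * exp(-(freqs - 2.5)^2 / (2 * 0.4^2))
  sp <- structure(list(freqs = freqs, power = power,
                       normalization = "power", window = "rectangular",
                       fs = 10, n = 400), class = "spectrum")
  got <- coherence(sp)
  fp <- attr(got, "peak_frequency")
  expect_lt(abs(fp - 2.5), 0.2)       # fitted peak near the true bump
  f <- freqs[freqs > 0]; p <- power[freqs > 0]
  fine <- seq(fp * 0.95, fp * 1.05, length.out = 2001)
  band <- oracle_trapz(fine, stats::approx(f, p, fine)$y)
  expect_equal(as.numeric(got), 100 * band / oracle_trapz(f, p),
               tolerance = 1e-3)
})

test_that("coherence and high-frequency contribution are scale invariant", {
  set.seed(8)
  tt <- (0:199) * 0.1
  x <- as.numeric(scale(rnorm(200) + sin(2 * pi * tt / 1.5)))
  s1 <- periodogram(x, times = tt)
  s2 <- s1; s2$power <- s2$power * 37.5
  expect_equal(as.numeric(coherence(s1)), as.numeric(coherence(s2)),
               tolerance = 1e-10)
  p1 <- periodogram(x, normalization = "psd", times = tt)
  p2 <- periodogram(3.3 * x, normalization = "psd", times = tt)
  expect_equal(high_freq_contribution(p1), high_freq_contribution(p2),
               tolerance = 1e-10)
})

test_that("high-frequency contribution has the right limits and errors", {
  tt <- (0:399) * 0.1
  slow <- sin(2 * pi * tt / 4)          # 0.25 cycles/h, far below cutoff
  expect_lt(high_freq_contribution(
    periodogram(slow, normalization = "psd", times = tt)), 1)
  fast <- sin(2 * pi * tt * 2.5)        # 2.5 cycles/h, above cutoff
  expect_gt(high_freq_contribution(
    periodogram(fast, normalization = "psd", times = tt)), 99)
  sp <- periodogram(slow, normalization = "psd", times = tt)
  expect_error(high_freq_contribution(sp, cutoff = 5), "Nyquist")
  expect_error(high_freq_contribution(periodogram(slow, times = tt)),
               "psd")
})

test_that("sharper oscillators have higher coherence; faster noise more HF", {
  g <- time_grid(0, 0.1, 121)
  coh_at <- function(alpha) {
    specs <- lapply(1:60, function(i)
      periodogram(zscore(sample_ouosc_trace(
        ouosc_params(alpha, 2 * pi / 1.5, 1), g,
        seed = 1000 * alpha + i)$values), times = grid_times(g)))
    as.numeric(coherence(aggregate_spectrum(specs)))
  }
  cohs <- vapply(c(1, 2, 4), coh_at, numeric(1))
  expect_true(all(diff(cohs) < 0))

  hf_at <- function(alpha) {
    mean(vapply(1:60, function(i)
      high_freq_contribution(periodogram(
        zscore(sample_ou_trace(ou_params(alpha, 1), g,
                               seed = 2000 * alpha + i)$values),
        normalization = "psd", times = grid_times(g))), numeric(1)))
  }
  hfs <- vapply(c(2, 15, 100), hf_at, numeric(1))
  expect_true(all(diff(hfs) > 0))
})
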