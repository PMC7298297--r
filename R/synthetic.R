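#' Sample an aperiodic Ornstein-Uhlenbeck trace
#'
#' Draws a stationary, zero-mean trace whose autocovariance is
#' \eqn{K_{OU}(\tau) = \sigma^2 e^{-\alpha_{OU}\tau}} using the exact
#' discrete-time recursion
#' \eqn{y_{t+dt} = y_t e^{-\alpha dt} + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2(1 - e^{-2\alpha dt}))}, initialised
#' from the stationary law.  The recursion is exact for the OU process,
#' so no time-discretisation error is incurred.
#'
#' @param params An [ou_params()] object.
#' @param grid A [time_grid()].
#' @param seed Optional integer seed; the same seed gives an identical
#'   trace and the global RNG stream is left untouched.
#' @param cell_id,channel Metadata for the returned [trace()].
#' @return A zero-mean [trace()].
#' @examples
#' tr <- sample_ou_trace(ou_params(2, 1), time_grid(0, 0.1, 200), seed = 1)
#' var(tr$values)
#' @export
sample_ou_trace <- function(params, grid, seed = NULL,
                            cell_id = "sim", channel = "venus") {
  stopifnot(inherits(params, "ou_params"), inherits(grid, "time_grid"))
  z <- with_seed(seed, stats::rnorm(grid$n))
  y <- ou_path(z, params$alpha_ou, params$sigma2, grid$dt)
  trace(cell_id, channel, grid_times(grid), y)
}

# exact OU update driven by standard normal innovations z
ou_path <- function(z, alpha, sigma2, dt) {
  e <- exp(-alpha * dt)
  innov <- sqrt(sigma2 * (1 - e^2)) * z
  innov[1L] <- sqrt(sigma2) * z[1L]             # stationary start
  as.numeric(stats::filter(innov, e, method = "recursive"))
}

#' Sample an oscillatory Ornstein-Uhlenbeck trace
#'
#' Draws a zero-mean trace from the multivariate normal whose covariance
#' is \eqn{K_{OUosc}(\tau) = \sigma^2 e^{-\alpha\tau}\cos(\beta\tau)}
#' evaluated on the grid.  The damped-cosine kernel has no simple
#' one-step recursion, so the dense covariance is factorised by
#' Cholesky with a small diagonal jitter (starting at `1e-6 * sigma2`,
#' escalating tenfold up to `1e-2 * sigma2` before failing).
#'
#' @inheritParams sample_ou_trace
#' @param params An [ouosc_params()] object.
#' @return A zero-mean [trace()].
#' @export
sample_ouosc_trace <- function(params, grid, seed = NULL,
                               cell_id = "sim", channel = "venus") {
  stopifnot(inherits(params, "ouosc_params"), inherits(grid, "time_grid"))
  tt <- grid_times(grid)
  D <- abs(outer(tt, tt, "-"))
  K <- params$sigma2 * exp(-params$alpha_ouosc * D) * cos(params$beta * D)
  U <- chol_with_jitter(K, jitter0 = 1e-6 * params$sigma2,
                        jitter_max = 1e-2 * params$sigma2)
  z <- with_seed(seed, stats::rnorm(grid$n))
  trace(cell_id, channel, tt, drop(crossprod(U, z)))
}

# Cholesky with escalating diagonal jitter; returns the upper factor.
chol_with_jitter <- function(K, jitter0, jitter_max) {
  U <- tryCatch(chol(K), error = function(e) NULL)
  jit <- jitter0
  while (is.null(U) && jit <= jitter_max) {
    U <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    jit <- jit * 10
  }
  if (is.null(U))
    stop("covariance factorization failed even with jitter up to ",
         format(jitter_max), call. = FALSE)
  U
}

#' Add i.i.d. Gaussian technical noise to a trace
#'
#' Emulates measurement noise of the magnitude observed in background
#' tracks: an independent Gaussian random variable per sample.
#'
#' @param trace A [trace()].
#' @param noise_sd Standard deviation of the technical noise (>= 0);
#'   zero returns the input unchanged.
#' @param seed Optional integer seed.
#' @return A [trace()] with noisy values.
#' @export
add_technical_noise <- function(trace, noise_sd, seed = NULL) {
  stopifnot(inherits(trace, "trace"))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L ||
      !is.finite(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be a single non-negative number")
  if (noise_sd == 0) return(trace)
  trace$values <- trace$values +
    noise_sd * with_seed(seed, stats::rnorm(length(trace$values)))
  trace
}

#' Superimpose a slow trend and linear photobleaching on a signal
#'
#' Builds a raw-intensity trace from a dimensionless signal:
#' `baseline * (1 - bleach_slope * t) * (1 + trend + signal)`, with
#' `t` measured from the first time point and
#' `trend = trend_amplitude * sin(2*pi*t/trend_timescale + trend_phase)`.
#' Bleaching is multiplicative on the baseline because fluorescence
#' loss scales with the signal itself.  The trend timescale must exceed
#' the 3 h detrending cutoff so that the injected trend lies in the band
#' the preprocessing stage removes.
#'
#' @param trace A [trace()] holding the dimensionless signal.
#' @param trend_amplitude Relative amplitude of the slow trend.
#' @param trend_timescale Period of the slow trend (h); must exceed 3 h.
#' @param bleach_slope Linear decay rate (fraction of baseline per h).
#' @param baseline Positive baseline intensity (arbitrary units).
#' @param trend_phase Phase of the trend sinusoid (rad).
#' @return A [trace()] on the raw intensity scale.
#' @export
add_trend_and_bleach <- function(trace, trend_amplitude = 0,
                                 trend_timescale = 6, bleach_slope = 0,
                                 baseline = 1, trend_phase = 0) {
  stopifnot(inherits(trace, "trace"))
  if (baseline <= 0) stop("`baseline` must be positive")
  if (trend_amplitude != 0 && trend_timescale <= 3)
    stop("`trend_timescale` must exceed the 3 h detrending cutoff")
  trel <- trace$times - trace$times[1L]
  decay <- 1 - bleach_slope * trel
  if (any(decay <= 0))
    stop("bleaching too strong: intensity decay factor reaches zero")
  trend <- trend_amplitude * sin(2 * pi * trel / trend_timescale + trend_phase)
  trace$values <- baseline * decay * (1 + trend + trace$values)
  trace
}

#' Configuration of a synthetic two-channel "embryo" dataset
#'
#' Defaults emulate the live-imaging regime the analysis assumes:
#' sampling every 6 min (dt = 0.1 h) for 12 h, paired reporter
#' ("venus") and nuclear-marker ("h2b") channels, minimal Venus
#' photobleaching and more pronounced H2B bleaching, a slow sinusoidal
#' trend in the detrending band, additive white technical noise per
#' channel, and at least two background tracks per channel.  Single-cell
#' dynamics are drawn from the aperiodic OU model (control-like
#' `alpha_ou = 2` per hour) or the oscillatory OUosc model (period
#' 1.5 h); a faster-decorrelating population uses `alpha_ou = 15`.
#'
#' @param n_cells Number of cells.
#' @param frac_oscillatory Fraction of cells whose reporter channel is
#'   built on OUosc dynamics (the rest are aperiodic OU).
#' @param ou,ouosc [ou_params()] / [ouosc_params()] generating the
#'   dimensionless single-cell signal (variance on the relative
#'   intensity scale).
#' @param noise_sd Named numeric: technical-noise sd per channel, raw
#'   intensity units.
#' @param bleach_slope Named numeric: linear decay per channel
#'   (fraction/h).
#' @param trend_amplitude,trend_timescale Slow-trend relative amplitude
#'   and period (h).
#' @param baseline Named numeric: baseline intensity per channel.
#' @param background_level Named numeric: mean level of background
#'   tracks per channel.
#' @param n_background Background traces per channel (>= 2, mirroring
#'   the minimum of two background tracks per experiment per channel).
#' @param grid A [time_grid()].
#' @param param_jitter_sd Optional log-normal sd applied per cell to the
#'   lengthscale parameters (0 = fixed parameters per condition).
#' @param seed Integer seed; the whole dataset is deterministic in it.
#' @return A list of class `synthetic_dataset_config`.
#' @export
synthetic_dataset_config <- function(n_cells = 50,
                                     frac_oscillatory = 0.5,
                                     ou = ou_params(2, 0.04),
                                     ouosc = ouosc_params(0.5, 2 * pi / 1.5, 0.04),
                                     noise_sd = c(venus = 10, h2b = 5),
                                     bleach_slope = c(venus = 0.005, h2b = 0.02),
                                     trend_amplitude = 0.1,
                                     trend_timescale = 6,
                                     baseline = c(venus = 100, h2b = 500),
                                     background_level = c(venus = 10, h2b = 10),
                                     n_background = 2,
                                     grid = time_grid(0, 0.1, 121),
                                     param_jitter_sd = 0,
                                     seed = 1) {
  if (frac_oscillatory < 0 || frac_oscillatory > 1)
    stop("`frac_oscillatory` must lie in [0, 1]")
  if (any(noise_sd < 0)) stop("`noise_sd` must be non-negative")
  if (n_background < 2)
    stop("`n_background` must be >= 2 (minimum two backgrounds per channel)")
  stopifnot(inherits(ou, "ou_params"), inherits(ouosc, "ouosc_params"),
            inherits(grid, "time_grid"))
  structure(list(n_cells = as.integer(n_cells),
                 frac_oscillatory = frac_oscillatory,
                 ou = ou, ouosc = ouosc,
                 noise_sd = noise_sd, bleach_slope = bleach_slope,
                 trend_amplitude = trend_amplitude,
                 trend_timescale = trend_timescale,
                 baseline = baseline, background_level = background_level,
                 n_background = as.integer(n_background),
                 grid = grid, param_jitter_sd = param_jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_dataset_config")
}

#' Generate a full synthetic "embryo" dataset
#'
#' Produces paired Venus/H2B traces on a common grid plus background
#' tracks per channel and a ground-truth table.  The configured
#' fraction of Venus signals is built on oscillatory OUosc dynamics,
#' the rest on aperiodic OU dynamics; H2B channels carry only
#' trend + bleach + technical noise (no ultradian signal), which makes
#' them usable as a negative control through the identical pipeline.
#'
#' @param config A [synthetic_dataset_config()].
#' @return A list of class `embryo_dataset` with elements `cells`
#'   (list of `list(venus, h2b)` trace pairs), `backgrounds` (lists of
#'   background traces per channel), `labels` (ground-truth data frame),
#'   `grid` and `config`.
#' @export
make_embryo_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_dataset_config"))
  cfg <- config
  grid <- cfg$grid
  n_osc <- round(cfg$frac_oscillatory * cfg$n_cells)
  with_seed(cfg$seed, {
    cells <- vector("list", cfg$n_cells)
    labels <- vector("list", cfg$n_cells)
    for (i in seq_len(cfg$n_cells)) {
      id <- sprintf("cell_%03d", i)
      oscillatory <- i <= n_osc
      jit <- function(x) {
        if (cfg$param_jitter_sd > 0)
          x * exp(stats::rnorm(1, 0, cfg$param_jitter_sd)) else x
      }
      if (oscillatory) {
        p <- ouosc_params(jit(cfg$ouosc$alpha_ouosc), cfg$ouosc$beta,
                          cfg$ouosc$sigma2)
        sig <- sample_ouosc_trace(p, grid, cell_id = id)
        labels[[i]] <- data.frame(cell_id = id, label = "oscillatory",
                                  alpha = p$alpha_ouosc, beta = p$beta,
                                  period_h = 2 * pi / p$beta,
                                  sigma2 = p$sigma2)
      } else {
        p <- ou_params(jit(cfg$ou$alpha_ou), cfg$ou$sigma2)
        sig <- sample_ou_trace(p, grid, cell_id = id)
        labels[[i]] <- data.frame(cell_id = id, label = "aperiodic",
                                  alpha = p$alpha_ou, beta = NA_real_,
                                  period_h = NA_real_, sigma2 = p$sigma2)
      }
      venus <- add_trend_and_bleach(sig,
                                    trend_amplitude = cfg$trend_amplitude,
                                    trend_timescale = cfg$trend_timescale,
                                    bleach_slope = cfg$bleach_slope[["venus"]],
                                    baseline = cfg$baseline[["venus"]],
                                    trend_phase = stats::runif(1, 0, 2 * pi))
      venus <- add_technical_noise(venus, cfg$noise_sd[["venus"]])
      flat <- trace(id, "h2b", grid_times(grid), numeric(grid$n))
      h2b <- add_trend_and_bleach(flat,
                                  trend_amplitude = cfg$trend_amplitude,
                                  trend_timescale = cfg$trend_timescale,
                                  bleach_slope = cfg$bleach_slope[["h2b"]],
                                  baseline = cfg$baseline[["h2b"]],
                                  trend_phase = stats::runif(1, 0, 2 * pi))
      h2b <- add_technical_noise(h2b, cfg$noise_sd[["h2b"]])
      cells[[i]] <- list(venus = venus, h2b = h2b)
    }
    backgrounds <- list(venus = vector("list", cfg$n_background),
                        h2b = vector("list", cfg$n_background))
    for (ch in c("venus", "h2b")) {
      for (j in seq_len(cfg$n_background)) {
        vals <- cfg$background_level[[ch]] +
          cfg$noise_sd[[ch]] * stats::rnorm(grid$n)
        backgrounds[[ch]][[j]] <- trace(sprintf("bg_%s_%02d", ch, j),
                                        paste0(ch, "_background"),
                                        grid_times(grid), vals)
      }
    }
    structure(list(cells = cells, backgrounds = backgrounds,
                   labels = do.call(rbind, labels),
                   grid = grid, config = cfg),
              class = "embryo_dataset")
  })
}

#' @export
print.embryo_dataset <- function(x, ...) {
  cat(sprintf(paste0("<embryo_dataset> %d cells (%d oscillatory by ",
                     "construction), %d background traces/channel, ",
                     "%d time points, dt = %.3g h\n"),
              length(x$cells), sum(x$labels$label == "oscillatory"),
              length(x$backgrounds$venus), x$grid$n, x$grid$dt))
  invisible(x)
}
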