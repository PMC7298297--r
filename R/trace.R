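#' Uniform sampling grid for a time series
#'
#' Time is measured in hours throughout the package; the default grid
#' corresponds to imaging every 6 minutes for 12 hours.
#'
#' @param t0 Start time (h).
#' @param dt Sampling interval (h); must be positive.
#' @param n Number of samples; at least 2.
#' @return An object of class `time_grid`.
#' @examples
#' g <- time_grid(0, 0.1, 121)
#' range(grid_times(g))
#' @export
time_grid <- function(t0 = 0, dt = 0.1, n = 121) {
  stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (hours)")
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2")
  structure(list(t0 = t0, dt = dt, n = n), class = "time_grid")
}

#' @rdname time_grid
#' @param grid A `time_grid`.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t0 + grid$dt * (seq_len(grid$n) - 1L)
}

#' Single-cell intensity trace
#'
#' A uniformly sampled intensity time series for one cell and one
#' channel, the basic currency of the analysis pipeline.
#'
#' @param cell_id Identifier for the cell (or background track).
#' @param channel One of `"venus"`, `"h2b"`, `"venus_background"`,
#'   `"h2b_background"`, or `"ratio"` for derived reporter/nuclear traces.
#' @param times Strictly increasing, uniformly spaced time points (h);
#'   relative deviation of the spacing must be below 1e-6.
#' @param values Finite intensity values, same length as `times`.
#' @param z_position Optional depth (micrometres) per time point, used
#'   only for QC reporting.
#' @return An object of class `trace`.
#' @export
trace <- function(cell_id, channel, times, values, z_position = NULL) {
  channel <- match.arg(channel,
                       c("venus", "h2b", "venus_background",
                         "h2b_background", "ratio"))
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2L) stop("a trace needs at least 2 time points")
  if (length(values) != length(times))
    stop("`times` and `values` lengths differ")
  if (!all(is.finite(values))) stop("trace values must be finite")
  check_uniform_times(times)
  if (!is.null(z_position)) {
    z_position <- as.numeric(z_position)
    if (length(z_position) != length(times))
      stop("`z_position` length must match `times`")
  }
  structure(list(cell_id = as.character(cell_id), channel = channel,
                 times = times, values = values, z_position = z_position),
            class = "trace")
}

# error unless spacing is uniform to relative tolerance 1e-6
check_uniform_times <- function(times, what = "trace") {
  dts <- diff(times)
  if (any(dts <= 0)) stop(what, ": times must be strictly increasing")
  m <- mean(dts)
  if (max(abs(dts - m)) / m >= 1e-6)
    stop(what, ": time grid is not uniform (relative deviation >= 1e-6)")
  invisible(m)
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> cell %s, channel %s: %d points, t = [%.3g, %.3g] h\n",
              x$cell_id, x$channel, length(x$times),
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

trace_dt <- function(trace) mean(diff(trace$times))

#' Parameters of the aperiodic Ornstein-Uhlenbeck covariance model
#'
#' The aperiodic model has covariance
#' \eqn{K_{OU}(\tau) = \sigma^2 \exp(-\alpha_{OU} \tau)}: `alpha_ou` is
#' the aperiodic lengthscale (1/h), the rate at which temporal
#' autocorrelation decays, and `sigma2` the signal variance (1 for
#' z-scored data).
#'
#' @param alpha_ou Aperiodic lengthscale (1/h), positive.
#' @param sigma2 Signal variance, positive.
#' @return An object of class `ou_params`.
#' @export
ou_params <- function(alpha_ou, sigma2 = 1) {
  if (!is.numeric(alpha_ou) || length(alpha_ou) != 1L ||
      !is.finite(alpha_ou) || alpha_ou <= 0)
    stop("`alpha_ou` must be a single positive number")
  if (!is.numeric(sigma2) || length(sigma2) != 1L ||
      !is.finite(sigma2) || sigma2 <= 0)
    stop("`sigma2` must be a single positive number")
  structure(list(alpha_ou = alpha_ou, sigma2 = sigma2),
            class = "ou_params")
}

#' Parameters of the oscillatory Ornstein-Uhlenbeck covariance model
#'
#' The oscillatory model multiplies the OU decay by a cosine:
#' \eqn{K_{OUosc}(\tau) = \sigma^2 \exp(-\alpha_{OUosc}\tau)\cos(\beta\tau)},
#' describing stochastic oscillations with period \eqn{P = 2\pi/\beta}
#' whose peak-to-peak phase coherence decays at rate `alpha_ouosc`.
#'
#' @param alpha_ouosc Periodic lengthscale (1/h), positive.
#' @param beta Angular frequency (rad/h), non-negative; `beta = 0`
#'   degenerates exactly to the aperiodic OU kernel (cos(0) = 1).
#' @param sigma2 Signal variance, positive.
#' @return An object of class `ouosc_params`.
#' @export
ouosc_params <- function(alpha_ouosc, beta, sigma2 = 1) {
  if (!is.numeric(alpha_ouosc) || length(alpha_ouosc) != 1L ||
      !is.finite(alpha_ouosc) || alpha_ouosc <= 0)
    stop("`alpha_ouosc` must be a single positive number")
  if (!is.numeric(beta) || length(beta) != 1L ||
      !is.finite(beta) || beta < 0)
    stop("`beta` must be a single non-negative number")
  if (!is.numeric(sigma2) || length(sigma2) != 1L ||
      !is.finite(sigma2) || sigma2 <= 0)
    stop("`sigma2` must be a single positive number")
  structure(list(alpha_ouosc = alpha_ouosc, beta = beta, sigma2 = sigma2),
            class = "ouosc_params")
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the global
# RNG state afterwards.  seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# deterministic sub-seed derivation; stays inside 32-bit integer range
mix_seed <- function(seed, stage, i = 0L) {
  s <- (as.double(seed) %% 1e6) * 1009 + stage * 9973 + i * 97
  as.integer(s %% 2147483647)
}
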