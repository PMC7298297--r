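#' Estimate the linear photobleaching rate of a channel
#'
#' Fits an ordinary least-squares line through the population-mean
#' intensity versus time and expresses its slope as a fraction of the
#' fitted t = 0 intercept per hour, so an intensity decaying as
#' `I0 * (1 - s * t)` returns `s`.  Bleaching is estimated per channel
#' across all traces of an experiment (a per-cell call with a single
#' trace is allowed).
#'
#' @param traces Non-empty list of [trace()]s from one channel, sharing
#'   a common grid.
#' @return Decay rate (fraction of intercept per hour); positive values
#'   mean decaying intensity.
#' @export
estimate_bleach_slope <- function(traces) {
  if (inherits(traces, "trace")) traces <- list(traces)
  if (length(traces) == 0L) stop("need at least one trace")
  tt <- traces[[1L]]$times
  for (tr in traces)
    if (length(tr$times) != length(tt) || max(abs(tr$times - tt)) > 1e-8)
      stop("all traces must share a common time grid")
  m <- rowMeans(vapply(traces, function(tr) tr$values, numeric(length(tt))))
  trel <- tt - tt[1L]
  fit <- stats::lm.fit(cbind(1, trel), m)
  a <- fit$coefficients[[1L]]
  b <- fit$coefficients[[2L]]
  if (abs(a) < .Machine$double.eps * 100)
    stop("fitted t = 0 intercept is zero; cannot express slope as a fraction")
  -b / a
}

#' Correct a trace for linear photobleaching
#'
#' Divides intensities by the normalised linear decay `1 - slope * t`
#' (t measured from the first time point), the algebraic inverse of the
#' multiplicative bleaching model.
#'
#' @param trace A [trace()].
#' @param slope Decay rate (fraction/h), e.g. from
#'   [estimate_bleach_slope()]; zero is the identity.
#' @return Corrected [trace()].
#' @export
correct_bleaching <- function(trace, slope) {
  stopifnot(inherits(trace, "trace"), is.numeric(slope), length(slope) == 1L)
  if (slope == 0) return(trace)
  decay <- 1 - slope * (trace$times - trace$times[1L])
  if (any(decay <= 0))
    stop("decay factor non-positive over the grid; slope too large")
  trace$values <- trace$values / decay
  trace
}

#' Normalise the reporter channel to the nuclear marker
#'
#' Pointwise ratio Venus/H2B, removing global concentration changes
#' (imaging depth, acquisition fluctuations) shared by both channels.
#'
#' @param venus,h2b [trace()]s on the same grid; `h2b` must be strictly
#'   positive.
#' @return A `ratio` channel [trace()] (Venus z-position carried over).
#' @export
normalize_to_nuclear <- function(venus, h2b) {
  stopifnot(inherits(venus, "trace"), inherits(h2b, "trace"))
  if (length(venus$times) != length(h2b$times) ||
      max(abs(venus$times - h2b$times)) > 1e-8)
    stop("venus and h2b traces must share the same time grid")
  bad <- which(h2b$values <= 0)
  if (length(bad))
    stop(sprintf("non-positive H2B value at time %.4g h (index %d)",
                 h2b$times[bad[1L]], bad[1L]))
  trace(venus$cell_id, "ratio", venus$times, venus$values / h2b$values,
        z_position = venus$z_position)
}

# Slow-trend estimator: orthogonal projection onto the numerically
# supported leading eigenmodes of the squared-exponential kernel with
# the stated lengthscale (its noise-free Gaussian-process regression
# limit).  Modes with relative eigenvalue >= rel_tol are kept; the SE
# spectrum decays super-exponentially, so the retained count is
# insensitive to the threshold (identical over 1e-3..1e-4 on the
# default grid).  A projection is exactly idempotent, which keeps
# repeated detrending stable.
gp_trend <- function(times, values, lengthscale, rel_tol = 1e-3) {
  mu <- mean(values)
  y <- values - mu
  if (stats::var(y) < .Machine$double.eps) return(rep(mu, length(values)))
  D <- outer(times, times, "-")
  K <- exp(-D^2 / (2 * lengthscale^2))
  eg <- eigen(K, symmetric = TRUE)
  k <- sum(eg$values >= rel_tol * eg$values[1L])
  B <- eg$vectors[, seq_len(k), drop = FALSE]
  mu + drop(B %*% crossprod(B, y))
}

#' Remove slow trends and z-score a trace
#'
#' Long-term trends (timescales above the cutoff, default 3 h) are
#' estimated by Gaussian-process regression with a squared-exponential
#' covariance whose lengthscale equals the cutoff, realised as the
#' orthogonal projection onto the kernel's numerically supported
#' leading eigenmodes (the noise-free regression limit, which makes
#' detrending exactly idempotent); the residual is z-scored so the
#' downstream covariance models see a signal with variance 1.  A cubic
#' polynomial trend is available as a fallback estimator.
#'
#' @param trace A [trace()].
#' @param cutoff Trend timescale boundary (h); the trace must be longer
#'   than this.
#' @param method `"gp"` (default) or `"poly"` (cubic polynomial).
#' @param zscore If `FALSE`, return the raw residual without z-scoring
#'   (used for background-noise calibration).
#' @return A list of class `preprocessed_trace`:
#'   `detrended` (z-scored residual [trace()]), `trend` ([trace()]),
#'   `center`/`scale` (affine bookkeeping: `ratio = trend +
#'   center + scale * detrended`), and the input trace as `ratio`.
#' @export
detrend <- function(trace, cutoff = 3, method = c("gp", "poly"),
                    zscore = TRUE) {
  stopifnot(inherits(trace, "trace"))
  method <- match.arg(method)
  dur <- trace$times[length(trace$times)] - trace$times[1L]
  if (dur <= cutoff)
    stop(sprintf("trace duration (%.3g h) must exceed the cutoff (%.3g h)",
                 dur, cutoff))
  tr_vals <- switch(method,
    gp = gp_trend(trace$times, trace$values, cutoff),
    poly = {
      fit <- stats::lm(trace$values ~ stats::poly(trace$times, 3))
      as.numeric(stats::fitted(fit))
    })
  resid <- trace$values - tr_vals
  center <- mean(resid)
  s <- stats::sd(resid)
  if (zscore) {
    if (s < 1e-12)
      stop("degenerate trace: residual variance is zero, cannot z-score")
    out <- (resid - center) / s
  } else {
    out <- resid
    center <- 0
    s <- 1
  }
  structure(list(
    detrended = trace(trace$cell_id, trace$channel, trace$times, out,
                      z_position = trace$z_position),
    trend = trace(trace$cell_id, trace$channel, trace$times, tr_vals),
    center = center, scale = s, ratio = trace),
    class = "preprocessed_trace")
}

#' QC correlation of intensity with imaging depth
#'
#' Pearson correlation between a trace's intensity and its recorded
#' z-position.  The value is reported for quality control only and is
#' never used to alter the data (no z-correction is applied in the
#' pipeline).
#'
#' @param trace A [trace()] with `z_position` recorded.
#' @return Correlation coefficient; `NaN` with a warning when the
#'   intensity (or depth) is constant.
#' @export
qc_z_correlation <- function(trace) {
  stopifnot(inherits(trace, "trace"))
  if (is.null(trace$z_position))
    stop("trace has no z_position; cannot compute depth correlation")
  if (stats::sd(trace$values) == 0 || stats::sd(trace$z_position) == 0) {
    warning("constant intensity or depth: correlation undefined")
    return(NaN)
  }
  stats::cor(trace$values, trace$z_position)
}

#' Full per-cell preprocessing chain
#'
#' Bleach-corrects both channels, normalises Venus to H2B, and detrends
#' and z-scores the ratio: the exact sequence applied to raw traces
#' before Gaussian-process model comparison.
#'
#' @param venus,h2b Raw [trace()]s for one cell.
#' @param venus_slope,h2b_slope Per-channel bleaching rates (from
#'   [estimate_bleach_slope()] on the experiment's traces).
#' @param cutoff Detrending cutoff (h).
#' @param method Trend estimator passed to [detrend()].
#' @return A `preprocessed_trace` (see [detrend()]).
#' @export
preprocess_cell <- function(venus, h2b, venus_slope = 0, h2b_slope = 0,
                            cutoff = 3, method = "gp") {
  v <- correct_bleaching(venus, venus_slope)
  h <- correct_bleaching(h2b, h2b_slope)
  detrend(normalize_to_nuclear(v, h), cutoff = cutoff, method = method)
}
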