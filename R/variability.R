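#' Local coefficient of variation of a trace
#'
#' The coefficient of variation (sd/mean) computed in local time
#' windows (default 1.5 h) and averaged over windows, which measures
#' expression variability while discounting slow changes in mean level.
#' Windows are contiguous and non-overlapping by default, with a final
#' partial window dropped; a sliding one-sample-stride variant is
#' available via `overlap = TRUE`.
#'
#' @param trace A positive-mean [trace()] (typically the Venus/H2B
#'   ratio before z-scoring).
#' @param window Window duration (h), default 1.5.
#' @param overlap Use overlapping windows with a one-sample stride.
#' @return The per-cell LCOV (a single non-negative number).
#' @export
local_cov <- function(trace, window = 1.5, overlap = FALSE) {
  stopifnot(inherits(trace, "trace"))
  if (window <= 0) stop("`window` must be positive")
  dt <- trace_dt(trace)
  w <- floor(window / dt + 1e-9)
  if (w < 2L) stop("window shorter than two samples")
  n <- length(trace$values)
  if (n < w) stop("trace shorter than one window")
  starts <- if (overlap) seq_len(n - w + 1L) else seq(1L, n - w + 1L, by = w)
  covs <- vapply(starts, function(s) {
    seg <- trace$values[s:(s + w - 1L)]
    m <- mean(seg)
    if (m <= 0)
      stop(sprintf("non-positive window mean at t = %.3g h", trace$times[s]))
    stats::sd(seg) / m
  }, numeric(1L))
  mean(covs)
}

#' Ratio of median local coefficients of variation between two groups
#'
#' `median(group_a) / median(group_b)`, the summary used to compare the
#' variability of one condition against another (e.g. a mutant against
#' its control).
#'
#' @param group_a,group_b Non-empty numeric vectors of per-cell LCOVs.
#' @return The ratio of medians.
#' @export
lcov_ratio <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  mb <- stats::median(group_b)
  if (mb == 0) stop("median of `group_b` is zero")
  stats::median(group_a) / mb
}

#' Sample excess kurtosis
#'
#' Fourth standardised moment minus 3 (bias-uncorrected moment
#' estimator), so a normal distribution scores 0.  Used to quantify
#' heterogeneity of expression-level distributions: heavy-tailed or
#' bimodal level distributions depart from the normal null.
#'
#' @param values Numeric vector, length >= 4, non-zero variance.
#' @return Excess kurtosis.
#' @export
excess_kurtosis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L) stop("need at least 4 values")
  m2 <- mean((values - mean(values))^2)
  if (m2 < .Machine$double.eps) stop("degenerate input: zero variance")
  mean((values - mean(values))^4) / m2^2 - 3
}
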