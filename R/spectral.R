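#' One-sided periodogram of a detrended trace
#'
#' Non-parametric spectrum estimate
#' \eqn{S(f_k) = \frac{1}{T F_s}\left|\sum_{n=0}^{T-1} x_T(n)
#' e^{-j 2\pi f_k n / F_s}\right|^2} at the native DFT frequencies
#' \eqn{f_k = k F_s / N} (no zero-padding), folded to one side with the
#' interior bins doubled so the trapezoidal integral of the spectrum
#' equals the mean square of the (windowed) signal.  An optional
#' Hamming window is multiplied onto the signal in the time domain,
#' trading leakage for smoothness.  In `"psd"` mode the spectrum is
#' normalised by its own total (trapezoidal) area, making single-cell
#' spectra comparable across cells; the normalised spectrum integrates
#' to 1.
#'
#' @param trace A detrended [trace()] (or numeric vector with `times`).
#' @param window `"rectangular"` (default) or `"hamming"`.
#' @param normalization `"power"` (default) or `"psd"`.
#' @param times Time points when `trace` is a bare numeric vector.
#' @return A list of class `spectrum`: `freqs` (cycles/h), `power`,
#'   `normalization`, `window`, `fs`, `n`.
#' @export
periodogram <- function(trace, window = c("rectangular", "hamming"),
                        normalization = c("power", "psd"), times = NULL) {
  window <- match.arg(window)
  normalization <- match.arg(normalization)
  yt <- as_values_times(trace, times)
  x <- yt$values
  n <- length(x)
  if (n < 8L) stop("need at least 8 samples for a periodogram")
  dt <- check_uniform_times(yt$times)
  fs <- 1 / dt
  w <- switch(window,
              rectangular = rep(1, n),
              hamming = 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1)))
  xw <- x * w
  s2 <- Mod(stats::fft(xw))^2 / (n * fs)    # two-sided, 1/(T*Fs) scaling
  half <- floor(n / 2)
  k <- 0:half
  pw <- s2[k + 1L]
  # fold: double interior bins (not DC; not Nyquist when n is even)
  interior <- k > 0 & !(n %% 2 == 0 & k == half)
  pw[interior] <- 2 * pw[interior]
  freqs <- k * fs / n
  if (normalization == "psd") {
    tot <- trapz(freqs, pw)
    if (tot <= 0) stop("zero total power; cannot psd-normalize")
    pw <- pw / tot
  }
  structure(list(freqs = freqs, power = pw, normalization = normalization,
                 window = window, fs = fs, n = n),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum> %d bins to %.3g cycles/h (%s window, %s normalization)\n",
    length(x$freqs), max(x$freqs), x$window, x$normalization))
  invisible(x)
}

#' Aggregate spectra across cells
#'
#' Per-bin arithmetic mean of single-cell spectra on identical frequency
#' grids, the population spectrum used for coherence.
#'
#' @param spectra Non-empty list of `spectrum` objects with identical
#'   frequency grids and normalization.
#' @return A `spectrum`.
#' @export
aggregate_spectrum <- function(spectra) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  if (!length(spectra)) stop("need at least one spectrum")
  ref <- spectra[[1L]]
  for (sp in spectra) {
    if (length(sp$freqs) != length(ref$freqs) ||
        max(abs(sp$freqs - ref$freqs)) > 1e-10)
      stop("spectra are on different frequency grids; cannot aggregate")
    if (sp$normalization != ref$normalization)
      stop("spectra mix normalization modes; cannot aggregate")
  }
  ref$power <- rowMeans(vapply(spectra, `[[`, numeric(length(ref$freqs)),
                               "power"))
  ref
}

#' Spectral coherence of an aggregate spectrum
#'
#' The concentration of power around the dominant frequency, as a
#' percentage of total power.  A polynomial (default order 6) is fitted
#' to the aggregate power versus frequency to smooth the spectral shape;
#' the peak frequency is the grid argmax of the fitted curve; coherence
#' is the trapezoidal integral of the *true* power over a band of total
#' width `band_fraction` of the peak frequency, centred on the peak,
#' divided by the total integral.  The zero-frequency bin is excluded
#' throughout (the data are detrended and zero-mean).
#'
#' @param aggregate A `spectrum` (typically from [aggregate_spectrum()]).
#' @param poly_order Order of the smoothing polynomial (default 6).
#' @param band_fraction Total band width as a fraction of the peak
#'   frequency (default 0.10); set `half_width = TRUE` for a +/- 10%
#'   band instead.
#' @param half_width Interpret `band_fraction` as a half-width.
#' @return Coherence in percent, with the detected peak frequency
#'   (cycles/h) attached as attribute `"peak_frequency"`.
#' @export
coherence <- function(aggregate, poly_order = 6, band_fraction = 0.10,
                      half_width = FALSE) {
  stopifnot(inherits(aggregate, "spectrum"))
  keep <- aggregate$freqs > 0
  f <- aggregate$freqs[keep]
  p <- aggregate$power[keep]
  if (length(f) < poly_order + 2L)
    stop("need at least poly_order + 2 positive-frequency bins")
  fit <- stats::lm(p ~ stats::poly(f, poly_order))
  smooth <- as.numeric(stats::fitted(fit))
  if (!all(is.finite(smooth))) stop("degenerate polynomial fit")
  f_peak <- f[which.max(smooth)]
  hw <- if (half_width) band_fraction else band_fraction / 2
  band <- c(f_peak * (1 - hw), f_peak * (1 + hw))
  res <- 100 * trapz_band(f, p, band[1L], band[2L]) / trapz(f, p)
  attr(res, "peak_frequency") <- f_peak
  res
}

#' High-frequency contribution of a single-cell spectrum
#'
#' Percentage of the power spectral density lying above the cutoff
#' (default 1.5 cycles/h, i.e. periods shorter than 40 min): the
#' trapezoidal area above the cutoff divided by the total area,
#' excluding the zero bin.  Requires a psd-normalised spectrum so
#' values are comparable across cells.
#'
#' @param psd_spectrum A `spectrum` with `normalization == "psd"`.
#' @param cutoff Boundary between ultradian and high-frequency ranges
#'   (cycles/h); must be below the Nyquist frequency.
#' @return Percentage in \[0, 100\].
#' @export
high_freq_contribution <- function(psd_spectrum, cutoff = 1.5) {
  stopifnot(inherits(psd_spectrum, "spectrum"))
  if (psd_spectrum$normalization != "psd")
    stop("high-frequency contribution requires a psd-normalized spectrum")
  nyq <- psd_spectrum$fs / 2
  if (cutoff >= nyq)
    stop(sprintf("cutoff (%.3g) must be below Nyquist (%.3g cycles/h)",
                 cutoff, nyq))
  keep <- psd_spectrum$freqs > 0
  f <- psd_spectrum$freqs[keep]
  p <- psd_spectrum$power[keep]
  100 * trapz_band(f, p, cutoff, max(f)) / trapz(f, p)
}

# trapezoidal rule
trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)])) / 2

# trapezoidal integral of piecewise-linear (x, y) over [a, b], with
# linear interpolation at the band edges
trapz_band <- function(x, y, a, b) {
  a <- max(a, x[1L]); b <- min(b, x[length(x)])
  if (b <= a) return(0)
  inner <- x > a & x < b
  xs <- c(a, x[inner], b)
  ys <- c(stats::approx(x, y, a)$y, y[inner], stats::approx(x, y, b)$y)
  trapz(xs, ys)
}
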