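#' Calibrate technical noise from background traces
#'
#' Pools the variance of detrended background tracks (tracks recorded
#' where the fluorophore is not expressed) into a single
#' observation-noise variance.  Each background is detrended with the
#' same trend estimator as the signal traces but *not* z-scored; the
#' pooled variance is the (n-1)-weighted average of the per-trace
#' residual variances.  The result is on the scale of the traces given:
#' [classify()] applies the ratio and per-cell z-score bookkeeping
#' before passing the variance to the model fits.
#'
#' @param background_traces List of at least two background [trace()]s
#'   (minimum two backgrounds per experiment per channel).
#' @param cutoff Detrending cutoff (h), as for the signal traces.
#' @return A [noise_model()] holding the pooled technical variance.
#' @export
calibrate_technical_noise <- function(background_traces, cutoff = 3) {
  if (inherits(background_traces, "trace"))
    background_traces <- list(background_traces)
  if (length(background_traces) < 2L)
    stop("need at least 2 background traces per channel")
  ss <- 0; df <- 0
  for (tr in background_traces) {
    res <- detrend(tr, cutoff = cutoff, zscore = FALSE)$detrended$values
    ss <- ss + sum((res - mean(res))^2)
    df <- df + length(res) - 1L
  }
  noise_model(ss / df)
}

#' Sample the null distribution of the log-likelihood ratio
#'
#' Generates synthetic aperiodic data from the fitted OU models and
#' records the LLR each synthetic trace attains, giving the null
#' distribution used for false-discovery-rate control.  Each draw
#' resamples (with replacement) one cell's fitted aperiodic lengthscale
#' (and, when per-cell noise variances are supplied, that same cell's
#' noise), samples an OU trace with signal variance 1, adds Gaussian
#' technical noise, and then sends the synthetic trace through the
#' identical processing and fitting path as the observed data:
#' detrending (which mildly band-passes even aperiodic signals and
#' would otherwise make the null too light-tailed), z-scoring, and both
#' model fits including the smooth-box prior.
#'
#' @param fitted_ou List of [ou_params()] (per-cell OU fits).
#' @param grid A [time_grid()] matching the observed traces.
#' @param noise A [noise_model()] on the z-scored scale, or a numeric
#'   vector of per-cell technical variances parallel to `fitted_ou`.
#' @param n_sims Number of null draws (>= 100).
#' @param seed Integer seed; identical seeds give identical null
#'   vectors.
#' @param prior [smoothbox_prior()] used in the oscillatory refits.
#' @param n_restarts Restarts per refit.
#' @param retry_cap Re-draws allowed per simulation on fit failure.
#' @param cutoff Detrending cutoff (h) applied to the synthetic draws,
#'   matching the observed-data preprocessing.
#' @return Numeric vector of `n_sims` null LLR statistics.
#' @export
null_llr_distribution <- function(fitted_ou, grid, noise, n_sims = 1000,
                                  seed = 1, prior = smoothbox_prior(),
                                  n_restarts = 5, retry_cap = 3,
                                  cutoff = 3) {
  stopifnot(inherits(grid, "time_grid"))
  if (n_sims < 100) stop("`n_sims` must be at least 100")
  if (inherits(fitted_ou, "ou_params")) fitted_ou <- list(fitted_ou)
  noise_vec <- if (inherits(noise, "noise_model"))
    rep(noise$technical_variance, length(fitted_ou))
  else as.numeric(noise)
  if (length(noise_vec) != length(fitted_ou))
    stop("per-cell noise vector must be parallel to `fitted_ou`")
  tt <- grid_times(grid)
  with_seed(seed, {
    vapply(seq_len(n_sims), function(k) {
      for (attempt in seq_len(retry_cap + 1L)) {
        j <- sample.int(length(fitted_ou), 1L)
        alpha <- fitted_ou[[j]]$alpha_ou
        tv <- noise_vec[j]
        y <- ou_path(stats::rnorm(grid$n), alpha, 1, grid$dt) +
          sqrt(tv) * stats::rnorm(grid$n)
        res <- tryCatch({
          p <- detrend(trace("null", "ratio", tt, y), cutoff = cutoff)
          suppressWarnings(
            llr_test(p$detrended, noise_model(tv / p$scale^2), prior,
                     n_restarts)$llr)
        }, error = function(e) NULL)
        if (!is.null(res)) return(res)
      }
      stop("null draw failed after ", retry_cap, " retries")
    }, numeric(1L))
  })
}

#' Convert observed log-likelihood ratios into q-values
#'
#' For each observed statistic `t` the estimated false discovery rate is
#' `FDR(t) = [fraction of null >= t] / [fraction of observed >= t]`
#' (with the null proportion conservatively set to 1).  The q-value of
#' a cell is the smallest estimated FDR over all rejection thresholds
#' that would include it (`min` of `FDR(t')` over `t' <= t`, a running
#' minimum along increasing t), so q-values never increase with the
#' LLR; values are capped at 1.
#'
#' @param observed_llr Non-empty numeric vector of per-cell LLRs.
#' @param null_llr Non-empty numeric vector of null LLRs.
#' @return Numeric vector of q-values parallel to `observed_llr`.
#' @export
q_values <- function(observed_llr, null_llr) {
  if (!length(observed_llr) || !length(null_llr))
    stop("both `observed_llr` and `null_llr` must be non-empty")
  n_obs <- length(observed_llr)
  fdr <- vapply(observed_llr, function(t) {
    mean(null_llr >= t) / (sum(observed_llr >= t) / n_obs)
  }, numeric(1L))
  ord <- order(observed_llr)           # ascending: running min over t' <= t
  q <- fdr
  q[ord] <- cummin(fdr[ord])
  pmin(q, 1)
}

#' Classify the cells of one experiment as oscillatory at a stated FDR
#'
#' The complete per-experiment decision pipeline: preprocess each
#' Venus/H2B pair (bleach correction, ratio, detrend, z-score),
#' calibrate technical noise from the Venus background tracks
#' (propagated to the ratio scale via the experiment-mean H2B level and
#' to each cell's z-scored scale via its recorded residual sd), fit
#' both covariance models per cell, build the synthetic aperiodic null
#' from the per-cell OU fits, and label a cell oscillatory when its
#' q-value falls at or below `fdr_threshold` (default 3%).
#' Classification is strictly per-experiment: the result depends only
#' on the dataset passed in.
#'
#' @param dataset An `embryo_dataset` (from [make_embryo_dataset()] or
#'   [assemble_dataset()]); must include Venus backgrounds.
#' @param fdr_threshold False-discovery-rate threshold (default 0.03).
#' @param n_sims Null draws (default 1000).
#' @param seed Integer seed controlling the null simulation.
#' @param channel `"venus"` analyses the reporter ratio (default);
#'   `"h2b"` runs the nuclear channel through the identical pipeline as
#'   a negative control.
#' @param prior,n_restarts,cutoff Passed to the fitting and detrending
#'   stages.
#' @return A list of class `classification_result`: per-cell table
#'   `cells` (fits, `llr`, `q_value`, `label`), `llr_null`,
#'   `fdr_threshold`, `proportion_oscillatory`, `noise` (the calibrated
#'   [noise_model()] on the ratio scale), and `experiment_id`.
#' @export
classify <- function(dataset, fdr_threshold = 0.03, n_sims = 1000,
                     seed = 1, channel = c("venus", "h2b"),
                     prior = smoothbox_prior(), n_restarts = 5,
                     cutoff = 3) {
  stopifnot(inherits(dataset, "embryo_dataset"))
  channel <- match.arg(channel)
  if (fdr_threshold < 0 || fdr_threshold > 1)
    stop("`fdr_threshold` must lie in [0, 1]")
  if (length(dataset$backgrounds$venus) < 2L)
    stop("dataset has fewer than 2 venus background traces")
  cells <- dataset$cells
  if (!length(cells)) stop("dataset has no cells")

  venus_tr <- lapply(cells, `[[`, "venus")
  h2b_tr <- lapply(cells, `[[`, "h2b")
  slope_v <- estimate_bleach_slope(venus_tr)
  slope_h <- estimate_bleach_slope(h2b_tr)

  # per-cell preprocessing; the H2B negative control is sent through the
  # identical chain with the roles swapped onto the same grid
  pre <- lapply(seq_along(cells), function(i) {
    if (channel == "venus") {
      preprocess_cell(venus_tr[[i]], h2b_tr[[i]], slope_v, slope_h,
                      cutoff = cutoff)
    } else {
      detrend(correct_bleaching(h2b_tr[[i]], slope_h), cutoff = cutoff)
    }
  })

  # technical noise on the analysed scale: background variance of the
  # relevant channel, divided by the mean nuclear level when the signal
  # is a ratio, then per-cell by the recorded z-score variance
  bg_ch <- if (channel == "venus") "venus" else "h2b"
  raw_noise <- calibrate_technical_noise(dataset$backgrounds[[bg_ch]],
                                         cutoff = cutoff)
  scale_fac <- if (channel == "venus") {
    h2b_corr <- lapply(h2b_tr, correct_bleaching, slope = slope_h)
    mean(vapply(h2b_corr, function(tr) mean(tr$values), numeric(1L)))^2
  } else 1
  noise_ratio_var <- raw_noise$technical_variance / scale_fac
  cell_noise <- vapply(pre, function(p) noise_ratio_var / p$scale^2,
                       numeric(1L))

  fits <- lapply(seq_along(pre), function(i) {
    suppressWarnings(
      llr_test(pre[[i]]$detrended, noise_model(cell_noise[i]),
               prior, n_restarts))
  })
  ou_list <- lapply(fits, function(f) f$fit_ou$params)
  llr_obs <- vapply(fits, `[[`, numeric(1L), "llr")

  llr_null <- null_llr_distribution(ou_list, dataset$grid, cell_noise,
                                    n_sims = n_sims, seed = seed,
                                    prior = prior, n_restarts = n_restarts,
                                    cutoff = cutoff)
  qv <- q_values(llr_obs, llr_null)
  lab <- ifelse(fdr_threshold > 0 & qv <= fdr_threshold,
                "oscillatory", "non_oscillatory")

  tab <- data.frame(
    cell_id = vapply(cells, function(cl) cl[[1L]]$cell_id, character(1L)),
    alpha_ou = vapply(fits, function(f) f$fit_ou$params$alpha_ou,
                      numeric(1L)),
    alpha_ouosc = vapply(fits, function(f) f$fit_ouosc$params$alpha_ouosc,
                         numeric(1L)),
    beta = vapply(fits, function(f) f$fit_ouosc$params$beta, numeric(1L)),
    period_h = vapply(fits, `[[`, numeric(1L), "period_h"),
    lml_ou = vapply(fits, function(f) f$fit_ou$log_marginal_likelihood,
                    numeric(1L)),
    lml_ouosc = vapply(fits,
                       function(f) f$fit_ouosc$log_marginal_likelihood,
                       numeric(1L)),
    llr = llr_obs, q_value = qv, label = lab,
    technical_variance = cell_noise,
    stringsAsFactors = FALSE)

  structure(list(cells = tab, llr_null = llr_null,
                 fdr_threshold = fdr_threshold,
                 proportion_oscillatory = mean(lab == "oscillatory"),
                 noise = noise_model(noise_ratio_var),
                 channel = channel,
                 experiment_id = "experiment_1",
                 preprocessed = pre),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  osc <- x$cells$label == "oscillatory"
  cat(sprintf(paste0("<classification_result> %d cells (%s channel), ",
                     "FDR %.3g: %.1f%% oscillatory\n"),
              nrow(x$cells), x$channel, x$fdr_threshold,
              100 * x$proportion_oscillatory))
  if (any(osc))
    cat(sprintf("  median period of oscillators: %.3g h\n",
                stats::median(x$cells$period_h[osc])))
  if (any(!osc))
    cat(sprintf("  median alpha_ou of non-oscillators: %.3g /h\n",
                stats::median(x$cells$alpha_ou[!osc])))
  invisible(x)
}

#' Per-experiment summary of a classification
#'
#' @param result A `classification_result`.
#' @return One-row data frame: number of cells, proportion oscillatory,
#'   median period of oscillators, median aperiodic lengthscale of
#'   non-oscillators.
#' @export
summarize_classification <- function(result) {
  stopifnot(inherits(result, "classification_result"))
  osc <- result$cells$label == "oscillatory"
  data.frame(
    experiment_id = result$experiment_id,
    n_cells = nrow(result$cells),
    proportion_oscillatory = result$proportion_oscillatory,
    median_period_h = if (any(osc))
      stats::median(result$cells$period_h[osc]) else NA_real_,
    median_alpha_ou = if (any(!osc))
      stats::median(result$cells$alpha_ou[!osc]) else NA_real_,
    fdr_threshold = result$fdr_threshold,
    stringsAsFactors = FALSE)
}
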