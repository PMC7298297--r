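#' Read a delimited trace table
#'
#' Reads the package's exchange format: a comma-separated table with
#' columns `cell_id`, `channel` (one of venus, h2b, venus_background,
#' h2b_background, ratio), `time_h`, `intensity`, and optionally
#' `z_um`.  Rows are grouped into one [trace()] per (cell_id, channel)
#' pair; each trace's grid is validated for uniform sampling.
#'
#' @param path Path to a CSV file.
#' @return A list of [trace()]s.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "channel", "time_h", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$time_h) | !is.finite(df$intensity))
  if (length(bad))
    stop("non-finite time or intensity at row ", bad[1L] + 1L,
         " (cell ", df$cell_id[bad[1L]], ")")
  df$.row <- seq_len(nrow(df)) + 1L   # file row incl. header
  keys <- unique(df[, c("cell_id", "channel")])
  traces <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$cell_id == keys$cell_id[i] & df$channel == keys$channel[i], ]
    sub <- sub[order(sub$time_h), ]
    dts <- diff(sub$time_h)
    if (length(dts)) {
      m <- mean(dts)
      off <- which(dts <= 0 | abs(dts - m) / m >= 1e-6)
      if (length(off))
        stop(sprintf(
          "irregular time grid for cell %s (%s) near file row %d",
          keys$cell_id[i], keys$channel[i], sub$.row[off[1L] + 1L]))
    }
    traces[[i]] <- trace(keys$cell_id[i], keys$channel[i], sub$time_h,
                         sub$intensity,
                         z_position = if ("z_um" %in% names(sub))
                           sub$z_um else NULL)
  }
  traces
}

#' Write traces to the delimited trace table
#'
#' @param traces A list of [trace()]s (or one trace).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    out <- data.frame(cell_id = tr$cell_id, channel = tr$channel,
                      time_h = tr$times, intensity = tr$values,
                      stringsAsFactors = FALSE)
    if (!is.null(tr$z_position)) out$z_um <- tr$z_position
    out
  })
  has_z <- vapply(rows, function(r) "z_um" %in% names(r), logical(1L))
  if (any(has_z) && !all(has_z))
    rows <- lapply(rows, function(r) {
      if (!"z_um" %in% names(r)) r$z_um <- NA_real_
      r
    })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Assemble an experiment dataset from a flat list of traces
#'
#' Pairs `venus`/`h2b` traces by `cell_id` and collects background
#' traces per channel, producing the same `embryo_dataset` structure as
#' [make_embryo_dataset()] (without ground-truth labels).
#'
#' @param traces List of [trace()]s, e.g. from [read_traces()].
#' @return An `embryo_dataset`.
#' @export
assemble_dataset <- function(traces) {
  ch <- vapply(traces, `[[`, character(1L), "channel")
  ids <- vapply(traces, `[[`, character(1L), "cell_id")
  venus <- traces[ch == "venus"]
  h2b <- traces[ch == "h2b"]
  vid <- ids[ch == "venus"]; hid <- ids[ch == "h2b"]
  common <- intersect(vid, hid)
  if (!length(common)) stop("no cell has both venus and h2b traces")
  cells <- lapply(common, function(id)
    list(venus = venus[[match(id, vid)]], h2b = h2b[[match(id, hid)]]))
  ref <- cells[[1L]]$venus
  for (cl in cells)
    for (tr in cl)
      if (length(tr$times) != length(ref$times) ||
          max(abs(tr$times - ref$times)) > 1e-8)
        stop("cell ", tr$cell_id, " is not on the common time grid")
  dts <- mean(diff(ref$times))
  structure(list(
    cells = cells,
    backgrounds = list(venus = traces[ch == "venus_background"],
                       h2b = traces[ch == "h2b_background"]),
    labels = NULL,
    grid = time_grid(ref$times[1L], dts, length(ref$times)),
    config = NULL),
    class = "embryo_dataset")
}

#' Serialise an embryo dataset to delimited tables
#'
#' Writes the trace table (all cell and background traces) and, when
#' ground truth is available, a `*_truth.csv` table of labels and true
#' parameters next to it.
#'
#' @param dataset An `embryo_dataset`.
#' @param path Output CSV path for the trace table.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "embryo_dataset"))
  all_traces <- c(unlist(dataset$cells, recursive = FALSE,
                         use.names = FALSE),
                  dataset$backgrounds$venus, dataset$backgrounds$h2b)
  write_traces(all_traces, path)
  if (!is.null(dataset$labels))
    utils::write.csv(dataset$labels,
                     sub("\\.csv$", "_truth.csv", path),
                     row.names = FALSE)
  invisible(path)
}

#' Run the full trace-analysis pipeline on one experiment
#'
#' Chains the stages in pipeline order: preprocessing (bleach
#' correction, nuclear normalisation, detrending), technical-noise
#' calibration, Gaussian-process model comparison and FDR
#' classification, spectral statistics (aggregate coherence and
#' per-cell high-frequency contribution) and the local coefficient of
#' variation.  The run is fully deterministic under `seed`.
#'
#' @param dataset An `embryo_dataset`.
#' @param fdr_threshold FDR for the oscillatory call (default 0.03).
#' @param n_sims Null draws for the FDR classification.
#' @param seed Master seed.
#' @param spectral_window Periodogram window (`"rectangular"` or
#'   `"hamming"`).
#' @param hf_cutoff High-frequency cutoff (cycles/h).
#' @param lcov_window LCOV window (h).
#' @param output_dir Optional directory; when given, result tables
#'   (`fits.csv`, `summary.csv`, `spectra.csv`, `qc.csv`) and a plain
#'   text run log are written there.
#' @return A list of class `pipeline_result`: `classification`,
#'   `summary` (one row), `spectra` (per-cell spectra list),
#'   `coherence_pct`, `high_freq_pct` (per cell), `lcov` (per cell),
#'   `qc` (per-cell table) and `log` (character vector).
#' @export
run_pipeline <- function(dataset, fdr_threshold = 0.03, n_sims = 1000,
                         seed = 1, spectral_window = "rectangular",
                         hf_cutoff = 1.5, lcov_window = 1.5,
                         output_dir = NULL) {
  stopifnot(inherits(dataset, "embryo_dataset"))
  log_lines <- c(
    sprintf("oscnoise pipeline run (%s)", format(Sys.time())),
    sprintf("seed=%d n_cells=%d n_sims=%d fdr_threshold=%g",
            seed, length(dataset$cells), n_sims, fdr_threshold),
    sprintf("spectral_window=%s hf_cutoff=%g lcov_window=%g",
            spectral_window, hf_cutoff, lcov_window))

  cls <- classify(dataset, fdr_threshold = fdr_threshold,
                  n_sims = n_sims, seed = mix_seed(seed, 2L))
  pre <- cls$preprocessed

  spectra <- lapply(pre, function(p)
    periodogram(p$detrended, window = spectral_window,
                normalization = "psd"))
  agg <- aggregate_spectrum(spectra)
  coh <- coherence(agg)
  hf <- vapply(spectra, high_freq_contribution, numeric(1L),
               cutoff = hf_cutoff)
  lcov <- vapply(pre, function(p) local_cov(p$ratio, window = lcov_window),
                 numeric(1L))

  qc <- data.frame(
    cell_id = cls$cells$cell_id,
    detrend_sd = vapply(pre, `[[`, numeric(1L), "scale"),
    lcov = lcov, high_freq_pct = hf,
    stringsAsFactors = FALSE)

  summary_row <- summarize_classification(cls)
  summary_row$coherence_pct <- coh
  summary_row$median_high_freq_pct <- stats::median(hf)
  summary_row$median_lcov <- stats::median(lcov)
  summary_row$seed <- seed

  log_lines <- c(log_lines,
                 sprintf("proportion_oscillatory=%.4f coherence_pct=%.2f",
                         cls$proportion_oscillatory, coh))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cls$cells, file.path(output_dir, "fits.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_row, file.path(output_dir, "summary.csv"),
                     row.names = FALSE)
    spec_tab <- do.call(rbind, lapply(seq_along(spectra), function(i)
      data.frame(cell_id = cls$cells$cell_id[i],
                 freq = spectra[[i]]$freqs,
                 power = spectra[[i]]$power)))
    utils::write.csv(spec_tab, file.path(output_dir, "spectra.csv"),
                     row.names = FALSE)
    utils::write.csv(qc, file.path(output_dir, "qc.csv"),
                     row.names = FALSE)
    writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  }

  structure(list(classification = cls, summary = summary_row,
                 spectra = spectra, coherence_pct = coh,
                 high_freq_pct = hf, lcov = lcov, qc = qc,
                 log = log_lines),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$classification)
  cat(sprintf("  coherence: %.1f%%; median high-frequency: %.1f%%; median LCOV: %.3f\n",
              x$coherence_pct, stats::median(x$high_freq_pct),
              stats::median(x$lcov)))
  invisible(x)
}
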