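# oscnoise

Is a single-cell gene-expression trace *oscillating*, or is it just
*noise* — and if it is noise, how fast does it fluctuate?

`oscnoise` is an R package for analysing uniformly sampled single-cell
fluorescence reporter time series (e.g. a Her6::Venus fusion paired
with a nuclear mKeima-H2B marker, imaged every 6 minutes for 10–12
hours).  It implements:

- **Preprocessing**: per-channel linear photobleaching correction,
  normalisation of the reporter to the nuclear marker, removal of slow
  trends (> 3 h) by Gaussian-process regression, z-scoring, and QC
  (depth correlation, bleach slopes).
- **Gaussian-process model comparison**: each detrended trace is
  modelled as a zero-mean GP under two competing stationary
  covariances — aperiodic Ornstein–Uhlenbeck,
  `K_OU(tau) = sigma^2 exp(-alpha_OU * tau)`, versus oscillatory,
  `K_OUosc(tau) = sigma^2 exp(-alpha_OUosc * tau) cos(beta * tau)`
  (period `P = 2*pi/beta`) — with the measurement-noise variance
  *calibrated from background traces and held fixed*.  The oscillatory
  fit places a smooth-box prior (knees 1 and 2 per hour, steepness 5)
  on the periodic lengthscale.  The per-cell statistic is the
  log-likelihood ratio `LLR = 2 * (LML_OUosc - LML_OU)`.
- **FDR classification**: a synthetic aperiodic null (OU traces
  resampled from the experiment's own fitted lengthscales, passed
  through the identical preprocessing and fitting path) converts LLRs
  into q-values; cells with `q <= 0.03` are labelled oscillatory.
- **Spectral statistics**: one-sided periodograms (rectangular or
  Hamming window), aggregate spectra, spectral *coherence* (power
  concentration around the polynomial-smoothed peak), and the
  *high-frequency contribution* (% of power above 1.5 cycles/h).
- **Variability statistics**: local coefficient of variation (1.5 h
  windows), group LCOV ratios, excess kurtosis of level distributions.
- **A stochastic network-motif model**: a noisy repressor Y
  (OU-distributed, adjustable aperiodic lengthscale) controlling a
  self-activating bistable target X via Hill functions, simulated
  open-loop or with feedback (Euler–Maruyama), with switching
  probabilities and fixed-point oracles.  Slow repressor noise permits
  switching; fast noise suppresses it.
- **A synthetic-data generator** producing full mock two-channel
  "embryo" datasets (signal + trend + bleach + calibrated technical
  noise + background tracks, with ground-truth labels), so the entire
  pipeline is testable without imaging data.

## Worked example

```r
library(oscnoise)

# a synthetic experiment: 20 cells, 60% oscillatory (period 1.5 h),
# the rest aperiodic OU noise; 12 h of 6-min sampling
ds <- make_embryo_dataset(synthetic_dataset_config(
  n_cells = 20, frac_oscillatory = 0.6, seed = 7))

res <- classify(ds, fdr_threshold = 0.03, n_sims = 500, seed = 1)
res
#> <classification_result> 20 cells (venus channel), FDR 0.03: 60.0% oscillatory
#>   median period of oscillators: 1.49 h
#>   median alpha_ou of non-oscillators: 3.56 /h

head(res$cells[, c("cell_id", "llr", "q_value", "period_h", "label")], 3)
#>    cell_id       llr    q_value period_h       label
#> 1 cell_001 109.53018 0.00000000 1.411650 oscillatory
#> 2 cell_002  12.76575 0.02666667 1.585445 oscillatory
#> 3 cell_003  33.43334 0.00000000 1.572184 oscillatory
```

All twelve simulated oscillators are recovered (60% called, matching
the simulated fraction) with none of the eight aperiodic cells
mislabelled, and the median recovered period (1.49 h) matches the
generating period of 1.5 h.  Q-values of clear oscillators are 0
because no null draw reaches their LLR; `cell_002` (q = 0.027) sits
just inside the 3% threshold.

The motif model, at its default parameters, is bistable and switches
only under slowly fluctuating repression:

```r
steady_states(motif_params(), Y_fixed = 6)
#>           x stable
#> 1 0.1578047   TRUE
#> 2 0.1793999  FALSE
#> 3 3.4569314   TRUE

sapply(c(2, 15, 100), function(a)
  switching_probability(motif_params(alpha_ou = a),
                        "open_loop", n_reps = 50, seed = 2)$p_switch)
#> [1] 1.00 0.88 0.02
```

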