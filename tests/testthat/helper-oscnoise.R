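# shared fixtures and independent oracles for the test suite

zscore <- function(x) (x - mean(x)) / stats::sd(x)

# independent dense-matrix log marginal likelihood oracle: LU-based
# solve and determinant, no Cholesky, no code shared with the package
dense_lml_oracle <- function(y, times, kfun, noise_var) {
  D <- abs(outer(times, times, "-"))
  C <- kfun(D) + diag(noise_var, length(y))
  quad <- drop(t(y) %*% solve(C, y))
  ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  -0.5 * quad - 0.5 * ld - 0.5 * length(y) * log(2 * pi)
}

# independent trapezoid integral used to cross-check spectral areas
oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1L))
    s <- s + (x[i + 1L] - x[i]) * (y[i] + y[i + 1L]) / 2
  s
}

# small fast dataset for classifier/workflow tests: 6 h traces
small_dataset <- function(n_cells = 12, frac = 0.5, seed = 7, n = 61) {
  make_embryo_dataset(synthetic_dataset_config(
    n_cells = n_cells, frac_oscillatory = frac, seed = seed,
    grid = time_grid(0, 0.1, n)))
}
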