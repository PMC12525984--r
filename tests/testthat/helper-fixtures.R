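# Shared fixtures: everything is generated in code at test time.

# compact VNIR grid for fast tests
small_grid <- function(n = 40) wavelength_grid(seq(520, 880, length.out = n))

# small labelled table under the default study conditions
small_table <- function(n_per = 30, grid = small_grid(), seed = 1, ...) {
  sample_spectra_table(c(control = n_per, early = n_per, severe = n_per),
                       grid = grid, seed = seed, ...)
}

# two clearly separated spherical Gaussian classes in 2-d
two_gaussians <- function(n = 40, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n), ncol = 2),
             matrix(rnorm(2 * n, mean = sep), ncol = 2))
  list(X = X, y = factor(rep(c("a", "b"), each = n)))
}

# brute-force SPA: re-run projection from scratch at every step using
# least-squares residualisation onto the chosen columns
spa_chain_bruteforce <- function(X, start, k) {
  chain <- start
  for (step in seq_len(k - 1)) {
    S <- X[, chain, drop = FALSE]
    norms <- rep(-Inf, ncol(X))
    for (c in setdiff(seq_len(ncol(X)), chain)) {
      r <- stats::lm.fit(S, X[, c])$residuals
      norms[c] <- sum(r^2)
    }
    chain <- c(chain, which.max(norms))
  }
  chain
}
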