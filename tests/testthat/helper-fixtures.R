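# Shared fixtures: all generated in code, scaled down for test speed.

# Reduced CNN: same layer structure as the default, fewer filters/units so
# a training run takes seconds, not minutes. The learning rate stays at
# the published 1e-4: larger rates let Adam's coordinate-wise steps drift
# the first FC layer's weights coherently negative over its all-positive
# post-ReLU inputs, killing the layer (see the methods vignette).
tiny_cnn_config <- function(seed = 1L, max_epochs = 20L, patience = 8L,
                            minibatch_size = 64L, learning_rate = 1e-4,
                            fc_widths = 16L) {
  cnn_config(conv_blocks = list(
    list(n_filters = 8L, filter_length = 20L, stride = 1L, padding = 0L),
    list(n_filters = 16L, filter_length = 20L, stride = 1L, padding = 0L)),
    fc_widths = fc_widths, minibatch_size = minibatch_size,
    learning_rate = learning_rate, max_epochs = max_epochs,
    patience = patience, seed = seed)
}

# Strongly separable world: large dose effect, little nuisance variation.
separable_config <- function(seed = 42L, spectra_per_map = 10L,
                             n_mice_per_arm = 3L) {
  generator_config(peaks = default_peak_table(0.05),
                   n_mice_per_arm = n_mice_per_arm,
                   spectra_per_map = spectra_per_map,
                   noise_sd = 0, mouse_sd = 0.02, section_sd = 0.02,
                   map_sd = 0.02, baseline_amplitude = 0, seed = seed)
}

# Null world: dose changes nothing AND hierarchy effects are off, so the
# two arms are exchangeable spectrum by spectrum. (With per-mouse random
# effects left on, a random-split classifier beats chance by memorizing
# mouse fingerprints even with zero dose effect -- the leakage phenomenon
# subject-wise validation exists to expose; see the methods vignette.)
null_config <- function(seed = 7L, spectra_per_map = 10L,
                        n_mice_per_arm = 5L) {
  generator_config(peaks = default_peak_table(0),
                   n_mice_per_arm = n_mice_per_arm,
                   spectra_per_map = spectra_per_map,
                   mouse_sd = 0, section_sd = 0, map_sd = 0,
                   noise_sd = 0.02, seed = seed)
}

small_library <- function(n = 5L, seed = 3L, grid = wavenumber_grid()) {
  generate_basis_library(grid, n, seed = seed)
}

# Brute-force NNLS oracle: enumerate every support set, solve the
# unconstrained LS on it, keep feasible solutions, return the best. Exact
# for small n; independent of the package's Lawson-Hanson path.
nnls_enumeration_oracle <- function(A, b) {
  n <- ncol(A)
  best <- list(x = numeric(n), obj = sum(b^2))
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    coef <- qr.coef(qr(A[, S, drop = FALSE]), b)
    coef[is.na(coef)] <- 0
    if (any(coef < -1e-9)) next
    x <- numeric(n)
    x[S] <- pmax(coef, 0)
    obj <- sum((b - A %*% x)^2)
    if (obj < best$obj - 1e-12) best <- list(x = x, obj = obj)
  }
  best
}
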