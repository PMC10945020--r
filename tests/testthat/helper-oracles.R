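# Small scene used across tests: 3 sausages, 70 px wide, default noise.
small_config <- function(seed = 42, n = 3, ...) {
  scene_config(n_sausages = n, image_height = 22 * n + 6,
               image_width = 70, seed = seed, ...)
}

noise_free <- function(seed = 42, n = 3, ...) {
  small_config(seed = seed, n = n,
               scatter_multiplicative_sd = 0, baseline_offset_sd = 0,
               sample_scatter_sd = 0, sample_offset_sd = 0,
               sample_tilt_sd = 0, noise_sd = 0, ...)
}

# Brute-force greedy Kennard-Stone: explicit loops, no shared code with
# the implementation.
ks_oracle <- function(X, n_cal) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(1L, 2L); bd <- -1
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(n), sel)
    bi <- NA_integer_; bv <- -1
    for (cc in cand) {
      v <- min(D[cc, sel])
      if (v > bv) { bv <- v; bi <- cc }
    }
    sel <- c(sel, bi)
  }
  sel
}

# Direct term-by-term evaluation of the coded quadratic (independent of
# the model-matrix implementation).
quad_oracle <- function(coefs, u) {
  val <- coefs[1]
  for (i in 1:5) val <- val + coefs[1 + i] * u[i]
  for (i in 1:5) val <- val + coefs[6 + i] * u[i]^2
  k <- 11
  for (i in 1:4) for (j in (i + 1):5) {
    k <- k + 1
    val <- val + coefs[k] * u[i] * u[j]
  }
  val
}
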