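# shared fixtures, memoized so several test files can reuse one session
.fixtures <- new.env(parent = emptyenv())

small_config <- function(seed = 42, n_channels = 16, n_trials = 30,
                         artifact_gain = 1e3, ...) {
  session_config(n_channels = n_channels, n_trials = n_trials,
                 artifact_gain = artifact_gain, seed = seed, ...)
}

small_session <- function(seed = 42) {
  key <- paste0("ses", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_session(small_config(seed))
  }
  .fixtures[[key]]
}

small_model <- function(seed = 42) {
  key <- paste0("mod", seed)
  if (is.null(.fixtures[[key]])) {
    ses <- small_session(seed)
    .fixtures[[key]] <- suppressWarnings(sass_fit(ses$stim, ses$no_stim))
  }
  .fixtures[[key]]
}

# random symmetric positive definite matrix
random_spd <- function(n) {
  m <- matrix(rnorm(n * n), n)
  crossprod(m) + diag(n) * 0.1
}

# independent GEVD oracle: det(A - lambda B) is a degree-n polynomial in
# lambda; evaluate it at n+1 nodes (base det(), LU-based), fit the
# coefficients through a Vandermonde solve, take polyroot()
gevd_oracle <- function(A, B) {
  n <- nrow(A)
  s <- sum(diag(A)) / sum(diag(B))
  nodes <- s * seq(-2, 2, length.out = n + 1)
  vals <- vapply(nodes, function(l) det(A - l * B), numeric(1))
  V <- outer(nodes, 0:n, `^`)
  coef <- solve(V, vals)
  r <- polyroot(coef)
  sort(Re(r), decreasing = TRUE)
}

# a tiny recording with sinusoidal content for filter tests
sinusoid_recording <- function(freqs, amps, fs = 500, dur = 20,
                               phases = rep(0, length(freqs))) {
  t <- (seq_len(dur * fs) - 1) / fs
  x <- rowSums(mapply(function(f, a, p) a * cos(2 * pi * f * t + p),
                      freqs, amps, phases))
  eeg_recording(matrix(x, 1), fs, "ch1")
}
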