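#' Welch power spectral density
#'
#' Welch periodogram over the entire (typically unfiltered) recording:
#' segments of `nfft` samples, Hann taper, 50% overlap, per-segment mean
#' removal, one-sided density in uV^2/Hz.
#'
#' @param x an `eeg_recording` or a numeric series.
#' @param nfft segment length = FFT length (default 2048).
#' @param fs sampling rate (taken from the recording if omitted).
#' @return object of class `power_spectrum`: list with `freqs`, `psd`
#'   (channels x freqs matrix), `method = "welch"`, `params`.
#' @export
welch_psd <- function(x, nfft = 2048, fs = NULL) {
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs
    mat <- x$data
  } else {
    if (is.null(fs)) stop("fs required for plain series input")
    mat <- matrix(x, nrow = 1)
  }
  n <- ncol(mat)
  if (n < nfft) {
    stop(sprintf("recording (%d samples) shorter than nfft = %d; ",
                 n, nfft), "use a smaller nfft")
  }
  step <- nfft %/% 2L
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nfft) - 1) / (nfft - 1)))  # Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nfft %/% 2L + 1L
  idx <- outer(seq_len(nfft) - 1L, starts, "+")
  psd <- matrix(0, nrow(mat), nfreq)
  for (ch in seq_len(nrow(mat))) {
    seg <- matrix(mat[ch, idx], nfft, length(starts))
    seg <- (seg - rep(colMeans(seg), each = nfft)) * w
    sp <- Mod(stats::mvfft(seg))^2
    p <- rowMeans(sp[seq_len(nfreq), , drop = FALSE]) * scale
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
    psd[ch, ] <- p
  }
  rownames(psd) <- rownames(mat)
  structure(list(freqs = seq(0, fs / 2, length.out = nfreq), psd = psd,
                 method = "welch",
                 params = list(nfft = nfft, overlap = 0.5,
                               window = "hann", n_segments = length(starts))),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %s, %d channel(s), %d bins up to %g Hz\n",
              x$method, nrow(x$psd), length(x$freqs), max(x$freqs)))
  invisible(x)
}

# matvec with the symmetric tridiagonal DPSS operator
dpss_tridiag_matvec <- function(x, dg, od) {
  y <- dg * x
  n <- length(x)
  y[2:n] <- y[2:n] + od * x[1:(n - 1)]
  y[1:(n - 1)] <- y[1:(n - 1)] + od * x[2:n]
  y
}

# C kernels: Sturm eigenvalue counts and shifted Thomas solves
sturm_count <- function(dg, od, x) {
  .Call("c_sturm_count", as.double(dg), as.double(od), as.double(x),
        PACKAGE = "sasseeg")
}

tridiag_shifted_solve <- function(b, dg, od, shift, guard) {
  .Call("c_tridiag_solve_shifted", as.double(dg), as.double(od),
        as.double(b), as.double(shift), as.double(guard),
        PACKAGE = "sasseeg")
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with half-bandwidth
#' product `nw` via the classic symmetric tridiagonal formulation: the
#' top-k eigenvalues are located exactly by Sturm-sequence bisection and
#' the eigenvectors obtained by deflated inverse iteration, both O(n) per
#' step, which scales to the 60000-sample segments used by
#' high-resolution spectra. Tapers are unit-norm rows.
#'
#' @param n taper length, samples.
#' @param nw time half-bandwidth product (W = nw/n cycles/sample).
#' @param k number of tapers (default `2 * nw - 1`).
#' @return k x n matrix of tapers, concentration-ordered.
#' @export
dpss_tapers <- function(n, nw, k = 2 * nw - 1) {
  if (k >= n) stop("k must be < n")
  w <- nw / n
  i <- 0:(n - 1)
  dg <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  od <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  scale <- max(abs(dg)) + 2 * max(od)
  # exact top-k eigenvalues by Sturm bisection on Gershgorin bounds
  lo0 <- min(dg - c(0, od) - c(od, 0))
  hi0 <- max(dg + c(0, od) + c(od, 0))
  evs <- numeric(k)
  for (j in seq_len(k)) {
    lo <- lo0
    hi <- hi0
    for (it in 1:80) {
      mid <- (lo + hi) / 2
      if (sturm_count(dg, od, mid) >= n - j + 1L) hi <- mid else lo <- mid
      if (hi - lo < 1e-14 * scale) break
    }
    evs[j] <- (lo + hi) / 2
  }
  # eigenvectors by inverse iteration at the exact shifts, deflating
  # against the already-accepted tapers (close eigenpairs stay apart)
  guard <- 1e-11 * scale
  tap <- matrix(0, n, k)
  for (j in seq_len(k)) {
    v <- sin(pi * j * (i + 1) / (n + 1))
    v <- v / sqrt(sum(v^2))
    for (it in 1:30) {
      v <- tridiag_shifted_solve(v, dg, od, evs[j], guard)
      if (j > 1) {
        prev <- tap[, seq_len(j - 1), drop = FALSE]
        v <- v - prev %*% crossprod(prev, v)
      }
      v <- v / sqrt(sum(v^2))
      res <- sqrt(sum((dpss_tridiag_matvec(v, dg, od) - evs[j] * v)^2))
      if (res < 1e-9 * scale) break
    }
    tap[, j] <- v
  }
  # polarity convention: positive mean (symmetric) / positive leading lobe
  for (j in seq_len(k)) {
    s <- sum(tap[, j])
    if (abs(s) < 1e-8) s <- sum(tap[seq_len(n %/% 2), j])
    if (s < 0) tap[, j] <- -tap[, j]
  }
  t(tap)
}

#' Thomson multitaper power spectral density
#'
#' High-resolution PSD: the series is split into consecutive segments
#' (default 120 s) and each segment receives a DPSS multitaper estimate
#' with half-bandwidth `nw / segment` Hz (default 6/120 = 0.05 Hz) using
#' `2 nw - 1` tapers. Used to look for sidebands around the stimulation
#' frequency that would betray slow modulation of the artifact.
#'
#' @param x numeric series, or an `eeg_recording` plus `channel`.
#' @param fs sampling rate, Hz (from the recording if omitted).
#' @param segment segment length, s.
#' @param nw time half-bandwidth product.
#' @param channel channel label when `x` is a recording.
#' @param allow_short if TRUE a series shorter than one segment is
#'   analyzed as a single shorter segment instead of erroring.
#' @return list of `power_spectrum` objects, one per segment.
#' @export
multitaper_psd <- function(x, fs = NULL, segment = 120, nw = 6,
                           channel = NULL, allow_short = FALSE) {
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs
    if (is.null(channel)) stop("give a channel label for recording input")
    x <- x$data[channel, ]
  }
  if (is.null(fs)) stop("fs required")
  nseg <- as.integer(round(segment * fs))
  if (length(x) < nseg) {
    if (!allow_short) {
      stop("recording shorter than one segment (", segment, " s); pass ",
           "allow_short = TRUE to analyze a single shorter segment")
    }
    nseg <- length(x)
  }
  k <- 2 * nw - 1
  tap <- dpss_tapers(nseg, nw, k)
  n_segments <- length(x) %/% nseg
  nfreq <- nseg %/% 2L + 1L
  freqs <- seq(0, fs / 2, length.out = nfreq)
  lapply(seq_len(n_segments), function(s) {
    seg <- x[((s - 1L) * nseg + 1L):(s * nseg)]
    seg <- seg - mean(seg)
    tx <- t(tap) * seg  # nseg x k tapered copies
    sp <- Mod(stats::mvfft(tx))^2
    p <- rowMeans(sp[seq_len(nfreq), , drop = FALSE]) / fs
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
    structure(list(freqs = freqs, psd = matrix(p, 1), method = "multitaper",
                   params = list(segment_s = nseg / fs, nw = nw, k = k,
                                 half_bandwidth_hz = nw / (nseg / fs))),
              class = "power_spectrum")
  })
}

#' Heartbeat modulation permutation test
#'
#' Tests whether the band envelope is modulated around ECG R-peaks: the
#' series is FIR filtered to `band` (default 5-15 Hz), Hilbert enveloped,
#' cut into `window` s segments centered on each R-peak, each segment's
#' temporal mean subtracted, and the across-segment mean trace compared
#' per timepoint against `n_perm` traces from random placements of the
#' same number of segments (placements may overlap; segments must fit
#' inside the recording). Two-sided permutation p-values, Bonferroni
#' corrected across timepoints.
#'
#' Under the random-placement null the mean trace is stationary, so its
#' values are exchangeable across timepoints; by default every timepoint
#' of every null trace contributes to one pooled null distribution
#' (`pool_null = TRUE`). This keeps detection attainable after Bonferroni:
#' with a strictly per-timepoint comparison the permutation floor
#' `1/(n_perm + 1)` times the number of timepoints can never reach 0.05.
#' `pool_null = FALSE` gives the literal per-timepoint comparison.
#'
#' @param x numeric broadband series, or an `eeg_recording` + `channel`.
#' @param r_peaks 0-based R-peak sample indices.
#' @param fs sampling rate, Hz.
#' @param n_perm number of random placements (default 1000).
#' @param band envelope band, Hz.
#' @param window segment length, s (centered: time grid `[-window/2,
#'   window/2]`).
#' @param channel channel label for recording input.
#' @param seed optional RNG seed for reproducible placements.
#' @param pool_null pool null values across timepoints (see above).
#' @return object of class `modulation_test_result`: `time` (s),
#'   `mean_envelope`, `p_values` (Bonferroni corrected), `p_uncorrected`,
#'   `n_permutations`, `n_segments`, `channel`.
#' @export
heartbeat_modulation_test <- function(x, r_peaks, fs = NULL, n_perm = 1000,
                                      band = c(5, 15), window = 4,
                                      channel = NULL, seed = NULL,
                                      pool_null = TRUE) {
  if (inherits(x, "eeg_recording")) {
    fs <- x$fs
    if (is.null(channel)) stop("give a channel label for recording input")
    x <- x$data[channel, ]
  }
  if (is.null(fs)) stop("fs required")
  if (!is.null(seed)) set.seed(seed)
  half <- as.integer(round(window / 2 * fs))
  n <- length(x)
  kern <- design_fir(filter_spec(band[1], band[2]), fs)
  env <- analytic_signal(fft_convolve_same(x, kern))$amplitude
  centers <- as.integer(r_peaks)
  ok <- centers - half >= 0L & centers + half < n
  if (!all(ok)) {
    warning(sprintf("%d R-peak segment(s) without full %g s context dropped",
                    sum(!ok), window))
    centers <- centers[ok]
  }
  if (length(centers) < 10L) stop("need >= 10 usable R-peaks")
  offs <- (-half):half
  nt <- length(offs)
  trace_of <- function(ctr) {
    e <- matrix(env[outer(ctr + 1L, offs, "+")], length(ctr))
    colMeans(e) - mean(rowMeans(e))
  }
  obs <- trace_of(centers)
  # all random placements at once, sweeping the offset (one gather per
  # offset instead of one segment matrix per permutation)
  nc <- length(centers)
  rc <- matrix(sample.int(n - 2L * half, nc * n_perm, replace = TRUE) +
                 half - 1L, nc, n_perm)
  nullmat <- matrix(0, n_perm, nt)
  for (j in seq_len(nt)) {
    nullmat[, j] <- colMeans(matrix(env[rc + offs[j] + 1L], nc))
  }
  nullmat <- nullmat - rowMeans(nullmat)  # per-placement mean removal
  if (pool_null) {
    spooled <- sort(abs(nullmat))
    ge <- length(spooled) - findInterval(abs(obs), spooled,
                                         left.open = TRUE)
    p_unc <- (1 + ge) / (1 + length(spooled))
  } else {
    null_ge <- colSums(abs(nullmat) >=
                         matrix(abs(obs), n_perm, nt, byrow = TRUE))
    p_unc <- (1 + null_ge) / (1 + n_perm)
  }
  structure(list(time = offs / fs, mean_envelope = obs,
                 p_values = pmin(p_unc * length(offs), 1),
                 p_uncorrected = p_unc,
                 n_permutations = n_perm, n_segments = length(centers),
                 channel = channel),
            class = "modulation_test_result")
}

#' @export
print.modulation_test_result <- function(x, ...) {
  sig <- sum(x$p_values < 0.05)
  cat(sprintf(paste0("<modulation_test_result> %d segments, %d ",
                     "permutations, %d/%d Bonferroni-significant ",
                     "timepoint(s)\n"),
              x$n_segments, x$n_permutations, sig, length(x$p_values)))
  invisible(x)
}
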