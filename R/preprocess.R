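#' FIR bandpass filter specification
#'
#' @param low lower band edge, Hz.
#' @param high upper band edge, Hz.
#' @param n_taps odd kernel length; if NULL it is chosen from the Hamming
#'   window-method rule of thumb for a `transition` Hz transition band
#'   (about 3.3 / (transition/fs) taps, rounded up to odd).
#' @param transition transition bandwidth in Hz used when `n_taps` is NULL.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(low, high, n_taps = NULL, transition = 2) {
  if (!(low >= 0 && high > low)) stop("need 0 <= low < high")
  structure(list(low = low, high = high, n_taps = n_taps,
                 transition = transition, window = "hamming",
                 type = if (low <= 0) "lowpass" else "bandpass"),
            class = "filter_spec")
}

# symmetric Hamming window of length n
hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Design a linear-phase FIR kernel by the Hamming window method
#'
#' Type-I (odd length, symmetric) kernel. Bandpass kernels are the
#' difference of two windowed-sinc lowpass prototypes; a pure lowpass is
#' obtained with `low = 0`.
#'
#' @param spec a [filter_spec()] (or use `low`/`high` directly).
#' @param fs sampling rate, Hz.
#' @return numeric kernel (tap weights), attributes `fs`, `band`.
#' @export
#' @examples
#' h <- design_fir(filter_spec(9, 11), fs = 500)
#' length(h) %% 2  # odd
design_fir <- function(spec, fs) {
  if (!inherits(spec, "filter_spec")) stop("spec must be a filter_spec")
  if (spec$high >= fs / 2) stop("band edges must lie below Nyquist")
  n <- spec$n_taps
  if (is.null(n)) {
    n <- ceiling(3.3 * fs / spec$transition)
    if (n %% 2L == 0L) n <- n + 1L
  }
  if (n %% 2L == 0L) stop("n_taps must be odd (type-I linear phase)")
  m <- (n - 1L) / 2L
  t <- seq(-m, m)
  sinc <- function(fc) {
    h <- 2 * fc / fs * sin(pi * 2 * fc / fs * t) / (pi * 2 * fc / fs * t)
    h[t == 0] <- 2 * fc / fs
    h
  }
  h <- if (spec$low <= 0) sinc(spec$high) else sinc(spec$high) - sinc(spec$low)
  h <- h * hamming_window(n)
  # normalize passband gain to 1 at band center (lowpass: at DC)
  f0 <- if (spec$low <= 0) 0 else (spec$low + spec$high) / 2
  g <- Mod(sum(h * exp(-2i * pi * f0 / fs * seq_along(h))))
  h <- h / g
  attr(h, "fs") <- fs
  attr(h, "band") <- c(spec$low, spec$high)
  h
}

#' Frequency response of an FIR kernel
#' @param kernel tap weights.
#' @param f frequencies in Hz at which to evaluate.
#' @param fs sampling rate, Hz (defaults to the kernel's `fs` attribute).
#' @return complex response at `f`.
#' @export
fir_response <- function(kernel, f, fs = attr(kernel, "fs")) {
  vapply(f, function(fi) {
    sum(kernel * exp(-2i * pi * fi / fs * seq_along(kernel)))
  }, complex(1))
}

#' Flag bad channels from the stimulation-free recording
#'
#' A channel is excluded when its broadband power exceeds 100 x the median
#' broadband power across channels (two orders of magnitude), or when it
#' saturates: at least `sat_run` consecutive samples within one quantization
#' step of the recording's own extreme value. Broadband power is the
#' variance of the signal (the recording is assumed anti-alias filtered;
#' no further filtering is applied). The returned label set, derived from
#' the no-stimulation condition, is meant to be applied to both conditions.
#'
#' @param rec an `eeg_recording` (stimulation-free condition).
#' @param power_factor exclusion threshold on power relative to the median.
#' @param sat_run minimum run length at the extremes to call saturation.
#' @param sat_tol closeness to the extreme counting as saturated, in units
#'   of the recording's value range.
#' @return character vector of excluded labels (possibly empty).
#' @export
exclude_bad_channels <- function(rec, power_factor = 100, sat_run = 10L,
                                 sat_tol = 1e-5) {
  if (n_channels(rec) < 3L) stop("need at least 3 channels")
  x <- rec$data
  pw <- apply(x, 1, stats::var)
  bad_power <- pw > power_factor * stats::median(pw)
  rng <- range(x)
  tol <- diff(rng) * sat_tol
  bad_sat <- apply(x, 1, function(ch) {
    at_ext <- ch >= rng[2] - tol | ch <= rng[1] + tol
    if (!any(at_ext)) return(FALSE)
    r <- rle(at_ext)
    any(r$lengths[r$values] >= sat_run)
  })
  bad <- rec$channel_labels[bad_power | bad_sat]
  if (length(bad) == length(rec$channel_labels)) {
    stop("all channels flagged bad; recording unusable")
  }
  bad
}

#' Zero-phase FIR filtering of a recording
#'
#' Applies a symmetric (linear-phase) kernel as a single centered FFT
#' convolution, which compensates the group delay exactly: the phase
#' response is identically zero -- single-trial phase is the endpoint of
#' the downstream analysis, so uncompensated delay is not acceptable. A
#' single pass preserves the energy of short bursts better than a
#' forward-backward pass (whose squared response doubles the edge loss of
#' a 2 s trial); `two_pass = TRUE` applies the kernel forward and backward
#' instead when extra stopband depth is wanted. Output length equals input
#' length; events and metadata are carried over. Edges (within one kernel
#' length of the boundaries) are attenuated, not trimmed.
#'
#' @param rec an `eeg_recording`.
#' @param kernel FIR taps from [design_fir()].
#' @param demean remove the channel mean before convolving (default TRUE
#'   for bandpass kernels): a DC offset convolved against the zero-padded
#'   boundary would otherwise inject an in-band step transient at the
#'   recording edges.
#' @param two_pass apply the kernel forward and backward (squared
#'   magnitude response) instead of one centered pass.
#' @return Filtered `eeg_recording` with attribute `band` set.
#' @export
filter_recording <- function(rec, kernel, demean = TRUE,
                             two_pass = FALSE) {
  nk <- length(kernel)
  if (nk >= n_samples(rec)) stop("kernel must be shorter than the recording")
  if (n_samples(rec) < 3L * nk) {
    stop("recording shorter than 3x the kernel; filtering unreliable")
  }
  x <- rec$data
  band <- attr(kernel, "band")
  if (demean && !is.null(band) && band[1] > 0) x <- x - rowMeans(x)
  k2 <- if (two_pass) fft_convolve_full(kernel, rev(kernel)) else kernel
  out <- replace_data(rec, fft_convolve_rows(x, k2))
  attr(out, "band") <- attr(kernel, "band")
  attr(out, "edge_samples") <- length(k2)
  out
}

#' Bandpass filter a recording around a band
#'
#' Convenience wrapper: design the default Hamming-window FIR for `band`
#' and apply it zero-phase.
#' @param rec an `eeg_recording`.
#' @param band numeric length-2, Hz (default 9-11 Hz, the stimulation
#'   target band).
#' @param ... passed to [filter_spec()].
#' @return filtered recording.
#' @export
bandpass_recording <- function(rec, band = c(9, 11), ...) {
  filter_recording(rec, design_fir(filter_spec(band[1], band[2], ...),
                                   rec$fs))
}

#' Segment a recording into fixed-length trials
#'
#' Trial t covers samples `[onset_t, onset_t + duration * fs)` (0-based,
#' half-open). Events whose window would run past the end of the recording
#' are dropped with a warning.
#'
#' @param rec an `eeg_recording` with events.
#' @param duration trial length in seconds (default 2 s).
#' @return object of class `eeg_epochs`: list with `data` (trials x
#'   channels x samples array), `fs`, `onsets`, `duration`,
#'   `channel_labels`.
#' @export
epoch_recording <- function(rec, duration = 2.0) {
  len <- as.integer(round(duration * rec$fs))
  onsets <- sort(as.integer(rec$events$sample))
  if (length(onsets) == 0L) {
    warning("no events; returning empty epochs")
  } else {
    keep <- onsets + len <= n_samples(rec)
    if (!all(keep)) {
      warning(sprintf("%d truncated trial(s) dropped", sum(!keep)))
      onsets <- onsets[keep]
    }
    if (length(onsets) > 1L && any(diff(onsets) < len)) {
      stop("overlapping trials")
    }
  }
  arr <- array(0, dim = c(length(onsets), n_channels(rec), len))
  for (t in seq_along(onsets)) {
    arr[t, , ] <- rec$data[, (onsets[t] + 1L):(onsets[t] + len),
                           drop = FALSE]
  }
  structure(list(data = arr, fs = rec$fs, onsets = onsets,
                 duration = duration,
                 channel_labels = rec$channel_labels),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  invisible(x)
}

#' Virtual occipital channel
#'
#' Unweighted mean across the available occipital channels, honoring the
#' bad-channel mask. Works on recordings (returns a numeric series) and on
#' epochs (returns a trials x samples matrix).
#'
#' @param x an `eeg_recording` or `eeg_epochs`.
#' @param labels occipital label set (default [OCCIPITAL_LABELS]).
#' @return numeric vector (recording) or matrix (epochs).
#' @export
virtual_occipital <- function(x, labels = OCCIPITAL_LABELS) {
  if (inherits(x, "eeg_recording")) {
    use <- setdiff(intersect(labels, x$channel_labels), x$bad_channels)
    if (length(use) == 0L) stop("no occipital channel available")
    colMeans(x$data[use, , drop = FALSE])
  } else if (inherits(x, "eeg_epochs")) {
    use <- intersect(labels, x$channel_labels)
    if (length(use) == 0L) stop("no occipital channel available")
    idx <- match(use, x$channel_labels)
    out <- matrix(0, dim(x$data)[1], dim(x$data)[3])
    for (i in idx) out <- out + x$data[, i, ]
    out / length(idx)
  } else {
    stop("x must be an eeg_recording or eeg_epochs")
  }
}
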