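#' Analytic signal via the Hilbert transform
#'
#' FFT-based analytic signal of a narrowband series. Applied to the
#' full-length series before epoching so that filter/transform edge
#' effects stay outside the trials.
#'
#' @param x numeric series (narrowband).
#' @return list with `amplitude` (envelope, >= 0) and `phase` (radians in
#'   (-pi, pi]).
#' @export
#' @examples
#' a <- analytic_signal(3 * cos(2 * pi * 10 * (0:4999) / 500))
#' range(a$amplitude[500:4500])
analytic_signal <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) stop("constant input: phase undefined")
  # lengths that are not 5-smooth slow the mixed-radix FFT (quadratically
  # so for prime lengths); mirror-pad to a smooth length and truncate
  # (the Hilbert kernel decays as 1/t, so this only touches the edges)
  pad <- 0L
  if (largest_prime_factor(n) > 5L) {
    m <- stats::nextn(n, c(2, 3, 5))
    pad <- m - n
    x <- c(x, x[seq(n, by = -1L, length.out = pad)])
  }
  np <- n + pad
  h <- numeric(np)
  if (np %% 2 == 0) {
    h[c(1, np / 2 + 1)] <- 1
    h[2:(np / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((np + 1) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE)[seq_len(n)] / np
  list(amplitude = Mod(z), phase = wrap_angle(Arg(z)))
}

#' Flicker reference phase
#'
#' The flicker defines the reference oscillation: phase is zero at each
#' trial onset and advances at `2 pi f / fs` per sample.
#'
#' @param onset_sample 0-based onset sample of the trial.
#' @param fs sampling rate, Hz.
#' @param f flicker frequency, Hz.
#' @param length number of samples to generate (from the onset).
#' @return wrapped phase series of the given length.
#' @export
flicker_phase <- function(onset_sample, fs, f, length) {
  idx <- seq_len(length) - 1L
  wrap_angle(2 * pi * f * idx / fs)
}

#' Single-trial SSVEP amplitude and phase table
#'
#' Implements the single-trial reduction: the band-filtered (and, if
#' applicable, SASS-cleaned) series is Hilbert transformed unsegmented,
#' then cut into trials; within each trial the envelope is averaged
#' arithmetically and the per-sample phase difference to the flicker is
#' averaged circularly, giving one amplitude and one phase difference per
#' trial. Trials whose within-trial phase differences have a near-zero
#' resultant (circular mean undefined) are flagged and should be excluded
#' from phase-locking summaries.
#'
#' @param series narrowband numeric series (e.g. the virtual occipital
#'   channel after SASS).
#' @param fs sampling rate, Hz.
#' @param onsets 0-based trial onset samples.
#' @param duration trial length, s.
#' @param f flicker frequency, Hz.
#' @param condition tag stored on the table (`no_stim`, `stim_raw`,
#'   `stim_sass`, ...).
#' @param min_resultant threshold on the within-trial resultant length
#'   below which a trial is flagged.
#' @return data.frame of class `trial_table` with columns `trial`,
#'   `amplitude` (uV), `phase_diff` (radians, (-pi, pi]), `flagged`.
#' @export
single_trial_metrics <- function(series, fs, onsets, duration = 2.0,
                                 f = 10, condition = "no_stim",
                                 min_resultant = 1e-3) {
  len <- as.integer(round(duration * fs))
  asig <- analytic_signal(series)
  n <- length(series)
  onsets <- as.integer(onsets)
  keep <- onsets + len <= n & onsets >= 0L
  if (!all(keep)) {
    warning(sprintf("%d trial(s) outside the recording dropped",
                    sum(!keep)))
    onsets <- onsets[keep]
  }
  ref <- flicker_phase(0L, fs, f, len)
  out <- lapply(seq_along(onsets), function(t) {
    idx <- (onsets[t] + 1L):(onsets[t] + len)
    amp <- mean(asig$amplitude[idx])
    dphi <- wrap_angle(asig$phase[idx] - ref)
    cm <- circ_mean(dphi)
    flagged <- cm$r < min_resultant
    if (flagged) {
      warning(sprintf("trial %d: circular mean undefined (resultant ~ 0)",
                      t))
    }
    data.frame(trial = t, amplitude = amp, phase_diff = cm$mean,
               flagged = flagged)
  })
  tab <- do.call(rbind, out)
  if (is.null(tab)) {
    tab <- data.frame(trial = integer(0), amplitude = numeric(0),
                      phase_diff = numeric(0), flagged = logical(0))
  }
  attr(tab, "condition") <- condition
  attr(tab, "fs") <- fs
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Phase-locking value
#'
#' Modulus of the mean unit phasor of per-trial phase differences:
#' `PLV = | mean(exp(i phi_n)) |`, with the resultant angle as the mean
#' phase. 1 means perfect locking to the flicker, 0 uniform phases.
#'
#' @param trial_phases radians, one per trial (n >= 2).
#' @return list of class `plv_result`: `plv` in `[0, 1]`, `n_trials`,
#'   `mean_angle` (radians).
#' @export
phase_locking_value <- function(trial_phases) {
  n <- length(trial_phases)
  if (n < 2L) stop("need at least 2 trials")
  z <- mean(exp(1i * trial_phases))
  structure(list(plv = Mod(z), n_trials = n,
                 mean_angle = wrap_angle(Arg(z))),
            class = "plv_result")
}

#' @export
print.plv_result <- function(x, ...) {
  cat(sprintf("PLV = %.3f (n = %d, mean angle = %.2f rad)\n",
              x$plv, x$n_trials, x$mean_angle))
  invisible(x)
}

#' Evoked response (trial average)
#'
#' Pointwise mean across trials. With flicker onsets randomized over the
#' stimulation envelope's phase, the stimulation artifact averages out at
#' roughly `1/sqrt(N)` of its single-trial size while the flicker-locked
#' SSVEP survives.
#'
#' @param epochs an `eeg_epochs` object or a trials x samples matrix.
#' @return channels x samples matrix (or vector for matrix input).
#' @export
evoked_response <- function(epochs) {
  if (inherits(epochs, "eeg_epochs")) {
    if (dim(epochs$data)[1] < 1L) stop("need at least 1 trial")
    out <- apply(epochs$data, c(2, 3), mean)
    rownames(out) <- epochs$channel_labels
    out
  } else {
    m <- as.matrix(epochs)
    if (nrow(m) < 1L) stop("need at least 1 trial")
    colMeans(m)
  }
}

#' Single-trial evaluation of one condition
#'
#' Convenience pipeline from a broadband recording to a trial table:
#' bandpass to `band`, optionally apply a SASS projection, form the virtual
#' occipital channel, and reduce to single-trial amplitude and phase.
#'
#' @param rec broadband `eeg_recording` with flicker events.
#' @param band numeric length-2, Hz.
#' @param model optional `sass_model` with projection (applied after
#'   filtering).
#' @param condition condition tag for the table.
#' @param f flicker frequency, Hz.
#' @param duration trial duration, s.
#' @param occipital occipital label set.
#' @return a `trial_table`.
#' @export
evaluate_condition <- function(rec, band = c(9, 11), model = NULL,
                               condition = "no_stim", f = 10,
                               duration = 2.0,
                               occipital = OCCIPITAL_LABELS) {
  # spatial projection and occipital averaging are linear and channel-wise
  # filtering commutes with them, so collapse to the single virtual series
  # first and filter that (orders of magnitude cheaper than filtering all
  # channels)
  use <- setdiff(intersect(occipital, rec$channel_labels),
                 rec$bad_channels)
  if (length(use) == 0L) stop("no occipital channel available")
  w <- rep(0, n_channels(rec))
  w[match(use, rec$channel_labels)] <- 1 / length(use)
  if (!is.null(model)) {
    P <- if (inherits(model, "sass_model")) model$P else as.matrix(model)
    if (is.null(P)) stop("model has no projection")
    w <- as.numeric(crossprod(P, w))
  }
  series <- as.numeric(w %*% rec$data)
  kern <- design_fir(filter_spec(band[1], band[2]), rec$fs)
  series <- fft_convolve_same(series - mean(series), kern)
  single_trial_metrics(series, rec$fs, rec$events$sample,
                       duration = duration, f = f, condition = condition)
}

#' Per-sensor single-trial amplitudes
#'
#' Same reduction as [single_trial_metrics()] but for every channel,
#' returning the trials x sensors amplitude matrix used by the spatial
#' cluster permutation test.
#'
#' @param rec broadband `eeg_recording` with events (or an already
#'   band-filtered one, with `prefiltered = TRUE`).
#' @param band numeric length-2, Hz.
#' @param model optional `sass_model` applied after filtering.
#' @param duration trial duration, s.
#' @param prefiltered set TRUE when `rec` is already band filtered, to
#'   skip the (expensive) filtering pass.
#' @param decimation envelope decimation factor: the band envelope is
#'   smooth (bandwidth below the band's upper edge), so it is computed on
#'   every `decimation`-th sample of the filtered signal, which changes 2 s
#'   trial means negligibly and cuts the per-channel transforms by the
#'   same factor. Must keep the decimated rate above twice the band's
#'   upper edge; 1 disables.
#' @return trials x channels matrix of mean within-trial envelopes (uV).
#' @export
sensor_trial_amplitudes <- function(rec, band = c(9, 11), model = NULL,
                                    duration = 2.0, prefiltered = FALSE,
                                    decimation = 8L) {
  filt <- if (prefiltered) rec else bandpass_recording(rec, band)
  if (!is.null(model)) filt <- apply_projection(model, filt)
  if (rec$fs / decimation < 2 * band[2]) {
    stop("decimation too aggressive for the band")
  }
  len <- as.integer(round(duration * rec$fs))
  onsets <- as.integer(rec$events$sample)
  onsets <- onsets[onsets + len <= n_samples(rec)]
  keep <- seq(1L, n_samples(rec), by = decimation)
  x <- t(filt$data[, keep, drop = FALSE])
  n <- nrow(x)
  pad <- 0L
  if (largest_prime_factor(n) > 5L) {
    m <- stats::nextn(n, c(2, 3, 5))
    pad <- m - n
    x <- rbind(x, x[seq(n, by = -1L, length.out = pad), , drop = FALSE])
  }
  np <- n + pad
  h <- numeric(np)
  if (np %% 2 == 0) {
    h[c(1, np / 2 + 1)] <- 1
    h[2:(np / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((np + 1) / 2)] <- 2
  }
  z <- stats::mvfft(x)
  env <- Mod(stats::mvfft(z * h, inverse = TRUE)[seq_len(n), ,
                                                 drop = FALSE] / np)
  out <- matrix(0, length(onsets), n_channels(rec))
  for (t in seq_along(onsets)) {
    i0 <- onsets[t] %/% decimation + 1L
    i1 <- (onsets[t] + len - 1L) %/% decimation + 1L
    out[t, ] <- colMeans(env[i0:i1, , drop = FALSE])
  }
  colnames(out) <- rec$channel_labels
  out
}
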