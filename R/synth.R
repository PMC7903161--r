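#' Configuration of a synthetic concurrent EEG / AM-tACS session
#'
#' Describes the emulated experiment: a 64-channel, 500 Hz EEG recording of
#' 200 two-second visual flicker trials (10 Hz) separated by random 0.5-1 s
#' inter-trial intervals, recorded once without stimulation and once while
#' amplitude-modulated tACS (220 Hz carrier, 10 Hz envelope) is applied.
#' The recorded artifact arises from a per-order memoryless polynomial
#' transduction of the AM waveform (even powers demodulate the envelope),
#' generated at 8x oversampling, anti-alias lowpass filtered at 125 Hz and
#' decimated -- so the carrier itself never reaches the recording, only its
#' demodulation products at the envelope frequency and harmonics, each with
#' its own scalp topography.
#'
#' @param n_channels number of electrodes (subset of the standard montage;
#'   the occipital set is always included).
#' @param fs sampling rate, Hz.
#' @param n_trials flicker trials per session.
#' @param trial_duration trial length, s (`trial_duration * flicker_freq`
#'   must be an integer number of cycles).
#' @param iti_range inter-trial interval bounds, s.
#' @param flicker_freq flicker / stimulation envelope frequency, Hz.
#' @param carrier_freq stimulation carrier frequency, Hz.
#' @param artifact_gain ratio of artifact to SSVEP RMS at the target
#'   frequency on the worst channel.
#' @param ssvep_amp SSVEP amplitude on the peak-topography channel, uV.
#' @param noise_exponent spectral slope of the 1/f^a background noise.
#' @param noise_rms per-channel broadband noise RMS, uV.
#' @param nonlinearity_coeffs polynomial coefficients (orders 1..length) of
#'   the transduction nonlinearity; only even orders produce baseband
#'   artifact energy.
#' @param amp_jitter_sdlog log-normal sd of per-trial SSVEP amplitude.
#' @param phase_jitter_sd sd (radians) of per-trial SSVEP phase jitter
#'   around the fixed flicker lag.
#' @param phase_lag SSVEP phase lag relative to the flicker, radians.
#' @param extra_artifact_sources number of additional independent in-band
#'   artifact sources (emulating e.g. fluctuating intermodulation products;
#'   the deterministic AM artifact contributes exactly one in-band source).
#' @param bad_channel_labels labels whose noise power is inflated to
#'   emulate broken electrodes.
#' @param bad_channel_factor power inflation factor for bad channels.
#' @param ecg optional list(`rate_hz`, `bump_height`, `bump_width`) adding a
#'   heartbeat-locked multiplicative modulation of the artifact; bump
#'   height 0 (the default world) reproduces the null finding that AM-tACS
#'   artifacts are not heartbeat-modulated.
#' @param seed integer seed for all randomness in the session.
#' @return list of class `session_config`.
#' @export
session_config <- function(n_channels = 64, fs = 500, n_trials = 200,
                           trial_duration = 2.0, iti_range = c(0.5, 1.0),
                           flicker_freq = 10, carrier_freq = 220,
                           artifact_gain = 1e3, ssvep_amp = 3,
                           noise_exponent = 1, noise_rms = 5,
                           nonlinearity_coeffs = c(1, 0.02, 0, 0.015),
                           amp_jitter_sdlog = 0.25, phase_jitter_sd = 0.1,
                           phase_lag = -pi / 4,
                           extra_artifact_sources = 0,
                           bad_channel_labels = character(),
                           bad_channel_factor = 101,
                           ecg = NULL, seed = 0L) {
  cyc <- trial_duration * flicker_freq
  if (abs(cyc - round(cyc)) > 1e-9) {
    stop("trial_duration * flicker_freq must be an integer cycle count")
  }
  if (iti_range[1] < 0) stop("iti lower bound must be >= 0")
  if (iti_range[2] < iti_range[1]) stop("iti upper bound < lower bound")
  if (fs <= 0 || n_trials < 1) stop("invalid fs or n_trials")
  structure(list(n_channels = n_channels, fs = fs, n_trials = n_trials,
                 trial_duration = trial_duration, iti_range = iti_range,
                 flicker_freq = flicker_freq, carrier_freq = carrier_freq,
                 artifact_gain = artifact_gain, ssvep_amp = ssvep_amp,
                 noise_exponent = noise_exponent, noise_rms = noise_rms,
                 nonlinearity_coeffs = nonlinearity_coeffs,
                 amp_jitter_sdlog = amp_jitter_sdlog,
                 phase_jitter_sd = phase_jitter_sd, phase_lag = phase_lag,
                 extra_artifact_sources = extra_artifact_sources,
                 bad_channel_labels = bad_channel_labels,
                 bad_channel_factor = bad_channel_factor,
                 ecg = ecg, seed = as.integer(seed)),
            class = "session_config")
}

# montage subset of size n that always contains the occipital set
montage_subset <- function(n) {
  m <- standard_montage()
  if (n > nrow(m)) stop("at most ", nrow(m), " channels available")
  must <- intersect(c(OCCIPITAL_LABELS, "CPz", "Iz", "Cz"), m$label)
  if (n < length(must)) must <- must[seq_len(n)]
  rest <- setdiff(m$label, must)
  extra <- rest[unique(round(seq(1, length(rest),
                                 length.out = n - length(must))))]
  keep <- m$label %in% c(must, extra)
  # top up if rounding collapsed indices
  i <- 1L
  while (sum(keep) < n) {
    if (!keep[i]) keep[i] <- TRUE
    i <- i + 1L
  }
  m[keep, , drop = FALSE]
}

# unit-norm topography decaying with distance from a seed electrode; the
# center is taken from the full standard montage so subsets that do not
# carry the electrode still get the right spatial anchor
gaussian_topography <- function(montage, center_label, sigma = 0.5,
                                jitter = 0) {
  full <- standard_montage()
  ctr <- unlist(full[full$label == center_label, c("x", "y", "z")])
  if (length(ctr) == 0L) stop("unknown electrode: ", center_label)
  d2 <- (montage$x - ctr[1])^2 + (montage$y - ctr[2])^2 +
    (montage$z - ctr[3])^2
  w <- exp(-d2 / (2 * sigma^2))
  if (jitter > 0) w <- abs(w + jitter * stats::rnorm(length(w)))
  w <- w / sqrt(sum(w^2))
  names(w) <- montage$label
  w
}

#' Spatially correlated 1/f background noise
#'
#' Independent spectrally shaped Gaussian series per channel, mixed across
#' channels to induce spatial correlation, then row-rescaled to the target
#' broadband RMS (with mild log-normal channel-to-channel spread, within a
#' factor 3). Power below 0.5 Hz is flattened to keep variance finite.
#'
#' @param config a [session_config()].
#' @param duration seconds (> 0).
#' @param montage montage data.frame (defaults to the config's subset).
#' @param mixing optional channels x channels spatial mixing matrix; pass
#'   the same matrix for recordings of the same head so that the noise
#'   covariance is stationary across conditions (as it is in practice).
#' @param target_rms optional per-channel broadband RMS vector, shared
#'   across conditions for the same reason.
#' @return channels x samples matrix, uV.
#' @export
background_noise <- function(config, duration,
                             montage = montage_subset(config$n_channels),
                             mixing = NULL, target_rms = NULL) {
  if (duration <= 0) stop("duration must be positive")
  fs <- config$fs
  nt <- as.integer(round(duration * fs))
  nch <- nrow(montage)
  nfft <- stats::nextn(nt, c(2, 3, 5))
  if (nfft %% 2L == 1L) nfft <- nfft + 1L
  f <- seq(0, fs / 2, length.out = nfft / 2 + 1)
  shape <- pmax(f, 0.5)^(-config$noise_exponent / 2)
  shape[1] <- 0
  src <- matrix(0, nch, nt)
  for (i in seq_len(nch)) {
    half <- (stats::rnorm(nfft / 2 + 1) +
               1i * stats::rnorm(nfft / 2 + 1)) * shape
    half[1] <- 0
    half[nfft / 2 + 1] <- Re(half[nfft / 2 + 1])
    spec <- c(half, Conj(rev(half[2:(nfft / 2)])))
    src[i, ] <- Re(stats::fft(spec, inverse = TRUE))[seq_len(nt)]
  }
  if (is.null(mixing)) {
    mixing <- noise_mixing_matrix(config, nch)
  }
  x <- mixing %*% src
  if (is.null(target_rms)) {
    target_rms <- noise_target_rms(config, montage)
  }
  x <- x * (target_rms / sqrt(rowMeans(x^2)))
  rownames(x) <- montage$label
  x
}

#' Gated SSVEP source: waveform and occipital topography
#'
#' A `flicker_freq` sinusoid gated to `[onset, onset + trial_duration)`
#' windows with a fixed phase lag to the flicker, per-trial log-normal
#' amplitude jitter around `ssvep_amp` and small per-trial phase jitter.
#' The topography is a unit-norm weight profile concentrated on the
#' occipital electrodes (peak at Oz); the waveform is scaled so the
#' peak-topography channel carries the stated amplitude.
#'
#' @param onsets 0-based flicker onset samples.
#' @param config a [session_config()].
#' @param n_total total samples of the session.
#' @param montage montage data.frame.
#' @return list with `series` (length `n_total`, peak-channel units),
#'   `topography` (unit norm), `channel_weights` (topography scaled to 1 at
#'   peak), `trial_amplitudes` (peak channel, uV), `trial_phases`
#'   (radians relative to the flicker).
#' @export
ssvep_component <- function(onsets, config, n_total,
                            montage = montage_subset(config$n_channels)) {
  if (length(onsets) == 0L) {
    warning("no onsets; SSVEP waveform is zero")
  }
  if (length(onsets) && (min(onsets) < 0 ||
                         max(onsets) + config$trial_duration * config$fs >
                         n_total)) {
    stop("onsets must lie within the recording")
  }
  topo <- gaussian_topography(montage, "Oz", sigma = 0.45)
  len <- as.integer(round(config$trial_duration * config$fs))
  amps <- config$ssvep_amp *
    exp(stats::rnorm(length(onsets), 0, config$amp_jitter_sdlog))
  phis <- wrap_angle(config$phase_lag +
                       stats::rnorm(length(onsets), 0,
                                    config$phase_jitter_sd))
  series <- numeric(n_total)
  for (t in seq_along(onsets)) {
    idx <- (onsets[t] + 1L):(onsets[t] + len)
    rel <- (idx - 1L - onsets[t]) / config$fs
    series[idx] <- amps[t] *
      cos(2 * pi * config$flicker_freq * rel + phis[t])
  }
  list(series = series, topography = topo,
       channel_weights = topo / max(topo),
       trial_amplitudes = amps, trial_phases = phis)
}

# 10 Hz (or h * f0) quadrature RMS per channel / per series
quadrature_rms <- function(x, fs, f) {
  t <- (seq_len(ncol(x)) - 1) / fs
  e <- exp(-2i * pi * f * t)
  amp <- 2 * Mod(x %*% e) / ncol(x)
  as.numeric(amp) / sqrt(2)
}

#' AM-tACS artifact as recorded through a nonlinear acquisition chain
#'
#' The stimulation waveform `m(t) = (1 + cos(2 pi f_env t))/2 *
#' sin(2 pi f_c t)` is generated at 8x oversampling; each polynomial order
#' `m^p` (coefficients from the config) receives its own scalp topography,
#' is lowpass filtered at 125 Hz (the recording chain's anti-alias filter)
#' and decimated to the recording rate. Odd powers carry only
#' carrier-band energy and vanish after the anti-alias filter; even powers
#' demodulate the envelope and produce components at the envelope frequency
#' and its harmonics with order-specific topographies.
#'
#' @param config a [session_config()].
#' @param duration seconds.
#' @param montage montage data.frame.
#' @param gain_trace optional multiplicative modulation (length
#'   `duration * fs`), e.g. from [ecg_locked_modulation()].
#' @return list with `data` (channels x samples, unscaled), `basis`
#'   (decimated per-order waveforms), `order_topographies`,
#'   `harmonic_topographies` (per-harmonic channel weights at f_env, 2
#'   f_env, 3 f_env, unit norm where nonzero).
#' @export
am_tacs_artifact <- function(config, duration,
                             montage = montage_subset(config$n_channels),
                             gain_trace = NULL) {
  if (duration <= 0) stop("duration must be positive")
  co <- config$nonlinearity_coeffs
  if (all(co == 0)) {
    warning("all nonlinearity coefficients zero: no artifact at the ",
            "target frequency")
  }
  over <- 8L
  fs_hi <- config$fs * over
  nt <- as.integer(round(duration * config$fs))
  nt_hi <- nt * over
  th <- (seq_len(nt_hi) - 1) / fs_hi
  m <- (1 + cos(2 * pi * config$flicker_freq * th)) / 2 *
    sin(2 * pi * config$carrier_freq * th)
  # stimulators ramp the current on and off; a raised-cosine ramp also
  # keeps onset splatter out of the recorded band
  nr <- min(as.integer(fs_hi), nt_hi %/% 10L)
  if (nr > 1L) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / (nr - 1)))
    m[seq_len(nr)] <- m[seq_len(nr)] * ramp
    m[nt_hi + 1L - seq_len(nr)] <- m[nt_hi + 1L - seq_len(nr)] * ramp
  }
  aa <- design_fir(filter_spec(0, 125, transition = 30), fs_hi)
  orders <- which(co != 0)
  # per-order topographies: the stimulation current enters at CPz and
  # leaves at the inion, so the artifact potential is dipolar between the
  # two, with an order-specific perturbation (capacitive effects make the
  # topography frequency dependent, so harmonics mix differently)
  topos <- lapply(orders, function(p) {
    # broad far-field pattern: large pads spread the potential over much
    # of the scalp, so no single electrode carries a dominant share
    w <- gaussian_topography(montage, "CPz", sigma = 0.9) -
      gaussian_topography(montage, "Iz", sigma = 0.9) +
      0.12 * stats::rnorm(nrow(montage))
    w <- w / sqrt(sum(w^2))
    names(w) <- montage$label
    w
  })
  basis <- matrix(0, length(orders), nt)
  for (j in seq_along(orders)) {
    b <- fft_convolve_same(m^orders[j], aa)
    basis[j, ] <- b[seq(1L, nt_hi, by = over)]
  }
  data <- matrix(0, nrow(montage), nt)
  for (j in seq_along(orders)) {
    data <- data + co[orders[j]] * outer(topos[[j]], basis[j, ])
  }
  if (!is.null(gain_trace)) {
    stopifnot(length(gain_trace) == nt)
    data <- sweep(data, 2, gain_trace, "*")
  }
  harm <- sapply(1:3, function(h) {
    w <- numeric(nrow(montage))
    for (j in seq_along(orders)) {
      a <- quadrature_rms(basis[j, , drop = FALSE], config$fs,
                          h * config$flicker_freq)
      w <- w + co[orders[j]] * a * topos[[j]]
    }
    if (sum(w^2) > 0) w <- w / sqrt(sum(w^2))
    w
  })
  rownames(data) <- montage$label
  rownames(harm) <- montage$label
  colnames(harm) <- paste0("h", 1:3)
  list(data = data, basis = basis,
       order_topographies = if (length(orders)) {
         stats::setNames(topos, paste0("p", orders))
       } else topos,
       harmonic_topographies = harm)
}

#' Heartbeat-locked multiplicative gain trace
#'
#' Gain is identically 1 (the null case, matching the observed absence of
#' heartbeat modulation under AM-tACS) unless a bump height is given, in
#' which case a raised-cosine bump of the stated height and width is
#' centered at each R-peak. Overlapping bumps sum, with a warning.
#'
#' @param n_total samples in the trace.
#' @param fs sampling rate, Hz.
#' @param r_peak_samples sorted 0-based R-peak sample indices.
#' @param height bump height (multiplicative, e.g. 0.1 = +10%).
#' @param width bump full width, s.
#' @return numeric gain trace of length `n_total`.
#' @export
ecg_locked_modulation <- function(n_total, fs, r_peak_samples,
                                  height = 0, width = 0.3) {
  g <- rep(1, n_total)
  if (height == 0 || length(r_peak_samples) == 0L) return(g)
  if (is.unsorted(r_peak_samples)) stop("r_peak_samples must be sorted")
  if (length(r_peak_samples) > 1L &&
      any(diff(r_peak_samples) < width * fs)) {
    warning("overlapping heartbeat bumps; they sum")
  }
  half <- as.integer(round(width * fs / 2))
  for (c0 in r_peak_samples) {
    idx <- max(0L, c0 - half):min(n_total - 1L, c0 + half)
    g[idx + 1L] <- g[idx + 1L] +
      height * 0.5 * (1 + cos(pi * (idx - c0) / half))
  }
  g
}

noise_mixing_matrix <- function(config, nch) {
  diag(nch) + 0.3 * matrix(stats::rnorm(nch * nch), nch) / sqrt(nch)
}

noise_target_rms <- function(config, montage) {
  config$noise_rms * exp(stats::rnorm(nrow(montage), 0, 0.15)) *
    ifelse(montage$label %in% config$bad_channel_labels,
           sqrt(config$bad_channel_factor), 1)
}

# draw flicker onsets: lead-in pad, then trial + uniform ITI
draw_onsets <- function(config, pad = 4) {
  fs <- config$fs
  len <- config$trial_duration * fs
  iti <- stats::runif(config$n_trials, config$iti_range[1],
                      config$iti_range[2])
  gaps <- as.integer(round(iti * fs))
  onsets <- as.integer(round(pad * fs)) +
    cumsum(c(0L, rep(as.integer(len), config$n_trials - 1L) +
               gaps[-config$n_trials]))
  onsets
}

#' Generate a synthetic stimulation-free and during-AM-tACS session pair
#'
#' Draws two recordings from the same generative law -- occipital SSVEP
#' source + spatially correlated 1/f noise -- and adds the nonlinearly
#' transduced AM-tACS artifact (calibrated so that its RMS at the target
#' frequency on the worst channel is `artifact_gain` times the SSVEP's) to
#' the stimulation session. Flicker onsets are drawn independently per
#' session with uniform inter-trial intervals, which distributes them
#' uniformly over the phase of the continuous stimulation envelope.
#'
#' @param config a [session_config()].
#' @param return_components if TRUE, the ground truth additionally carries
#'   the raw brain/noise/artifact matrices of the stimulation session
#'   (memory-heavy; meant for small test configs).
#' @return list with `no_stim` and `stim` (both `eeg_recording`) and
#'   `truth` (a `ground_truth` list: topographies, per-trial amplitudes --
#'   expressed on the virtual occipital channel -- and phases per
#'   condition, onsets, artifact scaling, R-peaks if configured).
#' @export
generate_session <- function(config, return_components = FALSE) {
  stopifnot(inherits(config, "session_config"))
  set.seed(config$seed)
  montage <- montage_subset(config$n_channels)
  occ <- intersect(OCCIPITAL_LABELS, montage$label)
  fs <- config$fs

  # the head and its ongoing-activity covariance are the same in both
  # sessions: one mixing matrix / RMS profile per session pair
  mixing <- noise_mixing_matrix(config, nrow(montage))
  target_rms <- noise_target_rms(config, montage)

  make_brain <- function() {
    onsets <- draw_onsets(config)
    n_total <- max(onsets) + config$trial_duration * fs + 1 * fs
    n_total <- as.integer(ceiling(n_total / fs) * fs)  # whole seconds
    sv <- ssvep_component(onsets, config, n_total, montage)
    noise <- background_noise(config, n_total / fs, montage, mixing,
                              target_rms)
    brain <- outer(sv$channel_weights, sv$series)
    occ_gain <- mean(sv$channel_weights[occ])
    list(onsets = onsets, n_total = n_total, sv = sv, noise = noise,
         brain = brain, occ_gain = occ_gain)
  }

  ns <- make_brain()
  st <- make_brain()

  art <- am_tacs_artifact(config, st$n_total / fs, montage)
  r_peaks <- NULL
  if (!is.null(config$ecg)) {
    rate <- if (is.null(config$ecg$rate_hz)) 1.0 else config$ecg$rate_hz
    beats <- cumsum(stats::rnorm(ceiling(st$n_total / fs * rate * 1.5),
                                 1 / rate, 0.05))
    beats <- beats[beats > 2 & beats < st$n_total / fs - 2]
    r_peaks <- as.integer(round(beats * fs))
    g <- ecg_locked_modulation(st$n_total, fs, r_peaks,
                               height = config$ecg$bump_height %||% 0,
                               width = config$ecg$bump_width %||% 0.3)
    art$data <- sweep(art$data, 2, g, "*")
  }
  # calibrate so that on the worst (largest-artifact) channel the ratio of
  # artifact RMS to the SSVEP's RMS (its peak-channel value; the SSVEP is
  # a pure target-frequency source, so overall RMS is RMS at the target
  # frequency) equals artifact_gain. The artifact's 10 Hz line is coherent
  # over the session, so a quadrature projection measures it.
  s_rms <- sqrt(rowMeans(st$brain^2))
  a_rms <- quadrature_rms(art$data, fs, config$flicker_freq)
  worst <- which.max(a_rms)
  scale <- if (a_rms[worst] > 0) {
    config$artifact_gain * max(s_rms) / a_rms[worst]
  } else 0
  art_scaled <- art$data * scale

  if (config$extra_artifact_sources > 0) {
    bp <- design_fir(filter_spec(config$flicker_freq - 1,
                                 config$flicker_freq + 1), fs)
    ref <- max(quadrature_rms(art_scaled, fs, config$flicker_freq))
    for (j in seq_len(config$extra_artifact_sources)) {
      ctr <- sample(montage$label, 1)
      topo <- gaussian_topography(montage, ctr, sigma = 0.5, jitter = 0.2)
      src <- fft_convolve_same(stats::rnorm(st$n_total), bp)
      src <- src / sqrt(mean(src^2)) * ref * 0.3
      art_scaled <- art_scaled + outer(topo, src)
    }
  }

  events <- function(onsets) {
    data.frame(sample = onsets, code = "flicker", stringsAsFactors = FALSE)
  }
  no_stim <- eeg_recording(ns$brain + ns$noise, fs, montage$label, montage,
                           events(ns$onsets))
  stim_data <- st$brain + st$noise + art_scaled
  stim <- eeg_recording(stim_data, fs, montage$label, montage,
                        events(st$onsets))

  truth <- structure(list(
    ssvep_topography = st$sv$topography,
    artifact_topographies = art$harmonic_topographies,
    artifact_order_topographies = art$order_topographies,
    artifact_scale = scale,
    artifact_gain = config$artifact_gain,
    occipital_gain = st$occ_gain,
    no_stim = list(onsets = ns$onsets,
                   amplitudes = ns$sv$trial_amplitudes * ns$occ_gain,
                   peak_amplitudes = ns$sv$trial_amplitudes,
                   phases = ns$sv$trial_phases),
    stim = list(onsets = st$onsets,
                amplitudes = st$sv$trial_amplitudes * st$occ_gain,
                peak_amplitudes = st$sv$trial_amplitudes,
                phases = st$sv$trial_phases),
    r_peaks = r_peaks), class = "ground_truth")
  if (return_components) {
    truth$components <- list(brain = st$brain, noise = st$noise,
                             artifact = art_scaled)
  }
  list(no_stim = no_stim, stim = stim, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
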