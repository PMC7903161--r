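test_that("session config rejects inconsistent worlds", {
  expect_error(session_config(trial_duration = 1.55), "integer cycle")
  expect_error(session_config(iti_range = c(1, 0.5)), "upper bound")
  expect_error(session_config(iti_range = c(-0.1, 1)), "lower bound")
  expect_silent(session_config(n_channels = 8, n_trials = 5))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 7, n_channels = 8, n_trials = 6)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$stim$data, b$stim$data)
  expect_identical(a$no_stim$data, b$no_stim$data)
  expect_identical(a$truth$stim$amplitudes, b$truth$stim$amplitudes)
})

test_that("artifact gain 0 leaves the two conditions statistically alike", {
  cfg <- small_config(seed = 11, artifact_gain = 0)
  ses <- generate_session(cfg)
  w1 <- welch_psd(ses$stim)
  w0 <- welch_psd(ses$no_stim)
  i10 <- which.min(abs(w1$freqs - 10))
  # same generative law, different draws: no systematic 10 Hz excess
  expect_lt(max(w1$psd[, i10]) / max(w0$psd[, i10]), 5)
  expect_gt(max(w1$psd[, i10]) / max(w0$psd[, i10]), 0.2)
})

test_that("default artifact dominates 10 Hz band power as configured", {
  # the stated gain is the artifact / SSVEP RMS ratio on the worst channel,
  # so the stim / no-stim Welch power ratio there must reach gain^2 / 2
  cfg <- session_config(n_trials = 30, seed = 13)
  ses <- generate_session(cfg)
  w1 <- welch_psd(ses$stim)
  w0 <- welch_psd(ses$no_stim)
  i10 <- which.min(abs(w1$freqs - 10))
  worst <- which.max(w1$psd[, i10])
  expect_gte(w1$psd[worst, i10] / w0$psd[worst, i10],
             cfg$artifact_gain^2 / 2)
})

test_that("ssvep component is a gated sinusoid with stated amplitude", {
  cfg <- session_config(n_channels = 16, n_trials = 1, ssvep_amp = 3,
                        amp_jitter_sdlog = 0, phase_jitter_sd = 0,
                        seed = 1)
  set.seed(1)
  sv <- ssvep_component(0L, cfg, 3000L)
  peak <- which.max(sv$channel_weights)
  expect_equal(names(peak), "Oz")
  x <- sv$series * sv$channel_weights[peak]
  expect_equal(sqrt(mean(x[1:1000]^2)), 3 / sqrt(2), tolerance = 1e-3)
  expect_identical(x[1001:3000], rep(0, 2000))  # exactly 0 outside trials
  expect_warning(ssvep_component(integer(0), cfg, 1000L), "no onsets")
  expect_error(ssvep_component(2500L, cfg, 3000L), "within the recording")
})

test_that("per-trial Hilbert amplitude recovers jittered truth without noise", {
  cfg <- session_config(n_channels = 8, n_trials = 20, seed = 3)
  set.seed(3)
  onsets <- sasseeg:::draw_onsets(cfg)
  n <- max(onsets) + 1500L
  sv <- ssvep_component(onsets, cfg, n)
  tt <- single_trial_metrics(sv$series, cfg$fs, onsets, condition = "x")
  err <- abs(tt$amplitude - sv$trial_amplitudes) / sv$trial_amplitudes
  expect_lt(median(err), 0.05)
  expect_lt(mean(abs(wrap_angle(tt$phase_diff - sv$trial_phases))), 0.05)
})

test_that("ideal AM transduction has no envelope-frequency energy", {
  cfg <- session_config(n_channels = 8,
                        nonlinearity_coeffs = c(1, 0, 0, 0), seed = 1)
  set.seed(1)
  art <- am_tacs_artifact(cfg, 24)
  ch <- which.max(rowSums(art$data^2))
  ps <- multitaper_psd(art$data[ch, ], fs = cfg$fs, allow_short = TRUE)[[1]]
  in10 <- ps$freqs > 9.5 & ps$freqs < 10.5
  expect_lt(max(ps$psd[1, in10]) / max(ps$psd[1, ]), 1e-8)
})

test_that("even-order transduction demodulates envelope and harmonics", {
  cfg <- session_config(n_channels = 8,
                        nonlinearity_coeffs = c(0, 1), seed = 1)
  set.seed(1)
  art <- am_tacs_artifact(cfg, 24)
  ch <- which.max(rowSums(art$data^2))
  ps <- welch_psd(art$data[ch, ], nfft = 2048, fs = cfg$fs)
  pk <- function(f) ps$psd[1, which.min(abs(ps$freqs - f))]
  floor15 <- ps$psd[1, which.min(abs(ps$freqs - 15))]
  expect_gt(pk(10) / floor15, 1e4)
  expect_gt(pk(20) / floor15, 1e3)
})

test_that("all-zero nonlinearity warns about the absent artifact", {
  cfg <- session_config(n_channels = 8,
                        nonlinearity_coeffs = c(0, 0), seed = 1)
  expect_warning(am_tacs_artifact(cfg, 2), "nonlinearity")
})

test_that("harmonic artifact topographies are distinct and powers decay", {
  cfg <- session_config(n_channels = 32, seed = 5)
  set.seed(5)
  art <- am_tacs_artifact(cfg, 30)
  h <- art$harmonic_topographies
  expect_lt(abs(sum(h[, 1] * h[, 2])), 0.999)
  expect_lt(abs(sum(h[, 2] * h[, 3])), 0.999)
  pw <- vapply(c(10, 20, 30), function(f) {
    max(sasseeg:::quadrature_rms(art$data, cfg$fs, f))
  }, numeric(1))
  expect_true(all(diff(pw) < 0))
})

test_that("background noise matches the requested spectral slope", {
  fit_slope <- function(exponent) {
    cfg <- session_config(n_channels = 4, noise_exponent = exponent,
                          seed = 2)
    set.seed(2)
    x <- background_noise(cfg, 120, montage_subset(4),
                          mixing = diag(4), target_rms = rep(5, 4))
    ps <- welch_psd(x[1, ], nfft = 4096, fs = cfg$fs)
    use <- ps$freqs >= 1 & ps$freqs <= 100
    unname(coef(lm(log10(ps$psd[1, use]) ~ log10(ps$freqs[use])))[2])
  }
  expect_lt(abs(fit_slope(0)), 0.1)
  expect_lt(abs(fit_slope(1) + 1), 0.2)
})

test_that("noisy channels injected by the generator are flagged downstream", {
  cfg <- small_config(seed = 21, bad_channel_labels = "Cz",
                      bad_channel_factor = 101)
  ses <- generate_session(cfg)
  expect_identical(exclude_bad_channels(ses$no_stim), "Cz")
})

test_that("heartbeat gain trace covers null and bump cases", {
  expect_identical(ecg_locked_modulation(100, 500, c(10L, 50L), height = 0),
                   rep(1, 100))
  expect_identical(ecg_locked_modulation(100, 500, integer(0), height = 0.5),
                   rep(1, 100))
  g <- ecg_locked_modulation(2000, 500, 1000L, height = 0.1, width = 0.3)
  expect_equal(max(g), 1.1, tolerance = 1e-6)
  expect_equal(g[1], 1)
  expect_equal(which.max(g), 1001)
  expect_warning(
    ecg_locked_modulation(2000, 500, c(500L, 520L), height = 0.1,
                          width = 0.3),
    "overlap")
  expect_error(
    ecg_locked_modulation(2000, 500, c(600L, 500L), height = 0.1),
    "sorted")
})

test_that("flicker onsets are uniform over the stimulation envelope phase", {
  cfg <- session_config(seed = 0)
  period <- cfg$fs / cfg$flicker_freq
  nonsig <- 0L
  for (s in 1:20) {
    set.seed(s)
    onsets <- sasseeg:::draw_onsets(cfg)
    ph <- 2 * pi * (onsets %% period) / period
    if (rayleigh_test(ph)$p_value > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 19L)
})

test_that("the generative model is additive before the recording output", {
  cfg <- small_config(seed = 31, n_channels = 8, n_trials = 5)
  ses <- generate_session(cfg, return_components = TRUE)
  cmp <- ses$truth$components
  expect_equal(ses$stim$data,
               cmp$brain + cmp$noise + cmp$artifact,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("ground truth satisfies its structural invariants", {
  ses <- small_session()
  tr <- ses$truth
  cfg <- small_config()
  for (cond in c("no_stim", "stim")) {
    g <- tr[[cond]]
    expect_length(g$amplitudes, cfg$n_trials)
    expect_true(all(diff(g$onsets) >=
                      (cfg$trial_duration + cfg$iti_range[1]) * cfg$fs))
    expect_true(all(g$phases > -pi & g$phases <= pi))
  }
  expect_equal(sum(tr$ssvep_topography^2), 1, tolerance = 1e-12)
})
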