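test_that("bad-channel exclusion follows the power and saturation rules", {
  set.seed(1)
  x <- matrix(rnorm(8 * 5000), 8)
  rec <- eeg_recording(x, 500, paste0("ch", 1:8))
  expect_identical(exclude_bad_channels(rec), character(0))

  x2 <- x
  x2[3, ] <- x2[3, ] * sqrt(101)  # 101x the median power
  rec2 <- eeg_recording(x2, 500, paste0("ch", 1:8))
  expect_identical(exclude_bad_channels(rec2), "ch3")

  x3 <- x
  x3[5, 1001:1500] <- max(x3) + 1  # clipped at a constant extreme for 1 s
  rec3 <- eeg_recording(x3, 500, paste0("ch", 1:8))
  expect_true("ch5" %in% exclude_bad_channels(rec3))

  rec4 <- eeg_recording(x[1:2, ], 500, c("a", "b"))
  expect_error(exclude_bad_channels(rec4), "at least 3")
})

test_that("FIR design meets the passband and stopband contract", {
  h <- design_fir(filter_spec(9, 11), fs = 500)
  expect_identical(length(h) %% 2L, 1L)
  expect_equal(as.numeric(h), rev(as.numeric(h)),
               tolerance = 1e-12)  # type-I symmetry
  g10 <- Mod(fir_response(h, 10))
  expect_gt(g10, 0.89)
  expect_lt(g10, 1.12)
  expect_lt(Mod(fir_response(h, 0)), 0.01)
  # >= 40 dB at 3 Hz outside the band edges
  expect_lt(Mod(fir_response(h, 6)), 10^(-40 / 20))
  expect_lt(Mod(fir_response(h, 14)), 10^(-40 / 20))
  expect_error(design_fir(filter_spec(9, 260), fs = 500), "Nyquist")
  expect_error(design_fir(filter_spec(9, 11, n_taps = 100), 500), "odd")
})

test_that("zero-phase filtering preserves in-band tones and kills others", {
  rec <- sinusoid_recording(10, 3, dur = 30)
  kern <- design_fir(filter_spec(9, 11), 500)
  out <- filter_recording(rec, kern)
  mid <- 5000:10000
  ref <- rec$data[1, mid]
  y <- out$data[1, mid]
  amp_ratio <- sqrt(mean(y^2) / mean(ref^2))
  expect_lt(abs(amp_ratio - 1), 0.02)
  # phase shift via complex demodulation at 10 Hz
  t <- (mid - 1) / 500
  ph <- Arg(sum(y * exp(-2i * pi * 10 * t))) -
    Arg(sum(ref * exp(-2i * pi * 10 * t)))
  expect_lt(abs(ph) * 180 / pi, 1)

  rec50 <- sinusoid_recording(50, 3, dur = 30)
  out50 <- filter_recording(rec50, kern)
  expect_lt(sqrt(mean(out50$data[1, mid]^2) / mean(rec50$data[1, mid]^2)),
            10^(-40 / 20))
  expect_false(anyNA(out$data))
  # edge transients stay bounded and inside 2 kernel lengths
  expect_lt(max(abs(out$data)), 2 * max(abs(rec$data)))
  core <- (2 * length(kern)):(n_samples(rec) - 2 * length(kern))
  expect_lt(max(abs(out$data[1, core])), 1.05 * max(abs(rec$data)))
})

test_that("repeated filtering composes like the squared response", {
  rec <- sinusoid_recording(c(10, 12), c(1, 1), dur = 30)
  kern <- design_fir(filter_spec(9, 11), 500)
  twice <- filter_recording(filter_recording(rec, kern), kern)
  squared <- filter_recording(rec, kern, two_pass = TRUE)
  mid <- 5000:10000
  expect_equal(twice$data[1, mid], squared$data[1, mid], tolerance = 1e-6)
})

test_that("filtering refuses degenerate geometries", {
  rec <- sinusoid_recording(10, 1, dur = 2)
  kern <- design_fir(filter_spec(9, 11), 500)  # 825 taps vs 1000 samples
  expect_error(filter_recording(rec, kern), "3x the kernel")
})

test_that("epoching is a pure half-open reindexing", {
  set.seed(2)
  x <- matrix(rnorm(3 * 10000), 3)
  onsets <- c(1000L, 3000L, 5000L)
  rec <- eeg_recording(x, 500, c("a", "b", "c"),
                       events = data.frame(sample = onsets, code = "f"))
  ep <- epoch_recording(rec, duration = 2)
  expect_identical(dim(ep$data), c(3L, 3L, 1000L))
  for (t in 1:3) {
    expect_identical(ep$data[t, , ],
                     x[, (onsets[t] + 1L):(onsets[t] + 1000L)])
  }

  rec2 <- eeg_recording(x, 500, c("a", "b", "c"),
                        events = data.frame(sample = c(onsets, 9900L),
                                            code = "f"))
  expect_warning(ep2 <- epoch_recording(rec2, 2), "truncated")
  expect_identical(dim(ep2$data)[1], 3L)

  rec3 <- eeg_recording(x, 500, c("a", "b", "c"),
                        events = data.frame(sample = c(1000L, 1500L),
                                            code = "f"))
  expect_error(epoch_recording(rec3, 2), "overlap")

  rec4 <- eeg_recording(x, 500, c("a", "b", "c"))
  expect_warning(ep4 <- epoch_recording(rec4, 2), "no events")
  expect_identical(dim(ep4$data)[1], 0L)
})

test_that("virtual occipital channel averages and honors exclusions", {
  set.seed(3)
  base <- rnorm(1000)
  x <- rbind(base, base, base)
  rec <- eeg_recording(x, 500, c("O1", "Oz", "O2"))
  expect_equal(virtual_occipital(rec), base, ignore_attr = TRUE)

  x2 <- rbind(base, -base)
  rec2 <- eeg_recording(x2, 500, c("O1", "O2"))
  expect_equal(virtual_occipital(rec2), rep(0, 1000), ignore_attr = TRUE)

  rec3 <- eeg_recording(x, 500, c("F1", "F2", "F3"))
  expect_error(virtual_occipital(rec3), "no occipital")

  rec4 <- rec
  rec4$bad_channels <- c("O1", "O2")
  expect_equal(virtual_occipital(rec4), base, ignore_attr = TRUE)
})

test_that("exclusion mask commutes with filtering (label-based)", {
  ses <- small_session()
  rec <- ses$no_stim
  bad <- rec$channel_labels[2]
  a <- bandpass_recording(drop_channels(rec, bad))
  b <- drop_channels(bandpass_recording(rec), bad)
  expect_equal(a$data, b$data, tolerance = 1e-10)
})
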