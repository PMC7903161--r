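test_that("band covariance matches elementary cases", {
  set.seed(1)
  x <- matrix(rnorm(2 * 20000), 2)
  rec <- eeg_recording(x, 500, c("a", "b"))
  C <- band_covariance(rec)$matrix
  expect_equal(diag(C), c(1, 1), tolerance = 0.05, ignore_attr = TRUE)
  expect_lt(abs(C[1, 2]), 0.05)

  topo <- c(1, 2, -1)
  s <- rnorm(5000)
  rec2 <- eeg_recording(outer(topo, s), 500, c("a", "b", "c"))
  C2 <- band_covariance(rec2)$matrix
  expect_equal(C2, var(s) * outer(topo, topo), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(eigen(C2, only.values = TRUE)$values > 1e-8), 1L)

  rec3 <- eeg_recording(rbind(s[1:100], 0 * s[1:100] + 2), 500,
                        c("a", "b"))
  expect_error(band_covariance(rec3), "zero-variance")
})

test_that("stim covariance is artifact-dominated as the gain dictates", {
  ses <- small_session()
  cfg <- small_config()
  A <- band_covariance(bandpass_recording(ses$stim), condition = "stim")
  B <- band_covariance(bandpass_recording(ses$no_stim))
  # the power ratio of the top artifact component during vs without
  # stimulation (the eigenvalue ratio of the joint diagonalization)
  m <- joint_diagonalize(A, B)
  expect_gte(m$lambdas[1], cfg$artifact_gain^2 / 10)
  # and the calibration itself: artifact / SSVEP RMS at the target
  # frequency on the worst channel equals the configured gain
  cfg2 <- small_config(seed = 5, n_channels = 8, n_trials = 10)
  ses2 <- generate_session(cfg2, return_components = TRUE)
  art <- ses2$truth$components$artifact
  brain <- ses2$truth$components$brain
  a_rms <- sasseeg:::quadrature_rms(art, cfg2$fs, 10)
  s_rms <- max(sqrt(rowMeans(brain^2)))
  expect_equal(max(a_rms) / s_rms, cfg2$artifact_gain, tolerance = 0.05)
})

test_that("joint diagonalization solves the generalized eigenproblem", {
  set.seed(2)
  A <- random_spd(4)
  m <- joint_diagonalize(A, A)
  expect_equal(m$lambdas, rep(1, 4), tolerance = 1e-8)

  m2 <- joint_diagonalize(diag(c(100, 1)), diag(2))
  expect_equal(m2$lambdas, c(100, 1), tolerance = 1e-10)
  w1 <- m2$W[1, ]
  expect_equal(abs(w1) / sqrt(sum(w1^2)), c(1, 0), tolerance = 1e-10)

  for (i in 1:20) {
    n <- sample(2:5, 1)
    A <- random_spd(n)
    B <- random_spd(n)
    m <- joint_diagonalize(A, B)
    # defining identities
    for (j in seq_len(n)) {
      w <- m$W[j, ]
      expect_equal(as.numeric(A %*% w), m$lambdas[j] * as.numeric(B %*% w),
                   tolerance = 1e-7)
      expect_equal(as.numeric(t(w) %*% B %*% w), 1, tolerance = 1e-8)
      expect_equal(m$lambdas[j],
                   as.numeric(t(w) %*% A %*% w / (t(w) %*% B %*% w)),
                   tolerance = 1e-8)
    }
    expect_true(all(diff(m$lambdas) <= 1e-12))
    # independent characteristic-polynomial oracle
    expect_equal(m$lambdas, gevd_oracle(A, B), tolerance = 1e-6)
  }
})

test_that("projection algebra: identity, idempotency, rank, invariance", {
  set.seed(3)
  for (i in 1:15) {
    n <- sample(3:8, 1)
    m <- joint_diagonalize(random_spd(n), random_spd(n))
    k <- sample(0:n, 1)
    mk <- if (k == n) suppressWarnings(build_projection(m, k)) else
      build_projection(m, k)
    P <- mk$P
    expect_lt(max(abs(P %*% P - P)), 1e-8)
    expect_equal(sum(svd(P)$d > 1e-8), n - k)
    if (k == 0) expect_equal(P, diag(n), tolerance = 1e-10,
                             ignore_attr = TRUE)
    # retained components' time courses are untouched
    S <- c(rep(0, k), rep(1, n - k))
    WP <- mk$W %*% P
    for (j in which(S == 1)) {
      expect_equal(WP[j, ], mk$W[j, ], tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
    # P is invariant to rescaling the eigenvectors
    m2 <- m
    m2$W <- m$W * runif(n, 0.5, 2)
    expect_equal(suppressWarnings(build_projection(m2, k))$P, P,
                 tolerance = 1e-8)
  }
  m <- joint_diagonalize(diag(c(100, 1)), diag(2))
  expect_equal(build_projection(m, 1)$P, diag(c(0, 1)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_warning(build_projection(m, 2), "zero matrix")
  expect_error(build_projection(m, 3), "0..n")
})

test_that("projection depends only on the invariant subspace under ties", {
  m <- joint_diagonalize(diag(c(2, 2, 1)), diag(3))
  P <- build_projection(m, 2)$P
  expect_equal(P, diag(c(0, 0, 1)), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("component-count selection minimizes the power mismatch", {
  ses <- small_session()
  nf <- bandpass_recording(ses$no_stim)
  B <- band_covariance(nf)
  m0 <- joint_diagonalize(B, B)
  m0 <- select_component_count(m0, B, B)
  expect_identical(m0$k_rejected, 0L)  # nothing to reject

  model <- small_model()
  expect_identical(model$k_rejected,
                   which.min(model$selection_curve) - 1L)
  expect_identical(model$k_rejected, 1L)  # one artifact source by design

  # the covariance shortcut equals cleaning the series and measuring power
  sf <- bandpass_recording(ses$stim)
  A <- band_covariance(sf, condition = "stim")
  edge <- attr(sf, "edge_samples")
  xc <- sf$data[, (edge + 1):(ncol(sf$data) - edge)]
  xc <- xc - rowMeans(xc)
  for (k in c(0L, 1L, 3L)) {
    P <- build_projection(model, k)$P
    direct <- apply(P %*% xc, 1, var)
    via_cov <- diag(P %*% A$matrix %*% t(P))
    expect_equal(direct, via_cov, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("residual artifact power is non-increasing up to the true k", {
  cfg <- small_config(seed = 47, extra_artifact_sources = 1)
  ses <- generate_session(cfg)
  sf <- bandpass_recording(ses$stim)
  nf <- bandpass_recording(ses$no_stim)
  A <- band_covariance(sf, condition = "stim")
  B <- band_covariance(nf)
  model <- joint_diagonalize(A, B)
  resid <- vapply(0:2, function(k) {
    P <- build_projection(model, k)$P
    sum(abs(diag(P %*% A$matrix %*% t(P)) - diag(B$matrix)))
  }, numeric(1))
  expect_true(all(diff(resid) < 0))
})

test_that("applying the projection cleans stim data without touching tags", {
  ses <- small_session()
  model <- small_model()
  rec <- ses$stim
  same <- apply_projection(diag(n_channels(rec)), rec)
  expect_equal(same$data, rec$data, ignore_attr = TRUE)

  cleaned <- apply_projection(model, rec)
  expect_identical(cleaned$events, rec$events)
  w1 <- welch_psd(cleaned)
  w0 <- welch_psd(ses$no_stim)
  wr <- welch_psd(rec)
  i10 <- which.min(abs(w1$freqs - 10))
  occ <- match(intersect(OCCIPITAL_LABELS, rec$channel_labels),
               rec$channel_labels)
  expect_gt(max(wr$psd[occ, i10] / w0$psd[occ, i10]), 1e4)
  ratio <- mean(w1$psd[occ, i10]) / mean(w0$psd[occ, i10])
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)

  bad <- ses$no_stim
  bad$channel_labels <- rev(bad$channel_labels)
  expect_error(apply_projection(model, bad), "labels")
})

test_that("SASS does not overcorrect the stimulation-free recording", {
  ses <- small_session()
  model <- small_model()
  before <- evaluate_condition(ses$no_stim, condition = "no_stim")
  after <- evaluate_condition(ses$no_stim, model = model,
                              condition = "no_stim")
  change <- abs(after$amplitude - before$amplitude) / before$amplitude
  expect_lt(median(change), 0.10)
})

test_that("per-harmonic models use the right bands and differ spatially", {
  ses <- small_session()
  hm <- suppressWarnings(
    harmonic_sass(ses$stim, ses$no_stim, f0 = 10, harmonics = 1:3))
  expect_equal(lapply(hm, `[[`, "band"),
               list(h1 = c(9, 11), h2 = c(19, 21), h3 = c(29, 31)))
  w10 <- hm$h1$W[1, ]
  w20 <- hm$h2$W[1, ]
  cs <- abs(sum(w10 * w20)) / sqrt(sum(w10^2) * sum(w20^2))
  expect_lt(cs, 0.99)
  # fundamental-only cleaning leaves the 20 Hz artifact in place
  cl <- apply_projection(hm$h1, ses$stim)
  w1 <- welch_psd(cl)
  w0 <- welch_psd(ses$no_stim)
  i20 <- which.min(abs(w1$freqs - 20))
  expect_gt(max(w1$psd[, i20] / w0$psd[, i20]), 10)
  expect_error(
    harmonic_sass(ses$stim, ses$no_stim, harmonics = 1:2, half_width = 6),
    "overlap")
})

test_that("SSP baseline is an orthogonal projection and costs more signal", {
  set.seed(4)
  A <- random_spd(5)
  expect_equal(ssp_baseline(A, 0), diag(5), tolerance = 1e-10)
  P <- ssp_baseline(A, 2)
  expect_equal(P, t(P), tolerance = 1e-10)
  expect_lt(max(abs(P %*% P - P)), 1e-10)

  # overlap fixture: artifact topography partially aligned with the SSVEP
  set.seed(5)
  n <- 12
  fs <- 500
  t <- (seq_len(60 * fs) - 1) / fs
  t_brain <- c(rep(1, 4), rep(0.2, 8))
  t_brain <- t_brain / sqrt(sum(t_brain^2))
  t_art <- 0.6 * t_brain + 0.8 * rnorm(n) / sqrt(n)
  t_art <- t_art / sqrt(sum(t_art^2))
  brain <- 2 * cos(2 * pi * 10 * t + 2 * pi * runif(1))
  gate <- rep(rep(c(1, 0), each = fs), 30)[seq_along(t)]
  brain <- brain * gate
  art <- 500 * cos(2 * pi * 10 * t + 1)
  noise <- matrix(rnorm(n * length(t)), n)
  labs <- paste0("ch", 1:n)
  stim <- eeg_recording(outer(t_brain, brain) + outer(t_art, art) + noise,
                        fs, labs)
  nostim <- eeg_recording(outer(t_brain, brain * 0.98) +
                            matrix(rnorm(n * length(t)), n), fs, labs)
  sf <- bandpass_recording(stim)
  nf <- bandpass_recording(nostim)
  A2 <- band_covariance(sf, condition = "stim")
  B2 <- band_covariance(nf)
  P_sass <- build_projection(joint_diagonalize(A2, B2), 1)$P
  P_ssp <- ssp_baseline(A2, 1)
  amp_of <- function(P) {
    y <- as.numeric((t_brain %*% P) %*% sf$data)
    sqrt(mean(y[gate == 1]^2))
  }
  expect_gte(amp_of(P_sass), 1.2 * amp_of(P_ssp))
})
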