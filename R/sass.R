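#' Narrowband sensor covariance
#'
#' Empirical covariance of the full-length (unsegmented) band-filtered
#' recording, channel means removed, unbiased (1/(N-1)) normalization.
#'
#' @param rec an `eeg_recording`, already bandpass filtered to `band`, bad
#'   channels removed.
#' @param band numeric length-2, Hz (defaults to the recording's `band`
#'   attribute set by [filter_recording()]).
#' @param condition `"stim"` or `"no_stim"` tag.
#' @param edge samples dropped from each end before estimation, to keep
#'   filter edge transients (which carry their own topography and would
#'   masquerade as extra artifact components) out of the covariance;
#'   defaults to the kernel length recorded by [filter_recording()].
#' @return object of class `sensor_cov`: list with `matrix`, `band`,
#'   `condition`, `n_samples_used`, `channel_labels`.
#' @export
band_covariance <- function(rec, band = attr(rec, "band"),
                            condition = c("no_stim", "stim"),
                            edge = attr(rec, "edge_samples")) {
  condition <- match.arg(condition)
  x <- rec$data
  if (!is.null(edge) && edge > 0 && ncol(x) > 3L * edge) {
    x <- x[, (edge + 1L):(ncol(x) - edge), drop = FALSE]
  }
  if (ncol(x) < nrow(x)) {
    warning("fewer samples than channels: covariance is rank deficient")
  }
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance channel present; exclude it first: ",
         paste(rec$channel_labels[v == 0], collapse = ", "))
  }
  xc <- x - rowMeans(x)
  C <- tcrossprod(xc) / (ncol(x) - 1)
  C <- (C + t(C)) / 2
  structure(list(matrix = C, band = band, condition = condition,
                 n_samples_used = ncol(x),
                 channel_labels = rec$channel_labels),
            class = "sensor_cov")
}

as_cov_matrix <- function(x) {
  if (inherits(x, "sensor_cov")) x$matrix else as.matrix(x)
}

#' Joint diagonalization of stimulation / no-stimulation covariances
#'
#' Solves the generalized eigenvalue problem `A w = lambda B w` for the
#' during-stimulation covariance A and the stimulation-free covariance B.
#' Each ratio `lambda_i = (w_i' A w_i)/(w_i' B w_i)` is the power of
#' component i during stimulation relative to without stimulation; large
#' ratios identify artifact components. Filters are normalized so
#' `w_i' B w_i = 1` (the projection built from them is invariant to this
#' choice). B receives a small ridge (`1e-9 * trace(B)/n`) when its
#' condition number exceeds 1e10.
#'
#' @param A,B `sensor_cov` objects (or plain symmetric matrices) with
#'   matching channels and band.
#' @return object of class `sass_model`: list with `W` (rows are filters
#'   `w_i'`), `lambdas` (descending), `band`, `channel_labels`;
#'   `k_rejected`, `P` and `selection_curve` are filled in later.
#' @export
joint_diagonalize <- function(A, B) {
  Am <- as_cov_matrix(A)
  Bm <- as_cov_matrix(B)
  labs <- if (inherits(A, "sensor_cov")) A$channel_labels else
    rownames(Am)
  band <- if (inherits(A, "sensor_cov")) A$band else NULL
  if (inherits(A, "sensor_cov") && inherits(B, "sensor_cov")) {
    if (!identical(A$channel_labels, B$channel_labels)) {
      stop("covariances have different channel sets")
    }
    if (!is.null(A$band) && !is.null(B$band) &&
        !isTRUE(all.equal(A$band, B$band))) {
      stop("covariances come from different bands")
    }
  }
  n <- nrow(Am)
  eb <- eigen(Bm, symmetric = TRUE, only.values = TRUE)$values
  if (eb[1] <= 0) stop("B is not positive definite")
  if (eb[n] <= 0 || eb[1] / eb[n] > 1e10) {
    Bm <- Bm + 1e-9 * sum(diag(Bm)) / n * diag(n)
    eb <- eigen(Bm, symmetric = TRUE, only.values = TRUE)$values
    if (eb[n] <= 0 || eb[1] / eb[n] > 1e14) {
      stop("B is singular beyond regularization; exclude bad channels ",
           "or increase the ridge")
    }
  }
  L <- t(chol(Bm))
  M <- forwardsolve(L, t(forwardsolve(L, Am)))
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  W <- t(backsolve(t(L), e$vectors))  # rows w_i', with w_i' B w_i = 1
  rownames(W) <- NULL
  structure(list(W = W, lambdas = e$values, k_rejected = NULL, P = NULL,
                 selection_curve = NULL, band = band,
                 channel_labels = labs),
            class = "sass_model")
}

#' @export
print.sass_model <- function(x, ...) {
  cat(sprintf("<sass_model> %d channels, lambda range [%.3g, %.3g]\n",
              nrow(x$W), min(x$lambdas), max(x$lambdas)))
  if (!is.null(x$k_rejected)) {
    cat(sprintf("  k_rejected = %d\n", x$k_rejected))
  }
  invisible(x)
}

pseudo_inverse <- function(W, tol = 1e-12) {
  s <- svd(W)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Build the SASS projection for a given rejection count
#'
#' `P = W^+ S W`, where S is diagonal with zeros at the positions of the k
#' largest eigenvalue ratios and ones elsewhere: the k strongest artifact
#' components are zeroed and the data projected back to sensor space.
#'
#' @param model a `sass_model` from [joint_diagonalize()].
#' @param k number of components to reject (0..n).
#' @return the model with `P` and `k_rejected` set.
#' @export
build_projection <- function(model, k) {
  n <- nrow(model$W)
  if (k < 0 || k > n) stop("k must be in 0..n")
  if (k == n) warning("k = n rejects all components; P is the zero matrix")
  s <- c(rep(0, k), rep(1, n - k))  # lambdas are sorted descending
  model$P <- pseudo_inverse(model$W) %*% (s * model$W)
  dimnames(model$P) <- list(model$channel_labels, model$channel_labels)
  model$k_rejected <- as.integer(k)
  model
}

#' Automatic selection of the number of rejected components
#'
#' For every candidate k the stimulation covariance is cleaned with P(k)
#' and the per-channel signal power in the band (variance of the
#' band-filtered signal, i.e. `diag(P A P')`) is compared with the
#' stimulation-free per-channel power; the selected k minimizes the mean
#' squared difference across channels. Ties break toward smaller k.
#'
#' Accepts either filtered recordings or precomputed `sensor_cov` objects;
#' for centered data the covariance route equals cleaning the time series
#' and measuring per-channel variance.
#'
#' @param model a `sass_model`.
#' @param stim,no_stim band-filtered `eeg_recording`s or `sensor_cov`s.
#' @return the model with `k_rejected`, `P` and `selection_curve` (mean
#'   squared power mismatch for k = 0..n) set.
#' @export
select_component_count <- function(model, stim, no_stim) {
  A <- if (inherits(stim, "eeg_recording")) {
    band_covariance(stim, condition = "stim")$matrix
  } else as_cov_matrix(stim)
  Bp <- if (inherits(no_stim, "eeg_recording")) {
    band_covariance(no_stim, condition = "no_stim")$matrix
  } else as_cov_matrix(no_stim)
  n <- nrow(model$W)
  p_target <- diag(Bp)
  curve <- vapply(0:n, function(k) {
    Pk <- suppressWarnings(build_projection(model, k))$P
    mean((diag(Pk %*% A %*% t(Pk)) - p_target)^2)
  }, numeric(1))
  k_best <- which.min(curve) - 1L  # which.min takes the first tie: min k
  model <- build_projection(model, k_best)
  model$selection_curve <- curve
  model
}

#' Apply a SASS projection to a recording
#'
#' Left-multiplies the data by P, sample-wise; events and metadata are
#' unchanged. P may be applied to narrowband data (for single-trial
#' metrics) or to broadband data (for spectra).
#'
#' @param model a `sass_model` with `P` set, or a plain projection matrix.
#' @param rec an `eeg_recording` whose channels match the model.
#' @return the cleaned recording.
#' @export
apply_projection <- function(model, rec) {
  P <- if (inherits(model, "sass_model")) {
    if (is.null(model$P)) stop("model has no projection; call ",
                               "build_projection() first")
    if (!is.null(model$channel_labels) &&
        !identical(model$channel_labels, rec$channel_labels)) {
      stop("channel labels of model and recording differ")
    }
    model$P
  } else as.matrix(model)
  if (ncol(P) != n_channels(rec)) stop("dimension mismatch")
  out <- replace_data(rec, P %*% rec$data)
  attr(out, "band") <- attr(rec, "band")
  out
}

#' Fit SASS for one frequency band
#'
#' Full fit: bandpass both recordings, estimate covariances, jointly
#' diagonalize, select the rejection count, build P.
#'
#' @param stim,no_stim broadband `eeg_recording`s (bad channels removed).
#' @param band numeric length-2, Hz.
#' @return a `sass_model` with projection and selection curve.
#' @export
sass_fit <- function(stim, no_stim, band = c(9, 11)) {
  sf <- bandpass_recording(stim, band)
  nf <- bandpass_recording(no_stim, band)
  A <- band_covariance(sf, band, "stim")
  B <- band_covariance(nf, band, "no_stim")
  model <- joint_diagonalize(A, B)
  select_component_count(model, A, B)
}

#' Per-harmonic SASS models
#'
#' The artifact topography differs across harmonics of the stimulation
#' frequency, so SASS must be fitted separately per harmonic. Bands are
#' `h * f0 +/- half_width`.
#'
#' @param stim,no_stim broadband `eeg_recording`s.
#' @param f0 fundamental (envelope) frequency, Hz.
#' @param harmonics integer multipliers (default 1:3).
#' @param half_width half bandwidth, Hz.
#' @return named list of `sass_model`s, one per harmonic, each with a
#'   `band` element.
#' @export
harmonic_sass <- function(stim, no_stim, f0 = 10, harmonics = 1:3,
                          half_width = 1) {
  bands <- lapply(harmonics, function(h) c(h * f0 - half_width,
                                           h * f0 + half_width))
  if (any(vapply(bands, function(b) b[2], 1) >= stim$fs / 2)) {
    stop("harmonic band above Nyquist")
  }
  edges <- do.call(rbind, bands)
  o <- order(edges[, 1])
  if (any(edges[o, 1][-1] < edges[o, 2][-length(harmonics)])) {
    stop("harmonic bands overlap")
  }
  out <- lapply(bands, function(b) sass_fit(stim, no_stim, b))
  names(out) <- paste0("h", harmonics)
  out
}

#' Signal-space projection baseline
#'
#' Orthogonal projection away from the top-k variance eigenvectors of the
#' during-stimulation covariance alone. Unlike SASS it ignores where brain
#' activity lives, which can cost signal when brain and artifact
#' topographies overlap.
#'
#' @param A `sensor_cov` or symmetric matrix (stimulation condition).
#' @param k number of components to remove.
#' @return symmetric idempotent projection matrix.
#' @export
ssp_baseline <- function(A, k) {
  Am <- as_cov_matrix(A)
  n <- nrow(Am)
  if (k < 0 || k > n) stop("k must be in 0..n")
  e <- eigen(Am, symmetric = TRUE)
  W <- t(e$vectors)  # orthonormal rows, variance-descending
  s <- c(rep(0, k), rep(1, n - k))
  t(W) %*% (s * W)
}
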