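#' Multichannel EEG recording container
#'
#' The carrier object passed between all stages: a channels x samples matrix
#' in microvolts plus sampling rate, channel labels, optional 3D positions,
#' stimulus events and a bad-channel set. Sample indices are 0-based and
#' intervals half-open throughout the package; phases are radians in
#' (-pi, pi].
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one unique label per row.
#' @param channel_positions optional data.frame/matrix with label, x, y, z.
#' @param events data.frame with columns `sample` (0-based integer index)
#'   and `code`, or NULL.
#' @param bad_channels character vector of excluded labels.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          channel_positions = NULL, events = NULL,
                          bad_channels = character()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric")
  if (anyNA(data) || any(!is.finite(data))) {
    stop("recording data contains NA/Inf")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar")
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("one label per channel required")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  rownames(data) <- channel_labels
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), code = character(0),
                         stringsAsFactors = FALSE)
  }
  if (!all(c("sample", "code") %in% names(events))) {
    stop("events needs columns sample, code")
  }
  if (nrow(events) &&
      (min(events$sample) < 0 || max(events$sample) >= ncol(data))) {
    stop("event sample indices must lie in [0, n_samples)")
  }
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 channel_positions = channel_positions,
                 events = events,
                 bad_channels = as.character(bad_channels)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  events: %d  bad channels: %s\n", nrow(x$events),
              if (length(x$bad_channels)) {
                paste(x$bad_channels, collapse = ", ")
              } else "none"))
  invisible(x)
}

#' Number of samples / channels of a recording
#' @param rec an `eeg_recording`.
#' @return integer count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
n_channels <- function(rec) nrow(rec$data)

#' Drop channels from a recording
#'
#' Removes the given labels from the data matrix (and positions); used to
#' apply the bad-channel mask derived from the stimulation-free condition
#' to both conditions.
#'
#' @param rec an `eeg_recording`.
#' @param labels labels to remove.
#' @return The reduced recording.
#' @export
drop_channels <- function(rec, labels) {
  keep <- !(rec$channel_labels %in% labels)
  if (!any(keep)) stop("cannot drop all channels")
  pos <- rec$channel_positions
  if (!is.null(pos)) pos <- pos[match(rec$channel_labels[keep], pos$label), ]
  eeg_recording(rec$data[keep, , drop = FALSE], rec$fs,
                rec$channel_labels[keep], pos, rec$events,
                setdiff(rec$bad_channels, labels))
}

# replace the data matrix, keeping metadata
replace_data <- function(rec, data) {
  eeg_recording(data, rec$fs, rec$channel_labels, rec$channel_positions,
                rec$events, rec$bad_channels)
}

#' Wrap angles to (-pi, pi]
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Circular mean and resultant length
#'
#' @param x angles in radians.
#' @return list with `mean` (radians, (-pi, pi]) and `r` (mean resultant
#'   length in `[0, 1]`).
#' @export
circ_mean <- function(x) {
  z <- mean(exp(1i * x))
  list(mean = wrap_angle(Arg(z)), r = Mod(z))
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that angles are uniform on the circle, using
#' the large-sample approximation with the standard small-sample correction
#' of the p-value.
#'
#' @param x angles in radians (n >= 2).
#' @return list with `r`, `statistic` (n r^2) and `p_value`.
#' @export
rayleigh_test <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 angles")
  r <- Mod(mean(exp(1i * x)))
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(r = r, statistic = z, p_value = max(min(p, 1), 0))
}

# von Mises sampler (Best & Fisher rejection method); used by tests and
# calibration fixtures
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- wrap_angle(mu + sign(u[3] - 0.5) * acos(f))
      i <- i + 1L
    }
  }
  out
}

# fast linear convolution via FFT, returning the "same"-size centered part
fft_convolve_same <- function(x, kernel) {
  nx <- length(x)
  nk <- length(kernel)
  nfft <- stats::nextn(nx + nk - 1L, c(2, 3, 5))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - nx))) *
                       stats::fft(c(kernel, numeric(nfft - nk))),
                     inverse = TRUE)) / nfft
  start <- (nk - 1L) %/% 2L + 1L
  y[start:(start + nx - 1L)]
}

# full linear convolution of two vectors via FFT
fft_convolve_full <- function(a, b) {
  n <- length(a) + length(b) - 1L
  nfft <- stats::nextn(n, 2)
  Re(stats::fft(stats::fft(c(a, numeric(nfft - length(a)))) *
                  stats::fft(c(b, numeric(nfft - length(b)))),
                inverse = TRUE))[seq_len(n)] / nfft
}

# convolve every row of a matrix with the same (real) kernel. Pairs of
# rows are packed into one complex series (a + ib) so each FFT carries two
# channels; conv(a) + i conv(b) = ifft(fft(a + ib) * K) for real kernels.
fft_convolve_rows <- function(mat, kernel) {
  nx <- ncol(mat)
  nk <- length(kernel)
  nr <- nrow(mat)
  nfft <- stats::nextn(nx + nk - 1L, c(2, 3, 5))
  npair <- (nr + 1L) %/% 2L
  pad <- matrix(0i, nfft, npair)
  for (j in seq_len(npair)) {
    a <- mat[2L * j - 1L, ]
    b <- if (2L * j <= nr) mat[2L * j, ] else numeric(nx)
    pad[seq_len(nx), j] <- complex(real = a, imaginary = b)
  }
  kf <- stats::fft(c(kernel, numeric(nfft - nk)))
  y <- stats::mvfft(stats::mvfft(pad) * kf, inverse = TRUE) / nfft
  start <- (nk - 1L) %/% 2L + 1L
  y <- y[start:(start + nx - 1L), , drop = FALSE]
  out <- matrix(0, nr, nx)
  for (j in seq_len(npair)) {
    out[2L * j - 1L, ] <- Re(y[, j])
    if (2L * j <= nr) out[2L * j, ] <- Im(y[, j])
  }
  rownames(out) <- rownames(mat)
  out
}

# largest prime factor (for FFT cost guards)
largest_prime_factor <- function(n) {
  f <- 1L
  d <- 2L
  while (d * d <= n) {
    while (n %% d == 0L) {
      f <- d
      n <- n %/% d
    }
    d <- d + 1L
  }
  max(f, n)
}
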