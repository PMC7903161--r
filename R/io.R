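pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

num_field <- function(x, width = 8) pad_field(sprintf("%.6g", x), width)

#' Write a recording to an EDF file
#'
#' European Data Format, 16-bit, physical units uV, one-second data
#' records. Recordings whose length is not a whole number of seconds are
#' zero-padded to the next second; the true sample count is stored in the
#' header's reserved field (`NSAMP=`) and honored by [read_edf()].
#' Requires an integer sampling rate.
#'
#' @param rec an `eeg_recording`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs integer fs")
  fs <- as.integer(round(fs))
  x <- rec$data
  nch <- nrow(x)
  n <- ncol(x)
  n_rec <- as.integer(ceiling(n / fs))
  if (n_rec * fs > n) {
    x <- cbind(x, matrix(0, nch, n_rec * fs - n))
  }
  pmin_ <- pmax_ <- numeric(nch)
  dig <- matrix(0L, nch, n_rec * fs)
  for (i in seq_len(nch)) {
    m <- max(abs(x[i, ]), 1e-6)
    pmin_[i] <- -m
    pmax_[i] <- m
    dig[i, ] <- as.integer(round((x[i, ] + m) / (2 * m) * 65535 - 32768))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad_field("0", 8))
  wr(pad_field("X", 80))
  wr(pad_field("X", 80))
  wr(pad_field("01.01.00", 8))
  wr(pad_field("00.00.00", 8))
  wr(pad_field(256 * (nch + 1), 8))
  wr(pad_field(sprintf("NSAMP=%d", n), 44))
  wr(pad_field(n_rec, 8))
  wr(pad_field("1", 8))
  wr(pad_field(nch, 4))
  for (f in list(function(i) pad_field(rec$channel_labels[i], 16),
                 function(i) pad_field("", 80),
                 function(i) pad_field("uV", 8),
                 function(i) num_field(pmin_[i]),
                 function(i) num_field(pmax_[i]),
                 function(i) pad_field("-32768", 8),
                 function(i) pad_field("32767", 8),
                 function(i) pad_field("", 80),
                 function(i) pad_field(fs, 8),
                 function(i) pad_field("", 32))) {
    for (i in seq_len(nch)) wr(f(i))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports the subset written by [write_edf()] plus standard EDF with
#' equal sampling rate across signals and physical unit uV (or unitless).
#'
#' @param path EDF file.
#' @param events optional events data.frame attached to the recording.
#' @return an `eeg_recording` (positions filled from the standard montage
#'   where labels match).
#' @export
read_edf <- function(path, events = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  rd(8)
  rd(80)
  rd(80)
  rd(8)
  rd(8)
  rd(8)
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  units <- vapply(seq_len(nch), function(i) rd(8), "")
  if (!all(units %in% c("uV", "µV", ""))) {
    stop("unsupported physical unit(s): ",
         paste(setdiff(units, c("uV", "")), collapse = ", "))
  }
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)
  nr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(nr)) != 1L) stop("per-signal sampling rates differ")
  fs <- nr[1] / rec_dur
  total <- n_rec * nr[1]
  x <- matrix(0, nch, total)
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = nch * nr[1], size = 2L,
                     endian = "little")
    blk <- matrix(block, nrow = nr[1])
    x[, ((r - 1L) * nr[1] + 1L):(r * nr[1])] <- t(blk)
  }
  for (i in seq_len(nch)) {
    x[i, ] <- pmin_[i] + (x[i, ] - dmin[i]) / (dmax[i] - dmin[i]) *
      (pmax_[i] - pmin_[i])
  }
  if (grepl("^NSAMP=", reserved)) {
    n <- as.integer(sub("^NSAMP=", "", reserved))
    x <- x[, seq_len(n), drop = FALSE]
  }
  m <- standard_montage()
  pos <- if (all(labels %in% m$label)) {
    m[match(labels, m$label), ]
  } else NULL
  eeg_recording(x, fs, labels, pos, events)
}

#' Read / write a 2-column event file
#'
#' Tab-separated, columns `sample` (0-based index) and `code`.
#'
#' @param path file path.
#' @param n_samples if given, indices are validated against
#'   `[0, n_samples)` and offenders reported.
#' @return data.frame with `sample`, `code`.
#' @export
read_events <- function(path, n_samples = NULL) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "code") %in% names(ev))) {
    stop("event file needs columns sample, code")
  }
  ev$sample <- as.integer(ev$sample)
  if (!is.null(n_samples)) {
    bad <- ev$sample < 0 | ev$sample >= n_samples
    if (any(bad)) {
      stop("event sample(s) outside [0, n_samples): ",
           paste(ev$sample[bad], collapse = ", "))
    }
  }
  ev
}

#' @rdname read_events
#' @param events data.frame with `sample`, `code`.
#' @export
write_events <- function(events, path) {
  utils::write.table(events[, c("sample", "code")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording plus its event file
#'
#' @param path EDF file.
#' @param events_path tab-separated event file (optional).
#' @return an `eeg_recording` with events attached.
#' @export
read_recording <- function(path, events_path = NULL) {
  rec <- read_edf(path)
  if (!is.null(events_path)) {
    rec$events <- read_events(events_path, n_samples(rec))
  }
  rec
}

#' @rdname read_recording
#' @param rec an `eeg_recording`.
#' @param events_path where to write the events (default: path with
#'   `.events.tsv` appended).
#' @export
write_recording <- function(rec, path, events_path = NULL) {
  write_edf(rec, path)
  if (is.null(events_path)) events_path <- paste0(path, ".events.tsv")
  write_events(rec$events, events_path)
  invisible(path)
}

#' Persist / load a SASS model (JSON)
#'
#' Stores W, eigenvalue ratios, rejection count, projection, band, labels
#' and the selection curve in a hierarchical JSON container.
#'
#' @param model a `sass_model`.
#' @param path file path.
#' @return the path / the model.
#' @export
write_sass_model <- function(model, path) {
  obj <- list(W = model$W, lambdas = model$lambdas,
              k_rejected = model$k_rejected, P = model$P,
              selection_curve = model$selection_curve,
              band = model$band, channel_labels = model$channel_labels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_sass_model
#' @export
read_sass_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W = as.matrix(obj$W), lambdas = as.numeric(obj$lambdas),
                 k_rejected = if (is.null(obj$k_rejected)) NULL else
                   as.integer(obj$k_rejected),
                 P = if (is.null(obj$P)) NULL else as.matrix(obj$P),
                 selection_curve = obj$selection_curve,
                 band = obj$band,
                 channel_labels = obj$channel_labels),
            class = "sass_model")
}

#' Export a trial table
#'
#' Tidy tab-separated file with columns trial, condition, amplitude_uV,
#' phase_diff_rad, flagged.
#'
#' @param tables one `trial_table` or a list of them.
#' @param path output file.
#' @export
write_trial_tables <- function(tables, path) {
  if (inherits(tables, "trial_table")) tables <- list(tables)
  rows <- lapply(tables, function(tt) {
    data.frame(trial = tt$trial,
               condition = attr(tt, "condition"),
               amplitude_uV = tt$amplitude,
               phase_diff_rad = tt$phase_diff,
               flagged = tt$flagged)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_tables
#' @export
read_trial_tables <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(split(df, df$condition), function(d) {
    tab <- data.frame(trial = d$trial, amplitude = d$amplitude_uV,
                      phase_diff = d$phase_diff_rad, flagged = d$flagged)
    attr(tab, "condition") <- d$condition[1]
    class(tab) <- c("trial_table", "data.frame")
    tab
  })
}
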