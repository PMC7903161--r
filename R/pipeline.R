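#' Pipeline configuration
#'
#' Bundles the parameters of a full fit -> apply -> evaluate -> stats run.
#' Defaults follow the standard validation setup: 9-11 Hz target band,
#' 2048-point Welch spectra, 1000 permutations, alpha 0.05.
#'
#' @param band target band, Hz.
#' @param harmonics harmonic multipliers for per-harmonic models (NULL =
#'   fundamental only).
#' @param occipital_labels virtual-channel electrode set.
#' @param flicker_freq flicker frequency, Hz.
#' @param trial_duration trial length, s.
#' @param nfft Welch FFT length.
#' @param n_perm permutation count for permutation tests.
#' @param alpha significance level.
#' @param seed RNG seed for permutation stages.
#' @param paths named list of file paths (stim, nostim, stim_events,
#'   nostim_events, out_dir, ...), all optional for in-memory runs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(band = c(9, 11), harmonics = NULL,
                            occipital_labels = OCCIPITAL_LABELS,
                            flicker_freq = 10, trial_duration = 2.0,
                            nfft = 2048, n_perm = 1000, alpha = 0.05,
                            seed = 0L, paths = list()) {
  structure(list(band = band, harmonics = harmonics,
                 occipital_labels = occipital_labels,
                 flicker_freq = flicker_freq,
                 trial_duration = trial_duration, nfft = nfft,
                 n_perm = n_perm, alpha = alpha, seed = as.integer(seed),
                 paths = paths),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj[!vapply(obj, is.null, TRUE)])
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> band %g-%g Hz, nfft %d, n_perm %d\n",
              x$band[1], x$band[2], x$nfft, x$n_perm))
  invisible(x)
}

#' Run the full artifact-rejection pipeline
#'
#' Executes the canonical stage order on a stimulation / no-stimulation
#' recording pair: channel quality control on the stimulation-free
#' condition (mask applied to both) -> bandpass both to the target band ->
#' narrowband covariances -> joint diagonalization -> automatic rejection
#' count -> projection applied to the filtered data for single-trial
#' metrics and to the broadband data for spectra -> Hilbert single-trial
#' amplitude/phase per condition -> condition statistics (three amplitude
#' t-tests, three Wallraff phase tests, PLV per condition). Every stage
#' appends a structured log record.
#'
#' @param config a [pipeline_config()].
#' @param stim,no_stim `eeg_recording`s; if NULL they are read from
#'   `config$paths`.
#' @param force_k optional fixed rejection count overriding automatic
#'   selection.
#' @return list with `model`, `metrics` (trial tables per condition),
#'   `plv`, `stats`, `spectra`, `excluded_channels`, `log`.
#' @export
run_pipeline <- function(config, stim = NULL, no_stim = NULL,
                         force_k = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  logs <- list()
  note <- function(stage, ...) {
    logs[[length(logs) + 1L]] <<- c(list(stage = stage,
                                         time = format(Sys.time())),
                                    list(...))
  }
  if (is.null(stim)) {
    stim <- read_recording(config$paths$stim, config$paths$stim_events)
  }
  if (is.null(no_stim)) {
    no_stim <- read_recording(config$paths$nostim,
                              config$paths$nostim_events)
  }
  note("load", n_stim = n_samples(stim), n_nostim = n_samples(no_stim))

  bad <- exclude_bad_channels(no_stim)
  if (length(bad)) {
    stim <- drop_channels(stim, bad)
    no_stim <- drop_channels(no_stim, bad)
  }
  note("qc", excluded = bad)

  set.seed(config$seed)
  model <- sass_fit(stim, no_stim, config$band)
  if (!is.null(force_k)) model <- build_projection(model, force_k)
  note("fit", k = model$k_rejected,
       selection_curve = model$selection_curve)

  occ <- config$occipital_labels
  f <- config$flicker_freq
  dur <- config$trial_duration
  metrics <- list(
    no_stim = evaluate_condition(no_stim, config$band, NULL, "no_stim",
                                 f, dur, occ),
    stim_raw = evaluate_condition(stim, config$band, NULL, "stim_raw",
                                  f, dur, occ),
    stim_sass = evaluate_condition(stim, config$band, model, "stim_sass",
                                   f, dur, occ))
  note("metrics", trials = vapply(metrics, nrow, 1L))

  plv <- lapply(metrics, function(tt) {
    phase_locking_value(tt$phase_diff[!tt$flagged])
  })
  amp <- lapply(metrics, function(tt) tt$amplitude)
  ph <- lapply(metrics, function(tt) tt$phase_diff[!tt$flagged])
  stats_out <- list(
    amplitude = list(
      nostim_vs_raw = t_compare(metrics$stim_raw$amplitude,
                                metrics$no_stim$amplitude,
                                "independent", "greater"),
      raw_vs_sass = t_compare(metrics$stim_sass$amplitude,
                              metrics$stim_raw$amplitude,
                              "dependent", "less"),
      nostim_vs_sass = t_compare(metrics$no_stim$amplitude,
                                 metrics$stim_sass$amplitude,
                                 "independent", "two")),
    phase = list(
      nostim_vs_raw = wallraff_test(ph$no_stim, ph$stim_raw,
                                    "independent"),
      raw_vs_sass = wallraff_test(ph$stim_raw, ph$stim_sass,
                                  "dependent"),
      nostim_vs_sass = wallraff_test(ph$no_stim, ph$stim_sass,
                                     "independent")))
  note("stats", p_amp = vapply(stats_out$amplitude, `[[`, 1, "p_value"),
       p_phase = vapply(stats_out$phase, `[[`, 1, "p_value"))

  stim_clean_broad <- apply_projection(model, stim)
  spectra <- list(no_stim = welch_psd(no_stim, config$nfft),
                  stim_raw = welch_psd(stim, config$nfft),
                  stim_sass = welch_psd(stim_clean_broad, config$nfft))
  note("spectra", nfft = config$nfft)

  out <- list(model = model, metrics = metrics, plv = plv,
              stats = stats_out, spectra = spectra,
              excluded_channels = bad, log = logs)
  if (!is.null(config$paths$out_dir)) {
    dir <- config$paths$out_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_trial_tables(metrics, file.path(dir, "metrics.tsv"))
    write_sass_model(model, file.path(dir, "model.json"))
    export <- list(
      plv = lapply(plv, unclass),
      amplitude = lapply(stats_out$amplitude, unclass),
      phase = lapply(stats_out$phase, unclass),
      excluded_channels = bad, k_rejected = model$k_rejected)
    jsonlite::write_json(export, file.path(dir, "stats.json"),
                         digits = NA, auto_unbox = TRUE)
    writeLines(vapply(logs, function(l) {
      jsonlite::toJSON(l, auto_unbox = TRUE, digits = NA)
    }, ""), file.path(dir, "log.jsonl"))
  }
  out
}
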