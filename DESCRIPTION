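Package: sasseeg
Title: Stimulation Artifact Source Separation for EEG During
    Amplitude-Modulated tACS
Version: 0.1.0
Authors@R:
    person("SASS", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatial filtering of electroencephalographic (EEG) recordings
    contaminated by amplitude-modulated transcranial alternating current
    stimulation (AM-tACS) artifacts.  The core method rejects sensor-space
    components obtained from a joint diagonalization (generalized eigenvalue
    decomposition) of narrowband covariance matrices estimated during and in
    absence of stimulation, with automatic selection of the number of
    rejected components.  Includes a synthetic concurrent EEG/AM-tACS
    session generator with known ground truth, FIR preprocessing, Hilbert
    based single-trial steady-state visual evoked potential (SSVEP)
    amplitude and phase metrics, phase-locking statistics, Welch and
    multitaper spectra, a heartbeat artifact-modulation permutation test,
    Wallraff circular tests, threshold-free cluster enhancement (TFCE)
    permutation maps, and power analysis utilities, together with EDF
    input/output and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
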