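---
title: "Separating AM-tACS artifacts from EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating AM-tACS artifacts from EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Transcranial alternating current stimulation injects currents orders of
magnitude larger than electric brain activity, so EEG recorded during
stimulation is dominated by the stimulation artifact exactly at the
frequency one wants to study. Amplitude-modulated tACS (AM-tACS) moves the
injected energy to a high-frequency carrier (here 220 Hz) whose amplitude
is modulated at the physiological target frequency (10 Hz); in a perfectly
linear recording chain no energy would appear at 10 Hz at all. In
practice, nonlinearities in the electrode-skin interface and the
acquisition chain partially demodulate the envelope, leaving an artifact
at the target frequency and its harmonics that can be orders of magnitude
larger than the brain signal of interest.

`sasseeg` implements stimulation artifact source separation (SASS): a
spatial filter that removes the sensor-space components carrying the
artifact while leaving brain activity essentially untouched, together
with the machinery needed to validate it end to end — a synthetic
session generator with known ground truth, FIR preprocessing, Hilbert
single-trial metrics, spectral estimators, and the inferential statistics
used to test for residual artifacts.

## The SASS model

Let $A$ and $B$ be the sensor covariance matrices of the narrowband
(9–11 Hz) EEG during and in absence of stimulation, estimated from the
full-length, unsegmented recordings. SASS solves the generalized
eigenvalue problem

$$ A w_i = \lambda_i B w_i, \qquad
   \lambda_i = \frac{w_i^\top A w_i}{w_i^\top B w_i}, $$

so each $\lambda_i$ is the power of component $i$ during stimulation
relative to without it. Artifact components have enormous $\lambda$;
brain components have $\lambda \approx 1$. With the filters stacked as
rows of $W$ (normalized so $w_i^\top B w_i = 1$; the projection is
invariant to this choice, which is property-tested), the cleaning
operator zeroes the $k$ largest-ratio components and maps back to sensor
space:

$$ P = W^{+} S W, \qquad S = \mathrm{diag}(\underbrace{0,\dots,0}_{k},
   1,\dots,1). $$

$P$ is idempotent and leaves the time course of every retained component
exactly invariant. It can be applied to narrowband data (for single-trial
phase/amplitude work) or broadband data (for spectra). Unlike
signal-space projection (SSP), which eigendecomposes $A$ alone and is
blind to where brain activity lives, the $B$-whitening makes the removal
oblique in just the way that protects brain sources whose topography
overlaps the artifact's; the package ships `ssp_baseline()` for the
comparison, and a test constructs an overlap fixture on which SASS
retains at least 20% more SSVEP amplitude at equal $k$.

### Choosing the number of rejected components

For every candidate $k$, the stimulation covariance is cleaned with
$P(k)$ and the per-channel band power $\mathrm{diag}(P A P^\top)$ is
compared to the stimulation-free band power $\mathrm{diag}(B)$; the
selected $k$ minimizes the mean squared difference across channels (ties
break toward smaller $k$, i.e. rejecting less). For centered data this
covariance shortcut is *exactly* the power of the cleaned time series,
which a test asserts. A component is worth rejecting under this criterion
as soon as $\lambda > 2$ (removing it changes its contribution to the
mismatch from $(\lambda - 1)^2$ to $1$ per unit of baseline power), which
has a practical consequence: with short recordings or many channels, the
sampling spread of the eigenvalue ratio of two finite-sample covariances
approaches 2 from below, and the selection begins to reject
sampling-noise components. At the default 64 channels and ~550 s of
narrowband data the top null ratio is ≈ 1.6 and selection is stable; the
component-count acceptance fixtures use 16 channels, where the null
ratio is comfortably below 2, so that the true source count (1 or 3) is
identifiable at all.

### What "one artifact source" means here

The demodulated AM artifact is deterministic: all of its 10 Hz energy
shares a single temporal waveform, so however many transduction orders
contribute, the in-band artifact is a rank-one addition to $A$ and the
correct rejection count is $k = 1$. Extra independent in-band sources
(`extra_artifact_sources`) model fluctuating intermodulation products
with their own topographies and random narrowband time courses; each adds
one rank.

## The synthetic world

`generate_session()` draws a stimulation-free and a during-stimulation
recording from one generative law:

* **SSVEP**: a 10 Hz sinusoid gated to 2 s flicker trials (integer cycles
  per trial), 200 trials separated by uniform 0.5–1 s intervals, with a
  fixed phase lag to the flicker ($-\pi/4$), per-trial log-normal
  amplitude jitter (sdlog 0.25, matching the ~20–45% coefficient of
  variation of published per-participant single-trial SDs) and small
  phase jitter (0.1 rad). The topography is a smooth occipital bump
  peaking at Oz, scaled so the peak channel carries `ssvep_amp` (3 uV).
  Because the inter-trial interval is not a multiple of the 10 Hz
  period, onsets distribute uniformly over the phase of the continuous
  stimulation envelope (verified by a Rayleigh test across seeds), which
  is what destroys flicker phase locking in the raw stimulation data.
* **Background noise**: spatially mixed $1/f$ noise, 5 uV broadband RMS
  per channel (a clean laboratory EEG floor; flattened below 0.5 Hz).
  The spatial mixing matrix and per-channel RMS profile are drawn *once
  per session pair*: the two recordings come from the same head minutes
  apart, and their background covariance must be stationary. (Drawing
  them independently creates directions with large stim/no-stim power
  ratios that no real session pair has, and the selection step then
  rejects those phantom components.)
* **Artifact**: the AM waveform $m(t) = \tfrac{1+\cos 2\pi f_{env} t}{2}
  \sin 2\pi f_c t$ is generated at 8x oversampling with raised-cosine
  on/off ramps (stimulators ramp; this also keeps onset splatter out of
  the band), passed through a per-order polynomial nonlinearity, lowpass
  filtered at 125 Hz (the recording chain's anti-alias filter) and
  decimated. Odd powers only carry carrier-band energy and vanish; even
  powers demodulate the envelope into 10/20/30/40 Hz components. Each
  order has its own dipolar topography (current enters at CPz and exits
  at the inion) with a per-order perturbation, so harmonic topographies
  differ — the default coefficients `c(1, 0.02, 0, 0.015)` give
  monotonically decaying 10/20/30 Hz peaks with measurably distinct
  topographies (|cos| < 0.99). The artifact is scaled so that its RMS at
  the target frequency on the worst channel is `artifact_gain` (1e3)
  times the SSVEP RMS there.
* **Heartbeat**: optional multiplicative gain with raised-cosine bumps at
  R-peaks; the default height of 0 encodes the empirical null (AM-tACS
  artifacts show no heartbeat modulation), while a nonzero height
  validates the detector.

What the generator does *not* emulate: volume-conduction lead fields,
eye/muscle artifacts, line noise, electrode drift, or nonstationary
alpha. A green recovery test therefore establishes that the algorithm
recovers what the model puts in — not that every real-world nuisance is
handled.

## Preprocessing choices

* **FIR design**: Hamming window method, band 9–11 Hz, transition 2 Hz,
  odd length by the standard $3.3/\Delta f$ rule (825 taps at 500 Hz).
* **Zero-phase application**: one *centered* pass of the symmetric
  kernel. Single-trial phase is the endpoint, so zero phase is
  non-negotiable; we chose the single pass over forward-backward because
  squaring the magnitude response narrows the effective passband and
  costs ~9% (vs ~7%) of a 2 s burst's measured amplitude — the burst's
  spectral main lobe is about 1 Hz wide against a 2 Hz passband, so some
  edge loss is structural either way. The deeper stopband of a double
  pass is unnecessary once the dominant artifact line is removed
  spatially (`two_pass = TRUE` remains available).
* **Covariance edges**: one kernel length is trimmed from each end
  before covariance estimation; filter edge transients carry their own
  topographies and would otherwise masquerade as artifact components.
* **Bad channels**: flagged on the stimulation-free condition (power
  more than 100x the median, or >= 10 consecutive samples at the
  recording's own extremes) and removed from both conditions.
* **Conventions**: 0-based sample indices, half-open trial windows,
  phases in $(-\pi, \pi]$ radians, covariance with $1/(N-1)$.

## Single-trial metrics

The (cleaned) narrowband virtual occipital channel — the unweighted mean
of O1, Oz, O2, PO3, PO4, PO7, PO8, POz — is Hilbert transformed
*unsegmented*, then cut into trials. Per trial, the amplitude is the
arithmetic mean of the envelope and the phase is the *circular* mean of
the per-sample difference to the flicker reference (zero phase at
onset); the arithmetic mean of wrapped angles is discontinuous at
$\pm\pi$ and is not used. Trials with a near-zero within-trial resultant
are flagged and excluded from phase-locking values,
$\mathrm{PLV} = |\,\mathrm{mean}(e^{i\varphi_n})\,|$. Because projection,
occipital averaging and filtering are all linear, the implementation
collapses them into a single weighted channel before filtering, which is
exact and much faster than filtering all channels.

## Spectral estimators and the heartbeat test

Welch periodograms use 2048-point segments, Hann taper, 50% overlap.
High-resolution spectra use Thomson multitapers on 120 s segments with
half-bandwidth 0.05 Hz (NW = 6, 11 tapers); the DPSS tapers are computed
from the classic tridiagonal formulation with exact Sturm-bisection
eigenvalues and deflated inverse iteration (O(n) kernels in C), which
stays fast and exact at 60 000-sample segments and is verified against an
independent implementation where available.

The heartbeat-modulation test filters 5–15 Hz, takes the Hilbert
envelope, cuts 4 s segments centered on R-peaks, removes each segment's
temporal mean, and compares the across-segment mean trace per timepoint
with traces from 1000 random placements, two-sided, Bonferroni-corrected
across timepoints. One design decision deserves emphasis: with a
strictly per-timepoint permutation comparison the smallest attainable
p-value is $1/(n_{perm}+1)$, and multiplying by ~2000 timepoints means
*no* modulation could ever reach corrected significance — the procedure
would be a null machine. Under the random-placement null the mean trace
is stationary, so its values are exchangeable across timepoints; the
default therefore pools all null values into one distribution, which
keeps the Bonferroni correction honest while making detection attainable
(`pool_null = FALSE` gives the literal per-timepoint variant, whose
p-value floor is asserted in the tests).

## Statistics

Amplitude comparisons use Student t-tests with the direction and pairing
of the validation design (raw-stim amplitudes larger than no-stim,
one-sided, independent; SASS smaller than raw, one-sided, dependent;
no-stim vs SASS two-sided — a residual artifact would show there). Phase
comparisons use Wallraff tests: angular distances to each group's own
circular center (mean by default; median behind a flag), compared by
Wilcoxon signed-rank (paired) or Mann-Whitney U (unpaired). In the
dependent case the cited procedure names a "rank-sum" test, which has no
paired form; the signed-rank test on paired distance differences is the
standard reading and is what is implemented.

Sensor-space maps use threshold-free cluster enhancement (E = 0.5,
H = 2, step 0.1 of the observed maximum) with max-statistic permutation
(1024 label shuffles or sign flips) for family-wise error control. The
power analysis solves for the minimal detectable Cohen's d by bisection
on the noncentral-t power function (the normal approximation is included
as a cross-check; for n = 200 per group at $\alpha = 0.05$ and power 0.8
they give 0.2808 and 0.2802). Group "mean ± sd" summaries use the
population SD (divide by N), the convention that reproduces the published
group numbers from the per-participant tables.

## Numerical choices and degenerate inputs

* $B$ receives a ridge of $10^{-9}\,\mathrm{tr}(B)/n$ only when its
  condition number exceeds $10^{10}$; beyond that the fit aborts with
  guidance rather than returning garbage.
* Pseudoinverse tolerance: singular values below $10^{-12}$ of the
  maximum are treated as zero.
* Equal-$\lambda$ ties: the projection depends only on the invariant
  subspace; a constructed-tie test asserts this.
* `k = n` rejects everything and warns; `k = 0` is the exact identity.
* Analytic signals mirror-pad to a 5-smooth FFT length (the mixed-radix
  FFT is slow for lengths with large prime factors, quadratically so for
  primes); the approximation touches only the edges.
* Per-sensor trial envelopes (used by the sensor-map tests) are computed
  on 8x decimated filtered data: the band envelope is band-limited far
  below the decimated Nyquist, so 2 s trial means are essentially
  unchanged while the per-channel transforms shrink 8-fold.
* The EDF writer pads to whole-second records and records the true
  sample count in the reserved header field; round-trips are exact to
  one 16-bit quantization step.

## Known limitations

* SASS is refit per session pair by design; models must not be
  transferred across sessions (the CLI's `fit` demands both recordings).
* The amplitude endpoint has a structural ~7% downward bias from band
  filtering a 2 s burst; it affects all conditions identically and
  cancels in condition comparisons, but is visible against synthetic
  ground truth.
* If entrained brain activity itself changed its covariance between the
  two sessions, SASS could attenuate it; nothing in the synthetic world
  models that possibility.
* The montage ships with approximate spherical 10-10 coordinates,
  adequate for adjacency and occipital selection, not for source
  modeling.
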