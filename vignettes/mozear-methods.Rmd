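---
title: "Models and methods behind mozear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mozear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mozear)
```

`mozear` covers two pipelines that meet in the biology of mosquito hearing:
a signal-analysis stack for laser-Doppler-vibrometry (LDV) recordings of the
antennal flagellum, and a simulation-based noise-floor procedure for calling
expressed transcripts in Johnston's-organ RNA-seq. This vignette explains
the models, the tunable parameters and their defaults, the numerical
choices, what the synthetic-data generators do and do not emulate, and the
known limitations. It states no empirical result beyond what the package's
tests and `scripts/acceptance.R` themselves compute.

## The mechanical-state model

A 1-s unstimulated displacement record is summarised by its amplitude
distribution. A flagellum at rest moves like filtered noise, so its
displacement histogram is Gaussian; a self-sustained oscillator (SSO) is
nearly sinusoidal, and a sinusoid sampled uniformly in time has the arcsine
density, which piles up at the turning points. The package models every run
as the two-component mixture

$$D(\alpha, x) = \alpha\,\frac{1}{\pi\sqrt{(x - A_{min})(A_{max} - x)}}
  + (1-\alpha)\,\frac{1}{\sqrt{2\pi}\sigma}e^{-(x-\mu)^2/2\sigma^2},$$

with the weight $\alpha$ the quantity of interest: 0 is purely quiescent, 1
purely oscillating, and intermediate values describe transient states. The
classification cut-offs are closed intervals, $\alpha \in [0, 0.1]$ for
QUIES and $\alpha \in [0.9, 1]$ for SSO, with everything between labelled
TRANSIENT. A fit must additionally account for 99.7% of the data or the run
is UNCLASSIFIED; and a run-level SSO label is only confirmed when it belongs
to a streak of at least three consecutive SSO runs (six seconds of the
alternating run structure), otherwise it is demoted to TRANSIENT. The
persistence rule can only remove SSO labels, never create them.

### Numerical choices in the fit

* **Criterion for "accounts for 99.7% of the data".** No specific statistic
  is canonical here; the package uses the coefficient of determination
  between the empirical CDF and the model CDF evaluated at the sample points
  (threshold `gof_threshold = 0.997`, configurable). A CDF criterion avoids
  the arbitrariness of histogram binning.
* **Likelihood with a singular density.** The arcsine density diverges at
  its support endpoints, so the raw likelihood is unbounded as
  $A_{min}, A_{max}$ approach data points. Samples are clamped strictly
  inside the support by half an amplitude-resolution step
  ($\tfrac{1}{2}\,\mathrm{range}/n$) when the arcsine term is evaluated,
  which bounds the likelihood while leaving the density essentially
  unchanged away from the endpoints.
* **Optimisation.** The likelihood has two well-separated local optima — a
  narrow-$\sigma$ regime where the normal term captures sensor noise, and a
  broad-$\sigma$ regime where it captures the oscillation body. The fitter
  therefore runs a cheap EM on $(\alpha, \mu, \sigma)$ with the support held
  at the robust extremes (0.1/99.9 percentiles widened by 1%) from both
  regimes, refines each candidate with bounded quasi-Newton (falling back to
  Nelder–Mead where the clamping kinks defeat the line search) and keeps the
  better final likelihood. The likelihood is evaluated on a deterministic
  thinning of at most 2500 samples for speed; the goodness of fit always
  uses the full record.
* **Raw samples, maximum likelihood.** The fit uses the raw displacement
  values of the section (not peak amplitudes, not a histogram), by maximum
  likelihood. This is one defensible reading of fitting "the amplitude
  distribution"; it is recorded here because least squares on a histogram
  would be an equally defensible alternative with slightly different
  behaviour.

### What classification accuracy does and does not mean

The generators place SSO components about two orders of magnitude above the
noise floor (a 400 nm oscillation over ~1 nm LDV displacement noise),
mirroring the roughly 1000-fold separation between oscillating and quiescent
receivers. In that regime the mixture fit recovers $\alpha$ near its true
value and the 0.997 goodness gate passes. As the signal-to-noise ratio drops
below a few tens, the measured amplitude distribution is the *convolution*
of arcsine and normal rather than their mixture: the fitted $\alpha$ drifts
downward and the goodness gate begins to refuse runs. That behaviour is a
property of the model itself, not of this implementation; passing tests on
synthetic data say nothing about recordings whose noise is non-Gaussian or
whose oscillation is strongly amplitude-modulated.

## Free-fluctuation spectra

Frequency and amplitude of SSO runs come from the FFT of the mean-detrended
1-s record: peak bin within a 100–1000 Hz search band, amplitude under the
sinusoid convention $2|X(f)|/N$ so that a pure sinusoid of amplitude $A$
reports $A$, resolution $1/\mathrm{duration}$ (1 Hz). No window taper is
applied by default — for near-stationary sinusoids over 1 s, the rectangular
window favours amplitude accuracy and resolution; a Hann option exists and
is recorded in the output.

Quiescent receivers produce no periodic signal and are refused a frequency.
The refusal rule compares the spectral peak to the median magnitude in its
neighbourhood (±150 Hz) after light smoothing (5-bin moving average), with
threshold `min_peak_ratio = 3`. The smoothing and locality matter: raw
magnitude bins of any noise process are Rayleigh-distributed, and the
max/median ratio of a few hundred Rayleigh draws concentrates near 3
regardless of the noise level, so an unsmoothed or whole-band ratio cannot
separate a sinusoid from band-limited noise reliably; the smoothed local
ratio sits near 1.7 for noise and orders of magnitude higher for a genuine
oscillation.

## Chirp responses and the driven damped oscillator

The stimulated half of each run is a linear frequency sweep (0→1 kHz over
1 s, followed by its mirrored version to expose hysteresis). The response
envelope is extracted by SNIP on the rectified signal: over `n_iterations =
24` passes with a clipping half-window decreasing linearly from
`window_samples` (default $f_s / (2 \times 50\,\mathrm{Hz})$, i.e. sized to
the narrowest resonance the envelope must preserve) down to 1, each point is
raised to the mean of its two neighbours at the current distance whenever it
lies below it. This fills the valleys between oscillation peaks and yields
the upper envelope, which is then mapped to frequency via the chirp's linear
time–frequency law (frequencies below 10 Hz are discarded as the sweep's
ill-defined near-DC region) and bin-averaged onto a 400-point grid.

The envelope is fitted by nonlinear least squares (Levenberg–Marquardt) with
the driven damped harmonic oscillator magnitude

$$X(\omega) = \frac{F_0/m}{\sqrt{(\omega_0^2-\omega^2)^2 +
  (2\zeta\omega_0\omega)^2}},$$

with force and effective mass absorbed into a single acceleration parameter.
Starting values come from the envelope argmax ($f_0$), the half-power width
($\zeta$) and the peak amplitude (accel); bounds are $\zeta \in (10^{-4},
0.9)$ and $f_0 \in (10, 1000)$ Hz. Two numerical details:

* **Additive background.** Rectification plus peak clipping lifts the
  envelope of a noisy record by a roughly constant floor (the expected
  magnitude of the noise), which, if ignored, biases $\zeta$ upward and
  shifts $f_0$. The fit therefore co-estimates a non-negative constant
  background by default (`background = TRUE`); it is reported and can be
  disabled.
* **Failure is explicit.** Non-convergence returns `converged = FALSE` with
  the optimiser's message; a peak on the grid boundary is flagged
  `band_limited`. Downstream functions refuse unconverged fits.

Derived quantities: $Q = 1/(2\zeta)$, and the peak frequency in **two
conventions**, because the commonly printed expression
$f_{opt} = f_0/\sqrt{1-2\zeta^2}$ (peak above the natural frequency) and the
analytic maximiser of $X(\omega)$ itself, $f_0\sqrt{1-2\zeta^2}$ (peak below
it), disagree for any $\zeta > 0$ while coinciding in the $\zeta \to 0$
limit. The package implements both, defaults to the printed form
(`"as_printed"`) for comparability with published tables, records the
convention in every output, and asserts neither as "correct". Up and down
sweeps are fitted separately and compared via `hysteresis()`; pooling them
would average away exactly the asymmetry the mirrored design probes.

## Force steps and stiffness

Steady-state stiffness is $K = F / x_{ss}$ with $x_{ss}$ the
baseline-corrected mean displacement over the final fraction
(`window_fraction = 0.1`) of the step interval. Settling is verified two
ways: the linear drift fitted across the window must stay below 1% of
$|x_{ss}|$, and the residual spread below 10% — the second criterion exists
because undecayed ringing is oscillatory and averages out of a slope check.
Unsettled responses are flagged and excluded from group statistics by
default. Drive calibration to a target displacement (±8000 nm) interpolates
trial drives linearly and refuses extrapolation beyond 20% outside the trial
range or non-monotone trials. The apparent-mass estimate $m = K/\omega_0^2$
is the plain simple-oscillator relation, labelled as such in outputs; an
externally derived mass can be supplied instead.

## The statistics layer

LDV measures are screened with Shapiro–Wilk and are typically non-normal, so
summaries are median ± MAD with the **unscaled** MAD (no 1.4826 factor),
matching the "351 ± 7 Hz" reporting style. Pairwise comparisons use the
two-sided Wilcoxon rank-sum test: for groups of at most 8 the permutation
p value is computed by complete enumeration of rank assignments (midranks
make the exact branch valid under ties); larger groups use the normal
approximation with tie-corrected variance and continuity correction. Holm
correction is applied within each comparison family, one family per measure,
matching per-panel starring. Categorical tables (mechanical states,
fibrillae erection) use Pearson's chi-squared without continuity correction;
expected counts below 5 set a flag but do not suppress the test.

The sampling unit is the run, as in published figure tables; because runs
within an animal are not independent, this pseudo-replicates, and an
animal-level option (`unit = "animal"`, median per animal first) is provided
for sensitivity analyses. The methods-vs-legends ambiguity between a paired
signed-rank and an unpaired rank-sum test is resolved in favour of the
unpaired rank-sum as the default, with `paired = TRUE` available; the
package does not assert which variant any published analysis used.

## The expression noise floor

Quantifiers assign some reads to transcripts that produced none —
misassignment between homologous sequences is the dominant mechanism. The
noise-floor procedure measures this directly: per round, 50 randomly chosen
transcripts are removed, reads are simulated from the remainder at the
experiment's coverage, quantified against the **full** transcriptome, and
the mean count landing on the held-out transcripts recorded; ten rounds give
ten round means whose normality is screened (Shapiro–Wilk; a warning below
p = 0.05, never an error) and whose mean defines the rate $\lambda$ of a
Poisson noise law. A transcript is called expressed when the upper-tail
probability of its mean count across samples under Poisson($\lambda$),
Benjamini–Hochberg adjusted across all transcripts, is at most 0.05.

Numerical and design choices:

* **Non-integer means.** Mean counts across samples are rarely integers; the
  tail is evaluated through the regularized incomplete gamma function
  ($P(X \ge \bar c) = P(\bar c, \lambda)$), which agrees with the discrete
  tail sum at integers and interpolates continuously between them, avoiding
  threshold artefacts at half-integers. A rounding mode exists for
  sensitivity checks.
* **The toy quantifier.** Each read is assigned to the transcript sharing
  the most k-mers with it (`k = 15`); ties — the misassignment mechanism
  between near-duplicates — are broken by a seeded uniform draw; reads
  sharing no k-mer stay unassigned. Real quantifier outputs can enter as
  plain count tables instead. Abundance profiles for the simulation default
  to uniform and are configurable.
* **Depth handling.** Round means are means over the held-out transcripts
  with no depth normalisation (a depth-normalising option is exposed through
  the abundance profile); sex-specific calling is running the caller per
  sample subset.

**Limitation.** The Poisson law models *homogeneous* noise. Misassignment
is heterogeneous: a transcript with a high-identity homolog receives far
more false counts than a singleton. The hold-out procedure calibrates
$\lambda$ on the population average, so false-positive control is
approximate for the most similar families and fails outright for identical
duplicates (an absent twin of an expressed transcript receives half its
reads and will always be called). The acceptance experiment therefore probes
false positives with 95%-identity pairs — the regime where misassignment is
partial and the Poisson floor is informative — and this caveat applies
equally to any pipeline built on this noise model.

## The synthetic-data generators

The generators define the study conditions under which the package is
verified. Defaults: 10 kHz sampling, 1-s sections (matching the alternating
1 s + 1 s run structure and comfortably sampling sub-kHz content); SSO
components around 350 Hz at hundreds of nm over ~1 nm Gaussian sensor noise;
quiescent runs as band-limited Gaussian noise centred on a 500 Hz best
frequency (width 200 Hz), synthesised by spectral shaping; transient runs as
contiguous on/off sinusoid bursts whose on-fraction is the target $\alpha$ —
chosen because it makes the time-domain amplitude distribution interpolate
between normal and arcsine, directly exercising the mixture weight.
Chirp responses offer an ODE mode (numerical integration of the equation of
motion) and a fast envelope mode (amplitude-modulating the chirp by
$X(\omega(t))$); the two agree on peak-normalised envelopes to within a few
percent for 1 kHz/s sweeps, which the tests check. Force-step responses use
the closed-form second-order step response. Experiment-level generation
draws each animal's mechanical state once per animal (states persist across
a run series, as the persistence rule presumes) rather than independently
per run. The read simulator emits fixed-length single-end reads with
uniform position, Poisson counts per transcript and per-base substitution
errors; paired ends, realistic error profiles and coverage biases are
deliberately out of scope because the noise-floor statistics depend only on
misassigned counts.

The LDV sampling rate and decoder bandwidth of real rigs are not encoded
anywhere; 10 kHz is a configuration default, not an inferred property of any
instrument. Likewise curation: the backscatter rule (a run fails when more
than 5% of samples fall below 20% of the channel maximum) is this package's
quantitative stand-in for laser-positioning curation, and both numbers are
configurable and reported per run in the curation report.

## Problem sizes in the checks

The test suite and `scripts/acceptance.R` verify: classification on 150–200
labelled traces; oscillator recovery over $f_0 \in \{300, 400, 500\}$ Hz
$\times$ $\zeta \in \{0.05, 0.2, 0.5\}$ with 5% envelope noise (5–10 seeds
per cell); stiffness recovery across 50–2000 µN/m; the Wilcoxon exact branch
against complete enumeration and a 2000-simulation null calibration; the
noise floor on a 150-transcript toy transcriptome with 30 homologous pairs
(10 hold-out rounds, 10–20 experiment seeds); and an end-to-end two-group
experiment of 6 animals × 6 runs (+3 force steps) per group. These sizes
were chosen as the smallest at which the statistical claims are stable.
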