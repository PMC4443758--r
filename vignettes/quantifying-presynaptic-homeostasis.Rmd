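---
title: "Quantifying presynaptic homeostatic plasticity: models, estimators and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying presynaptic homeostatic plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmjquant)
```

## The scientific problem

Synapses at the *Drosophila* larval neuromuscular junction (NMJ) hold their
evoked postsynaptic response at a set-point. When the postsynaptic response
to a single vesicle (the quantal size, measured as the mean miniature
EPSP/EPSC amplitude) is perturbed, the presynaptic terminal compensates by
adjusting the number of vesicles released per action potential (the quantal
content): receptor block that halves quantal size roughly doubles quantal
content (presynaptic homeostatic potentiation), and vesicular-transporter
overexpression that enlarges quanta by ~1.55x drives a matching decrease
(presynaptic homeostatic depression).

`nmjquant` implements the complete measurement stack used to characterize
this bidirectional control — quantal content, readily-releasable pool (RRP)
size, release-probability proxies, presynaptic calcium transients and
optical action-potential waveforms — together with stochastic generators
that produce every input with known ground truth. All validation in the
test suite runs against these generators; the `analysis/` scripts replay a
full synthetic two-genotype study through the same code paths.

## Quantal analysis

Quantal content of a recording is the ratio of the mean evoked amplitude
(30 stimuli per recording under the standard protocol) to the mean
miniature amplitude of the *same* recording. Condition-level quantal
content is the mean of per-recording ratios, never the ratio of condition
means — on heterogeneous populations the two differ, and the suite guards
the convention with a regression test. No nonlinear-summation correction is
applied to EPSP amplitudes: amplitudes enter the ratio raw, and this choice
is recorded here rather than silently embedded.

Recordings are gated by the muscle resting potential: recorded at Vm when
Vm <= -60 mV, clamped to -65 mV when -60 < Vm <= -55, discarded when more
depolarized than -55 mV. The boundary reading is strict ("more positive
than"), so -60 records at Vm and -55 clamps.

Miniature events are detected by thresholding the smoothed derivative of
the trace, locating each candidate's peak and measuring the amplitude
against a local pre-onset baseline; candidates closer than 10 ms are merged
keeping the larger. The event-detection algorithm is this package's own
(the threshold defaults to 4x a MAD-based noise SD); on clean synthetic
records it reaches recall and precision above 0.95 and amplitude bias below
5%, which is what the suite asserts. Those figures describe performance on
the generator's alpha-shaped, lognormal-amplitude events with white noise —
real records with overlapping events, drifting baselines or seal
instabilities will do worse, and passing tests should be read accordingly.

## The release model behind the train method

The generator implements the classical binomial depletion model: a pool of
`n_pool` vesicles, each released with probability `p_r` per stimulus,
quantal amplitudes lognormal (positivity; CV defaults to 0.3, a typical
quantal CV at this synapse), and constant-rate replenishment between
stimuli capped at the pool ceiling. Release probability couples to external
calcium as `p_eff = p_r (ca/ca_ref)^eta` with cooperativity `eta = 3`; a
scaled probability above 1 is an error unless clipping is requested
explicitly, so impossible parameter regimes cannot pass silently.

Two rendering details exist purely so that measurement code can be tested
against exact ground truth. Stimulus times are snapped to the sample grid,
and the EPSC kernel is a compact-support beta-shaped pulse normalized on
that grid and truncated to end before the next stimulus' 2 ms baseline
window. Measured per-stimulus amplitudes therefore equal the generator's
quantal sums to floating-point precision, which the suite asserts at 1e-9.
A real EPSC decays exponentially and overlaps the next response at 60 Hz;
the package's baseline-before-each-stimulus measurement rule absorbs that
overlap in practice, but the exactness claims hold only for the synthetic
kernel.

## RRP back-extrapolation, P_train, depression, paired pulses

For a 60 Hz, 30-stimulus train, per-stimulus amplitudes are measured as
peak minus the mean over the 2 ms before each onset. The cumulative
amplitude series is fitted by ordinary least squares over its last 10
points (stimuli 21-30) and back-extrapolated to stimulus index 0; the
intercept divided by the same-cell mean miniature amplitude is the RRP in
quanta. `P_train` is the first amplitude divided by that intercept, the
fraction of the pool consumed by one action potential. At least five trains
per synapse are averaged before fitting; per-train values are also
returned.

The estimator's validity domain deserves an explicit statement. With
constant-rate replenishment `R` per inter-stimulus interval and release
probability `p`, the cumulative series converges to
`cum_i ~ (N - R/p) + R i`, so the back-extrapolated intercept recovers
`N - R/p`, not `N`. Back-extrapolation is therefore reliable only in
depletion-dominated trains, where the per-interval refill is small against
the initial release — precisely why the assay is run at high frequency and
elevated (3 mM) calcium. The suite tests both sides of this statement:
recovery within 15% at a modest replenishment rate (300 vesicles/s,
5 per interval against a first-stimulus release of ~60), and convergence to
the analytic `N - R/p` value under strong replenishment (1200 vesicles/s),
so the structural bias is documented rather than hidden.

Accumulated depression is summarized by fitting
`a(i) = plateau + span * exp(-(i - 2)/tau)` to stimuli 2-10 of the averaged
train (Levenberg-Marquardt, started from a plateau guess over stimuli 8-10;
a non-positive fitted span is flagged "no-decay" rather than reported as a
time constant). Under pure depletion the expected amplitudes decay
geometrically and `tau = -1/log(1 - p)`, which the suite uses as a
closed-form oracle. The paired-pulse ratio uses the same amplitude
measurement on two-stimulus sweeps; under depletion with zero quantal CV
its expectation is `1 - p`, tested against the Monte-Carlo mean via the
ratio of means (the per-sweep ratio carries a small Jensen bias of order
`1/(N p)`, which the tests avoid rather than absorb into tolerance).

`P_train`'s denominator is the back-extrapolated intercept (the "total
RRP"); using the final cumulative amplitude instead would mix in
replenishment and is deliberately not the default.

## Calcium transients

Line scans across single boutons (313 Hz) yield an ROI trace and an
adjacent indicator-free background trace. The fractional change is
`dF/F = (F(t) - Fbaseline)/(Fbaseline - Fbackground)` with `Fbaseline` the
mean ROI fluorescence over the 300 ms before the stimulus and
`Fbackground` the background mean over the same window; a baseline at or
below background is a hard error, not a negative transient. Records are
excluded when resting fluorescence decreased by more than 15% or when
`Fbaseline` exceeds 650 a.u.; both thresholds are strict (values exactly at
the threshold are kept) and are exercised on both sides in the suite. The
drift estimator — the field's exclusion rule does not pin one down — compares the
mean resting fluorescence of the first and last second of the record with
the transient window masked; the generator's `drift_frac` is defined on the
same two windows so the rule can be tested exactly. The 650 a.u. threshold
is hardware-specific; it is a configurable default, not a portable
constant. Bouton averages use 8-12 scans (fewer is flagged, not refused),
and shape comparisons divide by the peak so that transients of different
amplitude but equal kinetics superimpose.

## Optical action-potential waveforms

Arch (Archaerhodopsin) spot imaging at 4 kHz gives sweeps containing
tissue-fluorescence photobleach decay, an indicator photocycle brightening
confined to the first ~10 ms, and the voltage transient. A single
exponential `a exp(-t/tau) + c` is fitted from 10 ms after sweep start to
5 ms before the stimulus (a log-spaced grid search over `tau` with linear
least squares for `a` and `c`, refined by Levenberg-Marquardt), then
extrapolated and subtracted. Starting the window at 10 ms excludes the
photocycle rather than modeling it. Sweeps with a second suprathreshold
peak (>= 50% of the stimulus-locked peak, outside stimulus +/- 5 ms) are
rejected; the 50%/5 ms operationalization is a package choice, exposed as
configuration. If every sweep is rejected, averaging errors with "no
accepted sweeps" rather than returning an empty waveform.

Widths are measured on the averaged waveform with sub-sample linear
interpolation between the bracketing samples at each flank; the peak
position is refined parabolically. Width at half maximum (WHM) is the
primary readout; "full width" is taken at 10% of peak — a convention this
package had to fix because no standard threshold exists, likewise exposed
as configuration. Optical amplitudes are not reported in physical units:
baseline Arch fluorescence cannot be separated from tissue fluorescence,
so only widths are meaningful. Group averages are peak-aligned (sub-sample)
and normalized before averaging.

The generator's AP transient is a generalized Gaussian
`exp(-|t/alpha|^beta)` in which *both* the full width and the WHM are free
parameters with closed-form `alpha` and `beta`, giving the width pipeline
an analytic oracle. End-to-end, the suite requires WHM recovery within one
sample-interpolation step (0.25 ms at 4 kHz) across 50 seeded noisy
simulations — the sensitivity needed to support a "no change in AP width"
conclusion. The nominal 2 kHz digital filter equals the Nyquist frequency
at 4 kHz sampling and is therefore an identity there; the filter is applied
only when the cutoff is meaningfully below Nyquist.

## Population fits

Calcium cooperativity is the slope of a least-squares line on
(log calcium, log quantal content); with the generator's power-law coupling
the expected single-AP quantal content is exactly proportional to
`ca^3` wherever the scaled release probability stays below 1, so the
log-log slope recovers 3 up to sampling noise. Under that power law, a
calcium signal reduced to fraction `f` predicts a release decrease of
`100 (1 - f^3)` percent: for `f = 0.5`, 87.5% — far more than a ~30%
release change, which is the quantitative argument for why a halved
spatially averaged calcium signal cannot alone explain modest release
changes.

The homeostasis curve (quantal content vs miniature amplitude) is fitted
two ways: a one-parameter reciprocal set-point model `QC = E0/mEPSP`, which
is what perfect homeostasis implies and is the scientific default (its
least-squares solution is closed-form), and a two-parameter exponential
`QC = a exp(b mEPSP)` as a descriptive alternative. Both report r-squared
on quantal content and the implied evoked amplitude per point
(`QC_fit * mEPSP`). Group comparisons use a two-sided Student's t-test with
pooled variance (Welch by flag), SEM error bars, and no multiple-testing
correction — raw p-values are reported as such.

## Synthetic-study conditions and problem sizes

The defaults encode a typical study at this synapse: pools of a few hundred
vesicles, `p_r` ~ 0.2-0.3 at 3 mM calcium, quantal amplitudes ~0.8 nA
(mEPSC) or ~0.9 mV (mEPSP) with CV 0.3, mini rates ~2 Hz, calcium
transients with peak dF/F ~0.35 and ~120 ms decay, 10 line scans per
bouton, 30-40 Arch sweeps per bouton, and an electrophysiology sampling
rate of 10 kHz (a package choice; the acquisition rate is not dictated by
the protocol, and it is recorded in trace metadata). The doubling scenario
uses 20 recordings per condition with 15% multiplicative noise on quantal
content; the cooperativity dataset uses five calcium levels spanning
0.3-1.5 mM with 50 single-AP sweeps per level, sized so the log-log slope
estimate is stable to well within +/-0.3. Monte-Carlo checks use 25-100
seeded replicates per property, sizes chosen to keep each oracle's
sampling error far below the tolerance it guards.

What the generators deliberately omit: biophysical action-potential
dynamics, spatial calcium microdomains, receptor saturation and
nonlinear summation, correlated noise, and any coupling between vesicle
size and release probability. Conclusions validated here are about the
*estimators*, not about biology: an estimator that is exact on these
idealized signals can still be biased on real data in ways the listed
omissions describe.

## Numerical choices

- Zero-phase filtering uses a 2nd-order Butterworth run forward and
  backward (4 poles effective) with odd-reflection padding, so DC gain is
  exactly 1 and edges carry no transient.
- Time windows are half-open `[start, end)` with a 1e-12 s guard against
  floating-point boundary jitter; all amplitudes are reported as
  magnitudes, with polarity fixed by channel (EPSPs up, EPSCs down).
- Trace CSVs store 12 significant digits; read/write round-trips are
  identity at that precision, and non-uniform (>1e-6 s) or non-monotonic
  time grids are rejected at read time.
- Nonlinear fits (photobleach exponential, depression decay, exponential
  homeostasis model) run Levenberg-Marquardt from deterministic starts
  (grid search or log-linear regression), so results are reproducible
  without global RNG state; fit failures surface as flags, not exceptions,
  except where a failed fit invalidates the sweep (photobleach).
- Every generator accepts a single integer seed and restores the caller's
  RNG state; identical seeds give bit-identical outputs, and the pipeline
  writes timestamp-free JSON so reruns are byte-identical.

## Known limitations

- RRP back-extrapolation inherits the `N - R/p` bias under sustained
  replenishment (see above); reported RRP values are lower bounds when
  replenishment is strong.
- Mini detection is not deconvolution-based; heavily overlapping events at
  high rates are merged and counted once.
- The drift estimator and the extra-AP rejection rule are reasonable
  operationalizations of qualitative criteria; their parameters are
  configuration, and different choices will change which sweeps survive QC.
- The homeostasis exponential model is descriptive; its parameters have no
  mechanistic reading, and on reciprocal-generated data it fits slightly
  worse than the set-point model at equal degrees of freedom.
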