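---
title: "Models and methods behind dgexcite"
author: "dgexcite authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dgexcite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgexcite)
```

# Overview

`dgexcite` implements the analysis chain used to compare dentate gyrus
granule-cell (GC) recruitment between genotypes in acute-slice experiments:
two-photon calcium imaging of perforant-path-evoked responses, calibration
of the indicator against ground-truth action potentials (APs), spike-count
inference by deconvolution, hierarchical mixed-model comparison across a
mouse / slice / field / cell design, and whole-cell electrophysiology
feature extraction. Every input the pipeline consumes can be generated
synthetically with known ground truth, which is how the package tests
itself end to end.

# The calcium model

A single AP produces a fluorescence transient modelled as a difference of
exponentials,

$$h(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r},$$

sampled on the acquisition grid (default 33.8 ms frame period, i.e. about
30 Hz, 500 frames) and normalised to unit peak *on that grid*, so that the
kernel parameter `unitAmplitude` is exactly the sampled peak dF/F0 of a
one-spike transient. Spike-count linearity is assumed throughout, matching
the linear AP-to-dF/F0 calibration the imaging analysis relies on. Default
time constants are `rise_s = 0.2`, `decay_s = 1.2` — a deliberately slow
indicator, which is what makes deconvolution non-trivial at 30 Hz. The
single-spike amplitude default (0.3 dF/F0) is a free choice: the
calibration experiments constrain the *linearity* of the relationship, not
its absolute slope, so the generator fixes a realistic value and the
calibration module estimates it back.

dF/F0 uses the mean of the first 50 frames as F0. Traces are low-pass
filtered before analysis with a zero-phase 4-pole Butterworth (default
cutoff 5 Hz at 30 Hz sampling; the filter type and cutoff are configurable
because the upstream acquisition chain does not fix them). The
zero-phase pass uses mirror padding of about ten filter time constants so
the forward-backward filter starts from a settled state; without padding
the end transient of the backward pass leaks several permille of the
signal amplitude into short traces.

## Activation calls

A cell is called active in a condition if its largest post-stimulus peak
of filtered dF/F0 exceeds `mean + 3 * SD` of its noise. Noise statistics
are estimated per cell from the pre-stimulus baseline frames by default;
a field-global estimate is available (`noiseScope = "field"`) because the
scope of the "mean noise" is an acquisition-analysis convention rather
than something the data dictate. It is worth knowing — and the test suite
measures — that this per-trace rule has a high per-cell false-positive
rate on pure noise (tens of percent over a 450-frame search window),
because it compares the *maximum* of hundreds of correlated samples
against a pointwise threshold. That is why the calibration module exists:
the principled single-AP detector fits a normal distribution to peak
dF/F0 values measured with 0 APs and thresholds at a stated tail
probability (default 0.001), which empirically controls the
false-positive rate at that level.

## Denominator filters

Field-level activation proportions support three denominators: all
GCaMP-expressing cells, only cells that respond under picrotoxin (when
synaptic inhibition is blocked nearly all connected cells respond, so
this filter removes deafferented cells), and only cells that respond to
the maximal stimulus delivered. The restricted modes require matched
reference responses and fail loudly on key mismatches.

# Deconvolution

Spike counts are inferred per trace by non-negative sparse deconvolution:

$$\min_{s \ge 0} \tfrac12 \lVert y - K s \rVert_2^2 + \lambda \mathbf{1}^\top s,$$

where $K$ is the causal convolution matrix of the calibrated kernel
(including its single-spike amplitude, so the solution is in spike
units). The problem is solved with FISTA and a non-negative
soft-threshold, restarted on objective increase; it is deterministic and
needs no tuning beyond the sparsity weight, which defaults to twice the
robust noise SD of the trace (median absolute deviation of first
differences divided by $\sqrt2$). The iteration cap (500) was chosen on
noiseless construct-and-invert problems where counts are recovered to
better than 0.03 spikes; running the solver much longer does not improve
count recovery.

Continuous activity is discretised by grouping contiguous positive frames
into events and discarding events smaller than half a spike. How
continuous deconvolved activity becomes "spikes" is a convention this
package defines; the half-spike rule reproduces integer counts exactly on
noiseless input and makes "active = at least one spike in the stimulation
window" well defined. Kernel calibration from ground-truth
pairs (`kernelFromGroundTruth`) fits rise, decay and amplitude by
minimising reconstruction error of count-scaled kernels, with the
amplitude solved in closed form for each candidate pair of time
constants.

# Population model and inference

The generator and the fitter share one scale: activation is Bernoulli
with probit-link linear predictor

$$\eta = \alpha + \beta \left(\log x - \log x_{max}\right) +
\gamma \,\mathrm{HET} + u_{mouse} + u_{slice} + u_{field},$$

with independent Gaussian random intercepts (defaults 0.3 / 0.2 / 0.2 on
the probit scale — moderate clustering of the kind nested slice
experiments show). The defaults are calibrated so the *marginal*
activation probability at the maximal stimulus,
$\Phi\!\left(\eta / \sqrt{1 + \sigma^2_{tot}}\right)$, equals 0.16
(wild-type) and 0.51 (mutant), the headline activation proportions the
design is meant to resolve; the implied conditional genotype effect is
$\gamma \approx 1.10$ probit units. Active-cell amplitudes are lognormal
with genotype-specific log means, i.e. the lognormal formulation of a
normal model with logarithmic link; `fitGlmm` accordingly fits
log-amplitude with a linear mixed model rather than a fragile
gaussian(log) GLMM, and adds a cell-level intercept for magnitude
responses, which repeat within cells across conditions.

`fitGlmm` aggregates Bernoulli cells to binomial counts per field and
condition before calling the probit GLMM — the likelihood is identical
because all covariates are field-constant, and fits are an order of
magnitude faster. Genotype curves are compared by a likelihood-ratio test
dropping all genotype terms.

## Small-sample calibration

Genotype is a between-mouse effect, and with 6 mice per genotype the
asymptotic Wald z test from the GLMM is anticonservative: across null
simulations under the default design its realised type-I error is about
0.10–0.15 at a nominal 0.05, driven by the extra variability of
maximum-likelihood estimates with 12 clusters. The package therefore:

* refers the GLMM Wald statistic to a t distribution with between-mouse
  degrees of freedom (mice minus genotype groups), the between-within
  convention for few clusters — this removes most but not all of the
  inflation; and
* provides `genotypeMouseTest`, a two-stage summary-measures analysis —
  each mouse reduced to $\Phi^{-1}\!\left((k + 1/2)/(n + 1)\right)$ of
  its maximal-stimulus activation, compared across genotypes by a Welch t
  test. Because mouse summaries are independent, this test holds its
  nominal level essentially exactly; the continuity correction keeps
  all-silent or all-active mice finite. Its cost is a small attenuation
  of the effect estimate (about 4% under the defaults, from
  marginalising the slice and field random effects inside each mouse).

`simulateOperatingCharacteristics` uses the mouse-summary test by default
and the GLMM Wald t as an option. Under the default design it reports
type-I near 0.05, power near 1 for the 0.16-to-0.51 effect, and effect
bias within 5%. This mirrors how the underlying experiments are
summarised (mouse-level means with SEMs) while the GLMM remains the tool
for curve-level description and likelihood-ratio comparison.

Paired within-field comparisons (e.g. stimulation with and without an
optogenetic manipulation) test the field-wise difference against zero
with random intercepts above the field level, reducing to the paired t
test when only field-level variation exists.

# Electrophysiology

All feature definitions are operational: spike threshold at the first
sample of the dV/dt $\ge$ 10 mV/ms run preceding a peak (central
differences), spikes require overshoot above 0 mV and at least 40 mV
amplitude; Rm is $\Delta V / I$ from small (|deflection| $\le$ 10 mV)
hyperpolarizing steps; the membrane time constant comes from a
single-exponential fit to the step onset; sag is
$100\,(V_{min} - V_{ss})/(V_{min} - V_{baseline})$ with the steady state
taken over the final 100 ms of the step; rheobase is the smallest step
current with a valid spike; half-widths interpolate the half-amplitude
crossings between samples (at 0.4–1 ms widths the sampling grid would
otherwise dominate the error); AHP time is measured from the
falling-phase threshold crossing to the trough — an interpretation, since
"AHP time" is not otherwise pinned down. Single-spike features are taken
from the first spike of the sweep closest to twice rheobase.

Synaptic responses: per-pulse amplitudes in 20 Hz trains are measured
after subtracting the extrapolated single-exponential decay of the
preceding response (linear extrapolation is available); the decay fit
starts 5 ms after the peak so the rising phase does not bias the time
constant. Stimulus-response curves are fit with the one-site binding form
$B_{max} x / (K + x)$ and genotypes are compared with the extra
sum-of-squares F test
$F = \frac{(SS_{pool} - SS_{sep}) / (df_{pool} - df_{sep})}{SS_{sep} / df_{sep}}$.
The binding optimiser retries from a small grid of starts and falls back
to Nelder-Mead on the log scale, flagging (never hiding)
non-convergence.

The current-clamp generator used for validation produces RC-exact
subthreshold responses, an additive difference-of-exponentials sag bump
on large hyperpolarizing steps (so the true sag percentage is computable
from the analytic waveform), and piecewise-linear AP templates with
constructed dV/dt profiles inserted at leaky integrate-and-fire spike
times. The LIF voltage threshold doubles as the template's AP threshold
and sits 2 pA below the steady-state rheobase deflection, which makes
rheobase land exactly on any step grid containing it. Segment durations
are rounded to whole samples so the closed-form feature values are exact
on the grid.

# What the synthetic data do and do not show

The generators emulate: spike-count-linear transients with a slow
indicator at 30 Hz, Gaussian trace noise, nested random effects on
binomial activation rising with stimulus intensity, lognormal response
amplitudes, analytic AP waveforms, and binding-law synaptic amplitudes
with paired-pulse depression. They deliberately do not emulate photon
shot noise, motion artifacts, neuropil contamination, overlapping ROIs,
biophysical conductances, or indicator nonlinearity at high spike counts.
Passing tests therefore demonstrate that the *analysis chain* is correct
and well calibrated under its own model assumptions — not that those
assumptions hold in any particular recording. In particular the
deconvolution benchmark (R² against ground truth at a single-spike
amplitude of five noise SDs) measures algorithmic fidelity at a
realistic signal-to-noise ratio, not robustness to model mismatch.

# Numerical choices and problem sizes

Degenerate inputs fail loudly: nonpositive baselines, empty windows,
all-zero calibration traces, unmatched field keys, missing genotypes.
Ties in peak detection resolve to the earliest frame
(`x[i] > x[i-1] & x[i] >= x[i+1]`). The FISTA solver's Lipschitz constant
comes from a deterministic power iteration; everything in the package is
deterministic given its seed arguments, which the pipeline threads
through every stage (the run report and all on-disk outputs are
byte-reproducible for a fixed configuration and seed).

Test and validation problem sizes were chosen so the full suite runs in
a couple of minutes on one core: 200-trace deconvolution benchmarks,
200-replicate operating-characteristic simulations, $10^5$-value
threshold calibrations, and $10^4$-cell generator-calibration checks.

# Known limitations

* Sweep input is the package's delimited dialect; ABF files are not
  parsed.
* The GLMM Wald test remains slightly anticonservative at very small
  mouse numbers even with between-within degrees of freedom; use
  `genotypeMouseTest` (the default in the operating-characteristic
  simulator) when the genotype test itself is the target.
* Intensity enters the activation model as an ordered factor or centred
  log intensity; no mechanistic recruitment curve is fit.
* Post-hoc per-intensity comparisons offer none/Bonferroni/Sidak
  corrections without asserting which convention upstream analyses used.
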