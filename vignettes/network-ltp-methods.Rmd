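---
title: "Quantifying network-level LTP on high-density MEA recordings"
author: "netLTP maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying network-level LTP on high-density MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netLTP)
```

## The problem

Long-term potentiation (LTP) is classically quantified at one or a few
extracellular electrodes: a test pulse evokes a field excitatory
postsynaptic potential (fEPSP), and the initial slope of that deflection
indexes synaptic strength. High-density CMOS microelectrode arrays
(here a 64 x 64 grid at 42 um pitch, sampled at 14 kHz per electrode)
record the same experiment at thousands of sites spanning every lamina of
a hippocampal slice, which turns LTP quantification into a network-level
mapping problem: which layers potentiate, by how much, with what change
in response timing, and which previously silent sites are recruited.

netLTP implements that mapping as a reusable, tested pipeline:

1. a **synthetic session generator** producing full-grid recordings of the
   standard protocol (input/output calibration sweep, baseline test
   pulses, a 100 Hz / 1 s high-frequency train, post-tetanic follow-up)
   with complete ground truth;
2. **preprocessing** (zero-phase 1-500 Hz Butterworth filtering, stimulus
   artifact blanking, stimulus-aligned epoching, baseline correction);
3. **LTP quantification** (fEPSP slopes, 60%-of-maximum intensity
   calibration, normalized potentiation time courses, the >= 40% LTP
   criterion, phase-integrated plasticity percentages, voltage-variation
   maps, Kolmogorov-Smirnov group contrasts);
4. **waveform classification** (PCA + k-means of evoked waveforms,
   confusion-matrix scoring against the anatomical layer map);
5. **temporal clustering** (peak latencies, initial/central/terminal
   clusters, latency-change and recruitment statistics);
6. **kernel current source density (kCSD)** estimation with ridge
   regularization, cross-validated selection, and sink/source
   quantification against an interpolated-potential baseline.

Because raw recordings of this kind are not publicly deposited, the
package validates itself by *parameter recovery*: the generator's default
effect sizes are the published layer-wise values (e.g. sustained gains of
82/47/31/54% in CA strata SO/SP/SR/SLM and 35/157/122% in DG ML/GCL/H;
recruitment folds 1.5/1.8/2.25 in CA and 1.8/1.7/1.9 in DG; latency
changes of -6/-4.8/-13.8% in CA and -7.3/-4.8/+10.8% in DG; an aged
profile with 38%/21% in SP/SR against young controls at 49.9%/24.8%), and
the analysis side must recover them.

## The synthetic data model

Each electrode belongs to a lamina (a parametric band of the grid:
straight, bowed, or V-shaped with optional jitter) or to no lamina.
Active electrodes carry a layer-specific evoked template:

* **EPSP**: difference of exponentials
  `a (exp(-t / tau_decay) - exp(-t / tau_rise))`, negative-going;
* **PS**: an EPSP with a narrow biphasic population-spike transient
  superposed on its rising phase (SP, GCL; a weaker mixed form in the
  hilus);
* **multiphasic**: an EPSP with a delayed opposite-sign lobe (SO).

Default amplitudes (SP -300 uV, SR -120 uV, SLM -80 uV, ...) and time
constants are modelling choices: the source experiments report relative
effects, not absolute template parameters. The per-layer kinetics are
deliberately distinct, since the classification stage is supposed to
separate laminae by waveform shape.

**Latency structure.** The peak latency of electrode *e* is
`baselineLatency + distance(e, stimulation site)/v + gap * (band - 1)`,
with propagation speed `v = 0.3 m/s` (a plausible unmyelinated-fibre
scale; only the ordering matters) and a 6 ms gap between the three
distance-tercile bands, which makes the initial/central/terminal
temporal clusters well-defined, as they are in the data this emulates.
Two implementation details matter for exact recovery:

* latencies are referenced to the **band-limited** waveform (the peak of
  the template after the 1-500 Hz zero-phase filter), because that is
  what peak detection measures — a 2 ms population-spike transient shifts
  visibly under the filter;
* the baseline-to-post latency shift is quantized to the sample grid per
  electrode, so baseline and post-tetanic waveforms are sampled at the
  same sub-sample phase and slope ratios are exact.

**Potentiation.** Post-tetanic responses are scaled per layer by a
biphasic gain curve (linear ramp peaking at 5 min, then linear decay to
60% of peak at 120 min), normalized so that its mean over the recorded
schedule equals the nominal gain — the quantity `plasticityPercent()`
measures. Per temporal band, a fixed fraction of labelled electrodes is
active at baseline (a multiple of 20, so every default recruitment fold
is an exact count ratio) and enough silent electrodes activate
post-tetanically to realize the fold exactly; recruited electrodes appear
at their band's scaled mean latency so injected per-cluster latency
changes are recovered exactly in the noise-free case.

**Noise.** Additive i.i.d. Gaussian noise (default SD 10 uV) from a
self-contained compiled generator (xoshiro256++ with a ziggurat normal
sampler), so sessions are bit-reproducible for a given seed regardless of
R's RNG state; with noise enabled, per-trial amplitudes jitter with a 5%
CV. What the generator does **not** emulate: spontaneous activity,
electrode drift or impedance variation, cross-electrode spatial
correlation of noise, and field spread between electrodes (each electrode
sees only its own template; spatially coupled potentials are exercised
separately through the CSD forward model). Passing recovery tests on
these sessions therefore shows the *analysis* is correct and calibrated,
not that it is robust to every artifact of real recordings.

**Problem sizes.** Recordings store one 120 ms segment per test pulse
(the events table carries both the within-trace time and the nominal
protocol minute), with 10 baseline pulses and 15 post-tetanic pulses on a
thinned schedule spanning 0-120 min, plus 150 ms silent margins per
phase. The full nominal schedule (one pulse per 30 s for two hours,
4096 channels at 14 kHz) would be hundreds of gigabytes per session;
the thinned schedule preserves every quantity the analysis estimates.

## Preprocessing choices

The band-pass is the protocol's fourth-order Butterworth, 1-500 Hz,
applied zero-phase (forward-backward) so peak latencies are undistorted.
A direct polynomial (b, a) realization of this filter is numerically
unstable at 14 kHz — the 1 Hz edge puts order-8 roots essentially on the
unit circle and a plain 50 Hz sine explodes — so the filter is designed
analytically as cascaded second-order sections (bilinear transform with
pre-warping, unit gain pinned at the geometric mid-band) and run in
compiled code with odd-reflection padding and steady-state
initialization. The implementation reproduces the reference Python
`sosfiltfilt` behaviour to four digits on identical inputs, and its
magnitude response matches the closed-form Butterworth expression to
1e-6 (a test).

Artifact blanking replaces `(0, 2 ms]` after each pulse by linear
interpolation *after* filtering, on the epochs; each epoch is then
centred on its 10 ms pre-stimulus mean. The 2 ms window is a default, not
a reported value. The generator renders no artifact by default (the
hardware this emulates suppresses them; an optional artifact amplitude
exists for testing the blanking path).

**Activity detection.** An electrode is "active" when its mean evoked
waveform exceeds `activityThresholdSd` (default 6) standard errors at
some post-blank sample. The standard error comes from the *across-trial*
variance at each sample, smoothed along time. This choice is forced by
the physics of the band: 1-500 Hz noise is autocorrelated over tens of
samples and its low-frequency component wanders relative to the
pre-stimulus anchor, so a pre-window SD underestimates the null
variability several-fold and floods the array with false activations —
whose downstream effect is catastrophic, because a falsely "active"
electrode that is later recruited contributes an enormous normalized
slope ratio. Threshold 6 keeps the familywise false-activation
probability per 4096-electrode array negligible given the t-like tails
of the statistic; evoked responses sit at z of around 50, so sensitivity
is unaffected. The threshold is recorded in every report.

## LTP quantification

Slopes are the magnitude of a least-squares fit over the 20-80% amplitude
span of the rising phase toward the dominant deflection, with the span
located on a 5-sample-smoothed copy of the waveform (so threshold
crossings are not flipped by single-sample noise) and the fit performed
on the raw samples. Estimator design here matters more than it may seem;
three successively weaker sources of bias in the post/baseline ratio had
to be engineered away, and each is documented because each would
otherwise silently inflate recovered plasticity:

1. selecting the span on every noisy epoch individually attenuates
   slopes (a selection-on-noise effect, up to ~10% in low-amplitude
   layers) — so spans are determined on **mean** waveforms and every
   pulse is fitted over fixed samples, which keeps least squares
   unbiased under additive noise;
2. determining the span independently per phase leaves a smaller
   SNR-dependent asymmetry (baseline means are noisier than post-tetanic
   ones) — so `pairedPhaseSlopes()` estimates each electrode's
   baseline-to-post latency shift from the half-amplitude rising
   crossing (sub-sample interpolated; a steep-slope feature, far more
   shift-sensitive than the peak or a cross-correlation maximum) and
   fits both phases over the *same* waveform-relative window, making the
   ratio exact for every realized window;
3. the ratio estimator itself carries an `E[1/mean]` convexity term from
   the finite number of baseline pulses — corrected to first order with
   a contiguous split-half variance estimate, which remains valid when
   band-passed noise is correlated across neighbouring pulses (a pooled
   per-pulse variance is not).

The single-epoch `fepspSlope()` keeps the self-contained definition; all
variants coincide on noise-free epochs (tested), and the recovered layer
gains match the injected ones within twice their seed-level standard
error on default noisy sessions.

Normalization is per electrode to its baseline mean (baseline = 100%);
electrodes silent at baseline are excluded from normalization and enter
only the recruitment counts. The LTP flag uses the first 60 post-HFS
minutes and the protocol's inclusive >= 40% criterion; the plasticity
percentage averages `normalized - 100` over the immediate (0-5 min),
intermediate (5-60 min) and long-term (60-120 min) windows, boundaries
inferred from the reported early peak (< 5 min) and late phase (up to
120 min) and configurable.

## Classification and temporal clustering

The classification feature space is `[z-scored scalars || mean waveform]`
with the waveform extracted in a window **aligned at each electrode's own
extremum**. Alignment matters: unaligned, the propagation latency
dominates Euclidean distance and k-means partitions by distance band
rather than waveform class; latency is not discarded — it remains one of
the scalar features. PCA keeps the fewest components explaining 90% of
variance (capped at 10); k-means runs 20 seeded k-means++-style restarts,
keeping the lowest inertia (ties to the lowest restart index), with k = 4
for CA and k = 3 for DG. Scoring maps clusters to layers by the
one-to-one assignment maximizing the row-normalized diagonal and reports
the mean diagonal probability. Degenerate all-identical inputs raise an
error rather than returning arbitrary clusters.

Temporal clustering is Ward-linkage (`ward.D2`) agglomerative clustering
of the one-dimensional latencies cut at three clusters, followed by a
local boundary refinement: optimal 1-D clusters are contiguous in sorted
order, and coordinate descent on the two cut boundaries repairs Ward's
greedy merges, which are measurably sub-optimal on small sets (plain
Ward matches the exact dynamic-programming optimum on only ~85% of random
small instances; with refinement, agreement is 96-99%, tested against an
exhaustive oracle). Clusters are renamed initial/central/terminal by
ascending mean latency; phases are matched by rank, not centroid
distance, mirroring how like-named clusters are compared across phases.

## kCSD estimation

The forward model is a homogeneous medium: a 2-D source density spread
uniformly across the 300 um slice thickness contributes
`V(x) = (1 / 4 pi sigma) \iint b(x') w(||x - x'||; h) dx'` with
`w(d; h) = 2 asinh(h / 2d)` and sigma = 0.3 S/m. Gaussian basis sources
(default 32 x 32 grid, width R = 2 pitches) are forward-modelled by
reducing the quadrature to one radial integral (the angular part is a
Bessel `I0`), tabulated and splined; far from a source the potential
matches the point-source `Q / (4 pi sigma r)` within 1% (a test). The
two-medium saline correction is deliberately out of scope — no saline
parameters are available to set it honestly — and the `ForwardModel`
type leaves room for it.

Estimation is ridge-regularized: `CSD = Kcross (K + lambda * s * I)^{-1} V`
with `s = mean(diag(K))`, making lambda dimensionless and candidate
grids geometry-independent. Lambda is selected by closed-form
leave-one-electrode-out prediction error (deterministic; a flat error
curve falls back to the smallest candidate with a message). The
"smoothing is monotone in lambda" property is asserted on the **L2
energy** of the map (which ridge shrinkage guarantees); the L1 integral
of |CSD| is genuinely non-monotone for any correct implementation, since
regularization spreads mass while lowering peaks. Sinks and sources are
4-connected components beyond 30% of the map's absolute maximum, with
integrals times cell area; the comparison baseline is bilinear
interpolation of the electrode potentials. Synthetic validation scenes
are forward-modelled by an independent polar quadrature (Gauss-Legendre
in a substituted radial variable, trapezoid in angle, accurate through
the logarithmic near-field), which agrees with the kernel tabulation
path to ~1e-8 while sharing no code with it.

The full-pipeline CSD stage runs on a stride-2 electrode sub-grid
(32 x 32) by default: the kernel solve is cubic in electrode count, and
the sub-grid loses little for maps whose structure is set by the basis
width.

## Degenerate inputs, tie rules, tolerances

* Peak ties resolve to the earlier sample; calibration ties to the lower
  intensity; inertia ties to the lower restart index.
* All thresholds (40% LTP, 60% calibration, activity) are inclusive;
  threshold comparisons carry a 1e-9 relative epsilon so exact-ratio
  boundary cases survive floating-point roundoff.
* Zero baseline counts make recruitment folds `NA` (undefined), with a
  warning; zero baseline slopes exclude an electrode with a message; a
  flat I/O curve or an all-silent array is an error.
* The container refuses unknown schema versions and truncated payloads
  instead of reinterpreting them.
* Noise-free recovery tolerances: latencies within one sample, counts
  exact, gains within 1% (residual: filter crosstalk between neighbouring
  120 ms segments, of order 0.01%).

## Reproducibility

Every stochastic step is seeded: the generator from its `seed` (noise
and jitter streams are derived offsets into the compiled RNG),
electrode selection through R's RNG under a saved-and-restored state,
k-means through the classification seed. `runPipeline()` derives all
module seeds from one master seed and re-running a configuration
reproduces the JSON report byte for byte (a test). Reports embed the
package version, seeds, and every threshold used.

## Known limitations

* The generator's electrodes are independent given their templates; it
  does not model volume conduction between electrodes, so classification
  and LTP recovery results do not speak to spatial leakage effects.
* Ward-plus-refinement is still a heuristic; the tests document a
  measured >= 95% agreement with the exhaustive 1-D optimum, not a
  guarantee.
* The kCSD stage assumes a homogeneous medium and a planar source sheet;
  absolute CSD units are meaningful only up to the forward model's
  idealizations.
* Runtime-bearing defaults (thinned pulse schedule, stride-2 CSD
  sub-grid, 16 x 16 validation scenes) are the package's problem-size
  choices and are configurable.
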