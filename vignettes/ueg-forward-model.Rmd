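---
title: "A forward model of the unipolar electrogram and its validation pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A forward model of the unipolar electrogram and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uegsim)
```

## The model

A unipolar electrogram (UEG) records the extracellular potential at one
cardiac site against a distant reference.  `uegsim` implements a
deliberately simple, nonionic forward model of the UEG during a paced
beat.  Each site $i = 1 \dots M$ carries a stylized transmembrane action
potential built from two logistic functions, one for the depolarization
upstroke and one for the repolarization downslope:

$$
AP_i(t) = A\,\frac{1}{1 + e^{-\beta_{AT}(t - \tau_{AT,i})}}
\left(1 - \frac{1}{1 + e^{-\beta_{RT}(t - \tau_{RT,i})}}\right) - V_{rest}.
$$

The timing parameters $\tau_{AT,i}$ and $\tau_{RT,i}$ are the local
activation time (AT) and repolarization time (RT); they are the steepest
upslope and steepest downslope of $AP_i$.  The shape parameters
($A$, $V_{rest}$, $\beta_{AT}$, $\beta_{RT}$) are position-independent:
every site has the same AP shape, shifted and stretched only through its
two local times.  Distant electrical activity is summarized by a remote
component equal to the mean AP over all sites,
$\overline{AP}(t) = \tfrac1M \sum_i AP_i(t)$, and the UEG is the
inverted, rescaled difference

$$
UEG_i(t) = -\alpha\,\bigl(AP_i(t) - \overline{AP}(t)\bigr),
\qquad \alpha = \frac{g_i}{g_i + g_e},
$$

with $g_i$, $g_e$ the intracellular and extracellular conductivities,
assumed homogeneous and isotropic; $\alpha = 0.25$ throughout.  Three
consequences follow directly from the mean subtraction and are enforced
as invariants in the test suite: the UEGs sum to zero across sites at
every sample; uniform timing produces identically zero UEGs; and for
$M = 2$ the two UEGs are exact mirror images.  The model predicts QS,
RS or R-wave QRS morphology at sites activating before, around or after
the remote component, and positive, biphasic or negative T-waves at
sites repolarizing before, around or after it — hence a positive
correlation between AT and signed QRS area and a negative correlation
between RT and signed T-wave area.

## Parameters and defaults

* `A = 100` mV, `V_rest = 80` mV — plateau near $+20$ mV, rest near
  $-80$ mV.  The source framework never fixes these; every correlation
  and polarity statistic in the package is invariant to the choice
  (asserted in the tests), so they are cosmetic.
* `beta_AT = 0.4` /ms, `beta_RT = 0.035` /ms — the centers of the
  search grids $\{0.2, 0.4, 0.6\}$ and
  $\{0.025, 0.035, 0.045, 0.055\}$ /ms used by `grid_search_beta()`.
* `alpha = 0.25` (`conductivity_scaling(1, 3)`), fixed during the grid
  search.
* Sampling: 1 kHz, beat window $[0, CL)$ ms from the stimulus, matching
  clinical sock acquisitions.  APs whose repolarization tail extends
  past the window are truncated with a warning.

## Marker detection

`detect_at()` returns the time of the minimum of the first derivative
within the QRS window (the intrinsic deflection); `detect_rt()` the time
of the maximum of the first derivative within the T-wave window — the
Wyatt method, applied identically to positive, biphasic and negative
T-waves.  Derivatives use central differences with one-sided boundary
stencils; ties go to the earliest sample; no smoothing is applied by
default because smoothing shifts extrema.  `compute_ari()` forms
ARI = RT − AT, the standard surrogate of local AP duration.

Windows are bootstrapped from the data by `auto_windows()`.  A first
pass locates every site's steepest negative deflection over the whole
(artifact-blanked) beat — unambiguous because $\beta_{AT} \gg \beta_{RT}$
makes the activation slope an order of magnitude steeper than any
repolarization slope.  The QRS window then spans 10 ms before the
earliest such deflection to 30 ms after the latest; the T-wave window
runs from there to 20 ms before the end of the beat.  An earlier design
split the beat at the minimum of the spatial mean of $|dV/dt|$ between
the two activity bursts, but the tail of late intrinsic deflections and
the terminal QRS rebound can outweigh the weak T-wave burst at short
cycle lengths; the two-pass rule has no such failure mode and is what
ships.

**Accuracy and the slow-remote condition.**  Marker times measured from
model UEGs equal the generating $\tau$ exactly only where the remote
component changes much more slowly than the local AP.  Activation
always satisfies this (the test suite shows exact AT recovery at every
site), but repolarization does not when the RT dispersion is comparable
to the downslope width $1/\beta_{RT} \approx 29$ ms: the remote T-wave
pulls the detected upslope maximum away from $\tau_{RT}$, early sites
earlier and late sites later, by up to $\sim$15–20 ms at a dispersion of
80 ms.  This is a property of the Wyatt marker applied to this signal
family, not a detection artifact.  It is also why the validation
pipeline compares *measured-recorded* against *measured-simulated*
markers, exactly as the clinical analysis does: the model is informed
with marker times measured from the recorded signals, so the same
remote-induced shift enters both sides and cancels to second order.
The package's acceptance experiments confirm a median recorded-minus-
simulated RT difference of 0–1 ms and correlations above 0.99 at every
cycle length, while the one-sided "cellular truth versus measured"
comparison retains the first-order shift.

## Quality control

Per site and per drive train (defaults from the clinical criteria):

* **Beat stability** — mean Pearson correlation between each beat and
  the per-sample median beat; reject below 0.98.
* **Spectral SNR** — $10\log_{10}$ of band power 1–40 Hz over band
  power 40–100 Hz on the signal-averaged beat; reject below 10 dB.
  The estimator is a Welch PSD (1 s Hann segments, 50% overlap,
  one-sided density scaling) implemented in the package, with band
  powers integrated by the trapezoidal rule — unambiguous and testable
  (a white-noise input must score $10\log_{10}(39/60) \approx -1.9$ dB).
  SNR is computed after averaging; a config flag switches to the median
  single beat.
* **Signal averaging** — per-sample mean over retained beats; reduces
  iid noise by $1/\sqrt{n}$, asserted by Monte Carlo in the tests.
* The first 5 beats of each train are discarded to approximate steady
  state; QC decisions use only the site's own beats.

Lowering either threshold can only grow the retained-site set
(monotonicity, tested).

## Steepness search

`grid_search_beta()` scores every $(\beta_{AT}, \beta_{RT})$ pair by the
median whole-beat Pearson correlation between the recorded
signal-averaged UEGs and UEGs simulated from the measured markers, and
returns the argmax (ties to the smaller $\beta_{AT}$, then smaller
$\beta_{RT}$).  The objective uses the entire beat rather than QRS or
T-wave sub-windows, and $\alpha$ stays at 0.25.  When the "recorded"
matrix is itself a model output and the markers equal the generating
times, the search recovers the generating pair with median correlation
exactly 1; under 5% additive noise it still recovers it in the majority
of seeds (both tested).  Note that when the markers informing the
search carry the remote-induced RT shift, a flatter $\beta_{RT}$ can
legitimately score higher — the search optimizes morphology, not
marker fidelity.

## The synthetic sock generator

No clinical sock recordings are distributable, so `synthetic_sock()`
fabricates a complete acquisition with known ground truth:

* **Geometry** — 240 electrodes on a base-truncated ellipsoid
  (35 × 35 × 55 mm semi-axes) along a golden-angle spiral with 0.5 mm
  seeded jitter.  Distances are straight-line, not geodesic — adequate
  for smooth monotone activation fields, and a documented limitation.
* **Timing fields** — activation spreads from the apex-most electrode
  at 1 mm/ms (≈95 mm maximal path, so AT ranges span roughly
  60–120 ms), plus a spatially correlated perturbation (Gaussian-kernel
  smoothed noise, 15 mm length scale, 4 ms sd).  APD is
  $120 + 0.25\,CL$ ms (restitution-like cycle-length dependence) with a
  20 ms apex-to-base gradient, a −0.45 coupling to local AT (late
  sites repolarize relatively earlier, standard restitution behavior,
  keeping RT dispersion at 40–100 ms, below the AT range), and its own
  5 ms smooth perturbation.  A `rt_dispersion_max` option shrinks the
  RT field around its mean when an experiment must stay inside a stated
  dispersion regime.
* **Pseudo-recorded signals** — built from the same logistic family but
  deliberately richer than the model under test: per-site ±15%
  perturbation of both steepness parameters, per-beat 1 ms timing
  jitter, additive 0.05 mV noise low-passed at 100 Hz, 0.3 mV / 0.3 Hz
  baseline wander with per-site phase, and a 2 ms biphasic pacing
  artifact.  Four corrupt channels exercise the QC chain: alternating-
  morphology channels (alternate beats inverted) collapse the
  beat-median correlation and trip the stability filter; 70 Hz, 5 mV
  interference channels are stable beat-to-beat but sit in the noise
  band and trip the SNR filter.  Everything is reproducible bit-for-bit
  from `(seed, config)`.

What the generator does **not** emulate: ionic AP dynamics, anisotropic
or heterogeneous conduction (scar), far-field atrial activity,
electrode contact artifacts beyond the stimulus spike, and respiration-
coupled motion beyond sinusoidal wander.  Passing tests therefore show
the pipeline's correctness and the model's internal consistency, not
clinical performance on human recordings.

## Numerical choices

* Marker times are snapped to the 1 kHz lattice before informing the
  model, as marker times measured on sampled recordings necessarily
  are; this is why the activation round trip is exact rather than
  subject to sub-sample rounding.
* Area baseline: median of the 20 ms before the stimulus when
  pre-stimulus samples exist, else the first beat sample.
* Whole-beat correlations exclude the first 10 ms after the stimulus
  (pacing artifact the model does not produce).
* Quartiles use linear interpolation (type 7); dispersion is the median
  absolute deviation without a consistency constant, written
  median(|X − median(X)|) — the source convention omits the absolute
  value typographically, but its printed dispersions are nonnegative,
  so the standard MAD is intended.  Outlier fences sit at
  Q1 − 1.5·IQR and Q3 + 1.5·IQR.
* Degenerate inputs (flat windows, zero-variance beats, uniform timing)
  are flagged with reason codes, never fatal per site; whole-pipeline
  stages abort only when zero sites survive.

## Problem sizes

The shipped experiments use 240 sites × 600 ms beats at 1 kHz, 30-beat
trains, and six cycle lengths from 350 to 600 ms; a full synthetic
acquisition generates in a few seconds and the end-to-end pipeline runs
in under ten, so the whole validation suite completes in well under a
minute of compute on one core.

## Worked example

```{r example, eval = FALSE}
ds <- synthetic_sock(generator_config(), seed = 7)
res <- run_validation(ds)
print(res)
```

`res$summary` carries the per-cycle-length row of the validation table:
marker differences and correlations between the recorded and simulated
sides, median morphology correlations for the whole beat, QRS and
T-wave, the searched steepness pair, and the timing–area correlations
for both sides.
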