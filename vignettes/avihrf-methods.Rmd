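---
title: "Methods: species-specific HRF estimation and event-related GLM for awake pigeon fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: species-specific HRF estimation and event-related GLM for awake pigeon fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avihrf)
```

## The problem

Event-related fMRI analysis assumes a hemodynamic response function (HRF)
linking neural events to the BOLD signal. The default double-gamma HRF
shipped by human fMRI packages does not fit birds: the avian pallium is
vascularized differently and the measured pigeon response peaks earlier
and narrower than the human canonical curve. This package implements the
full analysis chain for an awake-pigeon colour discrimination experiment:
estimating the pigeon HRF from visual-stimulation runs, first-level GLMs
for a Go/NoGo task using that HRF, cluster-level inference, quality
control, and signal-detection-theory (SDT) scoring of the operant
response (mandibulation — jaw movements recorded by a differential
piezo-electric sensor). A synthetic-session generator reproduces the
statistical structure of the protocol so every stage can be exercised and
validated without scanner data.

## The HRF model

The response to a stimulus of duration $d$ is modelled as a boxcar
convolved with a difference of two gamma densities,

$$
y(t) = \left[\Pi(t,0) - \Pi(t,d)\right] \otimes
A\left(
\frac{t^{\alpha_1-1}\beta_1^{\alpha_1}e^{-\beta_1 t}}{\Gamma(\alpha_1)}
- c\,
\frac{t^{\alpha_2-1}\beta_2^{\alpha_2}e^{-\beta_2 t}}{\Gamma(\alpha_2)}
\right)\Pi(t,0),
$$

where $\Pi(t,t_0)$ is the unit step at $t_0$, $\alpha_i,\beta_i$ are the
gamma shapes and rates of the response and undershoot lobes, $c$ is the
undershoot-to-response ratio and $A$ the amplitude. Each gamma term is a
unit-mass density, so the kernel integrates to $A(1-c)$. (Some published
statements of this model normalize both terms by $\Gamma(\alpha_1)$;
that cannot be the intended reading — the undershoot would be scaled by
$\Gamma(\alpha_2)/\Gamma(\alpha_1)\approx 6\times10^3$ and dominate the
curve — so the package uses $\Gamma(\alpha_2)$ and exposes a
`strict_gamma_norm` switch for the literal form.)

Two canonical parameter sets are built in:

```{r}
canonical_hrf("human")    # the standard default double-gamma
canonical_hrf("pigeon")   # best fit to awake-pigeon entopallium data
```

With the pigeon parameters and a 2 s stimulus, the modelled response
peaks near 4.9 s after onset:

```{r}
hdr_features(hrf_response(canonical_hrf("pigeon"), stim_duration = 2))
```

A subtlety worth noting: the full-width at half-maximum of the
*continuous* best-fit curve is about 3.76 s, while widths measured from
curves sampled at the characterization TR of 2 s (with linear
interpolation between samples, as any empirical measurement does) come
out near 4.5 s. Published empirical width ranges refer to the latter
kind of measurement; both numbers are reproducible with
`hdr_features()`.

## The synthetic session generator

The generator is first-class, tested code; its defaults *are* the study
conditions:

* **Task design** (`make_discrimination_design()`): three 10-min rest
  blocks around two 72-trial sessions; four equiprobable conditions
  (S+/S− at 20%/100% light intensity); 2 s stimulus, 0.8 s delay, 1 s
  reward slot; TR 4 s. Inter-trial intervals are a *balanced
  permutation* of an evenly spaced grid over 12.2–20.2 s (mean exactly
  16.2 s) rather than i.i.d. uniform draws — i.i.d. jitter cannot
  reproduce a fixed 78-min, 1170-volume run, which the protocol
  requires. The 4 s/5 s post-reward window overlaps the start of the
  ITI; that bookkeeping is what makes
  $144 \times 20\,\mathrm{s} + 30\,\mathrm{min} = 78\,\mathrm{min}$ hold.
* **HRF characterization design** (`make_hrf_design()`): 30 pre-volumes,
  30 trials of 2 s stimulus + 28 s darkness (15 red, 15 green), 10
  post-volumes at TR 2 s — 490 volumes.
* **BOLD** (`simulate_bold()`): a 16×16×4 voxel grid at a nominal
  0.47×0.47×1 mm³ voxel size — desk-scale while preserving the real
  geometry for smoothing and motion units. Active voxels carry
  condition boxcars convolved with the pigeon HRF (regressors normalized
  so betas read as peak percent signal change; the default 1.2% matches
  the 0.8–1.5% entopallium range); all voxels receive AR(1) noise
  (φ = 0.3), white innovations and a 120 s-period sinusoidal drift with
  random phase. The innovation scale (default 17 on a baseline of 1000)
  was calibrated once so the pipeline tSNR (high-pass 100 s, smooth,
  then mean/sd) has an in-mask median inside 110–220, the telencephalic
  range of the awake protocol.
* **Motion** (`simulate_motion()`): six smoothed, bounded random walks;
  default bounds 0.048 mm / 0.045°, the maxima observed in vivo.
* **Piezo** (`simulate_piezo()`): mandibulation bursts are 20 Hz damped
  oscillations of 150 ms (the burst shape and the 1000 Hz default rate
  are modelling choices; neither is constrained by published data).
  Hits occur with probability 0.9 at truncated-normal latencies
  (0.9 ± 0.4 s), false alarms with probability 0.1 at 0.7 ± 0.5 s;
  rewarded trials carry ~3 Hz drinking bursts; a sparse spontaneous
  rate (0.02 Hz) populates rest/ITI so the GLM's rest-mandibulation
  regressor has events. Common-mode gradient artifacts appear on both
  channels and must be cancelled by the differential detector.

What the generator does **not** emulate: susceptibility distortion, eye
movement artifacts, physiological (cardiac/respiratory) noise,
spatially correlated noise, motion-correlated signal, or attentional
drift. Passing tests therefore demonstrate internal consistency of the
estimators under the GLM's own assumptions — not robustness to every
artifact of real data.

## Preprocessing and QC

The task pipeline composes spatial smoothing → grand-mean scaling →
high-pass filtering, mirroring the acquisition pipeline's order.

* **Smoothing**: separable Gaussian, σ = FWHM/2.355 per axis in voxel
  units, kernel truncated at 4σ, half-sample symmetric reflection at the
  boundaries. With a symmetric kernel this boundary rule makes the
  smoothing operator doubly stochastic, so constant fields and spatial
  sums are preserved exactly. The acquisition protocol quotes its 8 mm
  FWHM *after* relabeling voxel sizes by a factor of 10; the package
  smooths in native units (0.8 mm) and treats the upscaling as pure
  metadata.
* **Grand-mean scaling**: one multiplicative factor per run bringing the
  4D in-mask mean to 10000.
* **High-pass filter**: regression on a discrete-cosine basis containing
  every component with period above the cutoff (60 s for the task GLM,
  100 s for tSNR), temporal mean restored afterwards. This approximates
  FSL's Gaussian-weighted running-line filter with a linear, idempotent
  operator whose frequency response is directly testable: >90%
  attenuation at 5× the cutoff period, >90% pass at a third of it.
* **Polynomial detrending** (HRF pipeline): projection on an orthogonal
  polynomial basis, default order 2 (the order is unstated in the
  protocol; order 2 removes linear and quadratic scanner drift without
  touching the 30 s trial periodicity).
* **tSNR**: voxelwise temporal mean over standard deviation, computed
  after the caller applies the 100 s high-pass and smoothing;
  zero-variance voxels get an `Inf` sentinel rather than being dropped,
  preserving map geometry. **MAD** is `median(|x - median(x)|)` with no
  consistency constant, the motion-QC statistic.

## HRF characterization

Run 1 of the characterization protocol localizes light-responsive voxels
with a GLM using the *human* canonical HRF (the species-specific HRF
does not exist yet at that stage; an imperfect kernel biases amplitude,
not location). The ROI is `z >= 3.1`. Runs 2–5 are averaged:
ROI-mean time course → polynomial detrend (signal level restored so
percent conversion stays well defined) → percent signal change against
the 2 s pre-onset baseline → trial average per run → grand average
across runs, SEM across runs.

`fit_hrf()` minimizes the residual sum of squares over
$(A,\alpha_1,\alpha_2,\beta_1,\beta_2,c)$ with bounded
Levenberg–Marquardt. Design choices:

* **Bounds** — α₁ ∈ [2, 14], α₂ ∈ [2, 25], β₁ ∈ [0.2, 4],
  β₂ ∈ [0.1, 3], c ∈ [0, 1], A ∈ [10⁻⁴, 100]: wide enough to contain
  both canonical sets with margin, tight enough to exclude degenerate
  optima. The original analysis also constrained its search to a
  "plausible range" without publishing it.
* **Multi-start** — 10 starts: the human canonical initialization plus
  log-uniformly jittered variants (c drawn uniformly in its bounds);
  best RSS wins. RSS is non-increasing in the number of starts by
  construction.
* **Model evaluation** — the boxcar convolution is computed in closed
  form from gamma CDF differences, exact at any sample time; no
  discretization error enters the fit.
* **Confidence intervals** — linearized (finite-difference Jacobian)
  covariance at the optimum, the standard curve-fit report. Estimates
  pinned at a bound are flagged; their linearized CIs should not be
  taken at face value.

`hrf_recovery_experiment()` packages the validation study: simulate
noisy averaged HDR curves from the pigeon point estimates (TR 2 s
sampling, noise 5% of peak — the residual noise scale of a ~60-trial
average), refit each, and compare the mean recovered parameters to the
generating values. With 50 replicates the means of α₁, β₁ and c land
within the published 95% CI half-widths of the point estimates; c shows
a small positive bias (~0.06) because the undershoot is weakly
identified from 16 coarse samples and c is bounded below.

## Task GLM and inference

`build_design_matrix()` constructs the seven task regressors — Hit,
Miss, CR, FA stimulus windows; reward (1 s, rewarded trials);
post-reward window (4 s after reward offset for rewarded trials, 5 s
after stimulus offset for NoGo); and rest/ITI mandibulation onsets
outside trial and post-reward epochs — convolved with the pigeon HRF on
a 0.1 s grid and decimated to the TR grid (sub-TR onset fidelity matters
with jittered designs), plus six demeaned motion parameters and an
intercept. Unrewarded S+ (Miss) trials are given the 5 s NoGo-style
post-window; the protocol enumerates only the rewarded and NoGo cases,
so this is the package's choice. Event types absent from a session are
dropped with a warning; contrasts referencing them error out.

Fitting is voxelwise OLS without prewhitening (the characterization of
serial correlation beyond the nuisance terms is out of scope; the
permutation null below does not rely on parametric residual
assumptions). Contrasts are converted `t → z` through the matching
normal quantile at the fit's degrees of freedom, one-sided, matching the
directional named contrasts (`go_gt_nogo_plus_mandibulation`,
`nogo_gt_go`, `mandibulation_gt_rest`).

**Cluster inference.** Voxels with z > 3.1 form face-connected
clusters. The critical extent is the smallest k such that the null
probability of a maximum cluster of size ≥ k is at most α = 0.05, with
the null built by permutation: residual-volume shuffling around the
reduced model at the first level (a Freedman–Lane-style scheme), subject
sign-flipping at the group level. Permutation replaces Gaussian random
field theory deliberately: GRF smoothness estimation is unreliable on
small grids, while the permutation null is exact up to Monte-Carlo error
under exchangeability. On small grids with a high cluster-forming
threshold the achievable FWE levels are discrete, so realized error is
conservative (at or below nominal); calibration is verified on smooth
null maps where the cluster-size distribution is rich.

**Group level.** The Bayesian mixed-effects group model of the original
analysis is intentionally replaced by a summary-statistics one-sample
t test on subject effect maps with the sign-flip cluster-FWE null —
assumption-light, desk-scale, same decision rule (z > 3.1, cluster
p < 0.05). Voxels with zero between-subject variance are flagged and
their z capped.

## Behaviour

The differential piezo signal (signal − reference) cancels common-mode
scanner artifacts. Detection operates on the log of a causal 50 ms RMS
envelope — the envelope of Gaussian noise is heavy-tailed, its log is
nearly Gaussian, so a robust z threshold (median/MAD, default 3) has a
predictable false-alarm rate (< 1 event/min at default noise).
Exceedances shorter than 20 ms are discarded and a 1.5-z hysteresis plus
100 ms refractory prevents re-triggering on a burst's decaying tail.

Trials are classified on the stimulus window only: S+ with ≥ 1 event →
Hit, else Miss; S− with ≥ 1 event → FA, else CR. Reaction time is the
first in-window event. `sdt_summary()` reports hit rate, FA rate and
$d' = \Phi^{-1}(h) - \Phi^{-1}(f)$ with the log-linear correction
(add 0.5 to each cell, 1 to each denominator) applied before the
transform — the original analysis states no correction, and the
log-linear rule keeps d′ finite at perfect performance. Mandibulation
rate is reported as the raw count per 2 s stimulus window with a
per-second convenience column, since the published "rate" leaves the
denominator ambiguous.

## Numerical and testing choices

Problem sizes in the test suite are chosen for a single CPU: the
simulation grid is 16×16×4 (8×8×2 in unit tests), permutation counts
are 200–500 where a distribution is needed, the FWE calibration uses
200 null group datasets of 8 subjects on a 10×10×3 grid, and the
parameter-recovery study uses 50 replicates. Every generator is a pure
function of `(spec, seed)`; the RNG state of the caller is never
touched.

Known limitations: no motion correction or slice-timing (synthetic data
are generated aligned; both steps belong to existing tools), no
prewhitening, no atlas registration or anatomical labelling, no
dispersion/temporal-derivative HRF terms, and the piezo burst shape and
amplitude units are conventions, not measurements.
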