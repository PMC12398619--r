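---
title: "From TMS pulses to significant current scattering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From TMS pulses to significant current scattering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

Single-pulse TMS over the left dorsolateral prefrontal cortex (DLPFC)
evokes a stereotyped EEG response — the TMS-evoked potential (TEP) with
components P30, N45, P60, N100 and P180 — and, downstream of the stimulated
site, secondary activations in connected regions. `tepscatter` implements a
complete analysis chain for such recordings:

1. **Artifact suppression** of the raw pulse-marked EEG (pulse-window
   excision, exponential decay regression, zero-phase filtering, trial and
   channel rejection, average referencing, baseline correction).
2. **Sensor-level TEP quantification**: mean amplitudes per component
   window at an analysis electrode (F3 by default, over the stimulated
   left DLPFC).
3. **Source imaging**: an analytic three-shell spherical forward model and
   a vector LCMV beamformer give a nonnegative source strength
   `ss(x, t)` per grid voxel and time point.
4. **Permutation masking**: a max-statistic pre-vs-post permutation test
   marks voxel–time cells with reliable post-stimulus activation while
   controlling the family-wise error.
5. **Significant current scattering (SCS)**:
   `SCS(x, t) = ss(x, t) · mask(x, t) · ‖x − x_stim‖`, aggregated over
   network-node ROIs (DMN: mPFC, PCC, angular; ECN: DLPFC, PPC; SN: ACC,
   insula, amygdala) in the N100 window. SCS is a distance-weighted
   measure of how far evoked activity propagates from the stimulated site,
   and is used as an effective-connectivity score.
6. **Group statistics**: t tests, one-way ANOVA with Tukey HSD and an
   automatic Welch fallback, rank tests, Pearson chi-square, linear
   mixed-effects models and logistic regression over subject-level SCS and
   TEP tables.

Because raw clinical recordings of this kind are not publicly deposited,
the package carries a first-class synthetic cohort generator
(`simulate_cohort()`, `null_cohort()`) that produces BrainVision-format
recordings with known source circuits, realistic artifacts and clinical
covariates, so every stage can be validated against ground truth.

## The forward model

The head is a three-shell concentric sphere (brain/skull/scalp, default
radii 80/85/92 mm, conductivities 0.33/0.0042/0.33 S/m) centred at
MNI (0, −18, 15) mm so that the DLPFC stimulation target [−44, 40, 29] and
all ROI centroids fall inside the innermost shell. Surface potentials of a
current dipole are computed by Legendre expansion; per harmonic order the
radial coefficients in the three layers satisfy a 5×5 linear system
(continuity of potential and normal current at the interfaces, zero normal
current at the scalp), solved with column equilibration for numerical
stability. The series converges like `(f/R)^n` for a dipole at depth ratio
`f/R`; the default 80 terms leave a relative tail below 1e−4 for the
deepest grid used here. In the homogeneous limit the solver reproduces the
classical bounded-sphere multipole solution to machine precision (this is a
unit test), and lead-field rows are average-referenced so they sum to zero
over channels.

A template boundary-element head model is deliberately **not** shipped: it
would require external geometry files. The spherical model keeps the
package self-contained; users with a precomputed lead field can construct a
`lead_field` object directly from their own matrices, since it is a plain
list of arrays.

The bundled montage (`standard_montage()`) uses the standard 10-10
direction table for a 64-channel cap, re-projected radially onto the scalp
shell; only the angular positions carry information.

## The synthetic cohort

`circuit_spec()` places a dipole at an MNI position with a latency window,
a peak moment, and per-group multiplicative gains. Each TMS pulse triggers
a squared-sine burst inside the circuit's window, projected through the
forward model. `default_circuits()` encodes the study design the analysis
targets: local responses at the stimulated site in the early windows
(alternating polarity, giving the canonical P30–N45–P60 sequence and a
P180), and N100-window downstream circuits at mPFC, ACC, PCC, angular,
PPC and insula. The SI group's gain is elevated (default 1.5×) for the
mPFC and ACC circuits only; angular and PPC act as equal-gain negative
controls. The default stimulation protocol follows the study conditions:
100 pulses at 5 s inter-stimulus interval with ±0.1–0.2 s uniform jitter.

Noise and artifacts (`noise_spec()`): per-channel 1/f background (default
SD 3 µV), 50 Hz line noise (1.5 µV), a post-pulse exponential decay with
random per-channel sign (25 µV, τ = 120 ms), and a clipped biphasic pulse
artifact (800 µV within −2..8 ms). Ocular/muscle bursts are available
behind `burst_amp` but default to off, since ICA-class cleanup is out of
scope. Covariates are drawn per group from the clinical cohort's
distributions (e.g. age 24.7 ± 11.0 years in SI vs 34.3 ± 16.4 in NSI,
HAMD ≈ 25 in both patient groups, per-group suicide-history probabilities
and antidepressant frequencies); Gaussians are truncated at zero and HAMD
clamped to its 0–76 range.

What the generator does **not** emulate: realistic cortical geometry and
orientation maps, ocular/muscle ICA components, amplifier saturation,
electrode drift, auditory evoked potentials, or between-subject anatomical
variability beyond head-model perturbation. Passing tests therefore
validate the *pipeline machinery and its statistical calibration*, not
claims about real patients.

Determinism: every generator is a pure function of its spec and seed.
Per-subject seeds are a polynomial hash of (master seed, subject id), so
cohort composition can change without reshuffling existing subjects'
draws.

## Preprocessing choices

The stages run in this order: excision → decay regression → decimation +
filtering + epoching → trial rejection → channel interpolation → average
reference → baseline correction.

- **Pulse-window excision (−10..25 ms)** replaces samples with a
  *least-squares* cubic fitted to 8 flanking samples per side. An
  interpolating spline through noisy flanks overshoots badly in the gap
  (we measured variance inflations of 5–30× at the interpolated samples),
  which would poison every downstream variance estimate; the LS cubic
  still restores polynomial signals up to degree three exactly.
- **Decay regression** fits `b + A·exp(−t/τ)` per channel and pulse over
  25–500 ms post-pulse, profiling the linear coefficients in closed form
  and searching τ in 5–1500 ms with `optimize`. This cannot fail to
  converge; channels with fitted |A| below `decay_floor_uv` (default
  5 µV) are untouched. Only the `A·exp(−t/τ)` part is subtracted, until
  the fitted decay is negligible or the next pulse begins.
- **Filtering** uses Butterworth designs (4th-order 1–100 Hz band-pass,
  2nd-order 48–52 Hz band-stop, 8th-order anti-alias low-pass before
  integer-factor decimation) applied zero-phase: the squared magnitude
  response — mathematically the response of a forward–backward pass — is
  applied in the frequency domain across all channels at once, with
  reflection padding at the recording edges. Zero-phase filtering
  preserves TEP latencies; the frequency-domain implementation avoids
  per-channel IIR transients and is an order of magnitude faster.
- **Trial rejection** uses the per-trial peak absolute amplitude across
  channels (excluding the excised window); trials beyond
  mean + 3 SD are dropped. **Bad channels** are flagged when their median
  per-trial RMS exceeds 5× the montage median (or falls below 0.2×,
  a dead channel) and replaced by the unweighted mean of their 4 nearest
  neighbours in 3-D montage distance. Both criteria are configurable,
  since the underlying study reports neither in detail.
- **Average reference** then **baseline correction** (−550..−50 ms mean
  per channel and trial) close the chain; the package tests both
  identities and the idempotence of re-referencing.

## Beamformer

The vector LCMV filter per voxel is
`W = (LᵀC⁻¹L)⁻¹LᵀC⁻¹` with `C` the channel covariance pooled over trials
in −500..500 ms and regularized by diagonal loading at 5% of the mean
eigenvalue (average-referenced data are rank-deficient, so loading is
required; the level is exposed in `beamformer_config()`). Source strength
is the Euclidean norm of the 3-D moment time series — rotation-invariant
and nonnegative, as the SCS definition requires. Orientation pooling is
deliberately not used.

The analysis grid defaults to 8 mm spacing on the spherical brain shell
(≈ 3.9k voxels); simulation experiments in this package use 20 mm
(≈ 270 voxels) and 12 mm (≈ 1.2k) grids to keep runtimes at desk scale.
Parameter-recovery experiments never commit the inverse crime: data are
generated under a head model with radii scaled by 1.02 and electrodes
jittered by 2 mm relative to the analysis model.

## Permutation masking

For each voxel and post-stimulus time (5..500 ms), the observed statistic
is the trial-mean post strength minus the trial-mean of the
reversed-index-matched pre strength (−500..−5 ms, so the first post sample
pairs with the last pre sample). The null is built by randomly swapping
each trial's pre/post assignment — equivalently, flipping the sign of its
paired difference — and recording the maximum statistic over all tested
cells; a cell is masked when `(1 + #[max_b ≥ obs]) / (B + 1) ≤ α`. The
max-statistic construction controls the family-wise error over the whole
voxel × time family.

Samples inside the excision window are *excluded from the tested family*
(the mask is fixed at 0 there): they are interpolated, not measured, and
their distorted variance breaks the pre/post exchangeability the
permutation null needs. With this exclusion the empirical family-wise
type-I error on 200 simulated null subjects stays below the nominal 5%
(`fwer_null_experiment()`, also the package's acceptance target); without
it, essentially every null subject shows spurious "activation" at the
interpolated samples — a cautionary observation for pipelines that test
into an interpolated window.

Masks are computed per subject (subject-level SCS covariates require it);
1000 permutations at α = 0.05 are the inference defaults, 200 are used in
the desk-scale experiments.

## SCS aggregation

The stimulation target is snapped to its nearest grid voxel (bias ≤ half
the grid spacing, consistent across subjects); distances are Euclidean mm.
ROI values are **sums** of `SCS(x, t)` over member voxels and window
samples — accumulated scattering, monotone in mask inclusion — with
`aggregate = "mean"` available where ROI-size invariance matters. ROIs are
spheres (10 mm default) at approximate AAL centroids of the network nodes,
pooling left and right labels; on grids coarser than the ROI radius the
effective radius is floored at half the lattice diagonal so every node
retains at least one voxel. Users with a genuine atlas can supply their
own `roi_spec` table or construct an atlas by hand. By construction the
stimulated voxel itself contributes ≈ 0 — SCS scores propagation, not
local activation.

## Statistics

- "Wilcoxon signed-rank" applied to two independent groups is internally
  inconsistent; `wilcoxon_rank()` therefore runs the rank-sum test for
  unpaired data and offers the signed-rank variant behind `paired = TRUE`.
- The Welch fallback triggers when a Brown–Forsythe/Levene test falls
  below p = 0.05 (`oneway_anova_auto()`); a `force_welch` override exists.
- Mixed models are fitted by REML with a random subject intercept and
  Wald-z tables. With one observation per subject the residual/intercept
  variance split is not identifiable; the fit is flagged and an OLS fit of
  the same fixed effects is reported alongside, and neither is asserted to
  be "the" published model.
- Logistic regression flags complete or quasi-complete separation instead
  of failing.
- Tukey HSD pairwise p-values are reported together with unadjusted
  pairwise t tests, mirroring the convention of quoting both.
- N components have negative mean amplitudes; comparisons of "greater
  N100" can be run on magnitudes via `extract_components(...,
  magnitude = TRUE)` with the sign still reported.

## Desk-scale problem sizes

The simulation experiments bundled with the package use sizes chosen once
as a realistic desk-scale compromise, and stated here as package choices:
family-wise error calibration with 200 null subjects, 40 trials each,
20 mm grid (~270 voxels), 250 Hz analysis rate, 200 permutations;
localization with 50 placements on a 12 mm grid; cohort recovery with
20 subjects per group. The experiments shorten the inter-stimulus interval
to 2.5 s — epochs span ±0.7 s, so consecutive epochs remain fully
separated — while `cohort_spec()` defaults keep the study protocol (100
pulses, 5 s ± 0.1–0.2 s).

## Known limitations

- The spherical head model misplaces deep and frontal-pole sources
  relative to a realistic BEM; localization accuracy claims are made only
  against the model's own geometry (under deliberate perturbation).
- Centroid-sphere ROIs are a stand-in for volumetric AAL labels; absolute
  SCS magnitudes depend on ROI size and grid spacing and are only
  comparable within a fixed configuration.
- Beamformer leakage lets strong sources bleed into neighbouring ROIs
  (visible as correlated SCS between ACC and insula in the synthetic
  cohorts); the equal-gain control ROIs in the recovery experiment are
  chosen distant from the elevated circuits.
- No ocular/muscle ICA: recordings with such artifacts need external
  cleanup before `preprocess()`.
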