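---
title: "Models and methods: pRF mapping and working-memory reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pRF mapping and working-memory reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

memotopy analyses fMRI experiments in which a retinotopically organised
structure (the motivating case is the human lateral geniculate nucleus) is
first mapped with a sweeping-bar retinotopy protocol and then probed with a
memory-guided saccade (MGS) task whose mirror transformations dissociate the
remembered location from both the retinal stimulus and the upcoming saccade.
This vignette describes the models, their assumptions, the tunable
parameters, and the design decisions taken where the methodology was
genuinely open. Everything stated here is computed by the package's tests or
by `scripts/acceptance.R`; no empirical claims beyond those appear.

## The pRF forward model

Each voxel's mapping-run response is modelled as an isotropic 2D Gaussian
receptive field with centre $(x_0, y_0)$ and size $\sigma$ (degrees of
visual angle). For a binary stimulus aperture $S_t(x,y)$ the neural drive at
frame $t$ is the normalised overlap

$$d_t = \frac{\sum_{x,y} S_t(x,y)\, e^{-((x-x_0)^2+(y-y_0)^2)/2\sigma^2}}
             {\sum_{x,y} e^{-((x-x_0)^2+(y-y_0)^2)/2\sigma^2}},$$

so a full-field aperture yields unit drive regardless of $\sigma$. The drive
is convolved with a two-parameter haemodynamic response function (HRF) and
scaled linearly: amplitude and baseline are profiled out by least squares at
every stage and never enter the nonlinear search.

**HRF family.** The HRF is a difference of two gamma densities with free
time-to-peak and time-to-undershoot, fixed dispersions of 1 s each, and a
fixed undershoot ratio of 1/6. Each gamma is re-parameterised so that its
mode is exactly the named delay and its SD the dispersion. This is the
smallest standard family that exposes the two delay parameters and nothing
else. Bounds: peak in [3, 9] s, undershoot in [8, 20] s.

**Convolution convention.** Predictions assume the pre-scan drive equalled
the first frame's drive (steady state). Mapping runs start with a blank, so
this only matters for degenerate stimuli — it makes a constant stimulus map
to an exactly constant prediction, which the fitting stages treat as
degenerate rather than as an onset transient.

**Three-stage fit.** (1) A coarse grid search over a 1-degree position
lattice spanning ±16 degrees and sizes {0.5, 1, 2, 4, 8} degrees, using the
stimulus compressed to 5% of its raster by antialiased bilinear
interpolation; candidates are pre-sorted so ties resolve to the smallest
eccentricity, then size. (2) Bounded minimisation of residual error over
the two HRF delays with the pRF fixed at the grid best. (3) Bounded
quasi-Newton (L-BFGS-B) refinement of $(x_0, y_0, \sigma)$ at full stimulus
resolution. Because the HRF delay and $\sigma$ estimates are coupled,
stages (2)-(3) alternate until variance explained improves by less than
1e-5 (at most six cycles; two suffice for most voxels). On noiseless
synthetic voxels this pipeline recovers position within 0.25 degrees, size
within 10%, and $r^2 > 0.999$ (the first acceptance block).

**Downsampling note.** "Bilinear" downscaling is implemented with a
triangular kernel matched to the coarse pixel pitch (antialiased); naive
point-sampled bilinear aliases away most of an 8-degree bar at 5%
compression. On the default 101-pixel synthetic raster, 5% leaves ~6-degree
pixels — far coarser than 5% of a real projector image — so the compressed
stimulus serves only to seed the search. The agreement between compressed
and full-resolution predictions (>0.99 correlation for $\sigma \ge 1$) is
asserted at a ~2-degree effective pitch, which is what 5% of a real
mapping display leaves.

## ROI selection and retinotopic summaries

Voxels enter the ROI when they lie in the anatomical mask (an input) and
their pRF model reaches $r^2 \ge 0.1$ (configurable). The field-of-view map
assigns every visual-field coordinate the maximum over voxels of a
unit-peak Gaussian at each voxel's pRF centre and size. The
size-eccentricity analysis bins voxels into 30 equal-width eccentricity
bins and fits an ordinary least-squares line (and Pearson correlation)
through the bin means, per variance-explained threshold.

## The working-memory task and its generator

Each 22.5 s trial presents a peripheral target (eight base angles
22.5°-337.5° in 45° steps, jittered ±10°, eccentricity 9-11°), whose colour
cues one of four transformations mapping it to the MGS goal: identity,
mirror across the horizontal meridian ($\theta \mapsto -\theta$), the
vertical meridian ($\theta \mapsto 180° - \theta$), or both
($\theta \mapsto \theta + 180°$). After a 10.5 s delay the subject makes a
visually guided saccade (VGS) to an unpredictable target, then the MGS.
Runs hold 16 trials (each base angle twice); conditions are counterbalanced
so each (angle, condition) cell occurs once per pair of successive runs.

The generator adds, per voxel: a 0.3 s visual transient at target onset
tuned to the target angle; a delay boxcar from target offset to delay end
with amplitude $g_{wm}\exp(\kappa(\cos(\theta_{mgs}-c)-1))$ (a von
Mises-shaped tuning with centre $c$, by default the voxel's pRF polar
angle); and an optional 0.4 s VGS transient at delay end. All drives are
convolved with the voxel's HRF at 0.1 s resolution, sampled at TR 1.5 s
(232 volumes per run), and corrupted with AR(1) Gaussian noise plus
optional linear drift.

**Timing arithmetic.** Sixteen 22.5 s trials occupy 360 s but a 232-volume
run lasts 348 s; trials are laid back-to-back from $t = 0$ and the final
inter-trial interval is truncated by the run end (epoching returns `NA`
for the missing TRs). Analogously, four 30 s sweeps plus two 12 s blanks
occupy 144 s of a 180 s mapping run; the remainder is a trailing blank.
Neither truncation touches the analysed epochs.

**Generator defaults and what they emulate.** Noise: innovation SD 0.5
z-units, AR(1) 0.3 — strong single-run noise, chosen once as a demanding
but workable regime for single-session recovery. Tuning: $g_{wm} = 0.3$
z-units, $\kappa = 2$. This is deliberately an order of magnitude above the
~0.05 z group-level delay effects reported for subcortical structures: the
synthetic data exist to validate the machinery by parameter recovery at
desk scale (hundreds of voxels, one session), not to reproduce empirical
effect sizes. Consequently, passing tests show the pipeline is correct and
calibrated, not that any given real dataset would yield significant
reconstructions. The generator also omits motion, physiological noise,
spatial correlations between voxels, scanner drift nonlinearity, and
anatomical structure.

## Univariate delay analysis

For each trial, RF-in voxels have pRF polar angle within 30° (circular
distance) of that trial's MGS goal and RF-out voxels within 30° of the
diametrically opposite angle. The wedge half-width is configurable because
the two natural readings — "within 30° of the target" versus "a 30°-wide
wedge" (half-width 15°) — differ; the default follows the former. The
late-delay summary averages the last 3 TRs of the delay (4.5 s) for the
univariate contrast and the last 4 TRs for the encoding model; both windows
end at delay offset (10.8 s after trial onset). The pre-trial baseline is
the mean of the two TRs preceding target onset; because the task leaves no
neutral period and the data are z-scored per run, both the baseline-relative
and zero-relative versions of the one-sample test are reported.

Group-level inference resamples subjects with replacement (1,000 draws).
The reported 95% CI is the t interval using the bootstrap SE
(`mean ± t0.975,n-1 · sd(bootstrap means)`); a calibration experiment in
the acceptance suite (200 meta-replicates of a null effect with eight
subjects) shows this form near nominal coverage, while the percentile
interval — also reported — undercovers at such small n.

## The spatial inverted encoding model

Nine information channels tile polar angle. The default channel form is the
raised cosine $f_k(\theta) = (1+\cos(\theta-\phi_k))/2$, the unique
single-peaked 360°-periodic squared cosine, with centres every 40° starting
at 0° (offset configurable; results are offset-invariant). Its channel sum
is exactly 4.5 at every angle.

**A rank caveat that shapes the implementation.** The raised-cosine basis
spans only $\{1, \cos\theta, \sin\theta\}$: any channel-by-trial design
built from it has rank 3, however many trials are sampled. The
channel-weight GLM is therefore solved by SVD pseudo-inverse least squares
(`W = B C^+`, and inversion by `W^+`), which coincides with the classical
normal-equation solutions whenever the system happens to be full rank —
the exact-roundtrip oracles in the tests exercise precisely that case.
Rank checks compare the realised design rank against the basis's own
attainable rank, so under-sampled angle designs still fail loudly. A
half-rectified cosine-power alternative (`form = "rectified"`, default
power 8), which does attain rank 9, is available behind a switch.

Training uses only trials where the visual target and MGS goal coincide
(the identity condition); testing uses the transformation conditions, so a
successful reconstruction cannot be inherited from retinal stimulation.
Trials enter as delay-window means (last 4 TRs). To raise SNR, trials are
combined into 2-fold averages: pairs are drawn within (condition × MGS
base angle) cells, preserving the location counterbalance. With 10-run
sessions the cells hold five trials each, so one trial per odd cell is
dropped at random per draw; the pairing (and drop) is re-drawn on every
bootstrap iteration so all trials contribute across the 2,000-iteration
(default) bootstrap. A strict mode errors on odd cells instead.

Reconstructions $r(\theta) = \sum_k \hat c_k f_k(\theta)$ are evaluated on
a 1° grid, circularly shifted so the chosen reference (visual target, VGS
target, or MGS goal) sits at 0°, and averaged across trials.

## Fidelity and inference

The base representational fidelity is the cosine projection
$F_0 = \operatorname{mean}_\theta\, r(\theta)\cos\theta$; it scales with
reconstruction gain. The modified form first centres and normalises,
$\tilde r = (r - \bar r)/\max|r-\bar r|$, making $F$ invariant to positive
gain and additive offset — it measures whether the reconstruction is
*shaped and centred* correctly rather than how large it is. The published
modification this realises is described only by its rationale (reducing the
metric's oversensitivity to peak gain), so both forms are always computed
side by side and labelled. A constant reconstruction has undefined shape;
its modified fidelity is reported as 0 with a flag.

Permutation nulls rebuild the entire train-invert-reconstruct-align-fidelity
chain after shuffling the training-trial target labels (2,000 permutations
by default; each draws its own 2-fold pairing). Subject-level inference
compares real and null fidelity distributions with a two-sample
Kolmogorov-Smirnov test; group-level inference is a paired t test on
per-subject real-minus-permuted fidelities after the subject bootstrap.
Reference tests are one-tailed — the question is whether a representation
exists *at* the reference — matching the direction of the fidelity metric.

**Why inference defaults to the rectified basis.** A label permutation can
only destroy structure the basis can distinguish. Under the rank-3 raised
cosine every trained weight matrix is a linear map into the
$\{1,\cos,\sin\}$ subspace, and any such map sends spatially tuned test
activity to channel responses that still traverse the circle coherently —
the permutation null inherits nearly the full first-harmonic amplitude of
the data, with only its phase randomised, and the permutation test has
almost no power (each reconstruction being an exact cosine, the modified
fidelity collapses to $0.5\cos(\text{phase error})$, and the base fidelity
faces a null almost as large as the signal). The full-rank rectified basis
does not have this property: shuffled training scatters the higher
harmonics and the null contracts. The pipeline and the acceptance checks
therefore run encoding-model *inference* with `form = "rectified"`
(`run_config(basis_form = )` switches it), while the raised cosine remains
the constructor default, carrying the algebraic properties
(constant sum 4.5, closed-form channel examples) the unit oracles assert.
The statistic compared against the null is the base fidelity, which
carries the reconstruction gain; the gain-invariant form is always
computed alongside.

One structural feature of the task is visible at high SNR: on
double-mirror trials the MGS goal sits exactly 180° from the visual
target, so the visual-aligned average retains a small coherent negative
component. It is negative — never mimicking a visual representation — and
at the reference noise level it stays below the one-tailed null bound, as
in the empirical pattern.

Finally, the pRF and encoding models are cross-validated per voxel: the
tuning curve $\sum_k W_{vk} f_k(\theta)$ is peaked (ties to the smallest
angle) and compared with the pRF polar angle by the Fisher-Lee circular
correlation, restricted to voxels at least 5° eccentric because the task
stimuli are peripheral.

## Saccade scoring

The generator scatters VGS endpoints isotropically around the VGS target
and MGS endpoints around the MGS goal, with shifted log-normal reaction
times and fixation breaks injected at a stated rate. Scoring computes the
Euclidean endpoint error, the precision (mean of the SDs of radial and
tangential endpoint components within each base-angle cluster), reaction
times, and fixation-break flags from delay-period gaze excursion. Raw
velocity-based saccade detection is out of scope; trials are not excluded
for fixation breaks by default.

## Problem sizes used by the tests

The acceptance suite runs: 100 noiseless voxels for exact pRF recovery;
20 seeds × 40 voxels at the default noise for noisy recovery and the
size-eccentricity slope (64-pixel raster, the resolution also used by the
stimulus-coverage oracle), each seed a 10-run mapping session averaged
before fitting — mapping protocols repeat the identical run many times
precisely because single-run SNR biases pRF size downward, most severely
for peripheral voxels whose stimulation window is brief; 20 seeds of the reference working-memory dataset
(200 voxels, 10 runs, VGS transient on) with 500-permutation nulls for the
reconstruction pattern; 200 null-effect simulations for the RF-in/RF-out
calibration; and 200 meta-replicates for bootstrap-CI coverage. These sizes
were chosen as the smallest at which the monitored quantities are stable.

## Known limitations

* The generator's voxels are statistically independent given the ground
  truth; real fMRI noise is spatially and temporally structured beyond
  AR(1).
* The encoding model spans polar angle only; eccentricity is not a model
  dimension (matching the task, whose targets sit in a thin annulus).
* The raised-cosine basis supports only first-harmonic reconstructions by
  construction; finer angular structure requires the rectified basis.
* The pipeline assumes trial onsets on the TR grid, which the task design
  guarantees; free-timed designs would need interpolation that is not
  implemented.
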