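# memotopy

Population receptive field (pRF) mapping and spatial inverted encoding
models (IEM) for working-memory fMRI, with a ground-truth synthetic BOLD
generator so that every analysis stage is testable by parameter recovery.

## The scientific problem

Retinotopically organised visual structures — cortical maps, and
subcortical nuclei such as the lateral geniculate nucleus — can be
characterised voxel by voxel with a Gaussian pRF model: each voxel's
mapping-run BOLD signal is predicted by projecting a sweeping-bar aperture
movie onto a 2D Gaussian receptive field (centre *x₀, y₀*, size *σ*, in
degrees of visual angle) and convolving with a two-parameter haemodynamic
response function,

> drive(t) = Σ₍ₓ,ᵧ₎ S_t(x,y) · exp(−((x−x₀)² + (y−y₀)²)/2σ²) / Σ G,
> prediction = HRF ∗ drive (amplitude and baseline by least squares).

Whether such a structure also *stores* spatial working memory is tested
with a memory-guided saccade (MGS) task whose colour-cued mirror
transformations (θ → −θ, 180°−θ, θ+180°) dissociate the remembered goal
from the retinal stimulus, and whose intervening visually guided saccade
(VGS) to a random target dissociates it from motor planning. Delay-period
activity is analysed two ways:

* **Univariate**: voxels whose pRF polar angle lies within a wedge of the
  MGS goal (RF-in) versus the opposite wedge (RF-out), late-delay means,
  subject-bootstrap t tests.
* **Multivariate**: a spatial IEM with nine squared-cosine channels over
  polar angle, f_k(θ) = (1 + cos(θ − φ_k))/2. Channel weights are trained
  by GLM on trials where target and goal coincide, inverted on the
  transformation trials, and the channel-weighted reconstruction r(θ) is
  aligned to the visual, VGS, or MGS reference. Reconstructions are scored
  by representational fidelity — the cosine projection mean_θ r(θ)cos(θ) —
  in both its raw (gain-sensitive) and gain/offset-invariant forms, against
  2,000-permutation label-shuffled nulls, with Kolmogorov-Smirnov tests per
  subject and bootstrap-paired t tests at the group level. pRF and IEM
  voxel tuning are cross-validated by Fisher-Lee circular correlation.

The bundled generator simulates bar-sweep mapping runs (120 volumes,
TR 1.5 s) and WM task runs (232 volumes, 16 counterbalanced 22.5 s trials,
10.5 s delays, eight jittered target angles at 9-11° eccentricity) from
known voxel ground truth, so recovery is checkable end to end.

## Worked example

```r
library(memotopy)

voxels  <- sim_voxels(60, seed = 42)          # ground truth population
mapping <- simulate_mapping_run(voxels, mapping_design(grid_px = 64), seed = 42)
fits    <- fit_prf(preprocess_bold(mapping$bold), mapping$apertures,
                   tr = 1.5, downsample = 0.08, n_cycles = 3)
glance(fits)
#> # A tibble: 1 × 6
#>   n_voxels n_above_threshold median_r2 median_sigma median_ecc n_converged
#>      <int>             <int>     <dbl>        <dbl>      <dbl>       <int>
#> 1       60                60     0.745         1.33       6.97          58
```

All 60 voxels clear the r² ≥ 0.1 ROI threshold at the default noise level
(innovation SD 0.5 z, AR(1) 0.3); the median fitted size and eccentricity
sit in the generator's range. Reconstruction of remembered locations from
the same population:

```r
session <- simulate_wm_session(voxels, n_runs = 10, seed = 42, vgs_gain = 1)
act  <- delay_activity(session, n_tr = 4)     # last 4 delay TRs per trial
bas  <- channel_basis(form = "rectified")     # full-rank basis for inference
boot <- bootstrap_iem(act$B, act$trials, n_iter = 50, seed = 7, basis = bas)
glance(boot)
#> # A tibble: 3 × 5
#>   reference fidelity      se fidelity_base n_iter
#>   <chr>        <dbl>   <dbl>         <dbl>  <int>
#> 1 mgs         0.312  0.00135       0.0917      50
#> 2 vgs         0.312  0.0116        0.0183      50
#> 3 visual     -0.0689 0.00571      -0.00426     50

null <- permutation_null(act$B, act$trials, n_perm = 200, seed = 8, basis = bas)
quantile(null$fidelity_base[null$reference == "mgs"], 0.975)
#>      97.5%
#> 0.05405479
```

Read these against their permutation nulls, not in isolation: the
MGS-aligned base fidelity (0.092) exceeds its label-shuffled null's 97.5th
percentile (0.054) — delay activity carries the remembered goal — while
the visual- and VGS-aligned base fidelities (−0.004, 0.018) do not rise
above theirs. The gain-invariant `fidelity` column is reported alongside;
the methods vignette explains why inference uses the full-rank rectified
basis and the gain-carrying base form. `autoplot(boot)` draws the three
aligned reconstructions.

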