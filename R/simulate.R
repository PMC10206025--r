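#' Ground-truth voxel population for simulation
#'
#' Draws a tibble of simulated voxels, each with a Gaussian pRF (centre,
#' size), its own two-parameter HRF, baseline/gain, a von-Mises-shaped
#' working-memory tuning over the MGS goal angle, and noise parameters. By
#' default pRF centres are uniform in polar angle with eccentricity spread
#' over the mapped field, pRF size grows linearly with eccentricity
#' (`sigma = sigma0 + sigma_slope * ecc`), and each voxel's WM tuning centre
#' equals its pRF polar angle (`wm_consistent = TRUE`), emulating a
#' retinotopically organised population whose delay activity is tuned to the
#' remembered location.
#'
#' @param n Number of voxels.
#' @param seed Integer seed.
#' @param ecc_range Eccentricity range (deg) for pRF centres.
#' @param sigma0,sigma_slope Intercept (deg) and slope (deg/deg) of the
#'   size-eccentricity line.
#' @param hrf_peak,hrf_under Mean HRF delays (s); per-voxel values jitter
#'   around these by `hrf_jitter`.
#' @param hrf_jitter SD of the per-voxel HRF delay jitter (s).
#' @param baseline,gain Baseline and response gain in z-units.
#' @param wm_gain Delay-period tuning amplitude (z-units).
#' @param wm_kappa Tuning concentration (unitless).
#' @param wm_consistent If `TRUE` the WM tuning centre is the pRF polar
#'   angle; otherwise uniform random.
#' @param noise_sd,ar1 Default per-voxel noise SD (z-units) and AR(1)
#'   coefficient recorded alongside the truth.
#' @return A tibble of class `ground_truth` with one row per voxel:
#'   `voxel`, `x0`, `y0`, `sigma`, `polar`, `ecc`, `hrf_peak`, `hrf_under`,
#'   `baseline`, `gain`, `wm_center`, `wm_kappa`, `wm_gain`, `noise_sd`, `ar1`.
#' @export
sim_voxels <- function(n, seed = 1L, ecc_range = c(1, 12), sigma0 = 0.5,
                       sigma_slope = 0.2, hrf_peak = 5.5, hrf_under = 14,
                       hrf_jitter = 0, baseline = 0, gain = 1,
                       wm_gain = 0.3, wm_kappa = 2, wm_consistent = TRUE,
                       noise_sd = 0.5, ar1 = 0.3) {
  withr::with_seed(seed, {
    polar <- stats::runif(n, 0, 360)
    ecc <- stats::runif(n, ecc_range[1], ecc_range[2])
    gt <- tibble::tibble(
      voxel = seq_len(n),
      x0 = ecc * cos(polar * pi / 180),
      y0 = ecc * sin(polar * pi / 180),
      sigma = sigma0 + sigma_slope * ecc,
      polar = polar,
      ecc = ecc,
      hrf_peak = hrf_peak + stats::rnorm(n, 0, hrf_jitter),
      hrf_under = hrf_under + stats::rnorm(n, 0, hrf_jitter),
      baseline = baseline,
      gain = gain,
      wm_center = if (wm_consistent) polar else stats::runif(n, 0, 360),
      wm_kappa = wm_kappa,
      wm_gain = wm_gain,
      noise_sd = noise_sd,
      ar1 = ar1
    )
  })
  stopifnot(all(gt$sigma > 0), all(gt$noise_sd >= 0),
            all(gt$ar1 >= 0 & gt$ar1 < 1))
  class(gt) <- c("ground_truth", class(gt))
  gt
}

#' Noise specification for simulated runs
#'
#' AR(1) plus white Gaussian noise with an optional linear drift. Noise
#' parameters are normally per voxel; this object, when supplied, applies
#' to all voxels and overrides the per-voxel `noise_sd`/`ar1` columns.
#'
#' @param sd Innovation SD in z-units.
#' @param ar1 AR(1) coefficient in `[0, 1)`.
#' @param drift_slope Linear drift in z-units per volume.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sd = 0.5, ar1 = 0.3, drift_slope = 0) {
  stopifnot(sd >= 0, ar1 >= 0, ar1 < 1)
  structure(list(sd = sd, ar1 = ar1, drift_slope = drift_slope),
            class = "noise_spec")
}

# AR(1) Gaussian noise (per-voxel innovation sd) plus unscaled linear drift
.sim_noise <- function(n_t, n_v, sd, ar1, drift_slope) {
  sd <- rep_len(sd, n_v)
  eps <- matrix(stats::rnorm(n_t * n_v), n_t, n_v) *
    rep(sd, each = n_t)
  if (any(ar1 > 0)) {
    ar1 <- rep_len(ar1, n_v)
    for (v in seq_len(n_v)) {
      if (ar1[v] > 0) eps[, v] <- stats::filter(eps[, v], ar1[v],
                                                method = "recursive")
    }
  }
  if (any(drift_slope != 0))
    eps <- eps + outer(seq_len(n_t) - (n_t + 1) / 2, rep_len(drift_slope, n_v))
  eps
}

#' Simulate a bar-sweep mapping run
#'
#' Forward model: each voxel's noiseless signal is
#' `baseline + gain * predict_timecourse(pRF, apertures, HRF)`, to which
#' AR(1) noise and drift are added. The noiseless signal is returned so that
#' fitting stages can be tested against an exact oracle.
#'
#' @param voxels A [sim_voxels()] tibble.
#' @param design A [mapping_design()].
#' @param noise A [noise_spec()], or `NULL` to use the per-voxel
#'   `noise_sd`/`ar1` columns with zero drift.
#' @param seed Integer seed (stimulus order and noise).
#' @return A list of class `sim_run` with elements `bold`
#'   (n_vols x n_voxels), `clean` (noiseless), `apertures`, `design`,
#'   `voxels`, `tr`, `seed`.
#' @export
simulate_mapping_run <- function(voxels, design = mapping_design(),
                                 noise = NULL, seed = 1L) {
  stopifnot(inherits(voxels, "ground_truth"))
  ap <- make_mapping_stimulus(design, seed = seed)
  clean <- withr::with_seed(seed + 1L, {
    vapply(seq_len(nrow(voxels)), function(v) {
      hrf <- hrf_model(voxels$hrf_peak[v], voxels$hrf_under[v])
      p <- predict_timecourse(c(voxels$x0[v], voxels$y0[v], voxels$sigma[v]),
                              ap, hrf, tr = design$tr)
      voxels$baseline[v] + voxels$gain[v] * p
    }, numeric(design$n_vols))
  })
  sdv <- if (is.null(noise)) voxels$noise_sd else noise$sd
  arv <- if (is.null(noise)) voxels$ar1 else noise$ar1
  dr <- if (is.null(noise)) 0 else noise$drift_slope
  eps <- withr::with_seed(seed + 2L,
    .sim_noise(design$n_vols, nrow(voxels), sdv, arv, dr))
  structure(list(bold = clean + eps, clean = clean, apertures = ap,
                 design = design, voxels = voxels, tr = design$tr,
                 seed = seed),
            class = "sim_run")
}

#' Simulate a session of repeated mapping runs
#'
#' Mapping protocols repeat the same bar-sweep run many times and average
#' the (detrended, z-scored) runs before fitting, which is how the pRF
#' model reaches peripheral voxels whose stimulation window is brief. All
#' runs share one stimulus (the sweep order is drawn once from `seed`);
#' each run gets independent noise.
#'
#' @inheritParams simulate_mapping_run
#' @param n_runs Number of repeated runs to average.
#' @param preprocess Detrend and z-score each run before averaging.
#' @return A list of class `sim_run` with `bold` (the run average),
#'   `clean`, `apertures`, `design`, `voxels`, `tr`, `n_runs`, `seed`.
#' @export
simulate_mapping_session <- function(voxels, design = mapping_design(),
                                     n_runs = 10, noise = NULL, seed = 1L,
                                     preprocess = TRUE) {
  base <- simulate_mapping_run(voxels, design, noise = noise, seed = seed)
  sdv <- if (is.null(noise)) voxels$noise_sd else noise$sd
  arv <- if (is.null(noise)) voxels$ar1 else noise$ar1
  dr <- if (is.null(noise)) 0 else noise$drift_slope
  acc <- matrix(0, design$n_vols, nrow(voxels))
  for (r in seq_len(n_runs)) {
    eps <- withr::with_seed(seed + 31L * r,
      .sim_noise(design$n_vols, nrow(voxels), sdv, arv, dr))
    run <- base$clean + eps
    acc <- acc + if (preprocess) preprocess_bold(run) else run
  }
  structure(list(bold = acc / n_runs, clean = base$clean,
                 apertures = base$apertures, design = design,
                 voxels = voxels, tr = design$tr, n_runs = n_runs,
                 seed = seed),
            class = "sim_run")
}

# von-Mises-shaped spatial tuning, peak 1 at the tuning centre
.vm_tune <- function(theta, center, kappa) {
  exp(kappa * (cos((theta - center) * pi / 180) - 1))
}

#' Simulate a working-memory task run
#'
#' Forward model per voxel and trial: a brief visual transient at target
#' onset tuned to the visual-target angle, a delay-period boxcar from target
#' offset to delay end with amplitude
#' `wm_gain * exp(wm_kappa * (cos(theta_mgs - wm_center) - 1))`, and an
#' optional brief transient at the visually-guided saccade (VGS) target angle
#' at delay end. The drive is convolved with each voxel's HRF at a fine time
#' step and sampled at the TR grid; AR(1) noise and drift are then added.
#'
#' @param voxels A [sim_voxels()] tibble.
#' @param trials Trial tibble for one run (one value of `run`), from
#'   [make_wm_design()].
#' @param noise A [noise_spec()] or `NULL` (per-voxel columns).
#' @param seed Integer seed.
#' @param n_vols Number of volumes (default 232).
#' @param tr Repetition time, seconds.
#' @param vis_gain Amplitude of the visual transient (z-units, default 1).
#' @param vgs_gain Amplitude of the VGS transient (default 0; the forward
#'   pathway for the VGS epoch is not constrained by theory, so it is off
#'   unless requested).
#' @param dt Internal simulation time step, seconds.
#' @return A list of class `sim_run` with `bold`, `clean`, `trials`,
#'   `voxels`, `tr`, `n_vols`, `seed`.
#' @export
simulate_task_run <- function(voxels, trials, noise = NULL, seed = 1L,
                              n_vols = 232, tr = 1.5, vis_gain = 1,
                              vgs_gain = 0, dt = 0.1) {
  stopifnot(inherits(voxels, "ground_truth"), nrow(trials) > 0)
  if (length(unique(trials$run)) != 1)
    stop("simulate_task_run(): 'trials' must describe a single run")
  t_fine <- seq(0, (n_vols - 1) * tr + 20, by = dt)
  vol_idx <- round(((seq_len(n_vols) - 1) * tr) / dt) + 1
  nv <- nrow(voxels)
  nt <- nrow(trials)
  tt <- .trial_timing
  # per-trial boxcar indicators on the fine grid (voxel-independent)
  box <- function(t0, t1) {
    vapply(seq_len(nt), function(i)
      as.numeric(t_fine >= t0[i] & t_fine < t1[i]), numeric(length(t_fine)))
  }
  M_vis <- box(trials$t_target_on, trials$t_target_on + tt$target)
  M_dly <- box(trials$t_target_on + tt$target, trials$t_delay_end)
  M_vgs <- box(trials$t_delay_end, trials$t_delay_end + 0.4)
  # per-trial, per-voxel tuned amplitudes (trials x voxels)
  tune_at <- function(th) {
    .vm_tune(matrix(th, nt, nv),
             matrix(voxels$wm_center, nt, nv, byrow = TRUE),
             matrix(voxels$wm_kappa, nt, nv, byrow = TRUE))
  }
  drive <- M_vis %*% (vis_gain * tune_at(trials$theta_vis)) +
    M_dly %*% (tune_at(trials$theta_mgs) *
                 matrix(voxels$wm_gain, nt, nv, byrow = TRUE))
  if (vgs_gain != 0)
    drive <- drive + M_vgs %*% (vgs_gain * tune_at(trials$theta_vgs))
  # convolve per unique HRF (all voxels share one by default)
  clean <- matrix(0, n_vols, nv)
  hrf_key <- paste(voxels$hrf_peak, voxels$hrf_under)
  for (key in unique(hrf_key)) {
    idx <- which(hrf_key == key)
    hrf <- hrf_model(voxels$hrf_peak[idx[1]], voxels$hrf_under[idx[1]])
    sig <- convolve_hrf(drive[, idx, drop = FALSE], hrf, dt)
    clean[, idx] <- sig[vol_idx, , drop = FALSE] +
      matrix(voxels$baseline[idx], n_vols, length(idx), byrow = TRUE)
  }
  sdv <- if (is.null(noise)) voxels$noise_sd else noise$sd
  arv <- if (is.null(noise)) voxels$ar1 else noise$ar1
  dr <- if (is.null(noise)) 0 else noise$drift_slope
  eps <- withr::with_seed(seed, .sim_noise(n_vols, nv, sdv, arv, dr))
  structure(list(bold = clean + eps, clean = clean, trials = trials,
                 voxels = voxels, tr = tr, n_vols = n_vols, seed = seed),
            class = "sim_run")
}

#' Simulate a multi-run working-memory session
#'
#' Convenience wrapper: generates the counterbalanced design and simulates
#' every run with per-run seeds derived from `seed`.
#'
#' @inheritParams simulate_task_run
#' @param n_runs Even number of runs.
#' @param seed Session seed.
#' @return List with `runs` (list of `sim_run`), `trials` (all runs),
#'   `voxels`.
#' @export
simulate_wm_session <- function(voxels, n_runs = 10, noise = NULL, seed = 1L,
                                vis_gain = 1, vgs_gain = 0, tr = 1.5,
                                n_vols = 232) {
  trials <- make_wm_design(n_runs, seed = seed)
  runs <- purrr::map(seq_len(n_runs), function(r) {
    simulate_task_run(voxels, dplyr::filter(trials, .data$run == r),
                      noise = noise, seed = seed * 1000L + r,
                      vis_gain = vis_gain, vgs_gain = vgs_gain,
                      tr = tr, n_vols = n_vols)
  })
  list(runs = runs, trials = trials, voxels = voxels)
}

#' Simulate saccade endpoints and reaction times
#'
#' VGS endpoints scatter isotropically around the VGS target and MGS
#' endpoints around the MGS goal, both in Cartesian degrees. Reaction times
#' follow a shifted log-normal. Fixation breaks are injected at a stated
#' rate by drawing a delay-period gaze excursion beyond the break threshold.
#'
#' @param trials Trial tibble from [make_wm_design()].
#' @param endpoint_sd Isotropic endpoint SD in degrees.
#' @param rt_shift,rt_meanlog,rt_sdlog Shifted log-normal RT parameters
#'   (seconds): `rt = rt_shift + rlnorm(meanlog, sdlog)`.
#' @param break_rate Probability of a fixation break per trial.
#' @param break_threshold Gaze excursion (deg) defining a break.
#' @param seed Integer seed.
#' @return Tibble with one row per trial: endpoint coordinates for both
#'   saccades, RTs, and the delay-period maximum gaze excursion
#'   `delay_excursion` (deg from fixation).
#' @export
simulate_saccades <- function(trials, endpoint_sd = 0.8, rt_shift = 0.2,
                              rt_meanlog = log(0.15), rt_sdlog = 0.3,
                              break_rate = 0, break_threshold = 2,
                              seed = 1L) {
  stopifnot(endpoint_sd >= 0)
  n <- nrow(trials)
  withr::with_seed(seed, {
    deg2xy <- function(th, ec) cbind(ec * cos(th * pi / 180),
                                     ec * sin(th * pi / 180))
    vgs <- deg2xy(trials$theta_vgs, trials$ecc_vgs) +
      matrix(stats::rnorm(2 * n, 0, endpoint_sd), n, 2)
    mgs <- deg2xy(trials$theta_mgs, trials$ecc_mgs) +
      matrix(stats::rnorm(2 * n, 0, endpoint_sd), n, 2)
    rt_vgs <- rt_shift + stats::rlnorm(n, rt_meanlog, rt_sdlog)
    rt_mgs <- rt_shift + stats::rlnorm(n, rt_meanlog, rt_sdlog)
    broke <- stats::runif(n) < break_rate
    exc <- stats::runif(n, 0, 0.5 * break_threshold)
    exc[broke] <- break_threshold + stats::rexp(sum(broke), 1)
  })
  tibble::tibble(
    run = trials$run, trial = trials$trial,
    vgs_x = vgs[, 1], vgs_y = vgs[, 2],
    mgs_x = mgs[, 1], mgs_y = mgs[, 2],
    rt_vgs = rt_vgs, rt_mgs = rt_mgs,
    delay_excursion = exc
  )
}
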