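#' Configuration for an end-to-end reproducible run
#'
#' Collects every tunable the pipeline uses, with the package defaults:
#' TR 1.5 s, ~32 deg screen, ROI threshold `r2 >= 0.1`, 30 deg RF wedge
#' half-width, 5 deg eccentricity floor for the pRF/IEM comparison,
#' 3-TR univariate and 4-TR encoding-model delay windows, and the iteration
#' counts of the bootstrap and permutation procedures.
#'
#' @param out_dir Directory for all stage outputs.
#' @param seed Master seed; per-stage seeds derive from it.
#' @param n_voxels,n_runs Synthetic population and session size.
#' @param tr,screen_deg Acquisition/display geometry.
#' @param r2_threshold,wedge_halfwidth,ecc_min Analysis thresholds.
#' @param window_univariate,window_iem Delay-window lengths in TRs.
#' @param n_boot,n_perm Bootstrap / permutation iteration counts.
#' @param noise_sd,ar1,wm_gain,wm_kappa,vis_gain,vgs_gain Generator settings.
#' @param grid_px Aperture raster resolution.
#' @param basis_form Channel form used for encoding-model inference;
#'   `"rectified"` (full rank, default) or `"raised_cosine"`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("memotopy_run_"), seed = 1L,
                       n_voxels = 50, n_runs = 8, tr = 1.5, screen_deg = 32,
                       r2_threshold = 0.1, wedge_halfwidth = 30, ecc_min = 5,
                       window_univariate = 3, window_iem = 4,
                       n_boot = 200, n_perm = 200,
                       noise_sd = 0.5, ar1 = 0.3, wm_gain = 0.3,
                       wm_kappa = 2, vis_gain = 1, vgs_gain = 0,
                       grid_px = 101, basis_form = "rectified") {
  cfg <- as.list(environment())
  counts <- c(cfg$n_voxels, cfg$n_runs, cfg$n_boot, cfg$n_perm,
              cfg$window_univariate, cfg$window_iem)
  if (any(counts < 1)) stop("run_config(): all counts must be >= 1")
  if (cfg$n_runs %% 2 != 0) stop("run_config(): n_runs must be even")
  structure(cfg, class = "run_config")
}

.stage <- function(manifest, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$stages[[name]] <- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
  list(value = value, manifest = manifest)
}

.file_hash <- function(path) rlang::hash(readBin(path, "raw", file.size(path)))

#' Run the full pipeline: simulate, fit pRFs, delay analysis, IEM, fidelity
#'
#' Executes every stage in order against files on disk, so that the run is
#' reproducible from its manifest alone: (1) simulate a mapping run, a
#' working-memory session, and saccades, writing NIfTI volumes and events
#' TSVs to `config$out_dir`; (2) fit pRFs to the mapping run and select the
#' ROI; (3) univariate RF-in/RF-out delay analysis and saccade scoring;
#' (4) bootstrap IEM reconstruction aligned to the visual, VGS, and MGS
#' references; (5) permutation null and fidelity tests; (6) pRF-vs-IEM
#' circular correlation. A JSON manifest records the config (and its hash),
#' seeds, stage wall-times, input-file checksums, and package version.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result` with elements `fits`, `roi`,
#'   `size_ecc`, `delay`, `saccades`, `iem`, `null`, `fidelity_summary`,
#'   `circcorr`, `manifest`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "memotopy",
                   version = as.character(utils::packageVersion("memotopy")),
                   seed = config$seed,
                   config = unclass(config),
                   # hash of the scientific configuration (paths excluded)
                   config_hash = rlang::hash(unclass(config)[
                     setdiff(names(config), "out_dir")]),
                   stages = list(), inputs = list())
  paths <- list(
    mapping_bold = file.path(config$out_dir, "mapping_bold.nii.gz"),
    apertures = file.path(config$out_dir, "apertures.nii.gz"),
    events = file.path(config$out_dir, "task_events.tsv"),
    truth = file.path(config$out_dir, "ground_truth.json")
  )

  # -- stage: simulate ------------------------------------------------------
  st <- .stage(manifest, "simulate", {
    voxels <- sim_voxels(config$n_voxels, seed = config$seed,
                         wm_gain = config$wm_gain, wm_kappa = config$wm_kappa,
                         noise_sd = config$noise_sd, ar1 = config$ar1)
    mdesign <- mapping_design(screen_deg = config$screen_deg,
                              grid_px = config$grid_px, tr = config$tr)
    mrun <- simulate_mapping_run(voxels, mdesign, seed = config$seed)
    session <- simulate_wm_session(voxels, n_runs = config$n_runs,
                                   seed = config$seed + 1L,
                                   vis_gain = config$vis_gain,
                                   vgs_gain = config$vgs_gain, tr = config$tr)
    gaze <- simulate_saccades(session$trials, seed = config$seed + 2L)
    write_bold_nifti(mrun$bold, paths$mapping_bold, tr = config$tr)
    write_apertures_nifti(mrun$apertures, paths$apertures)
    write_events_tsv(session$trials, paths$events)
    jsonlite::write_json(voxels, paths$truth, digits = NA)
    for (r in seq_len(config$n_runs)) {
      write_bold_nifti(session$runs[[r]]$bold,
                       file.path(config$out_dir, sprintf("task_run%02d.nii.gz", r)),
                       tr = config$tr)
    }
    list(session = session, gaze = gaze, voxels = voxels)
  })
  manifest <- st$manifest; sim <- st$value
  for (nm in names(paths)) manifest$inputs[[nm]] <- .file_hash(paths[[nm]])

  # -- stage: fit_prf -------------------------------------------------------
  st <- .stage(manifest, "fit_prf", {
    for (p in c(paths$mapping_bold, paths$apertures))
      if (!file.exists(p)) stop("missing input file: ", p)
    bold <- read_bold_nifti(paths$mapping_bold)
    ap <- read_apertures_nifti(paths$apertures, screen_deg = config$screen_deg)
    fit_prf(preprocess_bold(bold), ap, tr = config$tr)
  })
  manifest <- st$manifest; fits <- st$value

  # -- stage: roi -----------------------------------------------------------
  st <- .stage(manifest, "roi", {
    roi <- select_roi(fits, threshold = config$r2_threshold)
    write_prf_maps(fits, config$out_dir)
    se <- tryCatch(size_ecc_analysis(roi, ve_thresholds = config$r2_threshold),
                   error = function(e) NULL)
    list(roi = roi, size_ecc = se)
  })
  manifest <- st$manifest
  roi <- st$value$roi; size_ecc <- st$value$size_ecc

  # -- stage: timecourse ----------------------------------------------------
  st <- .stage(manifest, "timecourse", {
    if (!file.exists(paths$events)) stop("missing input file: ", paths$events)
    trials <- read_events_tsv(paths$events)
    epochs <- purrr::map(seq_len(config$n_runs), function(r) {
      p <- file.path(config$out_dir, sprintf("task_run%02d.nii.gz", r))
      if (!file.exists(p)) stop("missing input file: ", p)
      bold <- preprocess_bold(read_bold_nifti(p))
      epoch_trials(bold[, roi$voxel, drop = FALSE],
                   dplyr::filter(trials, .data$run == r), tr = config$tr)
    })
    delay <- delay_timecourse(epochs, roi,
                              wedge_halfwidth = config$wedge_halfwidth,
                              tr = config$tr)
    sacc <- score_saccades(sim$gaze, trials)
    readr::write_tsv(delay$timecourse,
                     file.path(config$out_dir, "delay_timecourse.tsv"))
    readr::write_tsv(sacc$scores,
                     file.path(config$out_dir, "saccade_scores.tsv"))
    list(delay = delay, saccades = sacc)
  })
  manifest <- st$manifest
  delay <- st$value$delay; saccades <- st$value$saccades

  # -- stage: iem -----------------------------------------------------------
  st <- .stage(manifest, "iem", {
    da <- delay_activity(sim$session, n_tr = config$window_iem)
    da$B <- da$B[roi$voxel, , drop = FALSE]
    boot <- bootstrap_iem(da$B, da$trials, n_iter = config$n_boot,
                          seed = config$seed + 3L,
                          basis = channel_basis(form = config$basis_form))
    list(da = da, boot = boot)
  })
  manifest <- st$manifest
  da <- st$value$da; boot <- st$value$boot

  # -- stage: fidelity ------------------------------------------------------
  st <- .stage(manifest, "fidelity", {
    null <- permutation_null(da$B, da$trials, n_perm = config$n_perm,
                             seed = config$seed + 4L,
                             basis = channel_basis(form = config$basis_form))
    summ <- purrr::map_dfr(unique(boot$fidelity$reference), function(rf) {
      re <- boot$fidelity$fidelity[boot$fidelity$reference == rf]
      nu <- null$fidelity[null$reference == rf]
      ks <- subject_fidelity_test(re, nu)
      tibble::tibble(reference = rf, fidelity = mean(re),
                     null_mean = mean(nu),
                     null_q975 = unname(stats::quantile(nu, 0.975)),
                     ks_D = ks$D, ks_p = ks$p)
    })
    readr::write_tsv(boot$fidelity,
                     file.path(config$out_dir, "fidelity_boot.tsv"))
    readr::write_tsv(null, file.path(config$out_dir, "fidelity_null.tsv"))
    recon <- tibble::as_tibble(boot$recon)
    recon$theta <- 0:359
    readr::write_tsv(recon, file.path(config$out_dir, "reconstructions.tsv"))
    jsonlite::write_json(
      list(seed = config$seed, n_boot = config$n_boot,
           n_perm = config$n_perm, basis_form = config$basis_form,
           references = colnames(boot$recon)),
      file.path(config$out_dir, "fidelity_sidecar.json"), auto_unbox = TRUE)
    list(null = null, summary = summ)
  })
  manifest <- st$manifest
  null <- st$value$null; fidelity_summary <- st$value$summary

  # -- stage: circcorr ------------------------------------------------------
  st <- .stage(manifest, "circcorr", {
    tf <- twofold_average(da$B, da$trials, seed = config$seed + 5L)
    tr_idx <- which(tf$trials$condition == "none")
    W <- train_iem(tf$B[, tr_idx, drop = FALSE], tf$trials$theta_mgs[tr_idx],
                   basis = channel_basis(form = config$basis_form))
    peaks <- voxel_tuning_peak(W)
    tryCatch(prf_iem_circcorr(roi, peaks, ecc_min = config$ecc_min),
             error = function(e) tibble::tibble(rho = NA_real_, n_voxels = 0L))
  })
  manifest <- st$manifest; circcorr <- st$value

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  structure(list(fits = fits, roi = roi, size_ecc = size_ecc, delay = delay,
                 saccades = saccades, iem = boot, null = null,
                 fidelity_summary = fidelity_summary, circcorr = circcorr,
                 manifest = manifest, config = config),
            class = "pipeline_result")
}
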