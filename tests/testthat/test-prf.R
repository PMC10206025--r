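test_that("predicted time courses respond to aperture structure", {
  des <- tiny_design()
  ap <- make_mapping_stimulus(des, seed = 1)
  hrf <- hrf_model()
  # all-blank movie gives a flat (zero) prediction
  blank <- ap; blank[] <- 0
  attributes(blank) <- attributes(ap)
  expect_equal(predict_timecourse(c(0, 0, 2), blank, hrf),
               rep(0, des$n_vols), tolerance = 1e-12)
  # full-field aperture every frame: constant drive, flat after centring
  full <- ap; full[] <- 1
  attributes(full) <- attributes(ap)
  expect_equal(predict_timecourse(c(3, 3, 2), full, hrf),
               rep(0, des$n_vols), tolerance = 1e-10)
  # single-frame impulse covering the pRF is proportional to the HRF kernel
  imp <- ap; imp[] <- 0; imp[, , 20] <- 1
  attributes(imp) <- attributes(ap)
  p <- predict_timecourse(c(0, 0, 2), imp, hrf)
  k <- c(hrf_kernel(hrf, dt = des$tr), rep(0, des$n_vols))
  ref <- rep(0, des$n_vols); ref[20:des$n_vols] <- k[1:(des$n_vols - 19)]
  expect_gt(cor(p, ref - mean(ref)), 0.99999)
  expect_error(predict_timecourse(c(0, 0, 1), array(0, c(4, 4, 0)), hrf),
               "empty")
})

test_that("coarse grid search finds the true cell and reports signed fits", {
  des <- tiny_design(64)
  vox <- oracle_voxel(5, 0, 1)
  run <- simulate_mapping_run(vox, des, seed = 3)
  cb <- coarse_basis(run$apertures, downsample = 0.08)
  cf <- coarse_fit(run$bold[, 1], basis = cb)
  expect_lte(abs(cf$x0 - 5), 1)
  expect_lte(abs(cf$y0 - 0), 1)
  # negated series: same r2, negative amplitude
  cf_neg <- coarse_fit(-run$bold[, 1], basis = cb)
  expect_equal(cf_neg$r2, cf$r2, tolerance = 1e-12)
  expect_lt(cf_neg$amplitude, 0)
  expect_gt(cf$amplitude, 0)
  expect_error(coarse_fit(rep(1, 120), basis = cb), "degenerate")
})

test_that("downsampled and full-resolution predictions agree for sigma >= 1", {
  # at an effective pixel pitch of ~2 deg the compressed stimulus carries
  # essentially the full prediction; the default 5% compression of the
  # synthetic raster (~6 deg pixels) is used only to seed the grid search
  des <- mapping_design(grid_px = 101,
                        sweep_order = c("LR", "RL", "TB", "BT"))
  ap <- make_mapping_stimulus(des, seed = 1)
  ds <- downsample_apertures(ap, 0.15)
  hrf <- hrf_model()
  for (prf in list(c(5, 0, 1), c(-4, 3, 2), c(0, -8, 4))) {
    p_full <- predict_timecourse(prf, ap, hrf)
    p_ds <- predict_timecourse(prf, ds, hrf)
    expect_gt(cor(p_full, p_ds), 0.99)
  }
})

test_that("HRF delays are recovered from noiseless data and bounds are respected", {
  des <- tiny_design()
  vox <- oracle_voxel(4, 2, 1.5, hrf_peak = 5.5, hrf_under = 14)
  run <- simulate_mapping_run(vox, des, seed = 5)
  h <- fit_hrf(run$bold[, 1], run$apertures, c(4, 2, 1.5))
  expect_equal(h$peak, 5.5, tolerance = 0.1)
  expect_error(fit_hrf(rep(0.3, 120), run$apertures, c(4, 2, 1.5)),
               "degenerate")
  # adversarial noise-only input stays inside the boxes
  for (s in 1:3) {
    y <- withr::with_seed(s, rnorm(120))
    h <- fit_hrf(y, run$apertures, c(4, 2, 1.5))
    expect_true(h$peak >= 3 && h$peak <= 9)
    expect_true(h$under >= 8 && h$under <= 20)
  }
})

test_that("three-stage fit recovers noiseless pRFs to stated tolerance", {
  des <- tiny_design(64)
  vox <- oracle_voxel(-4, 3, 1.5)
  run <- simulate_mapping_run(vox, des, seed = 6)
  fits <- fit_prf(run, downsample = 0.08)
  expect_lt(sqrt((fits$x0 + 4)^2 + (fits$y0 - 3)^2), 0.25)
  expect_lt(abs(fits$sigma - 1.5) / 1.5, 0.1)
  expect_gt(fits$r2, 0.999)
  expect_equal(fits$polar, wrap_deg(atan2(3, -4) * 180 / pi),
               tolerance = 2)
  expect_error(fine_fit(rep(1, 120), run$apertures, c(0, 0, 1)),
               "degenerate")
})

test_that("r2 is invariant to affine rescaling of the series", {
  des <- tiny_design()
  vox <- sim_voxels(1, seed = 12)
  run <- simulate_mapping_run(vox, des, seed = 7)
  y <- run$bold[, 1]
  f1 <- fine_fit(y, run$apertures, c(round(vox$x0), round(vox$y0), 1),
                 hrf = hrf_model(5.5, 14))
  f2 <- fine_fit(3.2 * y - 5, run$apertures,
                 c(round(vox$x0), round(vox$y0), 1), hrf = hrf_model(5.5, 14))
  expect_equal(f1$r2, f2$r2, tolerance = 1e-8)
  expect_true(f1$r2 >= 0 && f1$r2 <= 1)
})

test_that("coarse-stage r2 shrinks with added noise in expectation", {
  des <- tiny_design()
  vox <- oracle_voxel(5, 2, 1.5)
  run <- simulate_mapping_run(vox, des, seed = 8)
  cb <- coarse_basis(run$apertures, downsample = 0.08)
  r2_at <- function(sd, seeds) {
    vapply(seeds, function(s) {
      y <- run$clean[, 1] + withr::with_seed(s, rnorm(120, 0, sd))
      coarse_fit(y, basis = cb)$r2
    }, numeric(1))
  }
  seeds <- 1:50
  expect_gt(mean(r2_at(0.3, seeds)), mean(r2_at(0.9, seeds)))
})

test_that("ROI selection intersects mask and threshold", {
  fits <- fake_fits(polar = runif(100, 0, 360), ecc = runif(100, 1, 12))
  fits$r2 <- c(runif(30, 0.2, 0.9), runif(70, 0, 0.09))
  roi <- select_roi(fits, threshold = 0.1)
  expect_equal(sort(roi$voxel), 1:30)
  expect_equal(nrow(select_roi(fits, threshold = 0)), 100)
  expect_warning(empty <- select_roi(fits, mask = rep(FALSE, 100)),
                 "empty ROI")
  expect_equal(nrow(empty), 0)
  # mask applies voxel-wise
  m <- rep(c(TRUE, FALSE), 50)
  expect_true(all(select_roi(fits, mask = m, threshold = 0)$voxel %% 2 == 1))
})

test_that("field-of-view map is a max over unit-peak Gaussians", {
  f1 <- fake_fits(polar = 0, ecc = 5, sigma = 2)
  fov <- estimate_fov(f1, n_grid = 65)
  expect_equal(max(fov$fov), 1, tolerance = 1e-3)
  at_peak <- fov[which.max(fov$fov), ]
  expect_equal(c(at_peak$x, at_peak$y), c(5, 0), tolerance = 0.5)
  # duplicated voxels change nothing (max is idempotent)
  f2 <- dplyr::bind_rows(f1, f1)
  expect_equal(estimate_fov(f2, n_grid = 65)$fov, fov$fov)
  # invariant under voxel permutation
  f3 <- fake_fits(polar = c(0, 120, 240), ecc = 6, sigma = c(1, 2, 3))
  expect_equal(estimate_fov(f3[3:1, ], n_grid = 33)$fov,
               estimate_fov(f3, n_grid = 33)$fov)
  expect_true(all(fov$fov >= 0 & fov$fov <= 1))
})

test_that("size-eccentricity analysis recovers a linear generating slope", {
  set.seed(13)
  ecc <- runif(400, 0.5, 12)
  fits <- fake_fits(polar = runif(400, 0, 360), ecc = ecc,
                    sigma = 0.5 + 0.2 * ecc)
  se <- size_ecc_analysis(fits, n_bins = 30, ve_thresholds = 0.1)
  expect_equal(se$summary$slope, 0.2, tolerance = 0.002)
  expect_gt(se$summary$r, 0.999)
  # constant sigma: slope 0, r reported as 0 with flag
  fc <- fake_fits(polar = runif(50, 0, 360), ecc = runif(50, 1, 10),
                  sigma = 1.5)
  sc <- size_ecc_analysis(fc, n_bins = 10)
  expect_equal(sc$summary$slope, 0)
  expect_equal(sc$summary$r, 0)
  expect_true(sc$summary$constant_sigma)
  expect_error(size_ecc_analysis(fits[1:2, ]), "fewer than 3")
})
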