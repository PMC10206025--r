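test_that("preprocessing removes linear trends and normalises to unit SD", {
  set.seed(21)
  bold <- matrix(rnorm(120 * 5), 120, 5) + outer(1:120, runif(5, -0.1, 0.1))
  z <- preprocess_bold(bold)
  expect_equal(colMeans(z), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 5), tolerance = 1e-12)
  # idempotence
  expect_equal(preprocess_bold(z), z, tolerance = 1e-9, ignore_attr = TRUE)
  # a pure line becomes all zero and is flagged
  line <- matrix(5 + 0.3 * (1:120), ncol = 1)
  zl <- preprocess_bold(line)
  expect_true(all(zl == 0))
  expect_equal(attr(zl, "flagged"), 1L)
})

test_that("epoching conserves the run series on the TR grid", {
  trials <- dplyr::filter(make_wm_design(2, seed = 2), run == 1)
  bold <- matrix(rnorm(232 * 3), 232, 3)
  ep <- epoch_trials(bold, trials, tr = 1.5, n_tr = 15)
  expect_equal(dim(ep), c(15, 3, 16))
  for (i in 1:15) { # all but the truncated final trial are complete
    expect_equal(ep[, , i], bold[(i - 1) * 15 + 1:15, ])
  }
  # truncated final trial: first 7 TRs present, rest NA
  expect_equal(ep[1:7, , 16], bold[226:232, ])
  expect_true(all(is.na(ep[8:15, , 16])))
})

test_that("delay windows end at delay offset", {
  expect_equal(delay_window(3), 5:7)   # last 4.5 s of the delay
  expect_equal(delay_window(4), 4:7)   # last four TRs of the delay
})

test_that("RF-in/RF-out wedges are disjoint and wrap correctly", {
  fits <- fake_fits(polar = c(10, 190, 45, 350), ecc = 10)
  sets <- classify_rf_voxels(fits, theta_mgs = 10)
  expect_true(1 %in% sets$rf_in)
  expect_true(2 %in% sets$rf_out)
  expect_length(intersect(sets$rf_in, sets$rf_out), 0)
  # adding full turns changes nothing
  sets2 <- classify_rf_voxels(fits, theta_mgs = 370)
  expect_identical(sets, sets2)
  # expected wedge occupancy for uniform polar angles: 2 * 60/360
  set.seed(5)
  fu <- fake_fits(polar = runif(3600, 0, 360), ecc = 10)
  s <- classify_rf_voxels(fu, theta_mgs = 123)
  expect_equal(length(s$rf_in) / 3600, 1 / 6, tolerance = 0.03)
  expect_equal(length(s$rf_out) / 3600, 1 / 6, tolerance = 0.03)
})

test_that("constant epochs give a constant trial-averaged time course", {
  trials <- dplyr::filter(make_wm_design(2, seed = 3), run == 1)[1:8, ]
  ep <- array(0.4, dim = c(15, 6, 8))
  attr(ep, "trials") <- trials
  fits <- fake_fits(polar = seq(0, 300, by = 60), ecc = 10)
  dtc <- delay_timecourse(ep, fits)
  expect_true(all(abs(dtc$timecourse$mean - 0.4) < 1e-12))
  expect_true(all(abs(dtc$trial_means$delay_mean_3tr - 0.4) < 1e-12))
})

test_that("tuned populations show RF-in above RF-out in the late delay", {
  vox <- sim_voxels(60, seed = 31, wm_gain = 0.3)
  ses <- simulate_wm_session(vox, n_runs = 4, seed = 31)
  fits <- fake_fits(polar = vox$polar, ecc = vox$ecc)
  epochs <- lapply(ses$runs, function(r)
    epoch_trials(preprocess_bold(r$bold), r$trials, tr = r$tr))
  dtc <- delay_timecourse(epochs, fits)
  tm <- tidyr::pivot_wider(dtc$trial_means,
                           id_cols = c("run", "trial"),
                           names_from = "set",
                           values_from = "delay_mean_3tr")
  d <- tm$rf_in - tm$rf_out
  tt <- t.test(d, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("group delay test degenerates and transforms correctly", {
  expect_error(group_delay_test(1), "at least 2")
  g <- group_delay_test(rep(0.3, 6), seed = 2)
  expect_equal(c(g$ci_lo, g$ci_hi), c(0.3, 0.3))
  expect_equal(c(g$ci_lo_pct, g$ci_hi_pct), c(0.3, 0.3))
  # sign flip mirrors the interval (same bootstrap seed)
  x <- c(0.1, 0.4, 0.25, 0.3, 0.18)
  a <- group_delay_test(x, seed = 5, alternative = "two.sided")
  b <- group_delay_test(-x, seed = 5, alternative = "two.sided")
  expect_equal(a$ci_lo, -b$ci_hi)
  expect_equal(a$ci_hi, -b$ci_lo)
  expect_equal(a$p_boot, b$p_boot)
})

test_that("saccade precision converges to the endpoint SD", {
  # one large cluster of endpoints with isotropic SD 1 around one target
  n <- 10000
  trials <- tibble::tibble(
    run = 1, trial = seq_len(n), base_angle = 22.5,
    theta_vis = 22.5, ecc_vis = 10, condition = "none",
    theta_mgs = 22.5, ecc_mgs = 10,
    theta_vgs = runif(n, 0, 360), ecc_vgs = runif(n, 9, 11),
    t_target_on = 0, t_delay_end = 10.8, t_feedback = 12.2,
    onset = 0, duration = 22.5)
  gaze <- simulate_saccades(trials, endpoint_sd = 1, seed = 8)
  sc <- score_saccades(gaze, trials)
  mgs <- dplyr::filter(sc$scores, type == "mgs")
  expect_equal(mean(mgs$precision), 1, tolerance = 0.05)
})
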