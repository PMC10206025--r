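theta_grid <- (0:359) * pi / 180

test_that("fidelity of cosine reconstructions matches the closed form", {
  r_cos <- cos(theta_grid)
  f <- fidelity(r_cos)
  expect_equal(f$base, 0.5, tolerance = 1e-14)
  expect_equal(f$modified, 0.5, tolerance = 1e-14)
  f180 <- fidelity(cos(theta_grid - pi))
  expect_equal(f180$modified, -0.5, tolerance = 1e-14)
  expect_equal(f180$base, -0.5, tolerance = 1e-14)
})

test_that("modified fidelity is gain- and offset-invariant; base is linear in gain", {
  r_cos <- cos(theta_grid)
  for (A in c(0.2, 1, 7)) {
    for (b in c(-3, 0, 11)) {
      f <- fidelity(A * r_cos + b)
      expect_equal(f$modified, 0.5, tolerance = 1e-12)
      expect_equal(f$base, 0.5 * A, tolerance = 1e-12)
    }
  }
  fc <- fidelity(rep(2.2, 360))
  expect_equal(fc$modified, 0)
  expect_true(fc$flag)
})

test_that("two-sample KS test matches a brute-force ECDF computation", {
  set.seed(81)
  x <- rnorm(100); y <- rnorm(100, 0.4)
  ks <- subject_fidelity_test(x, y)
  # independent oracle: maximum ECDF gap over the pooled sample points
  gaps <- vapply(c(x, y), function(t) abs(mean(x <= t) - mean(y <= t)),
                 numeric(1))
  expect_equal(ks$D, max(gaps), tolerance = 1e-12)
  # identical samples: D = 0, p = 1
  ks0 <- subject_fidelity_test(x, x)
  expect_equal(ks0$D, 0)
  expect_equal(ks0$p, 1)
  # disjoint supports: D = 1
  ks1 <- subject_fidelity_test(x, x + 100)
  expect_equal(ks1$D, 1)
})

test_that("group fidelity test is degenerate-safe and antisymmetric", {
  real <- c(0.3, 0.3, 0.3, 0.3)
  perm <- rep(0, 4)
  g <- group_fidelity_test(real, perm, seed = 3)
  expect_equal(g$p_boot, 0)
  expect_equal(g$p_raw, 0)
  # swapping real and permuted flips the statistic
  x <- c(0.2, 0.5, 0.1, 0.35, 0.42)
  y <- c(0.05, 0.1, 0.2, 0.03, 0.3)
  a <- group_fidelity_test(x, y, seed = 4, alternative = "two.sided")
  b <- group_fidelity_test(y, x, seed = 4, alternative = "two.sided")
  expect_equal(a$t_boot, -b$t_boot)
  expect_equal(a$estimate, -b$estimate)
})

test_that("voxel tuning peaks follow the weighted channel sum", {
  bas <- channel_basis()
  for (th_star in c(12, 130, 255)) {
    w <- as.numeric(channel_responses(th_star, bas))
    expect_lte(circ_dist_deg(voxel_tuning_peak(w, bas), th_star), 1)
    # adding a constant to all weights leaves the peak unchanged
    expect_equal(voxel_tuning_peak(w + 3, bas), voxel_tuning_peak(w, bas))
  }
  # one-hot weights peak at that channel's centre
  e <- rep(0, 9); e[6] <- 1
  expect_equal(voxel_tuning_peak(e, bas), bas$centers[6])
})

test_that("pRF/IEM circular correlation cross-validates voxel tuning", {
  set.seed(83)
  fits <- fake_fits(polar = runif(200, 0, 360), ecc = runif(200, 5.5, 12))
  expect_equal(prf_iem_circcorr(fits, fits$polar)$rho, 1, tolerance = 1e-10)
  # independent peaks decorrelate
  f2 <- fake_fits(polar = runif(500, 0, 360), ecc = runif(500, 6, 12))
  expect_lt(abs(prf_iem_circcorr(f2, runif(500, 0, 360))$rho), 0.1)
  # the eccentricity floor filters voxels
  f3 <- fake_fits(polar = runif(20, 0, 360), ecc = runif(20, 1, 3))
  expect_error(prf_iem_circcorr(f3, f3$polar), "fewer than 5")
})

test_that("permuting labels of untuned data leaves fidelity distributions unchanged", {
  # independent noise-only datasets, one real and one permuted fidelity each,
  # so the two samples are iid and the KS comparison is valid
  vox <- sim_voxels(15, seed = 91, wm_gain = 0)   # no spatial code at all
  draw <- function(s) {
    ses <- simulate_wm_session(vox, n_runs = 4, seed = s, vis_gain = 0)
    da <- delay_activity(ses, n_tr = 4)
    real <- bootstrap_iem(da$B, da$trials, n_iter = 1, seed = s)
    null <- permutation_null(da$B, da$trials, n_perm = 1, seed = s + 500L)
    c(real = real$fidelity$fidelity[real$fidelity$reference == "mgs"],
      null = null$fidelity[null$reference == "mgs"])
  }
  fs <- vapply(1:40, draw, numeric(2))
  expect_gt(suppressWarnings(ks.test(fs["real", ], fs["null", ]))$p.value,
            0.01)
})
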