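test_that("raised-cosine channels peak at their centres and tile to 4.5", {
  bas <- channel_basis()
  expect_equal(bas$centers, seq(0, 320, by = 40))
  f <- channel_responses(bas$centers[4], bas)
  expect_equal(f[1, 4], 1)
  expect_equal(max(f), f[1, 4])
  # diametrically opposite angle silences that channel
  f180 <- channel_responses(bas$centers[4] + 180, bas)
  expect_equal(f180[1, 4], 0, tolerance = 1e-14)
  # constant basis sum at every angle (sum of equally spaced cosines is 0)
  th <- seq(0, 359.5, by = 0.5)
  sums <- rowSums(channel_responses(th, bas))
  expect_equal(sums, rep(4.5, length(th)), tolerance = 1e-12)
  # rectified alternative also peaks at centres and vanishes opposite
  br <- channel_basis(form = "rectified", power = 8)
  fr <- channel_responses(br$centers[2], br)
  expect_equal(fr[1, 2], 1)
  expect_equal(channel_responses(br$centers[2] + 180, br)[1, 2], 0)
  expect_equal(basis_rank(channel_basis()), 3L)
  expect_equal(basis_rank(br), 9L)
})

test_that("training recovers generating weights on full-rank designs", {
  set.seed(41)
  C <- matrix(runif(9 * 24), 9, 24)
  W_true <- matrix(rnorm(50 * 9), 50, 9)
  fit <- train_iem(W_true %*% C, C)
  expect_lt(max(abs(fit$W - W_true)), 1e-10)
  # duplicating trials leaves the estimate unchanged
  fit2 <- train_iem(W_true %*% C[, c(1:24, 1:24)], C[, c(1:24, 1:24)])
  expect_equal(fit2$W, fit$W, tolerance = 1e-10)
  # fewer trials than channels
  expect_error(train_iem(W_true %*% C[, 1:8], C[, 1:8]), "fewer trials")
  # explicit rank-deficient design names the problem
  Cd <- C; Cd[5, ] <- Cd[4, ]
  expect_error(train_iem(W_true %*% Cd, Cd), "rank deficient")
  # angle-built raised-cosine designs train through the pseudo-inverse but
  # still require enough distinct angles for the basis's own rank
  expect_error(train_iem(matrix(rnorm(20 * 9), 20, 9), rep(10, 9)),
               "rank deficient")
})

test_that("inversion is exact on noiseless full-rank systems and unbiased under noise", {
  set.seed(42)
  W <- matrix(rnorm(60 * 9), 60, 9)
  cc <- runif(9)
  expect_lt(max(abs(invert_iem(W, W %*% cc) - cc)), 1e-10)
  expect_equal(as.vector(invert_iem(W, matrix(0, 60, 2))),
               rep(0, 18))
  # E[c_hat] = c under additive voxel noise
  chat <- replicate(300, invert_iem(W, W %*% cc + rnorm(60, 0, 0.5)))
  bias <- rowMeans(chat) - cc
  se <- apply(chat, 1, sd) / sqrt(300)
  expect_true(all(abs(bias) < 4 * se + 1e-8))
})

test_that("reconstruction peaks at the encoded angle and respects structure", {
  bas <- channel_basis()
  for (th_star in c(0, 37, 200, 311)) {
    rec <- reconstruct(as.numeric(channel_responses(th_star, bas)), bas)
    expect_lte(circ_dist_deg(rec$theta[which.max(rec$r)], th_star), 1)
  }
  # uniform channel responses give a constant reconstruction
  rec_u <- reconstruct(rep(0.7, 9), bas)
  expect_lt(diff(range(rec_u$r)), 1e-12)
  # a one-hot channel reproduces that channel's tuning curve
  e4 <- rep(0, 9); e4[4] <- 1
  rec_e <- reconstruct(e4, bas)
  expect_equal(as.vector(rec_e$r),
               as.vector(channel_responses(0:359, bas)[, 4]))
  # adding a constant to all channels shifts r by a constant (basis-sum 4.5)
  rec_c <- reconstruct(e4 + 2, bas)
  expect_equal(as.vector(rec_c$r - rec_e$r), rep(9, 360), tolerance = 1e-12)
})

test_that("alignment rotates the reference to zero and inverts cleanly", {
  bas <- channel_basis()
  rec <- reconstruct(as.numeric(channel_responses(123, bas)), bas)
  expect_equal(align_recon(rec, 0)$r, rec$r)
  al <- align_recon(rec, 123)
  expect_equal(al$r[1, 1], max(al$r))
  # aligning a multi-trial reconstruction applies per-trial shifts
  C2 <- t(channel_responses(c(45, 290), bas))
  rec2 <- reconstruct(C2, bas)
  al2 <- align_recon(rec2, c(45, 290))
  expect_equal(which.max(al2$r[, 1]), 1)
  expect_equal(which.max(al2$r[, 2]), 1)
})

test_that("two-fold averaging halves counterbalanced designs and preserves cells", {
  vox <- sim_voxels(5, seed = 51, noise_sd = 0)
  ses <- simulate_wm_session(vox, n_runs = 8, seed = 51)
  da <- delay_activity(ses, n_tr = 4, preprocess = FALSE)
  tf <- twofold_average(da$B, da$trials, seed = 1)
  expect_equal(ncol(tf$B), 64)  # 128 trials -> 64 pseudo-trials
  # location histogram stays uniform and conditions stay balanced
  expect_true(all(table(tf$trials$base_angle) == 8))
  expect_true(all(table(tf$trials$condition) == 16))
  # paired trials share condition and MGS base angle (within jitter)
  expect_true(all(circ_dist_deg(tf$trials$theta_mgs,
                                transform_target(tf$trials$base_angle,
                                                 tf$trials$condition)) <= 10))
  # averaging two identical trials reproduces either one
  Bdup <- da$B[, rep(1, ncol(da$B))]
  trdup <- da$trials[rep(1, nrow(da$trials)), ]
  tfd <- twofold_average(Bdup, trdup, seed = 3)
  expect_true(all(apply(tfd$B, 2, function(col) all(col == da$B[, 1]))))
  # odd cells error under strict mode (10 runs -> 5 per cell)
  ses10 <- simulate_wm_session(sim_voxels(3, seed = 5), n_runs = 10, seed = 5)
  da10 <- delay_activity(ses10, n_tr = 4, preprocess = FALSE)
  expect_error(twofold_average(da10$B, da10$trials, odd = "error"),
               "odd trial count")
  # default drops one trial per odd cell
  tf10 <- twofold_average(da10$B, da10$trials, seed = 2)
  expect_equal(ncol(tf10$B), 64)
})

test_that("pseudo-trial noise shrinks by sqrt(2)", {
  trials <- make_wm_design(8, seed = 6)
  set.seed(60)
  sds <- replicate(40, {
    B <- matrix(rnorm(4 * nrow(trials)), 4, nrow(trials))
    tf <- twofold_average(B, trials, seed = sample.int(1e6, 1))
    sd(tf$B)
  })
  expect_equal(mean(sds), 1 / sqrt(2), tolerance = 0.02)
})

test_that("bootstrap pipeline is seed-reproducible", {
  # 8 runs -> 4 trials per cell, so the two-fold pairing actually varies
  vox <- sim_voxels(30, seed = 71)
  ses <- simulate_wm_session(vox, n_runs = 8, seed = 71)
  da <- delay_activity(ses, n_tr = 4)
  b1 <- bootstrap_iem(da$B, da$trials, n_iter = 1, seed = 9)
  b2 <- bootstrap_iem(da$B, da$trials, n_iter = 1, seed = 9)
  expect_identical(b1$fidelity, b2$fidelity)
  # two disjoint seeds give statistically indistinguishable mean fidelity
  # (the VGS reference, whose fidelity varies freely across pairings)
  b3 <- bootstrap_iem(da$B, da$trials, n_iter = 40, seed = 1000)
  b4 <- bootstrap_iem(da$B, da$trials, n_iter = 40, seed = 2000)
  f3 <- b3$fidelity$fidelity[b3$fidelity$reference == "vgs"]
  f4 <- b4$fidelity$fidelity[b4$fidelity$reference == "vgs"]
  expect_gt(t.test(f3, f4)$p.value, 0.01)
})
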