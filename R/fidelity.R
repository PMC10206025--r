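#' Representational fidelity of an aligned reconstruction
#'
#' The base form projects the aligned reconstruction onto a cosine centred
#' at 0 degrees: `F0 = mean_theta r(theta) * cos(theta)`; it grows linearly
#' with reconstruction gain. The modified form first removes the
#' reconstruction's mean and normalises by its maximum absolute deviation,
#' `r_tilde = (r - mean r) / max|r - mean r|`, making the metric invariant
#' to positive gain and additive offset and hence sensitive to tuning shape
#' and centring rather than amplitude. A constant reconstruction has no
#' shape; its modified fidelity is returned as 0 with `flag = TRUE`.
#'
#' @param r Aligned reconstruction sampled on the 1-degree grid (length-360
#'   numeric), or an `iem_recon` (its trial mean is used).
#' @return List: `base`, `modified`, `flag` (constant input).
#' @export
fidelity <- function(r) {
  if (inherits(r, "iem_recon")) r <- recon_mean(r)
  stopifnot(length(r) == 360)
  theta <- (0:359) * pi / 180
  base <- mean(r * cos(theta))
  dev <- r - mean(r)
  mx <- max(abs(dev))
  if (mx < .Machine$double.eps * 360) {
    return(list(base = base, modified = 0, flag = TRUE))
  }
  list(base = base, modified = mean(dev / mx * cos(theta)), flag = FALSE)
}

#' Permutation null distribution of fidelity
#'
#' Re-runs the full train-invert-reconstruct-align-fidelity pipeline
#' `n_perm` times after shuffling the training-trial target labels, yielding
#' the fidelity distribution expected when the training data carry no
#' consistent spatial code. Each permutation draws its own two-fold pairing,
#' mirroring the bootstrap of the unpermuted pipeline.
#'
#' @inheritParams bootstrap_iem
#' @param n_perm Number of permutations (default 2000).
#' @return Tibble: `perm`, `reference`, `fidelity`, `fidelity_base`.
#' @export
permutation_null <- function(B, trials, n_perm = 2000, seed = 1L,
                             basis = channel_basis(),
                             references = c("visual", "vgs", "mgs")) {
  ref_col <- c(visual = "theta_vis", vgs = "theta_vgs", mgs = "theta_mgs")
  fmod <- fbase <- matrix(NA_real_, n_perm, length(references),
                          dimnames = list(NULL, references))
  for (pm in seq_len(n_perm)) {
    tf <- twofold_average(B, trials, seed = seed + 7000L + pm)
    tr_idx <- which(tf$trials$condition == "none")
    te_idx <- which(tf$trials$condition != "none")
    shuffled <- withr::with_seed(seed + 14000L + pm,
                                 sample(tf$trials$theta_mgs[tr_idx]))
    W <- train_iem(tf$B[, tr_idx, drop = FALSE], shuffled, basis)
    chat <- invert_iem(W, tf$B[, te_idx, drop = FALSE])
    rec <- reconstruct(chat, basis)
    for (rf in references) {
      al <- align_recon(rec, tf$trials[[ref_col[[rf]]]][te_idx], rf)
      f <- fidelity(recon_mean(al))
      fmod[pm, rf] <- f$modified
      fbase[pm, rf] <- f$base
    }
  }
  tibble::tibble(
    perm = rep(seq_len(n_perm), times = length(references)),
    reference = rep(references, each = n_perm),
    fidelity = as.vector(fmod),
    fidelity_base = as.vector(fbase))
}

#' Subject-level Kolmogorov-Smirnov test
#'
#' Compares the bootstrap distribution of real fidelities with the
#' permutation null for one subject using the two-sample KS test.
#'
#' @param real Numeric vector of fidelities from the unpermuted pipeline.
#' @param null Numeric vector of permutation-null fidelities.
#' @return One-row tibble: `D`, `p`, `n_real`, `n_null`.
#' @export
subject_fidelity_test <- function(real, null) {
  ks <- suppressWarnings(stats::ks.test(real, null))
  tibble::tibble(D = unname(ks$statistic), p = ks$p.value,
                 n_real = length(real), n_null = length(null))
}

#' Group-level paired fidelity test with subject bootstrap
#'
#' Paired version of [group_delay_test()]: tests the per-subject differences
#' between real and permuted mean fidelity with a subject bootstrap.
#'
#' @param real,permuted Numeric vectors of per-subject mean fidelities
#'   (paired).
#' @param n_boot Bootstrap iterations.
#' @param seed Integer seed.
#' @param alternative Passed to [group_delay_test()].
#' @return The one-row tibble of [group_delay_test()] on the paired
#'   differences.
#' @export
group_fidelity_test <- function(real, permuted, n_boot = 1000, seed = 1L,
                                alternative = "greater") {
  stopifnot(length(real) == length(permuted))
  group_delay_test(real - permuted, n_boot = n_boot, seed = seed,
                   alternative = alternative)
}

#' Per-voxel polar-angle tuning peak from encoding weights
#'
#' Sums the channel tuning functions weighted by a voxel's fitted
#' regression coefficients and returns the angle (on the 1-degree grid)
#' where the resulting tuning curve peaks; ties resolve to the smallest
#' angle. Because the raised-cosine basis sums to a constant, adding the
#' same value to every weight does not move the peak.
#'
#' @param weights An `iem_weights` object or a voxel-by-channel matrix.
#' @param basis A [channel_basis()] (taken from `weights` when available).
#' @return Numeric vector of peak angles in degrees, one per voxel.
#' @export
voxel_tuning_peak <- function(weights, basis = NULL) {
  if (inherits(weights, "iem_weights")) {
    basis <- basis %||% weights$basis
    W <- weights$W
  } else W <- weights
  basis <- basis %||% channel_basis()
  if (!is.matrix(W)) W <- matrix(W, nrow = 1)
  theta <- 0:359
  curves <- channel_responses(theta, basis) %*% t(W)  # 360 x voxels
  theta[apply(curves, 2, which.max)]
}

#' Circular correlation between pRF angles and encoding-model tuning peaks
#'
#' Cross-validates the two voxel-tuning models: restricts to voxels whose
#' pRF centres are at least `ecc_min` degrees eccentric (the task stimuli
#' are peripheral) and computes the Fisher-Lee circular correlation between
#' pRF polar angle and the tuning-curve peak.
#'
#' @param fits A `prf_fit` tibble (needs `polar`, `ecc`).
#' @param peaks Tuning peaks in degrees, aligned with the rows of `fits`.
#' @param ecc_min Minimum pRF eccentricity in degrees.
#' @return One-row tibble: `rho`, `n_voxels`.
#' @export
prf_iem_circcorr <- function(fits, peaks, ecc_min = 5) {
  stopifnot(length(peaks) == nrow(fits))
  keep <- fits$ecc >= ecc_min
  if (sum(keep) < 5)
    stop("prf_iem_circcorr(): fewer than 5 voxels with ecc >= ", ecc_min)
  tibble::tibble(rho = circ_corr(fits$polar[keep], peaks[keep]),
                 n_voxels = sum(keep))
}
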