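#' Squared-cosine channel basis over polar angle
#'
#' Nine information channels tile the polar-angle circle, each a squared
#' one-dimensional cosine centred at one of nine equally spaced angles. The
#' default ("raised cosine") form is
#' `f_k(theta) = cos^2((theta - phi_k)/2) = (1 + cos(theta - phi_k))/2`,
#' the unique single-peaked 360-degree-periodic squared cosine; its sum over
#' channels is constant (`n_channels / 2`) at every angle. A half-rectified
#' power-cosine alternative is available.
#'
#' @param n_channels Number of channels (default 9).
#' @param offset Centre of the first channel in degrees (default 0).
#' @param form `"raised_cosine"` (default) or `"rectified"`
#'   (`max(0, cos(delta))^power`).
#' @param power Exponent for the rectified form.
#' @return Object of class `channel_basis` with fields `centers` (deg),
#'   `form`, `power`, `n_channels`.
#' @export
channel_basis <- function(n_channels = 9, offset = 0,
                          form = c("raised_cosine", "rectified"), power = 8) {
  form <- match.arg(form)
  structure(list(n_channels = as.integer(n_channels),
                 centers = wrap_deg(offset + (seq_len(n_channels) - 1) *
                                      360 / n_channels),
                 form = form, power = power),
            class = "channel_basis")
}

#' Evaluate channel tuning functions
#'
#' @param theta Angles in degrees (vector).
#' @param basis A [channel_basis()].
#' @return Matrix `length(theta) x n_channels` of channel responses.
#' @export
channel_responses <- function(theta, basis = channel_basis()) {
  d <- outer(theta, basis$centers, `-`) * pi / 180
  switch(basis$form,
         raised_cosine = (1 + cos(d)) / 2,
         rectified = {
           cd <- cos(d)
           cd[cd < 0] <- 0
           cd^basis$power
         })
}

# Moore-Penrose pseudo-inverse via SVD
.pinv <- function(M, tol = NULL) {
  sv <- svd(M)
  tol <- tol %||% (max(dim(M)) * .Machine$double.eps * max(sv$d, 0))
  pos <- sv$d > tol
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Attainable rank of a channel basis
#'
#' The raised-cosine form spans only the constant and first circular
#' harmonics, so designs built from it have rank at most 3 however many
#' trials are sampled; the rectified power form attains the full channel
#' count.
#'
#' @param basis A [channel_basis()].
#' @return Integer rank.
#' @export
basis_rank <- function(basis) {
  qr(channel_responses(seq(0, 359, by = 3), basis))$rank
}

#' Train encoding-model weights by per-voxel least squares
#'
#' Fits the general linear model `B = W C` with `B` the voxel-by-trial
#' activity and `C` the channel-by-trial design (channel responses at each
#' trial's angle). The solution is the minimum-norm least-squares estimate
#' `W = B C^+` (SVD pseudo-inverse), which coincides with
#' `B C' (C C')^-1` whenever `C` has full row rank. The raised-cosine basis
#' is intrinsically rank 3 (see [basis_rank()]), so the pseudo-inverse is
#' the GLM solution appropriate to it; the design is still required to
#' attain the basis's own rank, i.e. to sample enough distinct angles.
#'
#' @param B Voxel-by-trial activity matrix (training trials only).
#' @param C Channel-by-trial design matrix, or a vector of trial angles
#'   (degrees) from which the design is built with `basis`. A matrix given
#'   directly is required to have full row rank.
#' @param basis A [channel_basis()], used when `C` is an angle vector.
#' @return Object of class `iem_weights`: `W` (voxel x channel), `basis`.
#' @export
train_iem <- function(B, C, basis = channel_basis()) {
  from_angles <- !is.matrix(C)
  if (from_angles) C <- t(channel_responses(C, basis))
  stopifnot(ncol(B) == ncol(C))
  required <- if (from_angles) min(basis_rank(basis), nrow(C)) else nrow(C)
  if (ncol(C) < required)
    stop("train_iem(): fewer trials (", ncol(C),
         ") than identifiable channels (", required, ")")
  qrC <- qr(t(C))
  if (qrC$rank < required) {
    deficient <- setdiff(seq_len(nrow(C)), sort(qrC$pivot[seq_len(qrC$rank)]))
    stop("train_iem(): channel design is rank deficient (rank ", qrC$rank,
         " < ", required, "); unidentified channel(s): ",
         paste(deficient, collapse = ", "))
  }
  W <- B %*% .pinv(C)
  structure(list(W = W, basis = basis), class = "iem_weights")
}

#' Invert trained weights on held-out activity
#'
#' Estimates channel responses for each test trial by least squares through
#' the trained weights: `c_hat = (W'W)^-1 W' B_test` when `W` has full
#' column rank, and the minimum-norm pseudo-inverse solution
#' `c_hat = W^+ B_test` otherwise (the raised-cosine basis yields rank-3
#' weight matrices by construction).
#'
#' @param weights An [train_iem()] object (or a plain voxel x channel matrix).
#' @param B_test Voxel-by-trial activity matrix of held-out trials.
#' @return Channel-by-trial matrix of estimated channel responses.
#' @export
invert_iem <- function(weights, B_test) {
  W <- if (inherits(weights, "iem_weights")) weights$W else weights
  if (!is.matrix(B_test)) B_test <- matrix(B_test, ncol = 1)
  stopifnot(nrow(B_test) == nrow(W))
  .pinv(W) %*% B_test
}

#' Reconstruct the population representation over polar angle
#'
#' Averages the channel tuning functions weighted by the estimated channel
#' responses, sampled on a 1-degree grid:
#' `r(theta) = sum_k c_hat_k f_k(theta)`.
#'
#' @param chan Channel-response vector (one trial) or channel-by-trial
#'   matrix.
#' @param basis A [channel_basis()].
#' @return Object of class `iem_recon`: tibble with `theta` (0..359) and one
#'   `r` column per trial (named `r` for a single trial), plus attribute
#'   `reference = "none"`.
#' @export
reconstruct <- function(chan, basis = channel_basis()) {
  if (!is.matrix(chan)) chan <- matrix(chan, ncol = 1)
  theta <- 0:359
  Fm <- channel_responses(theta, basis)   # 360 x K
  R <- Fm %*% chan                         # 360 x n_trials
  structure(list(theta = theta, r = R, basis = basis, reference = "none",
                 aligned = FALSE),
            class = "iem_recon")
}

#' Align reconstructions to a reference angle
#'
#' Circularly shifts each reconstruction (to the nearest degree) so that its
#' reference angle maps to 0 degrees; trial-averaging is meaningful only
#' after alignment.
#'
#' @param recon An `iem_recon` object.
#' @param reference_theta Reference angle(s) in degrees, one per trial
#'   (recycled).
#' @param reference Label for the reference (`"visual"`, `"vgs"`, `"mgs"`,
#'   or free text).
#' @return An aligned `iem_recon`.
#' @export
align_recon <- function(recon, reference_theta, reference = "mgs") {
  stopifnot(inherits(recon, "iem_recon"))
  n <- ncol(recon$r)
  reference_theta <- rep_len(reference_theta, n)
  shift <- round(wrap_deg(reference_theta)) %% 360
  idx <- (outer(recon$theta, shift, `+`) %% 360) + 1          # 360 x n
  R <- matrix(recon$r[as.vector(idx) +
                        rep((seq_len(n) - 1) * 360, each = 360)],
              360, n)
  structure(list(theta = recon$theta, r = R, basis = recon$basis,
                 reference = reference, aligned = TRUE),
            class = "iem_recon")
}

#' Mean aligned reconstruction
#'
#' @param recon An `iem_recon`.
#' @return Numeric vector of length 360 (mean over trials).
#' @export
recon_mean <- function(recon) rowMeans(recon$r)

#' Two-fold trial averaging
#'
#' Pairs trials within each (condition x MGS base angle) cell and averages
#' the paired activity, halving the trial count while preserving the
#' counterbalancing of exemplars across memory locations. The pairing is
#' seed-determined and is meant to be re-drawn across bootstrap iterations.
#' Cells with an odd trial count drop one random trial for this draw by
#' default (`odd = "drop"`); `odd = "error"` enforces strictly even cells.
#'
#' @param B Voxel-by-trial activity matrix.
#' @param trials Trial tibble aligned with the columns of `B` (needs
#'   `condition`, `base_angle`, `theta_mgs`, `theta_vis`, `theta_vgs`).
#' @param seed Integer seed for the pairing.
#' @param odd `"drop"` or `"error"`.
#' @return List: `B` (voxel x pseudo-trial), `trials` (pseudo-trial tibble
#'   with circular-mean angles of each pair).
#' @export
twofold_average <- function(B, trials, seed = 1L, odd = c("drop", "error")) {
  odd <- match.arg(odd)
  stopifnot(ncol(B) == nrow(trials))
  # base angles sit at 22.5 + 45k and jitter is +/-10, so the 45-degree bin
  # starting at 45k uniquely recovers each trial's MGS base angle
  mgs_base <- wrap_deg(floor(wrap_deg(trials$theta_mgs) / 45) * 45 + 22.5)
  cells <- split(seq_len(nrow(trials)),
                 paste(trials$condition, mgs_base, sep = "/"))
  if (odd == "error" && any(lengths(cells) %% 2 == 1))
    stop("twofold_average(): odd trial count in a condition x location cell")
  idx <- withr::with_seed(seed, {
    unlist(lapply(cells, function(ix) {
      if (length(ix) %% 2 == 1) ix <- ix[-sample.int(length(ix), 1)]
      if (!length(ix)) return(integer(0))
      sample(ix)
    }), use.names = FALSE)
  })
  p1 <- idx[seq(1, length(idx), by = 2)]
  p2 <- idx[seq(2, length(idx), by = 2)]
  pair_mean <- function(th) {
    rad <- th * pi / 180
    wrap_deg(atan2(sin(rad[p1]) + sin(rad[p2]),
                   cos(rad[p1]) + cos(rad[p2])) * 180 / pi)
  }
  list(B = (B[, p1, drop = FALSE] + B[, p2, drop = FALSE]) / 2,
       trials = tibble::tibble(
         condition = trials$condition[p1],
         base_angle = trials$base_angle[p1],
         theta_mgs = pair_mean(trials$theta_mgs),
         theta_vis = pair_mean(trials$theta_vis),
         theta_vgs = pair_mean(trials$theta_vgs),
         n_trials = 2L))
}

#' Delay-window activity matrix for the encoding model
#'
#' Averages each voxel's epoched activity over the last `n_tr` TRs of the
#' delay (default 4) for every trial, across runs.
#'
#' @param session Output of [simulate_wm_session()] (or a list with `runs`
#'   of `sim_run` objects and `trials`), or a list of epoch arrays.
#' @param n_tr Delay-window length in TRs.
#' @param preprocess Detrend + z-score each run first (default `TRUE`).
#' @return List: `B` (voxel x trial matrix), `trials` (tibble, all runs).
#' @export
delay_activity <- function(session, n_tr = 4, preprocess = TRUE) {
  runs <- session$runs
  w <- delay_window(n_tr, runs[[1]]$tr)
  out <- purrr::map(runs, function(run) {
    bold <- if (preprocess) preprocess_bold(run$bold) else run$bold
    ep <- epoch_trials(bold, run$trials, tr = run$tr)
    B <- vapply(seq_len(dim(ep)[3]),
                function(i) colMeans(ep[w, , i, drop = FALSE][, , 1, drop = TRUE],
                                     na.rm = TRUE),
                numeric(dim(ep)[2]))
    list(B = B, trials = run$trials)
  })
  list(B = do.call(cbind, purrr::map(out, "B")),
       trials = dplyr::bind_rows(purrr::map(out, "trials")))
}

#' Bootstrap the IEM training/reconstruction pipeline
#'
#' Each iteration re-draws the two-fold pairing, trains the encoding model
#' on same-location pseudo-trials (condition `"none"`), inverts it on the
#' transformation pseudo-trials, reconstructs, aligns to each requested
#' reference, and records the mean aligned reconstruction and its fidelity
#' (both base and modified forms).
#'
#' @param B Voxel-by-trial delay activity, see [delay_activity()].
#' @param trials Trial tibble aligned with `B`.
#' @param n_iter Bootstrap iterations (default 2000).
#' @param seed Integer seed.
#' @param basis A [channel_basis()].
#' @param references Which references to align to.
#' @return A list of class `iem_boot`: `fidelity` (tibble: `iter`,
#'   `reference`, `fidelity`, `fidelity_base`), `recon` (mean aligned
#'   reconstruction per reference, averaged over iterations; 360 x
#'   n_references matrix), `basis`, `n_iter`.
#' @export
bootstrap_iem <- function(B, trials, n_iter = 2000, seed = 1L,
                          basis = channel_basis(),
                          references = c("visual", "vgs", "mgs")) {
  ref_col <- c(visual = "theta_vis", vgs = "theta_vgs", mgs = "theta_mgs")
  stopifnot(all(references %in% names(ref_col)))
  acc <- matrix(0, 360, length(references),
                dimnames = list(NULL, references))
  fmod <- fbase <- matrix(NA_real_, n_iter, length(references),
                          dimnames = list(NULL, references))
  for (it in seq_len(n_iter)) {
    tf <- twofold_average(B, trials, seed = seed + it)
    tr_idx <- which(tf$trials$condition == "none")
    te_idx <- which(tf$trials$condition != "none")
    W <- train_iem(tf$B[, tr_idx, drop = FALSE],
                   tf$trials$theta_mgs[tr_idx], basis)
    chat <- invert_iem(W, tf$B[, te_idx, drop = FALSE])
    rec <- reconstruct(chat, basis)
    for (rf in references) {
      al <- align_recon(rec, tf$trials[[ref_col[[rf]]]][te_idx], rf)
      m <- recon_mean(al)
      acc[, rf] <- acc[, rf] + m
      f <- fidelity(m)
      fmod[it, rf] <- f$modified
      fbase[it, rf] <- f$base
    }
  }
  fid <- tibble::tibble(
    iter = rep(seq_len(n_iter), times = length(references)),
    reference = rep(references, each = n_iter),
    fidelity = as.vector(fmod),
    fidelity_base = as.vector(fbase))
  structure(list(fidelity = fid,
                 recon = acc / n_iter, basis = basis, n_iter = n_iter,
                 seed = seed),
            class = "iem_boot")
}
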