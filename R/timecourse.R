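#' Detrend and z-score a run
#'
#' Per voxel and run: removes the least-squares linear trend over time and
#' divides by the residual SD, so every voxel leaves with mean 0 and SD 1.
#' Zero-variance voxels are returned as all-zero and flagged in the
#' `flagged` attribute for downstream exclusion.
#'
#' @param bold Time-by-voxel matrix.
#' @return Matrix of the same shape with attribute `flagged` (integer voxel
#'   indices with no residual variance).
#' @export
preprocess_bold <- function(bold) {
  bold <- as.matrix(bold)
  n_t <- nrow(bold)
  t <- seq_len(n_t)
  X <- cbind(1, t - mean(t))
  # residuals of OLS on [1, t] for all voxels at once
  beta <- solve(crossprod(X), crossprod(X, bold))
  res <- bold - X %*% beta
  s <- sqrt(colSums(res^2) / (n_t - 1))
  flagged <- which(s < 1e-12)
  s[s < 1e-12] <- 1
  out <- sweep(res, 2, s, `/`)
  out[, flagged] <- 0
  attr(out, "flagged") <- flagged
  out
}

#' Epoch a task run into trials
#'
#' Cuts the run into fixed-length trial epochs on the TR grid. Trial onsets
#' in this task fall exactly on TR boundaries; TRs past the end of the run
#' (the truncated final inter-trial interval) are returned as `NA`.
#'
#' @param bold Time-by-voxel matrix for one run.
#' @param trials Trial tibble for that run.
#' @param tr Repetition time in seconds.
#' @param n_tr Epoch length in TRs (default 15 = 22.5 s).
#' @return A 3D array `n_tr x n_voxels x n_trials` with attribute
#'   `trials`.
#' @export
epoch_trials <- function(bold, trials, tr = 1.5, n_tr = 15) {
  bold <- as.matrix(bold)
  n_t <- nrow(bold)
  out <- array(NA_real_, dim = c(n_tr, ncol(bold), nrow(trials)))
  for (i in seq_len(nrow(trials))) {
    start <- round(trials$onset[i] / tr) + 1
    idx <- start:(start + n_tr - 1)
    keep <- idx <= n_t & idx >= 1
    out[which(keep), , i] <- bold[idx[keep], , drop = FALSE]
  }
  attr(out, "trials") <- trials
  attr(out, "tr") <- tr
  out
}

#' TR indices of the late-delay window
#'
#' The delay ends 10.8 s after trial onset (0.3 s target + 10.5 s delay);
#' the window is the last `n_tr` TRs wholly inside the delay, i.e. ending at
#' delay offset. `n_tr = 3` (4.5 s) is the univariate default; `n_tr = 4`
#' (6 s) is the encoding-model default.
#'
#' @param n_tr Window length in TRs.
#' @param tr Repetition time in seconds.
#' @param delay_offset Delay end relative to trial onset, in seconds.
#' @return Integer TR indices within the epoch (1-based).
#' @export
delay_window <- function(n_tr = 3, tr = 1.5, delay_offset = 10.8) {
  last <- floor(delay_offset / tr + 1e-9)
  (last - n_tr + 1):last
}

#' Split voxels into RF-in and RF-out sets for one trial
#'
#' RF-in voxels have a pRF polar angle within `wedge_halfwidth` degrees
#' (circular distance) of the MGS goal; RF-out voxels are within the same
#' distance of the diametrically opposite angle. The sets are disjoint
#' whenever `wedge_halfwidth < 90`.
#'
#' @param fits A `prf_fit` tibble (or any tibble with `voxel` and `polar`).
#' @param theta_mgs MGS goal angle for the trial, degrees.
#' @param wedge_halfwidth Half-width of the wedge in degrees. The default 30
#'   follows the "within 30 deg of the target" membership rule; set 15 for a
#'   30 deg-wide wedge.
#' @return List with integer vectors `rf_in` and `rf_out` (row indices into
#'   `fits`).
#' @export
classify_rf_voxels <- function(fits, theta_mgs, wedge_halfwidth = 30) {
  stopifnot(wedge_halfwidth > 0, wedge_halfwidth < 90)
  d_in <- circ_dist_deg(fits$polar, theta_mgs)
  d_out <- circ_dist_deg(fits$polar, theta_mgs + 180)
  list(rf_in = which(d_in <= wedge_halfwidth),
       rf_out = which(d_out <= wedge_halfwidth))
}

#' Trial-averaged delay time courses for RF-in / RF-out voxels
#'
#' For each trial, averages the epoched signal over that trial's RF-in and
#' RF-out voxels, then averages over trials, yielding the per-TR mean and
#' SEM for each set. Also returns per-trial late-delay means for both the
#' univariate (last 3 TRs) and encoding-model (last 4 TRs) windows, and a
#' pre-trial baseline (mean of the `baseline_tr` TRs before target onset,
#' taken from the preceding epoch position in the run).
#'
#' @param epochs Array from [epoch_trials()] (single run) or a list of such
#'   arrays (multiple runs).
#' @param fits `prf_fit` tibble aligned with the voxel dimension.
#' @param wedge_halfwidth Passed to [classify_rf_voxels()].
#' @param tr Repetition time in seconds.
#' @return A list of class `delay_tc` with `timecourse` (tibble: `set`,
#'   `tr_index`, `time`, `mean`, `sem`, `n_trials`) and `trial_means`
#'   (tibble: trial metadata plus `set`, `delay_mean_3tr`, `delay_mean_4tr`,
#'   `baseline`).
#' @export
delay_timecourse <- function(epochs, fits, wedge_halfwidth = 30, tr = 1.5) {
  if (!is.list(epochs)) epochs <- list(epochs)
  per_trial <- purrr::map_dfr(epochs, function(ep) {
    trials <- attr(ep, "trials")
    purrr::map_dfr(seq_len(dim(ep)[3]), function(i) {
      sets <- classify_rf_voxels(fits, trials$theta_mgs[i], wedge_halfwidth)
      purrr::map_dfr(c("rf_in", "rf_out"), function(s) {
        vox <- sets[[s]]
        if (!length(vox)) return(NULL)
        m <- rowMeans(ep[, vox, i, drop = FALSE], na.rm = TRUE)
        w3 <- delay_window(3, tr); w4 <- delay_window(4, tr)
        tibble::tibble(run = trials$run[i], trial = trials$trial[i],
                       condition = trials$condition[i],
                       theta_mgs = trials$theta_mgs[i], set = s,
                       tc = list(m),
                       delay_mean_3tr = mean(m[w3]),
                       delay_mean_4tr = mean(m[w4]),
                       baseline = if (i > 1) {
                         prev <- ep[, vox, i - 1, drop = FALSE]
                         mean(prev[dim(ep)[1] - 1:0, , 1], na.rm = TRUE)
                       } else NA_real_)
      })
    })
  })
  n_tr <- length(per_trial$tc[[1]])
  tc <- per_trial |>
    tidyr::unnest_longer("tc", indices_to = "tr_index") |>
    dplyr::group_by(.data$set, .data$tr_index) |>
    dplyr::summarise(
      n_trials = sum(is.finite(.data$tc)),
      sem = stats::sd(.data$tc, na.rm = TRUE) /
        sqrt(pmax(1, sum(is.finite(.data$tc)))),
      mean = mean(.data$tc, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(time = (.data$tr_index - 1) * tr)
  structure(list(timecourse = tc,
                 trial_means = dplyr::select(per_trial, -"tc")),
            class = "delay_tc")
}

#' Group-level delay test with subject bootstrap
#'
#' Resamples subjects with replacement `n_boot` times, averaging the
#' per-subject delay means in each resample. Reports (i) the percentile 95%
#' CI of the bootstrap means, (ii) a t interval / one-tailed t statistic
#' using the bootstrap SE (`t = mean / sd(bootstrap means)`, df = n - 1),
#' and (iii) the raw-subject one-tailed t-test, so the bootstrap-smoothed
#' and plain inferences can be compared.
#'
#' @param subject_means Numeric vector, one delay mean per subject (or a
#'   difference, e.g. RF-in minus RF-out).
#' @param n_boot Bootstrap iterations.
#' @param seed Integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return One-row tibble: `estimate`, `ci_lo`, `ci_hi` (t interval with
#'   bootstrap SE), `ci_lo_pct`, `ci_hi_pct` (percentile), `t_boot`,
#'   `p_boot`, `t_raw`, `p_raw`, `n_subjects`, `n_boot`.
#' @export
group_delay_test <- function(subject_means, n_boot = 1000, seed = 1L,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- subject_means[is.finite(subject_means)]
  n <- length(x)
  if (n < 2) stop("group_delay_test(): needs at least 2 subjects")
  boots <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    rowMeans(matrix(x[idx], n_boot, n))
  })
  est <- mean(x)
  se_b <- stats::sd(boots)
  tq <- stats::qt(0.975, n - 1)
  t_boot <- if (se_b > 0) est / se_b else sign(est) * Inf
  p_boot <- if (alternative == "greater") stats::pt(t_boot, n - 1, lower.tail = FALSE)
            else 2 * stats::pt(abs(t_boot), n - 1, lower.tail = FALSE)
  if (stats::sd(x) > 0) {
    tt <- stats::t.test(x, alternative = if (alternative == "greater") "greater" else "two.sided")
    t_raw <- unname(tt$statistic); p_raw <- tt$p.value
  } else {
    t_raw <- sign(est) * Inf; p_raw <- if (est > 0) 0 else 1
  }
  tibble::tibble(
    estimate = est,
    ci_lo = est - tq * se_b, ci_hi = est + tq * se_b,
    ci_lo_pct = unname(stats::quantile(boots, 0.025)),
    ci_hi_pct = unname(stats::quantile(boots, 0.975)),
    t_boot = t_boot, p_boot = p_boot, t_raw = t_raw, p_raw = p_raw,
    n_subjects = n, n_boot = n_boot
  )
}

#' Score saccades against their targets
#'
#' Computes, per trial and saccade type, the Euclidean endpoint error, the
#' reaction time, and a fixation-break flag (delay-period gaze excursion
#' beyond `break_threshold`). Precision is the average of the SDs of the
#' tangential and radial endpoint components, computed per target-location
#' cluster (the eight base angles for MGS; a single pooled cluster for VGS,
#' whose targets are unstructured) and attached to each trial's cluster.
#'
#' @param gaze Tibble from [simulate_saccades()] (or matching columns).
#' @param trials Trial tibble from [make_wm_design()].
#' @param break_threshold Excursion threshold in degrees.
#' @return A list of class `saccade_scores` with `scores` (tibble: one row
#'   per trial x saccade type with `error`, `precision`, `rt`,
#'   `fixation_break`) and `summary` (per saccade type means).
#' @export
score_saccades <- function(gaze, trials, break_threshold = 2) {
  d <- dplyr::inner_join(trials, gaze, by = c("run", "trial"))
  deg2xy <- function(th, ec) cbind(ec * cos(th * pi / 180),
                                   ec * sin(th * pi / 180))
  score_one <- function(type) {
    tgt_th <- if (type == "vgs") d$theta_vgs else d$theta_mgs
    tgt_ec <- if (type == "vgs") d$ecc_vgs else d$ecc_mgs
    ep <- if (type == "vgs") cbind(d$vgs_x, d$vgs_y) else cbind(d$mgs_x, d$mgs_y)
    tgt <- deg2xy(tgt_th, tgt_ec)
    err <- sqrt(rowSums((ep - tgt)^2))
    # radial/tangential decomposition relative to the target direction
    u <- tgt / sqrt(rowSums(tgt^2))
    dv <- ep - tgt
    radial <- rowSums(dv * u)
    tangential <- dv[, 1] * (-u[, 2]) + dv[, 2] * u[, 1]
    cluster <- if (type == "mgs") {
      wrap_deg(floor(wrap_deg(tgt_th) / 45) * 45 + 22.5)  # base-angle bins
    } else 0
    prec <- tibble::tibble(cluster = cluster, radial = radial,
                           tangential = tangential) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::mutate(precision = (stats::sd(.data$radial) +
                                   stats::sd(.data$tangential)) / 2) |>
      dplyr::ungroup()
    rt <- if (type == "vgs") d$rt_vgs else d$rt_mgs
    tibble::tibble(run = d$run, trial = d$trial, type = type,
                   error = err, precision = prec$precision, rt = rt,
                   fixation_break = d$delay_excursion > break_threshold)
  }
  scores <- dplyr::bind_rows(score_one("vgs"), score_one("mgs"))
  summary <- scores |>
    dplyr::group_by(.data$type) |>
    dplyr::summarise(error = mean(.data$error),
                     precision = mean(.data$precision, na.rm = TRUE),
                     rt = mean(.data$rt),
                     break_rate = mean(.data$fixation_break),
                     .groups = "drop")
  structure(list(scores = scores, summary = summary),
            class = "saccade_scores")
}
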