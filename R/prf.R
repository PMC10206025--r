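#' Predict a pRF time course from an aperture movie
#'
#' The per-frame neural drive is the overlap between the binary aperture and
#' an isotropic 2D Gaussian receptive field, normalised by the Gaussian's
#' total mass (so a full-field aperture gives unit drive). The drive is then
#' convolved with the HRF sampled at the TR. The returned series is
#' mean-centred; amplitude and baseline are linear terms handled by least
#' squares in the fitting stages.
#'
#' @param prf Numeric `c(x0, y0, sigma)` in degrees, `sigma > 0`.
#' @param apertures Aperture array from [make_mapping_stimulus()] (or a
#'   downsampled version).
#' @param hrf An [hrf_model()].
#' @param tr Repetition time in seconds.
#' @return Mean-zero numeric vector, one value per frame.
#' @export
predict_timecourse <- function(prf, apertures, hrf = hrf_model(), tr = 1.5) {
  if (length(dim(apertures)) != 3 || dim(apertures)[3] < 1)
    stop("predict_timecourse(): empty aperture movie")
  stopifnot(length(prf) == 3, prf[3] > 0)
  fl <- flatten_apertures(apertures)
  g <- exp(-((fl$x - prf[1])^2 + (fl$y - prf[2])^2) / (2 * prf[3]^2))
  drive <- as.numeric(fl$A %*% g) / sum(g)
  p <- .conv_steady(drive, hrf_kernel(hrf, tr), tr)
  p - mean(p)
}

# causal convolution assuming the pre-scan drive equalled the first frame
# (steady state), so a constant stimulus maps to a constant response
.conv_steady <- function(drive, kern, tr) {
  n <- length(drive)
  m <- length(kern)
  x <- c(rep(drive[1], m), drive)
  stats::convolve(x, rev(kern), type = "open")[m + seq_len(n)] * tr
}

# centred prediction from a precomputed flattened stimulus environment
.predict_from_env <- function(env, x0, y0, sigma, kern, tr) {
  g <- exp(-((env$x - x0)^2 + (env$y - y0)^2) / (2 * sigma^2))
  sg <- sum(g)
  if (sg < .Machine$double.xmin) return(rep(0, nrow(env$A)))
  drive <- as.numeric(env$A %*% g) / sg
  p <- .conv_steady(drive, kern, tr)
  p - mean(p)
}

#' Default coarse-search grid
#'
#' Positions on a 1 deg lattice over +/- `extent` and a geometric ladder of
#' sizes. Candidates are ordered by eccentricity then sigma so that argmax
#' ties resolve to the smallest eccentricity, then the smallest size.
#'
#' @param extent Half-width of the position lattice in degrees.
#' @param step Lattice spacing in degrees.
#' @param sigmas Candidate pRF sizes in degrees.
#' @return Tibble of candidates `x0`, `y0`, `sigma`, `ecc`.
#' @export
coarse_grid <- function(extent = 16, step = 1, sigmas = c(0.5, 1, 2, 4, 8)) {
  xy <- seq(-extent, extent, by = step)
  g <- tidyr::expand_grid(x0 = xy, y0 = xy, sigma = sigmas)
  g$ecc <- sqrt(g$x0^2 + g$y0^2)
  dplyr::arrange(g, .data$ecc, .data$sigma, .data$x0, .data$y0)
}

#' Precompute coarse-stage candidate predictions
#'
#' Downsamples the stimulus by bilinear interpolation (default to 5% of its
#' original resolution) and evaluates the standardised predicted time course
#' for every grid candidate, so that per-voxel coarse fits reduce to one
#' matrix product.
#'
#' @param apertures Full-resolution aperture array.
#' @param grid Candidate tibble from [coarse_grid()].
#' @param hrf An [hrf_model()] used during the coarse stage.
#' @param tr Repetition time in seconds.
#' @param downsample Linear downsampling factor for the effective stimulus.
#' @return List of class `coarse_basis`: `P` (n_frames x n_candidates,
#'   columns mean-zero unit-SD; all-zero where degenerate), `grid`, `tr`.
#' @export
coarse_basis <- function(apertures, grid = coarse_grid(), hrf = hrf_model(),
                         tr = attr(apertures, "tr") %||% 1.5,
                         downsample = 0.05) {
  ds <- downsample_apertures(apertures, downsample)
  fl <- flatten_apertures(ds)
  kern <- hrf_kernel(hrf, tr)
  n_t <- nrow(fl$A)
  # Gaussian matrix: pixels x candidates
  G <- exp(-(outer(fl$x, grid$x0, `-`)^2 + outer(fl$y, grid$y0, `-`)^2) /
             (2 * matrix(grid$sigma^2, length(fl$x), nrow(grid), byrow = TRUE)))
  drive <- (fl$A %*% G) %*% diag(1 / colSums(G), nrow(grid))
  P <- apply(drive, 2, function(d) .conv_steady(d, kern, tr))
  P <- sweep(P, 2, colMeans(P))
  s <- sqrt(colSums(P^2))
  ok <- s > 1e-12
  P[, ok] <- sweep(P[, ok, drop = FALSE], 2, s[ok], `/`)
  P[, !ok] <- 0
  structure(list(P = P, grid = grid, tr = tr, ok = ok), class = "coarse_basis")
}

#' Coarse grid-search pRF fit
#'
#' Finds the grid candidate maximising variance explained for each voxel,
#' with amplitude and baseline fitted by ordinary least squares per
#' candidate. Ties resolve to the smallest eccentricity, then size.
#'
#' @param series Numeric vector (one voxel) or matrix (time x voxels).
#' @param basis A [coarse_basis()]; or pass `apertures` to build one.
#' @param apertures Aperture array (used when `basis` is `NULL`).
#' @param ... Passed to [coarse_basis()] when it must be built.
#' @return Tibble with one row per voxel: `x0`, `y0`, `sigma`, `r2`,
#'   `amplitude` (signed).
#' @export
coarse_fit <- function(series, basis = NULL, apertures = NULL, ...) {
  if (is.null(basis)) {
    if (is.null(apertures)) stop("coarse_fit(): supply 'basis' or 'apertures'")
    basis <- coarse_basis(apertures, ...)
  }
  Y <- if (is.matrix(series)) series else matrix(series, ncol = 1)
  sdy <- apply(Y, 2, stats::sd)
  if (any(sdy == 0))
    stop("coarse_fit(): degenerate input: voxel series ",
         paste(which(sdy == 0), collapse = ", "), " constant over time")
  Yc <- sweep(Y, 2, colMeans(Y))
  # correlation candidates x voxels; candidate columns are unit-norm
  R <- crossprod(basis$P, Yc) / rep(sqrt(colSums(Yc^2)), each = ncol(basis$P))
  best <- apply(R^2, 2, which.max)  # grid pre-sorted: first max = best tie-break
  out <- basis$grid[best, c("x0", "y0", "sigma")]
  out$r2 <- R[cbind(best, seq_len(ncol(Yc)))]^2
  out$amplitude <- R[cbind(best, seq_len(ncol(Yc)))] *
    sqrt(colSums(Yc^2))  # slope vs unit-norm predictor
  tibble::as_tibble(out)
}

#' Fit HRF delay parameters with the pRF fixed
#'
#' Bounded minimisation of residual sum of squares over the HRF time-to-peak
#' and time-to-undershoot, with the pRF held at its coarse-fit value and
#' amplitude/baseline profiled out by least squares.
#'
#' @param series Numeric vector, one voxel's time course.
#' @param apertures Aperture array (full resolution).
#' @param seed_prf `c(x0, y0, sigma)` from [coarse_fit()].
#' @param tr Repetition time in seconds.
#' @param bounds_peak,bounds_under Box bounds in seconds.
#' @param init Starting values `c(peak, under)`.
#' @return An [hrf_model()] with fitted delays.
#' @export
fit_hrf <- function(series, apertures, seed_prf, tr = 1.5,
                    bounds_peak = c(3, 9), bounds_under = c(8, 20),
                    init = c(6, 15)) {
  if (stats::sd(series) == 0)
    stop("fit_hrf(): degenerate input: series is constant")
  fl <- flatten_apertures(apertures)
  g <- exp(-((fl$x - seed_prf[1])^2 + (fl$y - seed_prf[2])^2) /
             (2 * seed_prf[3]^2))
  drive <- as.numeric(fl$A %*% g) / sum(g)
  n <- length(drive)
  yc <- series - mean(series)
  ssy <- sum(yc^2)
  obj <- function(par) {
    if (par[2] <= par[1] + 0.5) return(1e6)
    kern <- hrf_kernel(hrf_model(par[1], par[2]), tr)
    p <- .conv_steady(drive, kern, tr)
    pc <- p - mean(p)
    ssp <- sum(pc^2)
    if (ssp < 1e-20) return(1e6)
    r2 <- sum(pc * yc)^2 / (ssp * ssy)
    if (!is.finite(r2)) stop("fit_hrf(): non-finite residuals")
    1 - r2
  }
  fit <- stats::optim(init, obj, method = "L-BFGS-B",
                      lower = c(bounds_peak[1], bounds_under[1]),
                      upper = c(bounds_peak[2], bounds_under[2]),
                      control = list(factr = 1e4))
  hrf_model(fit$par[1], fit$par[2])
}

#' Fine nonlinear pRF refinement
#'
#' Bounded quasi-Newton minimisation of normalised residual sum of squares
#' over `(x0, y0, sigma)` using the full-resolution stimulus, seeded from the
#' coarse fit, with the HRF fixed. Amplitude and baseline are profiled out
#' analytically. If the optimiser fails to improve on the seed, the seed is
#' returned flagged with its coarse variance explained.
#'
#' @param series One voxel's time course.
#' @param apertures Full-resolution aperture array.
#' @param seed_prf `c(x0, y0, sigma)` from [coarse_fit()].
#' @param hrf An [hrf_model()], typically from [fit_hrf()].
#' @param tr Repetition time in seconds.
#' @param sigma_bounds Allowed pRF size range in degrees.
#' @param pos_extent Position bound in degrees (box `+/- pos_extent`).
#' @return One-row tibble: `x0`, `y0`, `sigma`, `hrf_peak`, `hrf_under`,
#'   `baseline`, `amplitude`, `r2`, `polar`, `ecc`, `converged`.
#' @export
fine_fit <- function(series, apertures, seed_prf, hrf = hrf_model(),
                     tr = 1.5, sigma_bounds = c(0.1, 20), pos_extent = 24) {
  if (stats::sd(series) == 0)
    stop("fine_fit(): degenerate input: series is constant")
  env <- flatten_apertures(apertures)
  kern <- hrf_kernel(hrf, tr)
  yc <- series - mean(series)
  ssy <- sum(yc^2)
  obj <- function(par) {
    p <- .predict_from_env(env, par[1], par[2], par[3], kern, tr)
    ssp <- sum(p^2)
    if (ssp < 1e-20) return(1)
    r2 <- sum(p * yc)^2 / (ssp * ssy)
    1 - r2
  }
  fit <- tryCatch(
    stats::optim(seed_prf, obj, method = "L-BFGS-B",
                 lower = c(-pos_extent, -pos_extent, sigma_bounds[1]),
                 upper = c(pos_extent, pos_extent, sigma_bounds[2]),
                 control = list(factr = 1e1, maxit = 500)),
    error = function(e) NULL)
  seed_val <- obj(seed_prf)
  converged <- !is.null(fit) && fit$convergence == 0 &&
    fit$value <= seed_val + 1e-12
  par <- if (!is.null(fit) && fit$value <= seed_val) fit$par else seed_prf
  val <- if (!is.null(fit)) min(fit$value, seed_val) else seed_val
  # final linear terms at the optimum
  p <- .predict_from_env(env, par[1], par[2], par[3], kern, tr)
  ssp <- sum(p^2)
  amp <- if (ssp > 0) sum(p * yc) / ssp else 0
  base <- mean(series)
  tibble::tibble(
    x0 = par[1], y0 = par[2], sigma = par[3],
    hrf_peak = hrf$peak, hrf_under = hrf$under,
    baseline = base, amplitude = amp,
    r2 = max(0, 1 - val),
    polar = wrap_deg(atan2(par[2], par[1]) * 180 / pi),
    ecc = sqrt(par[1]^2 + par[2]^2),
    converged = converged
  )
}

#' Fit Gaussian pRFs to a mapping run
#'
#' The three-stage pipeline per voxel: a sparse grid search on a bilinearly
#' downsampled stimulus, HRF delay estimation seeded from the grid best, and
#' a fine bounded quasi-Newton refinement at full stimulus resolution.
#'
#' @param bold Time-by-voxel matrix (z-units, e.g. from [preprocess_bold()])
#'   or a `sim_run` from [simulate_mapping_run()].
#' @param apertures Aperture array; taken from `bold` when it is a `sim_run`.
#' @param tr Repetition time in seconds.
#' @param grid Coarse candidate grid, see [coarse_grid()].
#' @param fit_hrf_delays If `FALSE`, skip HRF fitting and use `hrf0`.
#' @param hrf0 HRF used for the coarse stage (and throughout when
#'   `fit_hrf_delays = FALSE`).
#' @param downsample Coarse-stage stimulus downsampling factor.
#' @param n_cycles Maximum number of HRF-then-pRF refinement cycles. The
#'   HRF delay and pRF size estimates are coupled, so the two fits alternate
#'   until the variance explained stops improving (by less than `cycle_tol`)
#'   or `n_cycles` is reached; most voxels settle in two cycles.
#' @param cycle_tol Minimum r-squared improvement to continue cycling.
#' @return A tibble of class `prf_fit`, one row per voxel, with columns
#'   `voxel`, `x0`, `y0`, `sigma`, `hrf_peak`, `hrf_under`, `baseline`,
#'   `amplitude`, `r2`, `polar`, `ecc`, `converged`.
#' @export
fit_prf <- function(bold, apertures = NULL, tr = 1.5, grid = coarse_grid(),
                    fit_hrf_delays = TRUE, hrf0 = hrf_model(),
                    downsample = 0.05, n_cycles = 6, cycle_tol = 1e-5) {
  if (inherits(bold, "sim_run")) {
    apertures <- apertures %||% bold$apertures
    tr <- bold$tr
    bold <- bold$bold
  }
  if (is.null(apertures)) stop("fit_prf(): 'apertures' is required")
  cb <- coarse_basis(apertures, grid = grid, hrf = hrf0, tr = tr,
                     downsample = downsample)
  coarse <- coarse_fit(bold, basis = cb)
  fits <- purrr::map_dfr(seq_len(ncol(bold)), function(v) {
    seed <- as.numeric(coarse[v, c("x0", "y0", "sigma")])
    ff <- NULL
    r2_prev <- -Inf
    for (cyc in seq_len(max(1, n_cycles))) {
      hrf <- if (fit_hrf_delays) {
        tryCatch(fit_hrf(bold[, v], apertures, seed, tr = tr),
                 error = function(e) hrf0)
      } else hrf0
      ff <- fine_fit(bold[, v], apertures, seed, hrf = hrf, tr = tr)
      seed <- as.numeric(ff[1, c("x0", "y0", "sigma")])
      if (!fit_hrf_delays) break
      if (cyc >= 2 && ff$r2 - r2_prev < cycle_tol) break
      r2_prev <- ff$r2
    }
    if (!ff$converged && ff$r2 < coarse$r2[v]) ff$r2 <- coarse$r2[v]
    ff
  })
  fits <- dplyr::bind_cols(tibble::tibble(voxel = seq_len(ncol(bold))), fits)
  class(fits) <- c("prf_fit", class(fits))
  attr(fits, "tr") <- tr
  fits
}

#' Select an ROI by mask and model threshold
#'
#' Intersects in-mask voxels with voxels whose pRF model variance explained
#' reaches the threshold (default `r2 >= 0.1`).
#'
#' @param fits A `prf_fit` tibble.
#' @param mask Logical vector (or 0/1 array, flattened) with one entry per
#'   voxel in `fits`; `NULL` keeps all voxels in-mask.
#' @param threshold Variance-explained cutoff.
#' @return The subset of `fits` in the ROI (possibly empty, with a warning).
#' @export
select_roi <- function(fits, mask = NULL, threshold = 0.1) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(fits))
  mask <- as.logical(as.vector(mask))
  stopifnot(length(mask) == nrow(fits))
  keep <- mask & fits$r2 >= threshold
  if (!any(keep)) warning("select_roi(): empty ROI (no voxel passes mask and threshold)")
  fits[keep, , drop = FALSE]
}

#' Aggregate field-of-view map
#'
#' Each voxel contributes a 2D Gaussian at its pRF centre with its pRF size
#' and unit peak; every visual-field coordinate maps to the maximum value
#' across voxels, reflecting how effectively stimulation there drives the
#' population.
#'
#' @param fits A `prf_fit` tibble (or any tibble with `x0`, `y0`, `sigma`).
#' @param xlim,ylim Field extents in degrees.
#' @param n_grid Grid points per axis.
#' @return A tibble of class `fov_map` with columns `x`, `y`, `fov`
#'   (values in `[0, 1]`).
#' @export
estimate_fov <- function(fits, xlim = c(-16, 16), ylim = c(-16, 16),
                         n_grid = 101) {
  stopifnot(nrow(fits) >= 1)
  gx <- seq(xlim[1], xlim[2], length.out = n_grid)
  gy <- seq(ylim[1], ylim[2], length.out = n_grid)
  pts <- tidyr::expand_grid(x = gx, y = gy)
  d2 <- outer(pts$x, fits$x0, `-`)^2 + outer(pts$y, fits$y0, `-`)^2
  vals <- exp(-d2 / (2 * matrix(fits$sigma^2, nrow(pts), nrow(fits),
                                byrow = TRUE)))
  pts$fov <- apply(vals, 1, max)
  class(pts) <- c("fov_map", class(pts))
  pts
}

#' Size-eccentricity analysis
#'
#' Bins voxels by pRF eccentricity into equal-width bins, computes bin-mean
#' size, and fits an ordinary least-squares line and Pearson correlation
#' across the binned points, separately per variance-explained threshold.
#'
#' @param fits A `prf_fit` tibble.
#' @param n_bins Number of equal-width eccentricity bins.
#' @param ve_thresholds Variance-explained cutoffs to analyse.
#' @return A list of class `size_ecc` with `summary` (one row per
#'   threshold: `threshold`, `slope`, `intercept`, `r`, `p`, `n_voxels`,
#'   `n_bins_used`, `constant_sigma`) and `bins` (per-bin means).
#' @export
size_ecc_analysis <- function(fits, n_bins = 30, ve_thresholds = 0.1) {
  res <- purrr::map(ve_thresholds, function(th) {
    f <- fits[fits$r2 >= th, , drop = FALSE]
    if (nrow(f) < 3) stop("size_ecc_analysis(): fewer than 3 voxels at threshold ", th)
    brk <- seq(min(f$ecc), max(f$ecc), length.out = n_bins + 1)
    bin <- cut(f$ecc, brk, include.lowest = TRUE)
    bins <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(ecc = f$ecc, sigma = f$sigma, bin = bin),
                      .data$bin),
      ecc = mean(.data$ecc), sigma = mean(.data$sigma), n = dplyr::n(),
      .groups = "drop")
    bins <- bins[bins$n > 0, ]
    if (nrow(bins) < 3) stop("size_ecc_analysis(): fewer than 3 non-empty bins")
    constant <- stats::sd(bins$sigma) < 1e-12
    if (constant) {
      summ <- tibble::tibble(threshold = th, slope = 0,
                             intercept = mean(bins$sigma), r = 0, p = NA_real_,
                             n_voxels = nrow(f), n_bins_used = nrow(bins),
                             constant_sigma = TRUE)
    } else {
      lmfit <- stats::lm(sigma ~ ecc, data = bins)
      ct <- stats::cor.test(bins$ecc, bins$sigma)
      summ <- tibble::tibble(threshold = th,
                             slope = stats::coef(lmfit)[["ecc"]],
                             intercept = stats::coef(lmfit)[["(Intercept)"]],
                             r = unname(ct$estimate), p = ct$p.value,
                             n_voxels = nrow(f), n_bins_used = nrow(bins),
                             constant_sigma = FALSE)
    }
    list(summary = summ, bins = dplyr::mutate(bins, threshold = th))
  })
  structure(list(summary = purrr::map_dfr(res, "summary"),
                 bins = purrr::map_dfr(res, "bins")),
            class = "size_ecc")
}
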