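#' Bar-sweep mapping run design
#'
#' Describes a retinotopic mapping run: a bar of fixed width sweeping across
#' the screen in each of the four cardinal directions, flanked by
#' mean-luminance blanks. Defaults follow the common 1.5 s TR protocol: four
#' 30 s sweeps, 12 s blanks at the start and end, an 8 deg-wide bar on a
#' ~32 deg display. Any time not accounted for by sweeps and the two stated
#' blanks is spent as additional blank at the end of the run.
#'
#' @param screen_deg Screen width/height in degrees of visual angle.
#' @param grid_px Aperture raster resolution (pixels per side).
#' @param bar_width Bar width in degrees.
#' @param sweep_dur Duration of one sweep in seconds.
#' @param blank_dur Duration of the opening and closing blanks in seconds.
#' @param sweep_order Character vector, a permutation of
#'   `c("LR", "RL", "TB", "BT")`, or `NULL` to draw a seeded random order in
#'   [make_mapping_stimulus()].
#' @param tr Repetition time in seconds.
#' @param n_vols Number of volumes (aperture frames) in the run.
#' @return An object of class `mapping_design`.
#' @export
mapping_design <- function(screen_deg = 32, grid_px = 101, bar_width = 8,
                           sweep_dur = 30, blank_dur = 12,
                           sweep_order = NULL, tr = 1.5, n_vols = 120) {
  if (bar_width <= 0) stop("mapping_design(): bar_width must be positive")
  if (n_vols * tr < 4 * sweep_dur + 2 * blank_dur)
    stop("mapping_design(): run too short for four sweeps plus two blanks")
  if (!is.null(sweep_order)) {
    if (!setequal(sweep_order, c("LR", "RL", "TB", "BT")) ||
        length(sweep_order) != 4)
      stop("mapping_design(): sweep_order must permute LR, RL, TB, BT")
  }
  structure(
    list(screen_deg = screen_deg, grid_px = as.integer(grid_px),
         bar_width = bar_width, sweep_dur = sweep_dur, blank_dur = blank_dur,
         sweep_order = sweep_order, tr = tr, n_vols = as.integer(n_vols)),
    class = "mapping_design"
  )
}

#' Pixel-centre coordinates of the aperture raster
#'
#' @param screen_deg Screen extent in degrees.
#' @param grid_px Pixels per side.
#' @return List with vectors `x` (rightward) and `y` (upward), in degrees,
#'   origin at fixation.
#' @export
aperture_grid <- function(screen_deg, grid_px) {
  d <- screen_deg / grid_px
  x <- seq(-screen_deg / 2 + d / 2, screen_deg / 2 - d / 2, length.out = grid_px)
  list(x = x, y = x)
}

#' Generate a binary bar-sweep aperture movie
#'
#' One binary frame per volume; the bar is rasterised in degrees on the
#' aperture grid. The bar centre moves linearly from one screen edge to the
#' other over each sweep (evaluated at frame midpoints), spans the full
#' screen along its length, and is clipped at the edges. Frames outside the
#' sweeps are blank (all zero).
#'
#' @param design A [mapping_design()].
#' @param seed Integer seed; determines the sweep-order permutation when
#'   `design$sweep_order` is `NULL`.
#' @return A `grid_px x grid_px x n_vols` 0/1 array with attributes
#'   `grid` (pixel coordinates), `tr`, and `sweep_order`. First array index
#'   is x (rightward), second is y (upward).
#' @export
make_mapping_stimulus <- function(design, seed = 1L) {
  stopifnot(inherits(design, "mapping_design"))
  if (design$grid_px < 8) stop("make_mapping_stimulus(): grid_px < 8 is too coarse")
  order <- design$sweep_order
  if (is.null(order)) {
    order <- withr::with_seed(seed, sample(c("LR", "RL", "TB", "BT")))
  }
  g <- aperture_grid(design$screen_deg, design$grid_px)
  np <- design$grid_px
  ap <- array(0, dim = c(np, np, design$n_vols))
  t_mid <- (seq_len(design$n_vols) - 0.5) * design$tr
  half <- design$bar_width / 2
  s <- design$screen_deg
  for (k in seq_along(order)) {
    t0 <- design$blank_dur + (k - 1) * design$sweep_dur
    in_sweep <- which(t_mid >= t0 & t_mid < t0 + design$sweep_dur)
    for (i in in_sweep) {
      frac <- (t_mid[i] - t0) / design$sweep_dur
      centre <- switch(order[k],
        LR = -s / 2 + s * frac,
        RL = s / 2 - s * frac,
        TB = s / 2 - s * frac,   # top-to-bottom: y decreasing
        BT = -s / 2 + s * frac
      )
      axis <- if (order[k] %in% c("LR", "RL")) g$x else g$y
      on <- as.numeric(abs(axis - centre) <= half)
      ap[, , i] <- if (order[k] %in% c("LR", "RL")) {
        matrix(on, np, np, byrow = FALSE)   # varies along x (rows)
      } else {
        matrix(on, np, np, byrow = TRUE)    # varies along y (cols)
      }
    }
  }
  attr(ap, "grid") <- g
  attr(ap, "tr") <- design$tr
  attr(ap, "sweep_order") <- order
  ap
}

#' Flatten an aperture movie to a frames-by-pixels matrix
#'
#' @param apertures Array from [make_mapping_stimulus()].
#' @return List with `A` (n_frames x n_pixels matrix), `x`, `y`
#'   (per-pixel coordinates in degrees).
#' @keywords internal
flatten_apertures <- function(apertures) {
  d <- dim(apertures)
  g <- attr(apertures, "grid")
  if (is.null(g)) stop("flatten_apertures(): apertures lack a coordinate grid")
  A <- t(matrix(apertures, d[1] * d[2], d[3]))
  list(A = A,
       x = rep(g$x, times = d[2]),
       y = rep(g$y, each = d[1]))
}

#' Bilinear downsampling of an aperture movie
#'
#' Resamples each frame on a coarser pixel grid by separable bilinear
#' (triangular-kernel) interpolation with the kernel width matched to the
#' coarse pixel pitch, i.e. antialiased bilinear resampling — the
#' appropriate form of bilinear interpolation for heavy downscaling, where
#' point-sampled bilinear would alias away most of a thin bar. Used by the
#' coarse pRF stage, where the effective stimulus is reduced to a small
#' fraction of its original resolution.
#'
#' @param apertures Aperture array with a `grid` attribute.
#' @param factor Linear scale factor in (0, 1]; the new side length is
#'   `max(2, round(grid_px * factor))`.
#' @return A downsampled aperture array (values in `[0, 1]`) with updated
#'   `grid` attribute.
#' @export
downsample_apertures <- function(apertures, factor = 0.05) {
  stopifnot(factor > 0, factor <= 1)
  d <- dim(apertures)
  g <- attr(apertures, "grid")
  np2 <- max(2L, as.integer(round(d[1] * factor)))
  old <- g$x
  scr <- diff(range(old)) + (old[2] - old[1])
  new <- aperture_grid(scr, np2)$x
  pitch <- if (np2 > 1) new[2] - new[1] else scr
  # triangular weights, one column per coarse pixel, normalised
  W <- outer(old, new, function(o, n) pmax(0, 1 - abs(o - n) / pitch))
  W <- sweep(W, 2, colSums(W), `/`)
  out <- array(0, dim = c(np2, np2, d[3]))
  for (i in seq_len(d[3])) {
    out[, , i] <- crossprod(W, apertures[, , i]) %*% W
  }
  attr(out, "grid") <- list(x = new, y = new)
  attr(out, "tr") <- attr(apertures, "tr")
  attr(out, "sweep_order") <- attr(apertures, "sweep_order")
  out
}
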