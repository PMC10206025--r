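#' Hemodynamic response model
#'
#' A difference of two gamma densities parameterised by the time-to-peak of
#' the positive lobe and the time-to-undershoot of the negative lobe. The
#' gamma dispersions are fixed (1 s each) and the undershoot amplitude is a
#' fixed fraction (1/6) of the peak, so the model has exactly two free delay
#' parameters. Each gamma is re-parameterised so that its mode equals the
#' requested delay and its standard deviation equals the dispersion.
#'
#' @param peak Time-to-peak in seconds (default 6).
#' @param under Time-to-undershoot in seconds (default 15); must exceed `peak`.
#' @param dispersion Gamma SD in seconds for both lobes (default 1).
#' @param ratio Undershoot/peak amplitude ratio (default 1/6).
#' @return An object of class `hrf_model`.
#' @export
hrf_model <- function(peak = 6, under = 15, dispersion = 1, ratio = 1 / 6) {
  if (!is.finite(peak) || !is.finite(under) || peak <= 0)
    stop("hrf_model(): 'peak' must be positive and finite")
  if (under <= peak)
    stop("hrf_model(): 'under' must exceed 'peak'")
  structure(
    list(peak = peak, under = under, dispersion = dispersion, ratio = ratio),
    class = "hrf_model"
  )
}

# gamma density with mode m and SD d: rate r solves (k-1)/r = m, k/r^2 = d^2
.gamma_mode_sd <- function(t, m, d) {
  r <- (m + sqrt(m^2 + 4 * d^2)) / (2 * d^2)
  k <- 1 + m * r
  stats::dgamma(t, shape = k, rate = r)
}

#' Sample an HRF kernel on a regular time grid
#'
#' @param hrf An [hrf_model()].
#' @param dt Sampling interval in seconds.
#' @param duration Kernel length in seconds (default 32).
#' @return Numeric vector of kernel values at `t = 0, dt, 2*dt, ...`,
#'   normalised to unit maximum.
#' @export
hrf_kernel <- function(hrf, dt, duration = 32) {
  stopifnot(inherits(hrf, "hrf_model"), dt > 0)
  t <- seq(0, duration, by = dt)
  h <- .gamma_mode_sd(t, hrf$peak, hrf$dispersion) -
    hrf$ratio * .gamma_mode_sd(t, hrf$under, hrf$dispersion)
  h / max(h)
}

#' Convolve a neural drive with an HRF kernel
#'
#' Causal discrete convolution truncated to the length of the input.
#'
#' @param drive Numeric vector (or matrix, time in rows) of neural drive
#'   sampled every `dt` seconds.
#' @param hrf An [hrf_model()].
#' @param dt Sampling interval in seconds.
#' @return Object of the same shape as `drive`.
#' @export
convolve_hrf <- function(drive, hrf, dt) {
  k <- hrf_kernel(hrf, dt)
  vec <- !is.matrix(drive)
  if (vec) drive <- matrix(drive, ncol = 1)
  n <- nrow(drive)
  L <- stats::nextn(n + length(k) - 1)   # FFT-friendly padded length
  pad <- matrix(0, L, ncol(drive))
  pad[seq_len(n), ] <- drive
  K <- stats::fft(c(k, numeric(L - length(k))))
  out <- Re(stats::mvfft(stats::mvfft(pad) * K, inverse = TRUE)) / L
  out <- out[seq_len(n), , drop = FALSE] * dt
  if (vec) drop(out) else out
}
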