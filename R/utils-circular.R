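#' Wrap angles into [0, 360)
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Numeric vector of the same length with values in `[0, 360)`.
#' @export
wrap_deg <- function(theta) {
  ((theta %% 360) + 360) %% 360
}

#' Signed circular difference in degrees
#'
#' Smallest signed rotation taking `b` to `a`, in `(-180, 180]`.
#'
#' @param a,b Angles in degrees.
#' @return Signed differences in degrees.
#' @export
circ_diff_deg <- function(a, b) {
  d <- wrap_deg(a - b)
  ifelse(d > 180, d - 360, d)
}

#' Absolute circular distance in degrees
#'
#' @param a,b Angles in degrees.
#' @return Distances in `[0, 180]`.
#' @export
circ_dist_deg <- function(a, b) {
  abs(circ_diff_deg(a, b))
}

#' Circular mean of angles in degrees
#'
#' @param theta Angles in degrees.
#' @return A single angle in `[0, 360)`; `NA` if the resultant length is 0.
#' @export
circ_mean_deg <- function(theta) {
  rad <- theta * pi / 180
  s <- mean(sin(rad)); c <- mean(cos(rad))
  if (sqrt(s^2 + c^2) < .Machine$double.eps^0.5) return(NA_real_)
  wrap_deg(atan2(s, c) * 180 / pi)
}

#' Fisher-Lee circular correlation coefficient
#'
#' Rank-free circular-circular association measure of Fisher & Lee (1983):
#' \deqn{\rho = \frac{\sum_{i<j} \sin(a_i-a_j)\sin(b_i-b_j)}
#'   {\sqrt{\sum_{i<j}\sin^2(a_i-a_j)\ \sum_{i<j}\sin^2(b_i-b_j)}}}
#' Equals 1 when `b = a + const` (mod 360) and is near 0 for independent
#' uniform angles.
#'
#' @param a,b Paired angle vectors in degrees.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
circ_corr <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2) stop("circ_corr() needs at least 2 paired angles")
  ar <- a * pi / 180
  br <- b * pi / 180
  # pairwise sums over i < j, computed from full antisymmetric matrices
  sa <- outer(ar, ar, function(x, y) sin(x - y))
  sb <- outer(br, br, function(x, y) sin(x - y))
  num <- sum(sa * sb) / 2
  den <- sqrt(sum(sa^2) / 2) * sqrt(sum(sb^2) / 2)
  if (den == 0) return(0)
  num / den
}
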