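#' Plot an aggregate field-of-view map
#'
#' @param object A `fov_map` tibble from [estimate_fov()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.fov_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y, fill = .data$fov)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "max pRF") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)",
                  title = "Aggregate field of view") +
    ggplot2::theme_minimal()
}

#' Plot RF-in / RF-out trial-averaged time courses
#'
#' @param object A `delay_tc` from [delay_timecourse()].
#' @param ... Ignored.
#' @return A ggplot with mean +/- SEM ribbons per voxel set.
#' @export
autoplot.delay_tc <- function(object, ...) {
  tc <- object$timecourse
  ggplot2::ggplot(tc, ggplot2::aes(.data$time, .data$mean,
                                   colour = .data$set, fill = .data$set)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from target onset (s)", y = "BOLD (z)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot aligned reconstructions from a bootstrap run
#'
#' @param object An `iem_boot` from [bootstrap_iem()].
#' @param ... Ignored.
#' @return A ggplot of the mean aligned reconstruction per reference.
#' @export
autoplot.iem_boot <- function(object, ...) {
  df <- tibble::as_tibble(object$recon) |>
    dplyr::mutate(theta = 0:359) |>
    tidyr::pivot_longer(-"theta", names_to = "reference", values_to = "r") |>
    dplyr::mutate(theta = ifelse(.data$theta > 180, .data$theta - 360,
                                 .data$theta))
  ggplot2::ggplot(df, ggplot2::aes(.data$theta, .data$r)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$reference) +
    ggplot2::labs(x = "angle from reference (deg)", y = "reconstruction (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot the size-eccentricity relationship
#'
#' @param x A `size_ecc` from [size_ecc_analysis()].
#' @param ... Ignored.
#' @return A ggplot of binned pRF size against eccentricity with the fitted
#'   lines, one colour per variance-explained threshold.
#' @export
plot_size_ecc <- function(x, ...) {
  ggplot2::ggplot(x$bins, ggplot2::aes(.data$ecc, .data$sigma,
                                       colour = factor(.data$threshold))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "eccentricity (deg)", y = "pRF size (deg)",
                  colour = "VE threshold") +
    ggplot2::theme_minimal()
}
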