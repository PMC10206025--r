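#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pRF fit table
#'
#' @param x A `prf_fit` tibble.
#' @param ... Ignored.
#' @return A plain tibble, one row per voxel.
#' @export
tidy.prf_fit <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "prf_fit")
  out
}

#' One-row summary of a pRF fit table
#'
#' @param x A `prf_fit` tibble.
#' @param threshold Variance-explained cutoff used for the pass count.
#' @param ... Ignored.
#' @return Tibble with voxel counts and median parameters.
#' @export
glance.prf_fit <- function(x, threshold = 0.1, ...) {
  tibble::tibble(n_voxels = nrow(x),
                 n_above_threshold = sum(x$r2 >= threshold),
                 median_r2 = stats::median(x$r2),
                 median_sigma = stats::median(x$sigma),
                 median_ecc = stats::median(x$ecc),
                 n_converged = sum(x$converged))
}

#' Tidy the binned size-eccentricity points
#'
#' @param x A `size_ecc` object.
#' @param ... Ignored.
#' @return Tibble of per-bin mean eccentricity and size per threshold.
#' @export
tidy.size_ecc <- function(x, ...) x$bins

#' Per-threshold summary of the size-eccentricity fit
#'
#' @param x A `size_ecc` object.
#' @param ... Ignored.
#' @return Tibble with slope, intercept, Pearson r and p per threshold.
#' @export
glance.size_ecc <- function(x, ...) x$summary

#' Tidy bootstrap fidelities
#'
#' @param x An `iem_boot` object.
#' @param ... Ignored.
#' @return Tibble `iter`, `reference`, `fidelity`, `fidelity_base`.
#' @export
tidy.iem_boot <- function(x, ...) x$fidelity

#' Summarise bootstrap fidelities per reference
#'
#' @param x An `iem_boot` object.
#' @param ... Ignored.
#' @return Tibble with mean and SE of the modified fidelity per reference.
#' @export
glance.iem_boot <- function(x, ...) {
  x$fidelity |>
    dplyr::group_by(.data$reference) |>
    dplyr::summarise(se = stats::sd(.data$fidelity) / sqrt(dplyr::n()),
                     fidelity = mean(.data$fidelity),
                     fidelity_base = mean(.data$fidelity_base),
                     n_iter = dplyr::n(), .groups = "drop") |>
    dplyr::relocate("reference", "fidelity", "se", "fidelity_base", "n_iter")
}

#' Tidy saccade scores
#'
#' @param x A `saccade_scores` object.
#' @param ... Ignored.
#' @return Per-trial score tibble.
#' @export
tidy.saccade_scores <- function(x, ...) x$scores

#' Per-saccade-type summary
#'
#' @param x A `saccade_scores` object.
#' @param ... Ignored.
#' @return Tibble of mean error, precision, RT and break rate per type.
#' @export
glance.saccade_scores <- function(x, ...) x$summary
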