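#' Write a voxel time-series matrix as 4D NIfTI
#'
#' Voxels are laid out along the first spatial axis (V x 1 x 1 x T), with
#' the TR stored in the time pixdim. This layout round-trips arbitrary
#' ROI-shaped data without carrying a full scanner geometry.
#'
#' @param bold Time-by-voxel matrix.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @param tr Repetition time in seconds.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(bold, path, tr = 1.5) {
  arr <- array(t(bold), dim = c(ncol(bold), 1, 1, nrow(bold)))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(1, 1, 1, tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI written by [write_bold_nifti()]
#'
#' @param path NIfTI file.
#' @return Time-by-voxel matrix with attribute `tr`.
#' @export
read_bold_nifti <- function(path) {
  if (!file.exists(path)) stop("read_bold_nifti(): no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  mat <- t(matrix(img, prod(d[1:3]), d[4]))
  attr(mat, "tr") <- RNifti::pixdim(img)[4]
  mat
}

#' Write an aperture movie as 3D NIfTI
#'
#' @param apertures Aperture array from [make_mapping_stimulus()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_apertures_nifti <- function(apertures, path) {
  g <- attr(apertures, "grid")
  img <- RNifti::asNifti(unclass(apertures)[, , , drop = FALSE])
  img <- RNifti::`pixdim<-`(img, c(g$x[2] - g$x[1], g$y[2] - g$y[1],
                                   attr(apertures, "tr") %||% 1.5))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an aperture movie written by [write_apertures_nifti()]
#'
#' @param path NIfTI file.
#' @param screen_deg Screen extent in degrees used to rebuild coordinates.
#' @return Aperture array with `grid` and `tr` attributes.
#' @export
read_apertures_nifti <- function(path, screen_deg = 32) {
  if (!file.exists(path)) stop("read_apertures_nifti(): no such file: ", path)
  img <- RNifti::readNifti(path)
  ap <- array(as.numeric(img), dim = dim(img))
  attr(ap, "grid") <- aperture_grid(screen_deg, dim(ap)[1])
  attr(ap, "tr") <- RNifti::pixdim(img)[3]
  ap
}

#' Write a trial/event table as BIDS-style events TSV
#'
#' Columns `onset` and `duration` (seconds from run start) come first,
#' `trial_type` mirrors the condition, and all remaining trial fields
#' follow.
#'
#' @param trials Trial tibble from [make_wm_design()].
#' @param path Output `.tsv`.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(trials, path) {
  out <- dplyr::relocate(dplyr::mutate(trials, trial_type = .data$condition),
                         "onset", "duration", "trial_type")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an events TSV written by [write_events_tsv()]
#'
#' @param path `.tsv` file.
#' @return Trial tibble.
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) stop("read_events_tsv(): no such file: ", path)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write per-voxel pRF parameter maps and the fit table
#'
#' One NIfTI per parameter (`polar`, `ecc`, `sigma`, `r2`), with voxels
#' along the first axis in fit order, plus the full fit table as TSV.
#'
#' @param fits A `prf_fit` tibble.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of files written.
#' @export
write_prf_maps <- function(fits, dir, prefix = "prf") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (par in c("polar", "ecc", "sigma", "r2")) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, par))
    RNifti::writeNifti(RNifti::asNifti(array(fits[[par]],
                                             dim = c(nrow(fits), 1, 1))), p)
    paths[par] <- p
  }
  tab <- file.path(dir, sprintf("%s_fits.tsv", prefix))
  readr::write_tsv(tidy(fits), tab)
  paths["table"] <- tab
  invisible(paths)
}
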