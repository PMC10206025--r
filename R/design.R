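#' Mirror transformations of a memory target
#'
#' Maps the polar angle of the visual target to the goal of the later
#' memory-guided saccade (MGS). The cue colour in the task indicates one of
#' four geometric transformations: none, reflection across the horizontal
#' meridian, reflection across the vertical meridian, or reflection across
#' both (a point reflection). Eccentricity is unchanged by all of them.
#'
#' @param theta Polar angle(s) of the visual target, degrees in `[0, 360)`
#'   (0 = rightward horizontal meridian, counter-clockwise positive).
#' @param condition Character vector (recycled) among `"none"`,
#'   `"mirror_h"`, `"mirror_v"`, `"mirror_both"`.
#' @return Transformed polar angle(s) in `[0, 360)`.
#' @export
#' @examples
#' transform_target(22.5, "none")        # 22.5
#' transform_target(22.5, "mirror_h")    # 337.5
#' transform_target(100, "mirror_both")  # 280
transform_target <- function(theta, condition) {
  n <- max(length(theta), length(condition))
  theta <- rep_len(theta, n)
  condition <- rep_len(condition, n)
  bad <- setdiff(unique(condition), wm_conditions())
  if (length(bad))
    stop("transform_target(): unknown condition(s): ", paste(bad, collapse = ", "))
  out <- numeric(n)
  out[condition == "none"] <- theta[condition == "none"]
  out[condition == "mirror_h"] <- -theta[condition == "mirror_h"]
  out[condition == "mirror_v"] <- 180 - theta[condition == "mirror_v"]
  out[condition == "mirror_both"] <- theta[condition == "mirror_both"] + 180
  wrap_deg(out)
}

#' The four MGS transformation conditions
#' @return Character vector of condition labels.
#' @export
wm_conditions <- function() c("none", "mirror_h", "mirror_v", "mirror_both")

#' The eight base target angles
#' @return Angles 22.5, 67.5, ..., 337.5 degrees.
#' @export
wm_base_angles <- function() seq(22.5, 337.5, by = 45)

# trial phase durations in seconds
.trial_timing <- list(target = 0.3, delay = 10.5, saccades = 1.4,
                      feedback = 0.5, iti = 9.8)

#' Generate a counterbalanced working-memory task design
#'
#' Builds the trial table for `n_runs` runs of the memory-guided saccade
#' task. Each run has 16 trials of 22.5 s, sampling each of the eight base
#' angles exactly twice; angular jitter is uniform in +/-10 deg and
#' eccentricity uniform in 9-11 deg. The four transformation conditions are
#' counterbalanced across pairs of successive runs so that every
#' (base angle, condition) cell occurs exactly once per run pair. The
#' visually-guided saccade (VGS) target is drawn uniformly in angle and in
#' 9-11 deg eccentricity. The MGS goal is the transformed visual target.
#'
#' @param n_runs Even number of runs.
#' @param seed Integer seed; fully determines the design.
#' @return A tibble with one row per trial: `run`, `trial`, `base_angle`,
#'   `theta_vis`, `ecc_vis`, `condition`, `theta_mgs`, `ecc_mgs`,
#'   `theta_vgs`, `ecc_vgs`, `t_target_on`, `t_delay_end`, `t_feedback`,
#'   `onset`, `duration`.
#' @export
make_wm_design <- function(n_runs, seed = 1L) {
  if (n_runs < 2 || n_runs %% 2 != 0)
    stop("make_wm_design(): n_runs must be even (conditions are counterbalanced over run pairs)")
  tt <- .trial_timing
  trial_dur <- Reduce(`+`, tt)
  base <- wm_base_angles()
  withr::with_seed(seed, {
    runs <- purrr::map(seq_len(n_runs), function(r) {
      tibble::tibble(run = r, base_angle = rep(base, each = 2),
                     condition = NA_character_)
    })
    # condition assignment: per run pair, each (angle, condition) cell once;
    # per run, each angle twice with 2 of the 4 conditions, split at random
    for (p in seq_len(n_runs / 2)) {
      r1 <- 2 * p - 1; r2 <- 2 * p
      for (a in base) {
        conds <- sample(wm_conditions())
        runs[[r1]]$condition[runs[[r1]]$base_angle == a] <- conds[1:2]
        runs[[r2]]$condition[runs[[r2]]$base_angle == a] <- conds[3:4]
      }
    }
    des <- purrr::map_dfr(runs, function(d) {
      d <- d[sample(nrow(d)), ]  # trial order within run
      d$trial <- seq_len(nrow(d))
      d$theta_vis <- wrap_deg(d$base_angle + stats::runif(nrow(d), -10, 10))
      d$ecc_vis <- stats::runif(nrow(d), 9, 11)
      d$theta_vgs <- stats::runif(nrow(d), 0, 360)
      d$ecc_vgs <- stats::runif(nrow(d), 9, 11)
      d
    })
  })
  des$theta_mgs <- transform_target(des$theta_vis, des$condition)
  des$ecc_mgs <- des$ecc_vis
  des$onset <- (des$trial - 1) * trial_dur
  des$duration <- trial_dur
  des$t_target_on <- des$onset
  des$t_delay_end <- des$onset + tt$target + tt$delay
  des$t_feedback <- des$t_delay_end + tt$saccades
  dplyr::select(des, "run", "trial", "base_angle", "theta_vis", "ecc_vis",
                "condition", "theta_mgs", "ecc_mgs", "theta_vgs", "ecc_vgs",
                "t_target_on", "t_delay_end", "t_feedback", "onset", "duration")
}
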