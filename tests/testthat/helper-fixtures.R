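# Small shared fixtures, generated in code at test time.

# a fast low-resolution mapping design with a fixed sweep order
tiny_design <- function(grid_px = 48) {
  mapping_design(grid_px = grid_px, sweep_order = c("LR", "RL", "TB", "BT"))
}

# noiseless single-voxel population at a given pRF
oracle_voxel <- function(x0, y0, sigma, hrf_peak = 5.5, hrf_under = 14) {
  vox <- sim_voxels(1, seed = 1, noise_sd = 0, ar1 = 0, wm_gain = 0)
  vox$x0 <- x0; vox$y0 <- y0; vox$sigma <- sigma
  vox$polar <- wrap_deg(atan2(y0, x0) * 180 / pi)
  vox$ecc <- sqrt(x0^2 + y0^2)
  vox$hrf_peak <- hrf_peak; vox$hrf_under <- hrf_under
  vox
}

# a small counterbalanced session with strong tuning, shared across tests
small_session <- function(n_voxels = 40, n_runs = 4, seed = 7, ...) {
  vox <- sim_voxels(n_voxels, seed = seed, ...)
  simulate_wm_session(vox, n_runs = n_runs, seed = seed)
}

# a hand-built prf_fit-like tibble (no fitting involved)
fake_fits <- function(polar, ecc, sigma = 1, r2 = 1) {
  n <- length(polar)
  tibble::tibble(
    voxel = seq_len(n),
    x0 = ecc * cos(polar * pi / 180),
    y0 = ecc * sin(polar * pi / 180),
    sigma = rep_len(sigma, n),
    r2 = rep_len(r2, n),
    polar = wrap_deg(polar),
    ecc = rep_len(ecc, n)
  )
}
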