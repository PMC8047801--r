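# Shared fixture builders: tiny trajectories constructed in code.

# trajectory with static atoms at given positions (list role -> matrix n x 3)
static_traj <- function(positions, n_frames = 3L, box = 10) {
  coords <- lapply(positions, function(m) {
    m <- as.matrix(m)
    array(rep(m, each = n_frames), c(n_frames, nrow(m), 3))
  })
  trajectory(seq_len(n_frames) - 1, coords, rep(box, 3))
}

# one ion at the origin and one water following a radial path r(t) along x
radial_water_traj <- function(r_path, box = 10) {
  nf <- length(r_path)
  mg <- array(0, c(nf, 1, 3))
  ow <- array(0, c(nf, 1, 3))
  ow[, 1, 1] <- r_path
  trajectory(seq_len(nf) - 1, list(Mg = mg, Ow = ow), rep(box, 3))
}

# double-well radial PMF (k_B T): bound well, barrier, outer well, flat bulk
double_well_fun <- function(depth = 6, barrier = 3, outer = 2) {
  function(r) {
    -depth * exp(-(r - 0.21)^2 / (2 * 0.018^2)) +
      barrier * exp(-(r - 0.30)^2 / (2 * 0.02^2)) -
      outer * exp(-(r - 0.45)^2 / (2 * 0.03^2))
  }
}
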