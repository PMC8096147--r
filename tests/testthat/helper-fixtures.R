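# Generator truths used across tests: (dH kcal/mol, dS cal/(mol K)) pairs
# measured for the asymmetric 9-bp duplex, the GNRA-capped hairpin and the
# palindromic 8-bp duplex, each with its natural molecularity.
melt_truth <- list(
  hairpin = list(dH = -52.8, dS = -153, mol = "unimolecular_hairpin",
                 c_T = NA_real_),
  self    = list(dH = -64.6, dS = -172,
                 mol = "bimolecular_self_complementary", c_T = 1e-5),
  nonself = list(dH = -79.7, dS = -212, mol = "bimolecular_nonself",
                 c_T = 1e-5))

# brute-force rotation-grid superposition oracle: exhaustive search over
# z-y-x Euler angles; adequate for planar/small toys where the optimum is
# well separated
grid_superpose_rmsd <- function(P, Q, n_grid = 60) {
  angs <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  best <- Inf
  rot <- function(a, b, c) {
    Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3)
    Rz %*% Ry %*% Rx
  }
  for (a in angs) for (b in angs[seq(1, n_grid, by = 4)])
    for (c in angs[seq(1, n_grid, by = 4)]) {
      r <- sqrt(mean(rowSums((Pc %*% rot(a, b, c) - Qc)^2)))
      if (r < best) best <- r
    }
  best
}
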