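# Independent scalar oracles, deliberately written from the model equations
# rather than calling the package implementation.

# four-echo forward model for one parameter set (scalar arithmetic)
oracle_sage_signals <- function(s0, delta, r2star, r2, tes) {
  c(s0 * exp(-tes[1] * r2star),
    s0 * exp(-tes[2] * r2star),
    (s0 / delta) * exp((tes[3] - tes[4]) * r2star + (tes[4] - 2 * tes[3]) * r2),
    (s0 / delta) * exp(-tes[4] * r2))
}

# cylinder-model VSI by direct summation
oracle_vsi_histo <- function(radii) {
  (sum(radii^(4 / 3)) / sum(radii^2))^(-3 / 2)
}

# brute-force sphere membership: loop over every voxel
oracle_sphere_values <- function(map, center_mm, voxel_size, radius_mm) {
  d <- dim(map)
  vals <- c()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    dist <- sqrt(((i - 1) * voxel_size[1] - center_mm[1])^2 +
                   ((j - 1) * voxel_size[2] - center_mm[2])^2 +
                   ((k - 1) * voxel_size[3] - center_mm[3])^2)
    if (dist <= radius_mm) vals <- c(vals, map[i, j, k])
  }
  vals[is.finite(vals)]
}

# brute-force Mann-Whitney U: count pairwise wins (+ half-ties)
oracle_u_statistic <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# small noiseless phantom + simulated SAGE acquisition shared across tests
tiny_sage_sim <- function(noise_sigma = 0, tumor_leakage = 0, seed = 1,
                          n_timepoints = 40) {
  ph <- phantom_spec(grid_shape = c(16, 16, 4),
                     classes = phantom_classes(tumor_leakage = tumor_leakage),
                     noise_sigma = noise_sigma, seed = seed)
  sim <- simulate_sage_dataset(ph, bolus_model(t0 = 20),
                               n_timepoints = n_timepoints)
  list(phantom = ph, sim = sim)
}
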