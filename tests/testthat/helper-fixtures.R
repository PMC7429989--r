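# Shared fixtures, all built in code.

# Trapezoidal single-component VCG: x ramps linearly 0 -> 1 over [40, 60] ms,
# holds 1 until 120 ms, ramps back to 0 over [120, 140] ms, flat elsewhere.
# With filtering disabled the spatial velocity is piecewise constant
# (|slope| = 0.05 mV/ms on the ramps, half that at the corner samples), so
# the QRS window is analytically [40, 140] ms.
trapezoid_vcg <- function(fs = 1000, duration = 200) {
  t <- seq(0, duration, by = 1000 / fs)
  x <- ifelse(t < 40, 0,
       ifelse(t <= 60, (t - 40) / 20,
       ifelse(t <= 120, 1,
       ifelse(t <= 140, (140 - t) / 20, 0))))
  vcg_trace(cbind(x, 0, 0), fs)
}

# Hand-assembled rectangular-lattice patch model (nx x ny, unit spacing,
# 4-neighbour edges) for activation oracles; bypasses build_patch_model's
# shell geometry.
lattice_model <- function(nx = 5, ny = 5) {
  idx <- function(i, j) (j - 1) * nx + i
  n <- nx * ny
  pos <- cbind(px = rep(seq_len(nx), ny), py = rep(seq_len(ny), each = nx),
               pz = 0)
  edges <- NULL
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (i < nx) edges <- rbind(edges, c(idx(i, j), idx(i + 1, j)))
    if (j < ny) edges <- rbind(edges, c(idx(i, j), idx(i, j + 1)))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$length <- 1
  patches <- data.frame(
    px = pos[, "px"], py = pos[, "py"], pz = pos[, "pz"],
    phi = seq(-1, 1, length.out = n),   # distinct UVC tags for root lookup
    rho = 0, z = rep(seq(0, 1, length.out = ny), each = nx),
    chamber = "lv", dipole_strength = 1 / n,
    dx = 1, dy = 0, dz = 0,
    zone = factor(rep("healthy", n), levels = c("healthy", "low", "bz", "dense")),
    removed = FALSE)
  structure(list(patches = patches, graph = g, n_patches = n, seed = 0,
                 geometry = list(), free_wall_fraction = NA_real_),
            class = "patch_model")
}

# Independent Bellman-Ford shortest-path oracle (edge list with weights),
# deliberately not igraph.
bellman_ford <- function(n, edges, weights, sources, source_times) {
  dist <- rep(Inf, n)
  dist[sources] <- source_times
  for (pass in seq_len(n)) {
    changed <- FALSE
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]; w <- weights[e]
      if (dist[a] + w < dist[b]) { dist[b] <- dist[a] + w; changed <- TRUE }
      if (dist[b] + w < dist[a]) { dist[a] <- dist[b] + w; changed <- TRUE }
    }
    if (!changed) break
  }
  dist
}

# Minimal vcg_metrics stand-in for compare_rates unit tests.
fake_metrics <- function(qrsd = 100, vcg_max_mag = 1, qrs_area = 10,
                         vcg_mean_mag = 0.5, waa = 0, wae = 90,
                         t_vcg_max = 40,
                         mean_weighted_dipole = c(1, 0, 0),
                         max_dipole = c(1, 0, 0),
                         dipole_at_start = c(1, 0, 0),
                         dipole_at_mid = c(1, 0, 0),
                         dipole_at_end = c(1, 0, 0)) {
  structure(list(qrsd = qrsd, vcg_max_mag = vcg_max_mag, qrs_area = qrs_area,
                 vcg_mean_mag = vcg_mean_mag, waa = waa, wae = wae,
                 t_vcg_max = t_vcg_max,
                 mean_weighted_dipole = mean_weighted_dipole,
                 max_dipole = max_dipole, dipole_at_start = dipole_at_start,
                 dipole_at_mid = dipole_at_mid, dipole_at_end = dipole_at_end),
            class = "vcg_metrics")
}

# 3D rotation matrix about an arbitrary axis (Rodrigues).
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Small scarred scenario used by several tests.
quick_scenario <- function(bcl = 600, location = "lv_free_wall", seed = 3,
                           n_patches = 300, duration = 400) {
  simulation_scenario(bcl, scar_definition(location), seed = seed,
                      n_patches = n_patches, duration = duration)
}
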