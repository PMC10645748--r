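# Fixtures built in code; nothing is stored on disk.

# A population of n identical clusters on a regular grid, well separated
# relative to the rendering PSF, for exact count-recovery checks.
make_grid_population <- function(n = 50L, volume = 0.12, z = 2.0) {
  pop <- gen_cluster_population(cluster_spec(n, volume, seed = 1L))
  ncol_ <- 10L
  nrow_ <- ceiling(n / ncol_)
  gx <- rep(seq(0.64, 12.16, length.out = ncol_), times = nrow_)[seq_len(n)]
  gy <- rep(seq(1.28, 11.52, length.out = nrow_), each = ncol_)[seq_len(n)]
  pop$x_um <- gx
  pop$y_um <- gy
  pop$z_um <- rep(z, n)
  pop$volume_um3 <- rep(volume, n)
  pop
}

# High-SNR render: no background, no shot noise, optional read noise.
# Peak blob intensity is ~290 for a 0.12 um^3 cluster, so noise_sd = 15
# gives an amplitude SNR of ~20.
render_high_snr <- function(pop, noise_sd = 15, seed = 2L) {
  render_image_stack(pop, render_spec(background_level = 0,
                                      poisson_noise = FALSE,
                                      gaussian_sd = noise_sd,
                                      intensity_per_um3 = 1e5, seed = seed))
}

# Mean kappa estimate over replicate simulated sites.
kappa_recovery_mean <- function(kappa_true, n_seeds = 20L, frames = 2000L,
                                n_channels = 3L, open_prob = 0.1) {
  est <- vapply(seq_len(n_seeds), function(s) {
    sim <- gen_sparklet_trace(sparklet_spec(n_channels, kappa_true, open_prob,
                                            noise_sd = 0,
                                            duration = frames / 100,
                                            seed = 1000L + s))
    estimate_kappa(sim$record, n_channels)$kappa
  }, numeric(1))
  mean(est)
}

# Exact distribution over 3x3 occupancy patterns after `steps` synchronous
# updates from an empty periodic lattice. Independent of the package's
# update code: adjacency and per-site event probabilities are recomputed
# here from the model definition and composed into the full 512-state
# transition matrix.
exact_pattern_distribution <- function(p_n, p_g, p_r, steps = 2L) {
  coords <- expand.grid(r = 1:3, c = 1:3)
  wrap <- function(x) ((x - 1L) %% 3L) + 1L
  nbrs <- lapply(1:9, function(i) {
    r <- coords$r[i]; c <- coords$c[i]
    idx <- rbind(c(wrap(r + 1L), c), c(wrap(r - 1L), c),
                 c(r, wrap(c + 1L)), c(r, wrap(c - 1L)))
    unique((idx[, 2] - 1L) * 3L + idx[, 1])
  })
  states <- as.matrix(expand.grid(rep(list(0:1), 9)))
  occ_prob <- t(apply(states, 1, function(s) {
    adj <- vapply(1:9, function(i) any(s[nbrs[[i]]] == 1), logical(1))
    ifelse(s == 1, 1 - p_r, ifelse(adj, p_g, p_n))
  }))
  M <- matrix(0, 512, 512)
  for (i in 1:512) {
    p <- occ_prob[i, ]
    M[i, ] <- apply(states, 1, function(t) prod(ifelse(t == 1, p, 1 - p)))
  }
  v <- numeric(512); v[1] <- 1  # empty lattice
  for (s in seq_len(steps)) v <- as.numeric(v %*% M)
  v
}

# Encode a 3x3 occupancy matrix as a state index in 1..512 (column-major
# bits), matching the enumeration order of exact_pattern_distribution().
encode_pattern <- function(occupancy) {
  sum(as.integer(occupancy) * 2^(0:8)) + 1L
}
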