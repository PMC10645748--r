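#' Specification for a synthetic cluster population
#'
#' Describes a per-cell population of membrane ion-channel clusters with
#' exponentially distributed volumes (the steady-state size law observed for
#' stochastically self-assembled clusters) and centroids placed uniformly on
#' a box-shaped membrane shell.
#'
#' @param n_clusters number of clusters (>= 0).
#' @param mean_volume mean of the exponential volume distribution, um^3.
#' @param spatial_domain box extents `c(x, y, z)` in um.
#' @param membrane_shell_thickness thickness of the membrane shell, um.
#' @param seed integer seed; the same spec and seed give identical output.
#' @return an object of class `cluster_spec`.
#' @export
cluster_spec <- function(n_clusters, mean_volume,
                         spatial_domain = c(12.8, 12.8, 4.16),
                         membrane_shell_thickness = 0.4,
                         seed = 1L) {
  n_clusters <- assert_count(n_clusters, "n_clusters")
  assert_positive(mean_volume, "mean_volume")
  if (length(spatial_domain) != 3L || any(spatial_domain <= 0))
    stopf("`spatial_domain` must be three positive extents in um")
  assert_positive(membrane_shell_thickness, "membrane_shell_thickness")
  if (membrane_shell_thickness * 2 >= min(spatial_domain))
    stopf("membrane shell thickness too large for the domain")
  structure(list(n_clusters = n_clusters, mean_volume = mean_volume,
                 spatial_domain = as.numeric(spatial_domain),
                 membrane_shell_thickness = membrane_shell_thickness,
                 seed = as.integer(seed)),
            class = "cluster_spec")
}

#' Generate a synthetic cluster population
#'
#' Volumes are i.i.d. exponential with mean `spec$mean_volume`; centroids are
#' uniform on the box shell of the spatial domain (within
#' `membrane_shell_thickness` of a face), emulating plasma-membrane-restricted
#' clusters. The returned table is the ground truth for recovery tests.
#'
#' @param spec a [cluster_spec()].
#' @return a `cluster_population`: a data.frame with columns `id`,
#'   `volume_um3`, `x_um`, `y_um`, `z_um`, `on_membrane`, carrying the domain
#'   and seed as attributes.
#' @export
gen_cluster_population <- function(spec) {
  stopifnot(inherits(spec, "cluster_spec"))
  n <- spec$n_clusters
  dom <- spec$spatial_domain
  t <- spec$membrane_shell_thickness
  pop <- with_seed(spec$seed, {
    vols <- if (n > 0) rexp(n, rate = 1 / spec$mean_volume) else numeric(0)
    pts <- matrix(numeric(0), ncol = 3)
    while (nrow(pts) < n) {
      m <- max(2L * (n - nrow(pts)), 16L)
      cand <- cbind(runif(m, 0, dom[1]), runif(m, 0, dom[2]),
                    runif(m, 0, dom[3]))
      inner <- cand[, 1] > t & cand[, 1] < dom[1] - t &
        cand[, 2] > t & cand[, 2] < dom[2] - t &
        cand[, 3] > t & cand[, 3] < dom[3] - t
      pts <- rbind(pts, cand[!inner, , drop = FALSE])
    }
    pts <- pts[seq_len(n), , drop = FALSE]
    data.frame(id = seq_len(n), volume_um3 = vols,
               x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
               on_membrane = rep(TRUE, n))
  })
  structure(pop, class = c("cluster_population", "data.frame"),
            spatial_domain = dom, seed = spec$seed,
            mean_volume = spec$mean_volume)
}

#' Specification for rendering an image stack
#'
#' @param voxel_size `c(x, y, z)` voxel size in um; the axial step defaults
#'   to 0.13 um, the optical sectioning used for confocal stacks.
#' @param psf_sigma Gaussian point-spread sigma in um; scalar (isotropic) or
#'   length 3.
#' @param background_level constant background intensity.
#' @param poisson_noise apply Poisson shot noise to the rendered intensity.
#' @param gaussian_sd additive Gaussian read noise sd (0 = off).
#' @param intensity_per_um3 integrated above-background intensity produced
#'   per um^3 of cluster volume (the proportionality constant).
#' @param seed integer seed for the noise draws.
#' @return an object of class `render_spec`.
#' @export
render_spec <- function(voxel_size = c(0.1, 0.1, 0.13),
                        psf_sigma = 0.15,
                        background_level = 10,
                        poisson_noise = TRUE,
                        gaussian_sd = 0,
                        intensity_per_um3 = 1e4,
                        seed = 1L) {
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stopf("`voxel_size` must be three positive values (x, y, z) in um")
  if (length(psf_sigma) == 1L) psf_sigma <- rep(psf_sigma, 3L)
  if (length(psf_sigma) != 3L || any(psf_sigma <= 0))
    stopf("`psf_sigma` must be positive (scalar or length 3)")
  if (background_level < 0 || gaussian_sd < 0)
    stopf("background and noise sd must be non-negative")
  assert_positive(intensity_per_um3, "intensity_per_um3")
  structure(list(voxel_size = as.numeric(voxel_size),
                 psf_sigma = as.numeric(psf_sigma),
                 background_level = background_level,
                 poisson_noise = isTRUE(poisson_noise),
                 gaussian_sd = gaussian_sd,
                 intensity_per_um3 = intensity_per_um3,
                 seed = as.integer(seed)),
            class = "render_spec")
}

new_image_stack <- function(data, voxel_size_um) {
  structure(data, class = "image_stack", voxel_size_um = voxel_size_um)
}

#' Construct an image stack from a 3D array
#'
#' @param data numeric 3D array (x, y, z).
#' @param voxel_size_um `c(x, y, z)` voxel size in um.
#' @return an `image_stack` carrying voxel-size metadata.
#' @export
image_stack <- function(data, voxel_size_um) {
  if (length(dim(data)) != 3L) stopf("`data` must be a 3D array")
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stopf("`voxel_size_um` must be three positive values")
  new_image_stack(data, as.numeric(voxel_size_um))
}

#' @export
dim.image_stack <- function(x) dim(unclass(x))

#' Voxel size metadata of an image stack
#' @param stack an `image_stack`.
#' @return numeric length-3 voxel size in um, or NULL if absent.
#' @export
voxel_size <- function(stack) attr(stack, "voxel_size_um")

#' Render a cluster population into a 3D image stack
#'
#' Each cluster becomes a 3D Gaussian blob centered on its centroid whose
#' integrated above-background intensity is `intensity_per_um3 * volume`.
#' Clusters whose centroid falls outside the domain are clipped to it with a
#' warning. Noise follows the spec (Poisson shot noise and/or additive
#' Gaussian read noise).
#'
#' @param pop a `cluster_population`.
#' @param spec a [render_spec()].
#' @return an `image_stack` (3D numeric array) carrying voxel-size metadata.
#' @export
render_image_stack <- function(pop, spec) {
  stopifnot(inherits(pop, "cluster_population"), inherits(spec, "render_spec"))
  dom <- attr(pop, "spatial_domain")
  vs <- spec$voxel_size
  dims <- pmax(1L, as.integer(ceiling(dom / vs)))
  img <- array(0, dim = dims)

  centers <- lapply(1:3, function(k) (seq_len(dims[k]) - 0.5) * vs[k])
  vvol <- prod(vs)

  if (nrow(pop) > 0) {
    cx <- pop$x_um; cy <- pop$y_um; cz <- pop$z_um
    out <- cx < 0 | cx > dom[1] | cy < 0 | cy > dom[2] | cz < 0 | cz > dom[3]
    if (any(out)) {
      warnf("%d cluster(s) outside the spatial domain; clipped", sum(out))
      cx <- pmin(pmax(cx, 0), dom[1])
      cy <- pmin(pmax(cy, 0), dom[2])
      cz <- pmin(pmax(cz, 0), dom[3])
    }
    s <- spec$psf_sigma
    for (i in seq_len(nrow(pop))) {
      tot <- spec$intensity_per_um3 * pop$volume_um3[i]
      win <- function(k, c0) {
        lo <- max(1L, as.integer(floor((c0 - 4 * s[k]) / vs[k])))
        hi <- min(dims[k], as.integer(ceiling((c0 + 4 * s[k]) / vs[k])))
        lo:hi
      }
      ix <- win(1, cx[i]); iy <- win(2, cy[i]); iz <- win(3, cz[i])
      gx <- stats::dnorm(centers[[1]][ix], cx[i], s[1])
      gy <- stats::dnorm(centers[[2]][iy], cy[i], s[2])
      gz <- stats::dnorm(centers[[3]][iz], cz[i], s[3])
      blob <- (tot * vvol) * (gx %o% gy %o% gz)
      img[ix, iy, iz] <- img[ix, iy, iz] + blob
    }
  }

  img <- img + spec$background_level
  img <- with_seed(spec$seed, {
    if (spec$poisson_noise) img <- array(rpois(length(img), img), dim = dims)
    if (spec$gaussian_sd > 0)
      img <- img + array(rnorm(length(img), 0, spec$gaussian_sd), dim = dims)
    img
  })
  new_image_stack(img, vs)
}

#' Specification for a coupled-gating sparklet simulation
#'
#' Generative counterpart of the coupled Markov chain used for coupling
#' inference: `n_channels` binary channels whose joint transitions mix an
#' independent kernel (weight `1 - kappa_true`) with a synchronized kernel
#' (weight `kappa_true`) that moves all channels together.
#'
#' @param n_channels number of channels N at the site.
#' @param kappa_true coupling coefficient in `[0, 1]` (0 = independent
#'   gating, 1 = fully synchronized opening/closing).
#' @param open_prob per-channel stationary open probability in (0, 1); must
#'   satisfy `open_prob < mean_open_frames / (mean_open_frames + 1)`.
#' @param quantal_amplitude fluorescence units per open channel.
#' @param noise_sd Gaussian measurement noise sd, fluorescence units.
#' @param sampling_rate Hz; defaults to 100, the sparklet acquisition rate.
#' @param duration trace length in seconds.
#' @param mean_open_frames mean open dwell time in frames of the per-channel
#'   two-state chain.
#' @param seed integer seed.
#' @return an object of class `sparklet_spec`.
#' @export
sparklet_spec <- function(n_channels, kappa_true, open_prob,
                          quantal_amplitude = 1, noise_sd = 0,
                          sampling_rate = 100, duration = 10,
                          mean_open_frames = 2, seed = 1L) {
  n_channels <- assert_count(n_channels, "n_channels", min = 1L)
  assert_prob(kappa_true, "kappa_true")
  if (open_prob <= 0 || open_prob >= 1)
    stopf("`open_prob` must be in (0, 1)")
  pmax_allowed <- mean_open_frames / (mean_open_frames + 1)
  if (open_prob >= pmax_allowed)
    stopf("`open_prob` must be < %.3f for mean open time %g frames",
          pmax_allowed, mean_open_frames)
  assert_positive(quantal_amplitude, "quantal_amplitude")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  assert_positive(sampling_rate, "sampling_rate")
  assert_positive(duration, "duration")
  structure(list(n_channels = n_channels, kappa_true = kappa_true,
                 open_prob = open_prob,
                 quantal_amplitude = quantal_amplitude, noise_sd = noise_sd,
                 sampling_rate = sampling_rate, duration = duration,
                 mean_open_frames = mean_open_frames,
                 seed = as.integer(seed)),
            class = "sparklet_spec")
}

#' Simulate a sparklet fluorescence trace with known coupling
#'
#' Draws the latent per-frame open-channel count from the coupled Markov
#' chain (see [coupled_transition_matrix()]), then forms the observed trace
#' as `level * quantal_amplitude + Gaussian noise`.
#'
#' @param spec a [sparklet_spec()].
#' @return a list with `trace` (a `sparklet_trace` data.frame: `frame`,
#'   `signal`, with `sampling_rate` attribute) and `record` (the ground-truth
#'   `idealized_record`).
#' @export
gen_sparklet_trace <- function(spec) {
  stopifnot(inherits(spec, "sparklet_spec"))
  n_frames <- as.integer(round(spec$duration * spec$sampling_rate))
  P <- coupled_transition_matrix(spec$n_channels, spec$open_prob,
                                 spec$kappa_true, spec$mean_open_frames)
  pi0 <- stationary_distribution(P)
  levels <- with_seed(spec$seed, {
    lv <- integer(n_frames)
    lv[1] <- sample(0:spec$n_channels, 1L, prob = pi0)
    for (t in seq_len(n_frames - 1L))
      lv[t + 1L] <- sample(0:spec$n_channels, 1L, prob = P[lv[t] + 1L, ])
    noise <- if (spec$noise_sd > 0) rnorm(n_frames, 0, spec$noise_sd) else 0
    attr(lv, "noise") <- noise
    lv
  })
  noise <- attr(levels, "noise"); attributes(levels) <- NULL
  trace <- data.frame(frame = seq_len(n_frames),
                      signal = levels * spec$quantal_amplitude + noise)
  trace <- structure(trace, class = c("sparklet_trace", "data.frame"),
                     sampling_rate = spec$sampling_rate)
  record <- new_idealized_record(levels)
  list(trace = trace, record = record)
}

#' Specification for a single-molecule blink movie
#'
#' Fixture generator for localization and rendering: each frame shows a
#' Gaussian camera spot at a random subset of the emitters, with the apparent
#' position jittered by the localization error.
#'
#' @param emitter_positions matrix or data.frame of (x, y) positions in nm.
#' @param frames number of frames; defaults to 35000, a full localization
#'   acquisition (tests use far fewer).
#' @param blink_prob per-frame probability that an emitter is on.
#' @param localization_noise_sd positional jitter sd in nm.
#' @param frame_dim `c(nx, ny)` camera frame size in pixels.
#' @param camera_pixel_nm camera pixel size in nm.
#' @param psf_sigma_nm camera-spot Gaussian sigma in nm.
#' @param spot_photons photons per blink event.
#' @param seed integer seed.
#' @return an object of class `blink_spec`.
#' @export
blink_spec <- function(emitter_positions, frames = 35000L, blink_prob = 0.1,
                       localization_noise_sd = 20,
                       frame_dim = c(32L, 32L), camera_pixel_nm = 100,
                       psf_sigma_nm = 120, spot_photons = 500,
                       seed = 1L) {
  em <- as.matrix(emitter_positions)
  if (ncol(em) != 2L) stopf("`emitter_positions` must be (x, y) nm pairs")
  frames <- assert_count(frames, "frames", min = 1L)
  assert_prob(blink_prob, "blink_prob")
  if (localization_noise_sd < 0) stopf("`localization_noise_sd` must be >= 0")
  structure(list(emitter_positions = em, frames = frames,
                 blink_prob = blink_prob,
                 localization_noise_sd = localization_noise_sd,
                 frame_dim = as.integer(frame_dim),
                 camera_pixel_nm = camera_pixel_nm,
                 psf_sigma_nm = psf_sigma_nm, spot_photons = spot_photons,
                 seed = as.integer(seed)),
            class = "blink_spec")
}

#' Simulate a blink movie
#'
#' @param spec a [blink_spec()].
#' @return a `blink_movie`: numeric array `(nx, ny, frames)` with
#'   `camera_pixel_nm` and the true emitter positions as attributes.
#' @export
gen_blink_movie <- function(spec) {
  stopifnot(inherits(spec, "blink_spec"))
  nx <- spec$frame_dim[1]; ny <- spec$frame_dim[2]
  px <- spec$camera_pixel_nm
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  mov <- with_seed(spec$seed, {
    m <- array(0, dim = c(nx, ny, spec$frames))
    n_em <- nrow(spec$emitter_positions)
    for (f in seq_len(spec$frames)) {
      on <- which(runif(n_em) < spec$blink_prob)
      for (e in on) {
        pos <- spec$emitter_positions[e, ] +
          rnorm(2L, 0, spec$localization_noise_sd)
        gx <- stats::dnorm(xc, pos[1], spec$psf_sigma_nm)
        gy <- stats::dnorm(yc, pos[2], spec$psf_sigma_nm)
        m[, , f] <- m[, , f] + spec$spot_photons * px^2 * (gx %o% gy)
      }
    }
    m
  })
  structure(mov, class = "blink_movie", camera_pixel_nm = px,
            emitter_positions = spec$emitter_positions)
}
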