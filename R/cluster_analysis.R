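#' Segmentation configuration for 3D cluster detection
#'
#' Defaults encode the standard spot-detection rules for confocal channel
#' clusters: a fixed absolute intensity threshold, a minimum size of three
#' voxels (any bright signal with a volume greater than two voxels counts as
#' a cluster), and minimum physical extents of 100 nm laterally and 150 nm
#' axially.
#'
#' @param intensity_threshold fixed absolute intensity level.
#' @param min_voxels minimum component size in voxels (default 3).
#' @param min_lateral_extent_nm minimum x/y bounding-box extent, nm.
#' @param min_axial_extent_nm minimum z bounding-box extent, nm.
#' @param membrane_restrict keep only clusters overlapping the membrane mask.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(intensity_threshold,
                                min_voxels = 3L,
                                min_lateral_extent_nm = 100,
                                min_axial_extent_nm = 150,
                                membrane_restrict = FALSE) {
  if (!is.numeric(intensity_threshold) || length(intensity_threshold) != 1L)
    stopf("`intensity_threshold` must be a single number")
  min_voxels <- assert_count(min_voxels, "min_voxels", min = 1L)
  assert_positive(min_lateral_extent_nm, "min_lateral_extent_nm")
  assert_positive(min_axial_extent_nm, "min_axial_extent_nm")
  structure(list(intensity_threshold = intensity_threshold,
                 min_voxels = min_voxels,
                 min_lateral_extent_nm = min_lateral_extent_nm,
                 min_axial_extent_nm = min_axial_extent_nm,
                 membrane_restrict = isTRUE(membrane_restrict)),
            class = "segmentation_config")
}

#' Segment clusters from a 3D image stack
#'
#' Thresholds the stack, labels 3D connected components (26-connectivity),
#' drops components smaller than `min_voxels` or below the physical extent
#' minima, and converts voxel counts to volumes in um^3 using the stack's
#' voxel-size metadata. With `membrane_restrict` and a mask, only components
#' overlapping the mask are kept (and flagged `on_membrane`).
#'
#' @param stack an `image_stack` with voxel-size metadata.
#' @param config a [segmentation_config()].
#' @param membrane_mask optional logical array of the same shape.
#' @return a `cluster_population` data.frame (`id`, `volume_um3`, `x_um`,
#'   `y_um`, `z_um`, `n_voxels`, `on_membrane`).
#' @export
segment_stack <- function(stack, config, membrane_mask = NULL) {
  stopifnot(inherits(config, "segmentation_config"))
  vs <- voxel_size(stack)
  if (is.null(vs))
    stopf(paste("stack carries no voxel-size metadata; read it with",
                "read_stack() or attach it via render_image_stack()"))
  dat <- unclass(stack)
  mask <- dat > config$intensity_threshold
  labels <- label_components(mask, connectivity = 26L)
  nlab <- max(labels)
  if (nlab == 0L) {
    pop <- data.frame(id = integer(0), volume_um3 = numeric(0),
                      x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                      n_voxels = integer(0), on_membrane = logical(0))
    return(structure(pop, class = c("cluster_population", "data.frame"),
                     spatial_domain = dim(dat) * vs, voxel_size_um = vs))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  co <- arrayInd(idx, dim(dat))
  nvox <- tabulate(lab, nbins = nlab)

  ext <- function(k) {
    rng_max <- tapply(co[, k], lab, max)
    rng_min <- tapply(co[, k], lab, min)
    (rng_max - rng_min + 1) * vs[k] * 1000  # nm
  }
  ext_x <- ext(1); ext_y <- ext(2); ext_z <- ext(3)

  keep <- nvox >= config$min_voxels &
    ext_x >= config$min_lateral_extent_nm &
    ext_y >= config$min_lateral_extent_nm &
    ext_z >= config$min_axial_extent_nm

  on_mem <- rep(TRUE, nlab)
  if (!is.null(membrane_mask)) {
    hit <- tapply(membrane_mask[idx] != 0, lab, any)
    on_mem <- as.logical(hit)
    if (config$membrane_restrict) keep <- keep & on_mem
  }

  cx <- tapply(co[, 1] - 0.5, lab, mean) * vs[1]
  cy <- tapply(co[, 2] - 0.5, lab, mean) * vs[2]
  cz <- tapply(co[, 3] - 0.5, lab, mean) * vs[3]

  sel <- which(keep)
  pop <- data.frame(id = seq_along(sel),
                    volume_um3 = nvox[sel] * prod(vs),
                    x_um = as.numeric(cx[sel]), y_um = as.numeric(cy[sel]),
                    z_um = as.numeric(cz[sel]),
                    n_voxels = nvox[sel], on_membrane = on_mem[sel])
  structure(pop, class = c("cluster_population", "data.frame"),
            spatial_domain = dim(dat) * vs, voxel_size_um = vs)
}

#' Segment puncta/clusters from a 2D map
#'
#' 8-connected component labeling of a thresholded 2D image (e.g., a
#' rendered localization map), with areas in nm^2 from the pixel size.
#'
#' @param map a matrix, or a `localization_map` (its rendered grid is used).
#' @param threshold intensity threshold (strictly above).
#' @param pixel_size_nm pixel size in nm (taken from the map if present).
#' @param min_pixels minimum component size in pixels.
#' @return a `cluster_population_2d` data.frame (`id`, `area_nm2`, `x_nm`,
#'   `y_nm`, `n_pixels`).
#' @export
segment_map <- function(map, threshold = 0, pixel_size_nm = NULL,
                        min_pixels = 1L) {
  if (inherits(map, "localization_map")) {
    pixel_size_nm <- pixel_size_nm %||% map$pixel_size_nm
    map <- map$rendered
  }
  if (is.null(pixel_size_nm)) stopf("`pixel_size_nm` is required")
  labels <- label_components(map > threshold, connectivity = 8L)
  nlab <- max(labels)
  if (nlab == 0L) {
    return(structure(data.frame(id = integer(0), area_nm2 = numeric(0),
                                x_nm = numeric(0), y_nm = numeric(0),
                                n_pixels = integer(0)),
                     class = c("cluster_population_2d", "data.frame"),
                     pixel_size_nm = pixel_size_nm))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  co <- arrayInd(idx, dim(map))
  npx <- tabulate(lab, nbins = nlab)
  sel <- which(npx >= min_pixels)
  cx <- tapply(co[, 1] - 0.5, lab, mean) * pixel_size_nm
  cy <- tapply(co[, 2] - 0.5, lab, mean) * pixel_size_nm
  structure(data.frame(id = seq_along(sel),
                       area_nm2 = npx[sel] * pixel_size_nm^2,
                       x_nm = as.numeric(cx[sel]), y_nm = as.numeric(cy[sel]),
                       n_pixels = npx[sel]),
            class = c("cluster_population_2d", "data.frame"),
            pixel_size_nm = pixel_size_nm)
}

#' Per-cell cluster metrics
#'
#' Counts, total and mean cluster volume, percent of the surface membrane
#' occupied, and cluster density. Membrane occupancy uses the
#' sphere-equivalent cross-section of each membrane cluster,
#' `pi * r^2` with `r = (3V / 4 pi)^(1/3)`, summed over membrane-restricted
#' clusters and divided by the membrane area.
#'
#' @param pop a `cluster_population`.
#' @param membrane_area_um2 cell membrane area in um^2 (> 0).
#' @return a `cell_metrics` list: `clusters_per_cell`, `total_cluster_volume`,
#'   `mean_cluster_volume` (NA with `mean_defined = FALSE` when empty),
#'   `membrane_occupancy_pct`, `cluster_density_per_um2`.
#' @export
cell_metrics <- function(pop, membrane_area_um2) {
  assert_positive(membrane_area_um2, "membrane_area_um2")
  n <- nrow(pop)
  v <- pop$volume_um3
  mem <- if (n > 0) pop$on_membrane else logical(0)
  r <- (3 * v[mem] / (4 * pi))^(1 / 3)
  occ <- sum(pi * r^2) / membrane_area_um2 * 100
  structure(list(clusters_per_cell = n,
                 total_cluster_volume = sum(v),
                 mean_cluster_volume = if (n > 0) mean(v) else NA_real_,
                 mean_defined = n > 0,
                 membrane_occupancy_pct = if (n > 0) occ else 0,
                 cluster_density_per_um2 = n / membrane_area_um2),
            class = "cell_metrics")
}

#' Fit a single exponential to a size distribution
#'
#' Least-squares fit of `count = A * exp(-size / tau)` on bin centers, via
#' Levenberg-Marquardt with a log-linear starting point. `tau` estimates the
#' mean of the underlying exponential size law.
#'
#' @param dist a `size_distribution` with at least 3 non-empty bins.
#' @return a list with `amplitude`, `tau`, `decay_rate` (= 1/tau), and
#'   `r_squared`.
#' @export
fit_exponential <- function(dist) {
  d <- dist[dist$count > 0, ]
  if (nrow(d) < 3L)
    stopf("exponential fit needs at least 3 non-empty bins, got %d", nrow(d))
  lf <- lm(log(count) ~ size, data = d)
  tau0 <- unname(-1 / coef(lf)[2])
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- mean(d$size)
  A0 <- unname(exp(coef(lf)[1]))
  fit <- minpack.lm::nlsLM(count ~ A * exp(-size / tau), data = d,
                           start = list(A = A0, tau = tau0),
                           lower = c(1e-12, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  pr <- stats::predict(fit)
  ss_res <- sum((d$count - pr)^2)
  ss_tot <- sum((d$count - mean(d$count))^2)
  cf <- coef(fit)
  list(amplitude = unname(cf["A"]), tau = unname(cf["tau"]),
       decay_rate = 1 / unname(cf["tau"]),
       r_squared = 1 - ss_res / ss_tot)
}

#' Macro/micro cluster volume threshold
#'
#' The lower volume limit of a macro-cluster is the population mean minus two
#' standard deviations (a 95% lower bound); the equivalent diameter assumes a
#' spherical cluster, `d = (6V / pi)^(1/3)`.
#'
#' @param mean_volume mean cluster volume, um^3.
#' @param sd_volume standard deviation of cluster volumes, um^3 (>= 0).
#' @return a `macro_threshold` list: `mean_volume`, `sd_volume`, `threshold`
#'   (um^3), `equivalent_diameter_nm`. A non-positive threshold raises a
#'   warning.
#' @export
macro_threshold <- function(mean_volume, sd_volume) {
  assert_positive(mean_volume, "mean_volume")
  if (!is.numeric(sd_volume) || length(sd_volume) != 1L || sd_volume < 0)
    stopf("`sd_volume` must be a single non-negative number")
  thr <- mean_volume - 2 * sd_volume
  if (thr <= 0)
    warnf("macro/micro threshold is non-positive (%.4g um^3)", thr)
  diam <- if (thr > 0) (6 * thr / pi)^(1 / 3) * 1000 else NA_real_
  structure(list(mean_volume = mean_volume, sd_volume = sd_volume,
                 threshold = thr, equivalent_diameter_nm = diam),
            class = "macro_threshold")
}

#' Classify clusters as macro or micro
#'
#' A cluster is a macro-cluster iff its volume is strictly larger than the
#' threshold.
#'
#' @param pop a `cluster_population`, or a numeric vector of volumes.
#' @param threshold volume threshold in um^3 (> 0), or a `macro_threshold`.
#' @return a list: `macro_count`, `micro_count`, `macro_fraction`,
#'   `micro_fraction`.
#' @export
classify_macro_micro <- function(pop, threshold) {
  if (inherits(threshold, "macro_threshold")) threshold <- threshold$threshold
  assert_positive(threshold, "threshold")
  v <- if (is.numeric(pop)) pop else pop$volume_um3
  macro <- sum(v > threshold)
  micro <- length(v) - macro
  list(macro_count = macro, micro_count = micro,
       macro_fraction = if (length(v)) macro / length(v) else NA_real_,
       micro_fraction = if (length(v)) micro / length(v) else NA_real_)
}

# 2D Gaussian centroid fit on a small patch; returns (x, y) in pixel units
# (zero-based centers at i - 0.5) and the photon count. Falls back to the
# intensity-weighted centroid if the nonlinear fit fails.
.fit_spot <- function(patch, x0, y0) {
  xs <- seq_len(nrow(patch)) - 0.5 + x0
  ys <- seq_len(ncol(patch)) - 0.5 + y0
  w <- pmax(patch, 0)
  tot <- sum(w)
  mx <- sum(outer(xs, rep(1, length(ys))) * w) / tot
  my <- sum(outer(rep(1, length(xs)), ys) * w) / tot
  d <- data.frame(x = rep(xs, times = length(ys)),
                  y = rep(ys, each = length(xs)),
                  z = as.vector(patch))
  s0 <- max(0.8, sqrt(sum(w * ((d$x - mx)^2 + (d$y - my)^2)) / (2 * tot)))
  fit <- tryCatch(
    minpack.lm::nlsLM(z ~ A * exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2)),
                      data = d,
                      start = list(A = max(patch), cx = mx, cy = my, s = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(c(x = mx, y = my, photons = tot))
  cf <- coef(fit)
  c(x = unname(cf["cx"]), y = unname(cf["cy"]),
    photons = unname(2 * pi * cf["A"] * cf["s"]^2))
}

#' Localize single-molecule blinks and render a localization map
#'
#' Per frame: pixels above `detect_level` are grouped into spots
#' (8-connectivity), each spot is fit with a 2D Gaussian to localize its
#' centroid, and fits below `photon_threshold` photons are discarded.
#' Accepted centroids are accumulated over frames and rendered as a 2D count
#' histogram at `pixel_size_nm` per pixel (zero-based pixels, half-open
#' physical bins).
#'
#' @param movie a `blink_movie` (or plain 3D array plus `camera_pixel_nm`).
#' @param photon_threshold minimum fitted photons per localization.
#' @param pixel_size_nm rendering pixel size, nm (default 20).
#' @param detect_level detection intensity level; defaults to 20% of the
#'   movie maximum.
#' @param camera_pixel_nm camera pixel size; taken from the movie if present.
#' @return a `localization_map`: list with `points` (x, y in nm),
#'   `rendered` (count matrix), `pixel_size_nm`.
#' @export
localize_and_render <- function(movie, photon_threshold = 0,
                                pixel_size_nm = 20, detect_level = NULL,
                                camera_pixel_nm = NULL) {
  camera_pixel_nm <- camera_pixel_nm %||% attr(movie, "camera_pixel_nm")
  if (is.null(camera_pixel_nm)) stopf("`camera_pixel_nm` is required")
  dm <- dim(movie)
  if (length(dm) != 3L || dm[3] < 1L) stopf("movie must be a non-empty stack")
  detect_level <- detect_level %||% (0.2 * max(movie))
  pts <- list()
  for (f in seq_len(dm[3])) {
    fr <- movie[, , f]
    labels <- label_components(fr > detect_level, connectivity = 8L)
    nlab <- max(labels)
    if (nlab == 0L) next
    for (l in seq_len(nlab)) {
      w <- which(labels == l, arr.ind = TRUE)
      pad <- 2L
      rx <- max(1L, min(w[, 1]) - pad):min(dm[1], max(w[, 1]) + pad)
      ry <- max(1L, min(w[, 2]) - pad):min(dm[2], max(w[, 2]) + pad)
      est <- .fit_spot(fr[rx, ry, drop = FALSE], rx[1] - 1L, ry[1] - 1L)
      if (est["photons"] > photon_threshold)
        pts[[length(pts) + 1L]] <-
          c(est["x"] * camera_pixel_nm, est["y"] * camera_pixel_nm)
    }
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    matrix(numeric(0), ncol = 2)
  colnames(points) <- c("x_nm", "y_nm")
  extent_nm <- dm[1:2] * camera_pixel_nm
  render_localizations(points, extent_nm, pixel_size_nm)
}

#' Render localization points onto a pixel grid
#'
#' @param points matrix of (x, y) nm.
#' @param extent_nm `c(x, y)` physical extent of the grid, nm.
#' @param pixel_size_nm rendering pixel size, nm.
#' @return a `localization_map`.
#' @export
render_localizations <- function(points, extent_nm, pixel_size_nm = 20) {
  assert_positive(pixel_size_nm, "pixel_size_nm")
  npx <- pmax(1L, as.integer(ceiling(extent_nm / pixel_size_nm)))
  grid <- matrix(0, nrow = npx[1], ncol = npx[2])
  if (nrow(points)) {
    px <- floor(points[, 1] / pixel_size_nm)   # zero-based
    py <- floor(points[, 2] / pixel_size_nm)
    ok <- px >= 0 & px < npx[1] & py >= 0 & py < npx[2]
    for (i in which(ok))
      grid[px[i] + 1L, py[i] + 1L] <- grid[px[i] + 1L, py[i] + 1L] + 1
  }
  structure(list(points = points, rendered = grid,
                 pixel_size_nm = pixel_size_nm),
            class = "localization_map")
}

#' Pixel index of a physical coordinate
#'
#' Zero-based pixels with half-open bins: coordinate `x` nm lands in pixel
#' `floor(x / pixel_size)`.
#'
#' @param x_nm physical coordinate(s) in nm.
#' @param pixel_size_nm pixel size in nm.
#' @return integer pixel index (zero-based).
#' @export
point_to_pixel <- function(x_nm, pixel_size_nm) {
  as.integer(floor(x_nm / pixel_size_nm))
}

#' Gaussian blur of a rendered localization map
#'
#' Replaces each pixel by a Gaussian-weighted average of its neighbors
#' within `radius_nm` (sigma = radius/2, kernel truncated at the radius),
#' emulating the loss of resolution from localization to confocal imaging.
#' Convolution is circular, so total intensity is conserved exactly and the
#' operation is translation invariant.
#'
#' @param map a `localization_map` or plain matrix.
#' @param radius_nm blur kernel radius in nm (default 200); 0 returns the
#'   input unchanged.
#' @param pixel_size_nm pixel size (taken from the map if present).
#' @return the blurred map (same type as the input).
#' @export
gaussian_blur_gsd <- function(map, radius_nm = 200, pixel_size_nm = NULL) {
  is_map <- inherits(map, "localization_map")
  img <- if (is_map) map$rendered else map
  pixel_size_nm <- pixel_size_nm %||%
    (if (is_map) map$pixel_size_nm else NULL)
  if (is.null(pixel_size_nm)) stopf("`pixel_size_nm` is required")
  if (radius_nm < 0) stopf("`radius_nm` must be >= 0")
  if (radius_nm == 0) return(map)

  sigma_px <- (radius_nm / 2) / pixel_size_nm
  h <- max(1L, as.integer(ceiling(radius_nm / pixel_size_nm)))
  k1 <- stats::dnorm(seq(-h, h), sd = sigma_px)
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)

  nr <- nrow(img); nc <- ncol(img)
  if (2 * h + 1 > nr || 2 * h + 1 > nc)
    stopf("blur kernel (%d px) exceeds image size", 2 * h + 1)
  kpad <- matrix(0, nr, nc)
  kpad[1:(2 * h + 1), 1:(2 * h + 1)] <- kern
  # center the kernel at [1,1] with wrap-around
  kpad <- kpad[c((h + 1):nr, seq_len(h)), c((h + 1):nc, seq_len(h))]
  out <- Re(stats::fft(stats::fft(img) * stats::fft(kpad), inverse = TRUE)) /
    (nr * nc)
  if (is_map) {
    map$rendered <- out
    map
  } else out
}

#' Quantify proximity-ligation puncta for a cell
#'
#' @param puncta a `cluster_population_2d` of PLA puncta (areas in nm^2).
#' @param cell_area_um2 cell area, um^2 (> 0).
#' @return a `pla_result` list: `puncta_count`, `puncta_density_per_um2`,
#'   `total_puncta_area_um2`.
#' @export
pla_quantify <- function(puncta, cell_area_um2) {
  assert_positive(cell_area_um2, "cell_area_um2")
  n <- nrow(puncta)
  area_um2 <- if (n > 0) sum(puncta$area_nm2) / 1e6 else 0
  structure(list(puncta_count = n,
                 puncta_density_per_um2 = n / cell_area_um2,
                 total_puncta_area_um2 = area_um2),
            class = "pla_result")
}
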