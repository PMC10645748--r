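test_that("segmentation applies the voxel-count and extent rules", {
  vs <- c(0.1, 0.1, 0.13)
  dat <- array(0, dim = c(16, 16, 8))
  dat[4:6, 4:6, 3:5] <- 100            # 27-voxel blob
  stk <- image_stack(dat, vs)
  cfg <- segmentation_config(intensity_threshold = 50)
  pop <- segment_stack(stk, cfg)
  expect_equal(nrow(pop), 1L)
  expect_equal(pop$n_voxels, 27L)
  expect_equal(pop$volume_um3, 27 * prod(vs))
  # centroid at the blob center, physical units
  expect_equal(pop$x_um, 4.5 * 0.1)
  expect_equal(pop$z_um, 3.5 * 0.13)

  # a 2-voxel blob is rejected: clusters must exceed two voxels
  dat2 <- array(0, dim = c(16, 16, 8))
  dat2[4:5, 4, 3] <- 100
  expect_equal(nrow(segment_stack(image_stack(dat2, vs), cfg)), 0L)

  # three voxels in a lateral row fail the axial 150 nm minimum
  dat3 <- array(0, dim = c(16, 16, 8))
  dat3[4:6, 4, 3] <- 100
  expect_equal(nrow(segment_stack(image_stack(dat3, vs), cfg)), 0L)
  # ... but pass when stacked over two z planes
  dat4 <- array(0, dim = c(16, 16, 8))
  dat4[4:6, 4, 3:4] <- 100
  expect_equal(nrow(segment_stack(image_stack(dat4, vs), cfg)), 1L)

  # missing voxel metadata is refused
  expect_error(segment_stack(structure(dat, class = "image_stack"), cfg),
               "metadata")
})

test_that("segmentation is idempotent on its own binary output", {
  pop <- make_grid_population(12)
  stk <- render_high_snr(pop, noise_sd = 0)
  cfg <- segmentation_config(intensity_threshold = 100)
  seg1 <- segment_stack(stk, cfg)
  binary <- image_stack((unclass(stk) > 100) * 1000, voxel_size(stk))
  seg2 <- segment_stack(binary, cfg)
  expect_equal(nrow(seg2), nrow(seg1))
  expect_equal(sort(seg2$n_voxels), sort(seg1$n_voxels))
})

test_that("membrane restriction keeps only mask-overlapping clusters", {
  vs <- c(0.1, 0.1, 0.13)
  dat <- array(0, dim = c(16, 16, 8))
  dat[2:4, 2:4, 2:4] <- 100
  dat[10:12, 10:12, 5:7] <- 100
  mask <- array(FALSE, dim = dim(dat))
  mask[1:5, 1:5, ] <- TRUE
  cfg <- segmentation_config(intensity_threshold = 50,
                             membrane_restrict = TRUE)
  pop <- segment_stack(image_stack(dat, vs), cfg, membrane_mask = mask)
  expect_equal(nrow(pop), 1L)
  expect_true(all(pop$on_membrane))
})

test_that("cell metrics aggregate volumes and occupancy correctly", {
  pop <- make_grid_population(2)
  pop$volume_um3 <- c(0.05, 0.07)
  m <- cell_metrics(pop, membrane_area_um2 = 100)
  expect_equal(m$clusters_per_cell, 2L)
  expect_equal(m$total_cluster_volume, 0.12)
  expect_equal(m$mean_cluster_volume, 0.06)
  expect_equal(m$cluster_density_per_um2, 0.02)
  r <- (3 * c(0.05, 0.07) / (4 * pi))^(1 / 3)
  expect_equal(m$membrane_occupancy_pct, sum(pi * r^2))

  empty <- gen_cluster_population(cluster_spec(0, 0.1))
  m0 <- cell_metrics(empty, 100)
  expect_equal(m0$clusters_per_cell, 0L)
  expect_equal(m0$membrane_occupancy_pct, 0)
  expect_false(m0$mean_defined)

  pop500 <- gen_cluster_population(cluster_spec(500, 0.14, seed = 2))
  m500 <- cell_metrics(pop500, 600)
  expect_lt(abs(m500$mean_cluster_volume - 0.14), 3 * 0.14 / sqrt(500))
})

test_that("exponential fits recover the size-law mean and its ordering", {
  pop <- gen_cluster_population(cluster_spec(1e4, 0.07, seed = 1))
  d <- size_distribution(pop$volume_um3, binwidth = 0.02)
  fit <- fit_exponential(d)
  expect_lt(abs(fit$tau - 0.07) / 0.07, 0.05)
  expect_gt(fit$r_squared, 0.95)

  pop2 <- gen_cluster_population(cluster_spec(1e4, 0.14, seed = 2))
  fit2 <- fit_exponential(size_distribution(pop2$volume_um3, binwidth = 0.02))
  expect_gt(fit2$tau, fit$tau)

  lone <- structure(data.frame(size = c(1, 2, 3), count = c(0, 5, 0),
                               relative_frequency = c(0, 1, 0)),
                    class = c("size_distribution", "data.frame"))
  expect_error(fit_exponential(lone), "3 non-empty bins")
})

test_that("macro/micro threshold and classification follow the volume rule", {
  thr <- macro_threshold(0.12, 0.03)
  expect_equal(thr$threshold, 0.06)
  expect_equal(thr$equivalent_diameter_nm, (6 * 0.06 / pi)^(1 / 3) * 1000)
  expect_equal(round(thr$equivalent_diameter_nm), 486)
  expect_equal(macro_threshold(0.1, 0)$threshold, 0.1)
  expect_warning(macro_threshold(0.05, 0.04), "non-positive")
  expect_error(macro_threshold(0.1, -0.01), "non-negative")

  cls <- classify_macro_micro(c(0.05, 0.07), 0.06)
  expect_equal(cls$macro_count, 1L)
  expect_equal(cls$micro_count, 1L)
  # boundary volume is micro: strictly larger than the threshold is macro
  expect_equal(classify_macro_micro(c(0.06), 0.06)$macro_count, 0L)
  expect_equal(classify_macro_micro(c(0.01, 0.02), 0.06)$macro_fraction, 0)

  # raising the threshold never increases the macro count
  v <- gen_cluster_population(cluster_spec(2000, 0.1, seed = 3))$volume_um3
  counts <- vapply(seq(0.02, 0.3, by = 0.02),
                   function(t) classify_macro_micro(v, t)$macro_count,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("localization maps use zero-based half-open pixel bins", {
  expect_equal(point_to_pixel(100, 20), 5L)
  expect_equal(point_to_pixel(c(0, 19.9, 20), 20), c(0L, 0L, 1L))
  map <- render_localizations(cbind(100, 100), extent_nm = c(400, 400),
                              pixel_size_nm = 20)
  expect_equal(which(map$rendered > 0, arr.ind = TRUE)[1, ],
               c(row = 6L, col = 6L))  # pixel (5, 5), zero-based
})

test_that("the confocal-emulating blur conserves intensity and merges", {
  # delta image -> kernel image with the same total
  map <- render_localizations(cbind(500, 500), extent_nm = c(1000, 1000),
                              pixel_size_nm = 20)
  bl <- gaussian_blur_gsd(map, 200)
  expect_equal(sum(bl$rendered), sum(map$rendered), tolerance = 1e-6)
  expect_gt(max(map$rendered), max(bl$rendered))

  # radius 0 returns the input untouched
  expect_identical(gaussian_blur_gsd(map, 0), map)

  # translation invariance up to the (circular) edge rule
  img <- matrix(0, 40, 40); img[10, 12] <- 3
  shift <- function(m, k) m[c((nrow(m) - k + 1):nrow(m), 1:(nrow(m) - k)), ]
  b1 <- gaussian_blur_gsd(shift(img, 5), 200, pixel_size_nm = 20)
  b2 <- shift(gaussian_blur_gsd(img, 200, pixel_size_nm = 20), 5)
  expect_equal(b1, b2, tolerance = 1e-10)

  # two point groups < 200 nm apart blur into one connected blob
  pts <- rbind(c(400, 400), c(550, 400))
  map2 <- render_localizations(pts, extent_nm = c(1000, 1000),
                               pixel_size_nm = 20)
  expect_equal(nrow(segment_map(map2, threshold = 0)), 2L)
  bl2 <- gaussian_blur_gsd(map2, 200)
  expect_equal(nrow(segment_map(bl2, threshold = 1e-4)), 1L)
})

test_that("PLA quantification is density and area bookkeeping", {
  pts <- make_grid_population(10)  # reuse ids only
  puncta <- structure(data.frame(id = 1:10, area_nm2 = rep(2e4, 10),
                                 x_nm = runif(10, 0, 1e4),
                                 y_nm = runif(10, 0, 1e4),
                                 n_pixels = rep(50L, 10)),
                      class = c("cluster_population_2d", "data.frame"))
  res <- pla_quantify(puncta, cell_area_um2 = 100)
  expect_equal(res$puncta_density_per_um2, 0.1)
  expect_equal(res$total_puncta_area_um2, 10 * 2e4 / 1e6)

  none <- puncta[0, ]
  res0 <- pla_quantify(none, 100)
  expect_equal(res0$puncta_count, 0L)
  expect_equal(res0$total_puncta_area_um2, 0)

  # homogeneous Poisson placement: estimated density within 3 SE of truth
  set.seed(8)
  rho <- 0.5; area <- 400
  n <- rpois(1, rho * area)
  pp <- structure(data.frame(id = seq_len(n), area_nm2 = rep(1e3, n),
                             x_nm = runif(n, 0, 2e4), y_nm = runif(n, 0, 2e4),
                             n_pixels = rep(1L, n)),
                  class = c("cluster_population_2d", "data.frame"))
  est <- pla_quantify(pp, area)$puncta_density_per_um2
  expect_lt(abs(est - rho), 3 * sqrt(rho / area))
})
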