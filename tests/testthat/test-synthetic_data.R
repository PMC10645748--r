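test_that("cluster populations match their generating spec", {
  expect_equal(nrow(gen_cluster_population(cluster_spec(0, 0.1))), 0L)
  expect_error(cluster_spec(10, -0.1), "mean_volume")
  expect_error(cluster_spec(10, 0), "mean_volume")

  # law of large numbers: sample mean within 3 SE of the exponential mean
  pop <- gen_cluster_population(cluster_spec(1e4, 0.07, seed = 1))
  se <- 0.07 / sqrt(1e4)
  expect_lt(abs(mean(pop$volume_um3) - 0.07), 3 * se)

  # volumes pass an exponential goodness-of-fit test at alpha = 0.01
  pop2 <- gen_cluster_population(cluster_spec(2000, 0.12, seed = 4))
  ks <- suppressWarnings(stats::ks.test(pop2$volume_um3, "pexp",
                                        rate = 1 / 0.12))
  expect_gt(ks$p.value, 0.01)

  # centroids stay on the membrane shell
  dom <- attr(pop2, "spatial_domain")
  t <- 0.4
  inner <- pop2$x_um > t & pop2$x_um < dom[1] - t &
    pop2$y_um > t & pop2$y_um < dom[2] - t &
    pop2$z_um > t & pop2$z_um < dom[3] - t
  expect_false(any(inner))
})

test_that("generators are deterministic under a fixed seed", {
  a <- gen_cluster_population(cluster_spec(500, 0.07, seed = 7))
  b <- gen_cluster_population(cluster_spec(500, 0.07, seed = 7))
  expect_identical(a, b)

  s <- sparklet_spec(3, 0.4, 0.1, noise_sd = 0.2, duration = 2, seed = 7)
  expect_identical(gen_sparklet_trace(s), gen_sparklet_trace(s))

  bs <- blink_spec(cbind(1600, 1600), frames = 20, blink_prob = 0.5, seed = 7)
  expect_identical(gen_blink_movie(bs), gen_blink_movie(bs))
})

test_that("rendered stacks have volume-proportional integrated intensity", {
  pop <- make_grid_population(1, volume = 0.1)
  spec <- render_spec(background_level = 0, poisson_noise = FALSE,
                      gaussian_sd = 0, intensity_per_um3 = 1e5)
  stk <- render_image_stack(pop, spec)
  expect_equal(sum(stk) / (1e5 * 0.1), 1, tolerance = 0.01)
  expect_equal(voxel_size(stk), c(0.1, 0.1, 0.13))

  # empty population: background plus noise only
  empty <- gen_cluster_population(cluster_spec(0, 0.1))
  stk0 <- render_image_stack(empty, render_spec(background_level = 5,
                                                poisson_noise = FALSE,
                                                gaussian_sd = 0))
  expect_true(all(stk0 == 5))

  # a centroid outside the domain is clipped with a warning
  out_pop <- make_grid_population(1)
  out_pop$x_um <- -1
  expect_warning(render_image_stack(out_pop, spec), "clipped")
})

test_that("coupled-trace marginals match the coupling endpoints", {
  # kappa = 1, N = 3: only levels 0 and N occur
  sim1 <- gen_sparklet_trace(sparklet_spec(3, 1, 0.1, duration = 20,
                                           seed = 3))
  expect_true(all(sim1$record$levels %in% c(0L, 3L)))

  # kappa = 0, N = 2: aggregate level is Binomial(2, p)
  sim0 <- gen_sparklet_trace(sparklet_spec(2, 0, 0.1, duration = 200,
                                           seed = 5))
  obs <- tabulate(sim0$record$levels + 1L, nbins = 3L)
  expected <- stats::dbinom(0:2, 2, 0.1)
  chi <- suppressWarnings(stats::chisq.test(obs, p = expected))
  expect_gt(chi$p.value, 0.01)

  # duration x sampling rate fixes the frame count
  sim <- gen_sparklet_trace(sparklet_spec(2, 0.5, 0.1, duration = 10,
                                          sampling_rate = 100, seed = 1))
  expect_equal(nrow(sim$trace), 1000L)

  expect_error(sparklet_spec(2, 1.5, 0.1), "kappa")
  expect_error(sparklet_spec(2, 0.5, 0.9), "open_prob")
})

test_that("blink movies place jittered spots at emitters", {
  em <- cbind(1600, 1600)
  expect_true(all(gen_blink_movie(blink_spec(em, frames = 5,
                                             blink_prob = 0)) == 0))
  mov <- gen_blink_movie(blink_spec(em, frames = 150, blink_prob = 1,
                                    localization_noise_sd = 20, seed = 9))
  locs <- localize_and_render(mov, detect_level = 1)
  pts <- locs$points
  expect_gt(nrow(pts), 100)
  se <- apply(pts, 2, stats::sd) / sqrt(nrow(pts))
  expect_lt(abs(mean(pts[, 1]) - 1600), 3 * se[1])
  expect_lt(abs(mean(pts[, 2]) - 1600), 3 * se[2])
})
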