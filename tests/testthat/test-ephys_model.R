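test_that("functional-fraction scaling reproduces reported densities", {
  male <- myocyte_reference_iv("male")
  female <- myocyte_reference_iv("female")

  expect_equal(scale_current(male, 0.5)$reported_density, 3503)
  expect_equal(scale_current(male, 0.1)$reported_density, 701)
  expect_equal(scale_current(male, 0.01)$reported_density, 70.1)
  expect_equal(scale_current(female, 0.5)$reported_density, 8646)
  expect_equal(scale_current(female, 0.1)$reported_density, 1729)
  expect_equal(scale_current(female, 0.01)$reported_density, 173)

  # identity at f = 1
  expect_equal(scale_current(male, 1)$predicted_density, male$density_pA_pF)
  expect_error(scale_current(male, 1.2), "fraction")
  expect_error(scale_current(male, -0.1), "fraction")
})

test_that("scaling is multiplicative before report-time rounding", {
  ref <- reference_iv(seq(-50, 50, 25), c(0, 10, 250, 1500, 7006))
  a <- 0.4; b <- 0.25
  one <- scale_current(ref, a * b)$predicted_density
  two <- scale_current(reference_iv(ref$voltage_mV,
                                    scale_current(ref, a)$predicted_density),
                       b)$predicted_density
  expect_equal(one, two, tolerance = 1e-12)
})

test_that("drug subtraction isolates the blocker-sensitive component", {
  rec <- synthetic_kv_recording()
  zero <- drug_subtraction(rec, rec)
  expect_true(all(zero$traces == 0))

  # post = pre - known component: subtraction recovers the component exactly
  comp <- synthetic_kv_recording(g_max = 4, v_half = 10)
  post <- step_recording(rec$time_ms, rec$traces - comp$traces,
                         rec$voltages, rec$capacitance_pF)
  sens <- drug_subtraction(rec, post)
  expect_equal(sens$traces, comp$traces)

  # subtraction then addition round-trips the original traces
  back <- step_recording(post$time_ms, post$traces + sens$traces,
                         post$voltages, post$capacitance_pF)
  expect_equal(back$traces, rec$traces)

  # null-genotype analogue: post = pre + noise, sensitive current ~ 0
  set.seed(2)
  noisy <- step_recording(rec$time_ms,
                          rec$traces + rnorm(length(rec$traces), 0, 1),
                          rec$voltages, rec$capacitance_pF)
  resid <- drug_subtraction(rec, noisy)
  per_v <- colMeans(resid$traces)
  expect_true(all(abs(per_v) < 3 * 1 / sqrt(nrow(resid$traces))))

  mism <- synthetic_kv_recording(voltages = seq(-60, 60, 10))
  expect_error(drug_subtraction(rec, mism), "protocols differ|voltage")
})

test_that("IV construction windows, normalizes, and validates", {
  rec <- synthetic_kv_recording(capacitance_pF = 16)
  iv <- build_iv(rec)
  # Boltzmann conductance: monotone increasing above activation
  up <- iv$density_pA_pF[iv$voltage_mV >= 0]
  expect_true(all(diff(up) > 0))

  # doubling capacitance halves densities
  rec2 <- step_recording(rec$time_ms, rec$traces, rec$voltages, 32)
  expect_equal(build_iv(rec2)$density_pA_pF, iv$density_pA_pF / 2)

  # all-zero traces give an all-zero IV
  z <- step_recording(rec$time_ms, rec$traces * 0, rec$voltages, 16)
  expect_true(all(build_iv(z)$density_pA_pF == 0))

  expect_error(build_iv(rec, window = c(400, 600)), "window")

  # junction-potential correction shifts the voltage axis only
  cor <- correct_junction_potential(iv, 13)
  expect_equal(cor$voltage_mV, iv$voltage_mV - 13)
  expect_equal(cor$density_pA_pF, iv$density_pA_pF)
})
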