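test_that("a single stirred tank with a large reservoir follows 1 - exp(-t/tau)", {
  mod <- washout_model(chamber_volume = 4.8e-6, reservoir_volume = 1,
                       flow_rate = 1e-6 / 60, n_tanks = 1,
                       bypass_fraction = 0, noise_cv = 0,
                       sampling_times = 0:30)
  sim <- simulate_washout(mod)
  tau <- 4.8
  expected <- (1 - exp(-(0:30) / tau))
  expected <- expected / max(expected)
  expect_equal(sim$clean_normalized, expected, tolerance = 1e-6)
  # 95% of the asymptote is reached at 3*tau = 14.4 min -> first sample 15
  expect_equal(sim$truth_equilibration_time, 15)
  expect_false(sim$overshoot_truth)
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_washout(washout_model(seed = 7))
  b <- simulate_washout(washout_model(seed = 7))
  d <- simulate_washout(washout_model(seed = 8))
  expect_identical(a$series, b$series)
  expect_false(identical(a$series$raw, d$series$raw))
})

test_that("noise-free series are monotone without bypass, single-peaked with", {
  mono <- simulate_washout(washout_model(noise_cv = 0, bypass_fraction = 0))
  expect_true(all(diff(mono$series$normalized) >= -1e-9))
  over <- simulate_washout(washout_model(noise_cv = 0, bypass_fraction = 0.6,
                                         reservoir_volume = 2e-6,
                                         chamber_volume = 4e-6))
  v <- over$series$normalized
  ipk <- which.max(v)
  expect_lt(ipk, length(v))                       # peaks before the end
  expect_true(all(diff(v[1:ipk]) >= -1e-9))       # rises to the peak
  expect_lt(v[length(v)], v[ipk] - 0.1)           # then clearly declines
  expect_true(over$overshoot_truth)
})

test_that("the estimator recovers the truth exactly without noise", {
  suite <- recovery_suite(list(washout_model(noise_cv = 0, seed = 1)))
  expect_equal(suite$bias_min, 0)
})

test_that("recovery bias stays within one sampling interval at 5% noise", {
  models <- lapply(1:30, function(s) washout_model(seed = s, noise_cv = 0.05))
  suite <- recovery_suite(models)
  expect_lte(stats::median(abs(suite$bias_intervals)), 1)
  # halving the sampling cadence does not increase the median bias (min)
  models2 <- lapply(1:30, function(s)
    washout_model(seed = s, noise_cv = 0.05, sampling_times = seq(0, 30, 0.5)))
  suite2 <- recovery_suite(models2)
  expect_lte(stats::median(abs(suite2$bias_min)),
             stats::median(abs(suite$bias_min)) + 1e-9)
})

test_that("manufactured solutions expose their closed forms", {
  ch <- manufactured_solution("channel_flow", flow_rate = 1e-6 / 60,
                              height = 2e-3, depth = 10e-3)
  umean <- (1e-6 / 60) / (2e-3 * 10e-3)
  expect_equal(ch$peak, 1.5 * umean)
  expect_equal(ch$u(1e-3), ch$peak)
  expect_equal(ch$tau_wall, 6 * 1e-3 * (1e-6 / 60) / (10e-3 * (2e-3)^2))
  ag <- manufactured_solution("advected_gaussian", D = 1e-8, sigma0 = 1e-3)
  expect_equal(ag$sigma2(10), 1e-6 + 2e-7)
  bz <- manufactured_solution("bead_zero_order", radius = 125e-6)
  expect_equal(bz$center, zero_order_center(bead_problem(radius = 125e-6)))
  expect_equal(bz$c(125e-6), 0.214)
  expect_error(manufactured_solution("warp_field"), "unknown case")
})

test_that("washout models validate their structure", {
  expect_error(washout_model(bypass_fraction = 1), "\\[0, 1\\)")
  expect_error(washout_model(n_tanks = 0), ">= 1")
  expect_error(washout_model(sampling_times = c(0, 1)), "4 increasing")
  expect_error(washout_model(noise_cv = -0.1), "non-negative")
})
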