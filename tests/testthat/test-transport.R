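test_that("a step equal to the initial concentration leaves the field constant", {
  fx <- channel_flow_fixture(0.2e-3)
  ser <- solve_transient_transport(
    fx$sol, species_transport("tc", 1e-8),
    transport_scenario(1, initial_concentration = 1, duration = 60, dt = 5,
                       output_every = 30))
  expect_equal(ser$series$min, rep(1, nrow(ser$series)), tolerance = 1e-10)
  expect_equal(ser$series$mean, rep(1, nrow(ser$series)), tolerance = 1e-10)
})

test_that("plug-flow breakthrough arrives at the residence time", {
  m <- generate_mesh(build_channel(length = 20e-3, height = 2e-3,
                                   depth = 10e-3), 0.2e-3)
  u <- 1e-4
  sol <- uniform_flow_solution(m, u)
  t_res <- 20e-3 / u   # 200 s
  ser <- solve_transient_transport(
    sol, species_transport("tc", 1e-10),
    transport_scenario(1, duration = 400, dt = 1, output_every = 5))
  # mid-rise of the outlet curve marks the front arrival
  t_half <- with(ser$series, stats::approx(outlet, time, xout = 0.5)$y)
  expect_equal(t_half, t_res, tolerance = 0.10)
})

test_that("a diffusing Gaussian follows the analytic variance growth", {
  m <- generate_mesh(build_channel(length = 20e-3, height = 2e-3,
                                   depth = 10e-3), 0.2e-3)
  sol <- solve_flow(m, bc = flow_bc(0))
  D <- 1e-8; s0 <- 1e-3; x0 <- 10e-3
  ms <- manufactured_solution("advected_gaussian", D = D, sigma0 = s0, x0 = x0)
  init <- matrix(rep(exp(-(m$xc - x0)^2 / (2 * s0^2)), m$ny), m$nx, m$ny)
  tend <- 60
  ser <- solve_transient_transport(
    sol, species_transport("tc", D),
    transport_scenario(1e-30, duration = tend, dt = 0.5, output_every = tend),
    store_fields = TRUE, initial_field = init)
  f <- ser$fields[[length(ser$fields)]]
  # variance of the x-marginal
  wcol <- rowSums(f * m$vol, na.rm = TRUE)
  mu <- sum(wcol * m$xc) / sum(wcol)
  v2 <- sum(wcol * (m$xc - mu)^2) / sum(wcol)
  expect_equal(v2, ms$sigma2(tend), tolerance = 0.02)
  # initial mass is conserved (no advection, walls are no-flux)
  expect_lt(ser$mass_balance_error, 1e-10)
})

test_that("discrete mass balance closes once-through and in closed loop", {
  ser <- fb_transient_fixture(1e-8)
  expect_lt(ser$mass_balance_error, 0.01)
  expect_lt(ser$mass_balance_error, 1e-10)   # exact by construction
  # maximum principle for the conservative species
  expect_lte(max(ser$final), 1 + 1e-9)
  expect_gte(min(ser$final), -1e-12)

  res <- device_flow_fixture("fluidizedbed")
  rec <- solve_transient_transport(
    res$flow, species_transport("tc", 1e-8),
    transport_scenario(1, recirculating = TRUE, reservoir_volume = 2e-6,
                       duration = 1800, dt = 1, output_every = 60))
  expect_lt(rec$mass_balance_error, 0.01)
  # reservoir is being diluted toward the closed-loop equilibrium
  expect_lt(utils::tail(rec$series$reservoir, 1), 1)
  expect_gt(utils::tail(rec$series$reservoir, 1),
            2e-6 / (2e-6 + 4.8e-6) * 0.9)
})

test_that("uniformity timing handles trivial and unreachable cases", {
  ser <- fb_transient_fixture(1e-8)
  tu <- time_to_uniformity(ser)
  expect_true(is.finite(tu) && tu > 0)
  # stricter threshold that the run never sustains
  tu99 <- time_to_uniformity(ser, threshold = 1.01)
  expect_true(is.na(tu99))
  expect_true(attr(tu99, "final_fraction") > 0.9)
  # already uniform from the start
  fx <- channel_flow_fixture(0.2e-3)
  ser0 <- solve_transient_transport(
    fx$sol, species_transport("tc", 1e-8),
    transport_scenario(1, initial_concentration = 1, duration = 60, dt = 5,
                       output_every = 30))
  expect_equal(time_to_uniformity(ser0), 0)
})

test_that("oxygen with no sink equilibrates at the source concentration", {
  res <- device_flow_fixture("quasivivo")
  scen <- oxygen_scenario(inlet_concentration = 0.214, sink_vmax = c())
  o <- solve_oxygen_steady(res$flow, scen)
  expect_equal(min(o$C, na.rm = TRUE), 0.214, tolerance = 1e-6)
  expect_equal(max(o$C, na.rm = TRUE), 0.214, tolerance = 1e-6)
  expect_equal(min_concentration(o)$min, 0.214, tolerance = 1e-6)
  expect_error(min_concentration(o, "nope"), "empty region")
})

test_that("oxygen consumption is bounded by capacity and balances supply", {
  res <- fixture("fb_oxygen", run_scenario(scenario_spec("fluidizedbed",
                                                         mode = "oxygen")))
  o <- res$oxygen
  cap <- res$spec$cell_count * res$spec$params$kinetics$per_cell_rate
  expect_lte(o$consumption, cap * (1 + 1e-6))
  expect_lt(o$balance_error, 0.01)
  expect_true(o$converged)
  expect_gte(min(o$C, na.rm = TRUE), -1e-9)
  expect_lte(max(o$C, na.rm = TRUE), 0.214 * (1 + 1e-6))
})

test_that("oxygen scenarios validate sink regions and gas fractions", {
  res <- device_flow_fixture("quasivivo")
  bad <- oxygen_scenario(sink_vmax = stats::setNames(list(1), "scaffold"))
  expect_error(solve_oxygen_steady(res$flow, bad), "not present")
  expect_error(oxygen_scenario(gas_fraction = 1.5), "\\(0, 1\\]")
})
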