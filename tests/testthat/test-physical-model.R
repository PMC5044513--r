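test_that("Henry's law conversions round-trip and match the default constants", {
  law <- henry_law(k_o2 = 932.4)
  expect_equal(henry_concentration(0, law), 0)
  # air-equilibrated medium: P = K * C with C = 2.14e-4 mol/L
  expect_equal(henry_pressure(0.214, law), 932.4 * 2.14e-4, tolerance = 1e-12)
  p <- c(0.01, 0.1995, 0.5, 1)
  expect_equal(henry_pressure(henry_concentration(p, law), law), p,
               tolerance = 1e-12)
  expect_equal(default_params()$c0, 0.214)
  expect_error(henry_law(k_o2 = -1), "positive")
})

test_that("the Michaelis constant converts from mmHg via Henry's law", {
  expect_equal(km_to_concentration(5.6), 5.6 / 760 / 932.4 * 1000,
               tolerance = 1e-12)
  expect_equal(km_to_concentration(5.6), 7.90e-3, tolerance = 1e-3)
  expect_equal(km_to_concentration(760), 1 / 932.4 * 1000, tolerance = 1e-12)
  expect_error(km_to_concentration(0), "positive")
  # the converted affinity sits above the critical level, as the graded
  # response near c_cr requires
  expect_gt(km_to_concentration(5.6), 2.82e-3)
})

test_that("the low-oxygen cutoff is bounded, monotone and C1", {
  c_cr <- 2.82e-3
  expect_equal(stepdown_delta(c_cr, c_cr), 1)
  expect_equal(stepdown_delta(-c_cr, c_cr), 0)
  expect_equal(stepdown_delta(0, c_cr), 0.5)
  x <- seq(-2, 2, by = 1e-3) * c_cr
  d <- stepdown_delta(x, c_cr)
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diff(d) >= -1e-15))
  # first-derivative continuity at the knots (finite differences)
  h <- 1e-7 * c_cr
  slope_scale <- 0.75 / c_cr   # interior slope at c = 0
  for (knot in c(-c_cr, c_cr)) {
    left <- (stepdown_delta(knot, c_cr) - stepdown_delta(knot - h, c_cr)) / h
    right <- (stepdown_delta(knot + h, c_cr) - stepdown_delta(knot, c_cr)) / h
    expect_lt(abs(left - right) / slope_scale, 1e-6)
  }
  expect_error(stepdown_delta(0, -1), "positive")
})

test_that("oxygen consumption follows Michaelis-Menten with the cutoff", {
  kin <- oxygen_kinetics(vmax = 2, km = 1, c_cr = 1e-6)
  expect_equal(oxygen_consumption_rate(0, kin), 0)
  expect_equal(oxygen_consumption_rate(1, kin), 1, tolerance = 1e-5) # half-sat
  expect_equal(oxygen_consumption_rate(1e6, kin), 2, tolerance = 1e-5)
  cs <- seq(0, 10, by = 0.01)
  r <- oxygen_consumption_rate(cs, kin)
  expect_true(all(r <= kin$vmax))
  expect_true(all(diff(r) >= -1e-15))
  # above the critical level the cutoff is exactly 1
  kin2 <- oxygen_kinetics(vmax = 2, km = 1, c_cr = 0.5)
  ca <- seq(0.6, 5, by = 0.1)
  expect_equal(oxygen_consumption_rate(ca, kin2),
               kin2$vmax * ca / (ca + kin2$km), tolerance = 1e-12)
  expect_error(oxygen_kinetics(vmax = -1), "positive")
})

test_that("compartment vmax derives from cell count and volume", {
  expect_equal(vmax_from_cells(15e6, 0.4e-9 / 1e6, 1.4e-6),
               15e6 * 4e-16 / 1.4e-6)
  expect_error(vmax_from_cells(0, 1e-16, 1e-6), "positive")
  expect_error(vmax_from_cells(1e6, 1e-16, 0), "positive")
  # bead interior at 50% v/v with 20-um cells
  expect_equal(bead_vmax(bead_loading(0.5, 20e-6, 500e-6)),
               0.5 / (pi / 6 * (20e-6)^3) * 0.4e-9 / 1e6, tolerance = 1e-12)
  expect_equal(bead_vmax(bead_loading()), 4.77e-2, tolerance = 1e-3)
})

test_that("cells per bead counts spheres within spheres", {
  expect_equal(cells_per_bead(bead_loading(0.5, 20e-6, 500e-6)), 7812)
  expect_equal(cells_per_bead(bead_loading(0.5, 20e-6, 250e-6)), 976)
  tiny <- cells_per_bead(bead_loading(1e-9, 20e-6, 500e-6))
  expect_equal(tiny, 0)
  expect_error(bead_loading(1.2), "between 0 and 1")
  expect_error(bead_loading(0.5, -1e-6), "positive")
})

test_that("parameter defaults validate overrides and scale with gas fraction", {
  p <- default_params()
  expect_equal(p$kinetics$km, km_to_concentration(5.6), tolerance = 1e-12)
  expect_equal(p$o2_solubility_ref, 0.2)  # recorded but unused
  expect_error(default_params(list(nonsense = 1)), "unknown parameter")
  expect_equal(oxygen_source_concentration(0.21, p), p$c0)
  expect_equal(oxygen_source_concentration(0.42, p), 2 * p$c0)
  expect_error(oxygen_source_concentration(0, p), "\\(0, 1\\]")
})
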