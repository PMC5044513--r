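test_that("a bead without consumption stays at the surface concentration", {
  kin <- oxygen_kinetics(vmax = 1e-300)
  sol <- solve_bead(bead_problem(radius = 125e-6, kinetics = kin))
  expect_equal(sol$c, rep(0.214, length(sol$c)), tolerance = 1e-9)
  expect_equal(sol$dead_core_radius, 0)
})

test_that("the full solve matches the zero-order oracle where MM saturates", {
  pb <- bead_problem(radius = 125e-6)
  sol <- solve_bead(pb)
  oracle <- zero_order_center(pb)
  # center far above km: MM correction is a few percent at most
  expect_gt(sol$center_concentration, 10 * pb$kinetics$km)
  expect_equal(sol$center_concentration, oracle, tolerance = 0.03)
  # in the true zero-order limit (km -> 0) the match is exact
  kin0 <- oxygen_kinetics(vmax = pb$kinetics$vmax, km = 1e-9,
                          c_cr = pb$kinetics$c_cr)
  sol0 <- solve_bead(bead_problem(radius = 125e-6, kinetics = kin0))
  expect_equal(sol0$center_concentration, oracle, tolerance = 1e-4)
  # cylinder symmetry has its own closed form
  pbc <- bead_problem(radius = 125e-6, kinetics = kin0, symmetry = "cylinder")
  expect_equal(solve_bead(pbc)$center_concentration,
               zero_order_center(pbc), tolerance = 1e-4)
})

test_that("surface flux balances volume-integrated consumption", {
  sol <- solve_bead(bead_problem(radius = 125e-6))
  expect_equal(sol$flux_at_surface, sol$consumption, tolerance = 0.005)
})

test_that("radial profiles are monotone, convex and grid-converged", {
  sol <- solve_bead(bead_problem(radius = 125e-6))
  expect_true(all(diff(sol$c) >= -1e-12))
  # convexity wherever consumption is active (c > c_cr here everywhere)
  expect_true(all(diff(diff(sol$c)) >= -1e-12))
  sol2 <- solve_bead(bead_problem(radius = 125e-6), n = 800L)
  expect_equal(sol2$center_concentration, sol$center_concentration,
               tolerance = 0.005)
})

test_that("center oxygen falls with bead diameter and a dead core appears", {
  tb <- center_vs_diameter(c(250, 500, 1000) * 1e-6)
  expect_true(all(diff(tb$center) < 0))
  expect_true(all(tb$center >= 0 & tb$center <= 0.214))
  expect_equal(tb$dead_core_radius[1], 0)
  expect_gt(tb$dead_core_radius[3], 0)       # 1-mm bead starves at the center
  # small beads stay far above the critical level
  expect_gt(tb$center[1], 10 * 2.82e-3)
  expect_error(center_vs_diameter(c(-1, 1) * 1e-6), "positive")
})

test_that("the zero-order oracle floors at the dead-core limit", {
  pb <- bead_problem(radius = 500e-6)   # 1-mm bead: demand exceeds supply
  expect_equal(zero_order_center(pb), 0)
  pb2 <- bead_problem(radius = 125e-6)
  expect_equal(zero_order_center(pb2),
               0.214 - pb2$kinetics$vmax * (125e-6)^2 / (6 * 3e-9),
               tolerance = 1e-12)
})
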