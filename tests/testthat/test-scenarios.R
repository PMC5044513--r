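test_that("percent errors reproduce the published comparison arithmetic", {
  expect_equal(percent_error(18, 25)$percent_error, 28)
  expect_equal(percent_error(18, 25)$direction, "underestimate")
  expect_equal(percent_error(40, 25)$percent_error, 60)
  expect_equal(percent_error(40, 25)$direction, "overestimate")
  expect_equal(percent_error(7, 7)$percent_error, 0)
  expect_equal(percent_error(7, 7)$direction, "exact")
  expect_error(percent_error(10, 0), "positive")
})

test_that("the full comparison table carries all four printed percentages", {
  cmp <- equilibration_comparison()
  tab <- cmp$table
  g <- function(b, m) tab[tab$bioreactor == b & tab$model == m, ]
  expect_equal(g("realbio", "2d")$percent_error, 28)
  expect_equal(g("realbio", "2d")$direction, "underestimate")
  expect_equal(g("realbio", "3d")$percent_error, 60)
  expect_equal(g("realbio", "3d")$direction, "overestimate")
  expect_equal(g("quasivivo", "2d")$percent_error, 40)
  expect_equal(g("quasivivo", "3d")$percent_error, 75)
  expect_equal(g("fluidizedbed", "2d")$percent_error, 25)
  expect_equal(g("fluidizedbed", "3d")$percent_error, 0)
  # fold summaries recomputed as means of per-device ratios
  expect_equal(cmp$fold_summary$underestimate_2d,
               mean(c(25 / 18, 8 / 6, 10 / 6)), tolerance = 1e-12)
  expect_equal(cmp$fold_summary$overestimate_3d,
               mean(c(40 / 25, 1, 17.5 / 10)), tolerance = 1e-12)
})

test_that("equilibration estimation crosses thresholds and flags overshoot", {
  expect_equal(estimate_equilibration_time(c(0, 5, 10, 15),
                                           c(0, 0.5, 0.96, 0.99)), 10)
  # exact stirred-tank curve, tau = 4.8 min, sampled every minute
  t <- 0:30
  curve <- 1 - exp(-t / 4.8)
  est <- estimate_equilibration_time(t, curve / max(curve))
  expect_equal(as.numeric(est), 15)   # first sample at/after 3*tau = 14.4
  # overshoot-then-decline series reports the first peak
  over <- c(0, 0.7, 1.0, 0.9, 0.75, 0.6, 0.5, 0.45, 0.42, 0.41, 0.40)
  est2 <- estimate_equilibration_time(seq_along(over) - 1, over)
  expect_true(isTRUE(attr(est2, "overshoot")))
  expect_equal(as.numeric(est2), 2)
  expect_error(estimate_equilibration_time(1:3, c(0, 1, 1)), "4 samples")
  expect_error(estimate_equilibration_time(1:5, c(0, 0.5, 2, 1, 1)),
               "\\[0, 1.05\\]")
})

test_that("scenario specs validate their inputs", {
  expect_error(scenario_spec("petri_dish"), "unknown bioreactor")
  expect_error(scenario_spec("quasivivo", flow_rate = -1), "positive")
  expect_error(scenario_spec("quasivivo", gas_fraction = 0), "\\(0, 1\\]")
  sp <- scenario_spec("quasivivo")
  expect_equal(sp$flow_rate, 0.5e-6 / 60)
  expect_equal(sp$cell_count, 1.5e6)
})

test_that("a single-value sweep equals the plain scenario run", {
  sp <- scenario_spec("quasivivo", mode = "oxygen", resolution = 0.5e-3)
  sw <- sweep_scenario(sp, "flow_rate", sp$flow_rate)
  single <- run_scenario(sp)
  expect_equal(sw$table$min_o2_uM, single$min_o2_uM, tolerance = 1e-9)
  expect_error(sweep_scenario(sp, "flow_rate", c(2, 1) * 1e-8),
               "strictly increasing")
})

test_that("scenario summaries are JSON-ready scalars", {
  res <- device_flow_fixture("quasivivo")
  s <- scenario_summary(res)
  expect_equal(s$bioreactor, "quasivivo")
  expect_equal(s$flow_rate_mL_min, 0.5, tolerance = 1e-12)
  expect_true(is.finite(s$reynolds_inlet))
  txt <- jsonlite::toJSON(s, auto_unbox = TRUE)
  expect_true(nchar(txt) > 0)
})
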