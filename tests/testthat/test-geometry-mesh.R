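test_that("default geometries reconstruct their stated volumes", {
  expect_equal(build_realbio()$volume(), 7.0e-6, tolerance = 0.10)
  expect_equal(build_fluidizedbed()$volume(), 4.8e-6, tolerance = 0.10)
  expect_equal(build_quasivivo()$volume(), 4.0e-6, tolerance = 0.10)
  # and the meshes reproduce the analytic volumes within quadrature error
  for (g in list(build_realbio(), build_fluidizedbed(), build_quasivivo())) {
    m <- generate_mesh(g, 0.4e-3)
    expect_equal(region_volume(m), g$volume(), tolerance = 0.02)
  }
})

test_that("device-stated dimensions are honored", {
  expect_equal(build_realbio()$dims$scaffold_thickness, 1e-3)
  expect_equal(build_fluidizedbed("original")$dims$max_width, 27.3e-3)
  expect_equal(build_fluidizedbed("oval")$dims$max_width, 16.7e-3)
  expect_equal(build_fluidizedbed("narrow")$dims$max_width /
                 build_fluidizedbed("original")$dims$max_width, 22.2 / 27.3)
  qv <- build_quasivivo()
  expect_equal(unname(qv$port_ids), c(1e-3, 2e-3))
  expect_error(build_fluidizedbed("roundish"), "arg")
  expect_error(build_realbio(list(scaffold_thickness = 0)), "non-positive")
  expect_error(build_quasivivo(list(bogus = 1)), "unknown dimension")
})

test_that("Kozeny-Carman permeability matches the closed form and is monotone", {
  expect_equal(kozeny_permeability(0.3, 100e-6),
               (1e-4)^2 * 0.3^3 / (180 * 0.7^2), tolerance = 1e-12)
  expect_equal(kozeny_permeability(0.3, 100e-6), 1.1e-12, tolerance = 0.05)
  expect_gt(kozeny_permeability(0.5, 100e-6), kozeny_permeability(0.3, 100e-6))
  expect_lt(kozeny_permeability(1e-4, 100e-6), 1e-20)
  expect_error(kozeny_permeability(1.1, 1e-4), "between 0 and 1")
})

test_that("meshes refine, tag every boundary and keep region areas stable", {
  g <- build_quasivivo()
  m1 <- generate_mesh(g, 0.5e-3)
  m2 <- generate_mesh(g, 0.25e-3)
  expect_gte(m2$n_cells, 3 * m1$n_cells)
  # region volumes stable under refinement
  for (r in c("lumen", "bead_bed"))
    expect_equal(region_volume(m2, r), region_volume(m1, r), tolerance = 0.01)
  # port openings match the configured 2D widths exactly
  b1 <- mesh_summary(m2)$boundaries
  expect_equal(b1$length_m[b1$tag == "inlet"], 1e-3, tolerance = 1e-9)
  expect_equal(b1$length_m[b1$tag == "outlet"], 2e-3, tolerance = 1e-9)
  bfb <- mesh_summary(generate_mesh(build_fluidizedbed(), 0.4e-3))$boundaries
  expect_equal(bfb$length_m[bfb$tag == "inlet"], 1.5e-3, tolerance = 1e-9)
  # every active cell carries a region tag, inactive cells none
  expect_false(anyNA(m2$region[m2$active]))
  expect_true(all(is.na(m2$region[!m2$active])))
  # no boundary face of an active cell is untagged
  expect_false(anyNA(m2$utag[cbind(which(m2$active, arr.ind = TRUE)[, 1],
                                   which(m2$active, arr.ind = TRUE)[, 2])]))
})

test_that("meshing refuses resolutions too coarse for the ports", {
  expect_error(generate_mesh(build_quasivivo(), 0.8e-2), "too coarse")
  expect_error(generate_mesh(build_quasivivo(), -1), "positive")
})
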