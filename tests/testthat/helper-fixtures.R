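# Shared fixtures, computed once per test run. Solver runs are cached in an
# environment so flow fields are reused across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]]))
    assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

channel_flow_fixture <- function(res = 0.1e-3) {
  fixture(paste0("channel_", res), {
    m <- generate_mesh(build_channel(length = 20e-3, height = 2e-3,
                                     depth = 10e-3), res)
    list(mesh = m, sol = solve_flow(m, bc = flow_bc(1e-6 / 60)))
  })
}

device_flow_fixture <- function(name) {
  fixture(paste0("flow_", name), {
    spec <- scenario_spec(name, mode = "flow")
    run_scenario(spec)
  })
}

fb_transient_fixture <- function(D = 1e-8) {
  fixture(paste0("fb_transient_", D), {
    res <- device_flow_fixture("fluidizedbed")
    ser <- solve_transient_transport(
      res$flow, species_transport("test_compound", D),
      transport_scenario(1, duration = 1200, dt = 1, output_every = 30))
    ser
  })
}
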