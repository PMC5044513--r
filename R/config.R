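# Configuration and output plumbing: YAML scenario configs with validated
# keys and physical defaults, CSV/JSON outputs with a JSON run manifest.

config_schema <- list(
  scenario = c("bioreactor", "flow_rate_mL_min", "gas_fraction",
               "cell_count", "mode", "resolution_mm", "duration_min", "seed"),
  params = c("viscosity", "density", "temperature", "d_test", "d_oxygen",
             "k_o2", "c0", "km_mmHg", "c_cr", "per_cell_rate"),
  geometry = NULL,    # forwarded to the builder, which validates names
  solver = c("flow_maxit", "flow_tol", "oxygen_maxit", "oxygen_tol",
             "transport_dt", "output_every", "uniformity_threshold"),
  output = c("dir")
)

#' Load and validate a scenario configuration file
#'
#' Reads a YAML file with sections `scenario`, `params`, `geometry`,
#' `solver` and `output`; unknown sections or keys are rejected with an
#' itemized error. Missing entries are filled with the package defaults
#' (the bundled physical-constant profile of [default_params()] and the
#' documented geometry defaults); every filled default is recorded in the
#' returned object so run manifests can log them. An empty file yields the
#' full default configuration for the scaffold chamber.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`: `scenario` (a
#'   [scenario_spec()]), `solver` settings, `output` settings, `raw` (the
#'   parsed file) and `filled_defaults` (character vector of keys that
#'   fell back to defaults).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)

  errs <- character(0)
  unknown_sections <- setdiff(names(raw), names(config_schema))
  if (length(unknown_sections))
    errs <- c(errs, paste0("unknown section(s): ",
                           paste(unknown_sections, collapse = ", ")))
  for (sec in names(config_schema)) {
    keys <- config_schema[[sec]]
    if (is.null(keys) || is.null(raw[[sec]])) next
    bad <- setdiff(names(raw[[sec]]), keys)
    if (length(bad))
      errs <- c(errs, paste0("unknown key(s) in '", sec, "': ",
                             paste(bad, collapse = ", ")))
  }
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)

  filled <- character(0)
  gv <- function(sec, key, default) {
    v <- raw[[sec]][[key]]
    if (is.null(v)) { filled <<- c(filled, paste0(sec, ".", key)); default }
    else v
  }

  # physical parameters (validated by the constructors)
  p_over <- list()
  pr <- raw$params
  params <- default_params()
  if (!is.null(pr)) {
    fluid <- fluid_properties(
      density = gv("params", "density", 1000),
      viscosity = gv("params", "viscosity", 1e-3),
      temperature = gv("params", "temperature", 37))
    henry <- henry_law(k_o2 = gv("params", "k_o2", 932.4))
    kin <- oxygen_kinetics(
      vmax = 1,
      km = km_to_concentration(gv("params", "km_mmHg", 5.6), henry),
      c_cr = gv("params", "c_cr", 2.82e-3),
      per_cell_rate = gv("params", "per_cell_rate", 0.4e-9 / 1e6))
    params <- default_params(list(
      fluid = fluid, henry = henry, kinetics = kin,
      c0 = gv("params", "c0", 0.214),
      species = list(
        test_compound = species_transport("test_compound",
                                          gv("params", "d_test", 1e-8)),
        oxygen = species_transport("oxygen",
                                   gv("params", "d_oxygen", 3e-9), TRUE))))
  } else {
    filled <- c(filled, "params.*")
  }

  bioreactor <- gv("scenario", "bioreactor", "realbio")
  res_mm <- raw$scenario$resolution_mm
  dur_min <- raw$scenario$duration_min
  spec <- scenario_spec(
    bioreactor = bioreactor,
    flow_rate = {
      fr <- raw$scenario$flow_rate_mL_min
      if (is.null(fr)) { filled <- c(filled, "scenario.flow_rate_mL_min"); NULL }
      else fr * 1e-6 / 60
    },
    gas_fraction = gv("scenario", "gas_fraction", 0.21),
    cell_count = raw$scenario$cell_count,
    mode = gv("scenario", "mode", "all"),
    resolution = if (is.null(res_mm)) NULL else res_mm * 1e-3,
    duration = if (is.null(dur_min)) NULL else dur_min * 60,
    seed = gv("scenario", "seed", 1L),
    params = params,
    geometry_overrides = if (is.null(raw$geometry)) list() else raw$geometry)

  solver <- list(
    flow_maxit = gv("solver", "flow_maxit", 30L),
    flow_tol = gv("solver", "flow_tol", 1e-8),
    oxygen_maxit = gv("solver", "oxygen_maxit", 200L),
    oxygen_tol = gv("solver", "oxygen_tol", 1e-8),
    transport_dt = gv("solver", "transport_dt", 1),
    output_every = gv("solver", "output_every", 30),
    uniformity_threshold = gv("solver", "uniformity_threshold", 0.95))
  output <- list(dir = gv("output", "dir", "hepaflow-results"))

  structure(list(scenario = spec, solver = solver, output = output,
                 raw = raw, filled_defaults = filled, path = path,
                 km_conversion = params$meta$km_conversion),
            class = "run_config")
}

#' Write scenario outputs and a run manifest
#'
#' Writes the metric summary (JSON), the transport time series (CSV) and
#' oxygen field (CSV of cell-center coordinates and concentrations) where
#' available, plus a `manifest.json` recording the configuration hash, the
#' package version, wall time, per-stage status and the file inventory.
#' Re-running an identical configuration reproduces byte-identical CSV
#' metric tables; only the manifest carries timing information.
#'
#' @param result A `scenario_result` (or a partial result with an `error`
#'   field for failed stages).
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` for provenance.
#' @return Invisibly, the manifest as a list.
#' @export
write_outputs <- function(result, dir, config = NULL) {
  t0 <- Sys.time()
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  status <- list()

  wr <- function(writer, name) {
    path <- file.path(dir, name)
    ok <- tryCatch({ writer(path); TRUE },
                   error = function(e) { status[[name]] <<- conditionMessage(e); FALSE })
    if (ok) { files <<- c(files, name); status[[name]] <<- "ok" }
    invisible(ok)
  }

  if (inherits(result, "scenario_result")) {
    summ <- scenario_summary(result)
    wr(function(p) jsonlite::write_json(summ, p, auto_unbox = TRUE,
                                        digits = NA, pretty = TRUE),
       "summary.json")
    if (!is.null(result$transport))
      wr(function(p) utils::write.csv(result$transport$series, p,
                                      row.names = FALSE), "transport_series.csv")
    if (!is.null(result$oxygen)) {
      m <- result$mesh
      act <- which(m$active)
      ij <- arrayInd(act, dim(m$active))
      df <- data.frame(x_m = m$xc[ij[, 1]], y_m = m$yc[ij[, 2]],
                       region = m$region[act],
                       oxygen_uM = 1000 * result$oxygen$C[act])
      wr(function(p) utils::write.csv(df, p, row.names = FALSE),
         "oxygen_field.csv")
    }
    if (!is.null(result$shear)) {
      sh <- region_surface_shear(result$flow, result$geometry$sink_region)
      wr(function(p) utils::write.csv(sh, p, row.names = FALSE),
         "shear_profile.csv")
    }
  } else if (!is.null(result$error)) {
    status[["run"]] <- paste("failed:", result$error)
  }

  cfg_hash <- if (!is.null(config)) {
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(config$raw, tmp)
    unname(tools::md5sum(tmp))
  } else NA_character_
  manifest <- list(
    package = "hepaflow",
    version = as.character(utils::packageVersion("hepaflow")),
    config_hash = cfg_hash,
    config_path = if (!is.null(config)) config$path else NA_character_,
    filled_defaults = if (!is.null(config)) config$filled_defaults else NULL,
    km_conversion = if (!is.null(config)) config$km_conversion else NULL,
    wall_time_s = as.numeric(Sys.time() - t0, units = "secs"),
    created = format(Sys.time(), tz = "UTC"),
    stages = status,
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
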