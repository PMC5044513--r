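#' Fluid properties of the culture medium
#'
#' Culture medium is treated as water at incubator temperature: Newtonian,
#' incompressible, constant properties.
#'
#' @param density Mass density (kg/m^3). Must be positive.
#' @param viscosity Dynamic viscosity (kg/m/s). Must be positive.
#' @param temperature Temperature (degrees C). Informational only; no
#'   temperature-dependent property model is applied.
#'
#' @return An object of class `fluid_properties`.
#' @export
#' @examples
#' fluid_properties()
fluid_properties <- function(density = 1000, viscosity = 1e-3, temperature = 37) {
  stopifnot(is.numeric(density), length(density) == 1L,
            is.numeric(viscosity), length(viscosity) == 1L)
  if (density <= 0) stop("`density` must be positive", call. = FALSE)
  if (viscosity <= 0) stop("`viscosity` must be positive", call. = FALSE)
  structure(list(density = density, viscosity = viscosity,
                 temperature = temperature),
            class = "fluid_properties")
}

#' Transport properties of a dissolved species
#'
#' @param name Species label.
#' @param diffusion_coefficient Diffusion coefficient in aqueous medium (m^2/s).
#' @param reactive Logical; `TRUE` for oxygen (consumed by cells), `FALSE` for
#'   a conservative test compound.
#'
#' @return An object of class `species_transport`.
#' @export
#' @examples
#' species_transport("test_compound", 1e-8)
#' species_transport("oxygen", 3e-9, reactive = TRUE)
species_transport <- function(name, diffusion_coefficient, reactive = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(diffusion_coefficient) || length(diffusion_coefficient) != 1L ||
      diffusion_coefficient <= 0)
    stop("`diffusion_coefficient` must be a positive number", call. = FALSE)
  structure(list(name = name,
                 diffusion_coefficient = diffusion_coefficient,
                 reactive = isTRUE(reactive)),
            class = "species_transport")
}

#' Henry's-law description of dissolved oxygen
#'
#' Gas-liquid equilibrium of oxygen, `P_O2 = K_O2 * C` with `C` in mol/L.
#'
#' @param k_o2 Henry constant (atm per mol/L). Must be positive.
#' @param p_o2 Gas-phase oxygen partial pressure (atm). Must be non-negative.
#'
#' @return An object of class `henry_law`.
#' @export
#' @examples
#' h <- henry_law()
#' henry_concentration(h$p_o2, h) # inlet-equilibrium concentration, mol/m^3
henry_law <- function(k_o2 = 932.4, p_o2 = 932.4 * 0.214e-3) {
  if (!is.numeric(k_o2) || length(k_o2) != 1L || k_o2 <= 0)
    stop("`k_o2` must be a positive number", call. = FALSE)
  if (!is.numeric(p_o2) || length(p_o2) != 1L || p_o2 < 0)
    stop("`p_o2` must be non-negative", call. = FALSE)
  structure(list(k_o2 = k_o2, p_o2 = p_o2), class = "henry_law")
}

#' Dissolved-oxygen concentration at a given partial pressure
#'
#' Inverts Henry's law: `C = p_o2 / K_O2`, converted from mol/L to mol/m^3.
#'
#' @param p_o2 Oxygen partial pressure (atm), non-negative.
#' @param law A [henry_law()] object.
#'
#' @return Concentration in mol/m^3.
#' @export
#' @examples
#' henry_concentration(0.1995, henry_law()) # ~0.214 mol/m^3
henry_concentration <- function(p_o2, law = henry_law()) {
  stopifnot(inherits(law, "henry_law"))
  if (any(p_o2 < 0)) stop("`p_o2` must be non-negative", call. = FALSE)
  p_o2 / law$k_o2 * 1000
}

#' Partial pressure implied by a dissolved-oxygen concentration
#'
#' Inverse of [henry_concentration()].
#'
#' @param conc Concentration (mol/m^3).
#' @param law A [henry_law()] object.
#' @return Partial pressure in atm.
#' @export
henry_pressure <- function(conc, law = henry_law()) {
  stopifnot(inherits(law, "henry_law"))
  conc / 1000 * law$k_o2
}

#' Convert a Michaelis constant from mmHg to mol/m^3
#'
#' Oxygen affinities of hepatocytes are commonly reported as partial
#' pressures. The value is converted to atm (1 atm = 760 mmHg) and passed
#' through Henry's law, so the Michaelis-Menten rate law can be evaluated
#' directly on dissolved concentrations. The conversion is done once at
#' configuration time and recorded in run metadata.
#'
#' @param km_mmHg Michaelis constant (mmHg), positive.
#' @param law A [henry_law()] object.
#' @return Concentration in mol/m^3.
#' @export
#' @examples
#' km_to_concentration(5.6) # ~7.9e-3 mol/m^3 (7.9 uM)
km_to_concentration <- function(km_mmHg, law = henry_law()) {
  if (!is.numeric(km_mmHg) || any(km_mmHg <= 0))
    stop("`km_mmHg` must be positive", call. = FALSE)
  henry_concentration(km_mmHg / 760, law)
}

#' Smooth low-oxygen cutoff factor
#'
#' Cubic switch that extinguishes cellular consumption as the local
#' concentration approaches the critical level `c_cr`:
#' 0 for `c < -c_cr`, `0.5 + 0.75 (c/c_cr) - 0.25 (c/c_cr)^3` for
#' `|c| <= c_cr`, and 1 for `c > c_cr`. The function is continuous with a
#' continuous first derivative at both knots, which keeps low-oxygen steady
#' solves stable. Slightly negative concentrations from numerical transport
#' are admitted on purpose and are driven to zero consumption.
#'
#' @param c Concentration (mol/m^3); may be a vector, may be slightly negative.
#' @param c_cr Critical concentration (mol/m^3), positive.
#' @return Dimensionless factor in \[0, 1\].
#' @export
#' @examples
#' stepdown_delta(c(-1, 0, 1) * 2.82e-3, 2.82e-3) # 0, 0.5, 1
stepdown_delta <- function(c, c_cr) {
  if (!is.numeric(c_cr) || length(c_cr) != 1L || c_cr <= 0)
    stop("`c_cr` must be a positive number", call. = FALSE)
  x <- c / c_cr
  ifelse(x < -1, 0,
         ifelse(x > 1, 1, 0.5 + 0.75 * x - 0.25 * x^3))
}

#' Oxygen consumption kinetics of a cell compartment
#'
#' Volumetric Michaelis-Menten consumption with a smooth cutoff near the
#' critical oxygen concentration. `km` is stored in concentration units; use
#' [km_to_concentration()] when the affinity is given as a partial pressure.
#'
#' @param vmax Maximal volumetric consumption rate (mol/m^3/s), positive.
#' @param km Michaelis constant (mol/m^3), positive.
#' @param c_cr Critical oxygen concentration (mol/m^3), positive.
#' @param per_cell_rate Consumption per cell at saturation (mol/s/cell),
#'   positive. Kept alongside `vmax` so compartment rates can be re-derived
#'   from cell counts.
#' @return An object of class `oxygen_kinetics`.
#' @export
oxygen_kinetics <- function(vmax, km = km_to_concentration(5.6),
                            c_cr = 2.82e-3, per_cell_rate = 0.4e-9 / 1e6) {
  vals <- c(vmax = vmax, km = km, c_cr = c_cr, per_cell_rate = per_cell_rate)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all kinetic parameters must be positive and finite", call. = FALSE)
  structure(as.list(vals), class = "oxygen_kinetics")
}

#' Volumetric oxygen consumption rate
#'
#' `R(c) = vmax * c / (c + km) * delta(c)`, with `delta` the smooth cutoff of
#' [stepdown_delta()]. For `c > c_cr` this is plain Michaelis-Menten; the
#' rate is bounded by `vmax` and is monotone non-decreasing for `c >= 0`.
#'
#' @param c Concentration (mol/m^3); vectorized, may be slightly negative.
#' @param kin An [oxygen_kinetics()] object.
#' @return Consumption rate (mol/m^3/s).
#' @export
oxygen_consumption_rate <- function(c, kin) {
  stopifnot(inherits(kin, "oxygen_kinetics"))
  d <- stepdown_delta(c, kin$c_cr)
  mm <- ifelse(c + kin$km > 0, c / (c + kin$km), 0)
  kin$vmax * mm * d
}

#' Volumetric maximal consumption rate from a cell count
#'
#' The compartment-scale `vmax` is the cell-normalized consumption rate times
#' the number of cells, divided by the volume of the compartment that hosts
#' them.
#'
#' @param n_cells Number of cells (> 0).
#' @param per_cell_rate Saturated consumption per cell (mol/s/cell, > 0).
#' @param compartment_volume Volume of the cell compartment (m^3, > 0).
#' @return `vmax` in mol/m^3/s.
#' @export
#' @examples
#' vmax_from_cells(15e6, 0.4e-9 / 1e6, 1.4e-6)
vmax_from_cells <- function(n_cells, per_cell_rate, compartment_volume) {
  vals <- c(n_cells, per_cell_rate, compartment_volume)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("`n_cells`, `per_cell_rate` and `compartment_volume` must be positive",
         call. = FALSE)
  n_cells * per_cell_rate / compartment_volume
}

#' Hepatocyte loading of an alginate bead
#'
#' @param cell_volume_fraction Volume fraction of the bead occupied by cells,
#'   strictly between 0 and 1.
#' @param cell_diameter Hepatocyte diameter (m), positive.
#' @param bead_diameter Bead diameter (m), positive.
#' @return An object of class `bead_loading`.
#' @export
bead_loading <- function(cell_volume_fraction = 0.5, cell_diameter = 20e-6,
                         bead_diameter = 500e-6) {
  if (!is.numeric(cell_volume_fraction) || cell_volume_fraction <= 0 ||
      cell_volume_fraction >= 1)
    stop("`cell_volume_fraction` must lie strictly between 0 and 1", call. = FALSE)
  if (cell_diameter <= 0 || bead_diameter <= 0)
    stop("diameters must be positive", call. = FALSE)
  structure(list(cell_volume_fraction = cell_volume_fraction,
                 cell_diameter = cell_diameter,
                 bead_diameter = bead_diameter),
            class = "bead_loading")
}

#' Number of hepatocytes per bead
#'
#' Both bead and cells are spheres; the count is the bead volume times the
#' loading fraction divided by the single-cell volume, rounded down.
#'
#' @param loading A [bead_loading()] object.
#' @return Integer cell count.
#' @export
#' @examples
#' cells_per_bead(bead_loading(0.5, 20e-6, 500e-6)) # 7812
cells_per_bead <- function(loading) {
  stopifnot(inherits(loading, "bead_loading"))
  vb <- pi / 6 * loading$bead_diameter^3
  vc <- pi / 6 * loading$cell_diameter^3
  floor(vb * loading$cell_volume_fraction / vc)
}

#' Volumetric vmax inside a hepatocyte-loaded bead
#'
#' Consumption per unit bead volume: loading fraction divided by single-cell
#' volume, times the per-cell rate.
#'
#' @param loading A [bead_loading()] object.
#' @param per_cell_rate Saturated consumption per cell (mol/s/cell).
#' @return `vmax` in mol/m^3/s (about 4.8e-2 for 50% v/v, 20-um cells).
#' @export
bead_vmax <- function(loading, per_cell_rate = 0.4e-9 / 1e6) {
  stopifnot(inherits(loading, "bead_loading"))
  vc <- pi / 6 * loading$cell_diameter^3
  loading$cell_volume_fraction / vc * per_cell_rate
}

#' Default physical parameter set
#'
#' The literature-derived constants used throughout the package: medium
#' treated as water at 37 C; test-compound and oxygen diffusivities of 1e-8
#' and 3e-9 m^2/s; Henry constant 932.4 atm/(mol/L); inlet dissolved-oxygen
#' concentration 0.214 mol/m^3 (214 uM, air-equilibrated); hepatocyte
#' consumption 0.4 nmol/s per 1e6 cells with a Michaelis constant of 5.6 mmHg
#' (7.9e-3 mol/m^3 after conversion) and a critical concentration of
#' 2.82e-3 mol/m^3; beads loaded at 50% v/v with 20-um cells. A reference
#' oxygen solubility of 0.2 mol/m^3 is recorded but unused; the inlet and
#' membrane concentration used everywhere is `c0 = 0.214 mol/m^3`.
#'
#' Device-scale constants (estimated cell counts of 15, 70 and 1.5 million
#' for the scaffold chamber, fluidized bed and single-chamber device, and
#' feed rates of 1, 1 and 0.5 mL/min) are included so scenarios can be built
#' without repetition. Any entry can be overridden from a configuration file
#' (see [load_config()]).
#'
#' @param overrides Named list of replacement values applied on top of the
#'   defaults (top-level names only).
#' @return A list of class `hepaflow_params`.
#' @export
#' @examples
#' p <- default_params()
#' p$c0                      # 0.214 mol/m^3
#' p$kinetics$km             # 7.9e-3 mol/m^3, converted from 5.6 mmHg
default_params <- function(overrides = list()) {
  henry <- henry_law(k_o2 = 932.4, p_o2 = 932.4 * 0.214e-3)
  p <- list(
    fluid = fluid_properties(density = 1000, viscosity = 1e-3, temperature = 37),
    species = list(
      test_compound = species_transport("test_compound", 1e-8, reactive = FALSE),
      oxygen = species_transport("oxygen", 3e-9, reactive = TRUE)
    ),
    henry = henry,
    c0 = 0.214,                    # mol/m^3, inlet + gas-membrane oxygen
    o2_solubility_ref = 0.2,       # mol/m^3, recorded but unused
    gas_fraction_ref = 0.21,       # gas fraction at which c0 applies
    kinetics = oxygen_kinetics(
      vmax = 1,                    # placeholder; scenarios derive it from cells
      km = km_to_concentration(5.6, henry),
      c_cr = 2.82e-3,
      per_cell_rate = 0.4e-9 / 1e6
    ),
    km_mmHg = 5.6,
    bead = bead_loading(0.5, 20e-6, 500e-6),
    cell_counts = c(realbio = 15e6, fluidizedbed = 70e6, quasivivo = 1.5e6),
    flow_rates = c(realbio = 1, fluidizedbed = 1, quasivivo = 0.5) * 1e-6 / 60,
    meta = list(km_conversion = "5.6 mmHg / 760 atm/mmHg / 932.4 atm/(mol/L) * 1000")
  )
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("`overrides` must be a fully named list", call. = FALSE)
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown))
      stop("unknown parameter override(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(overrides)] <- overrides
  }
  class(p) <- "hepaflow_params"
  p
}

#' Scale the dissolved-oxygen source concentration with the gas fraction
#'
#' Dirichlet oxygen sources (inlet, gas membranes) scale linearly with the
#' gas-phase oxygen fraction via Henry's law; at the reference fraction
#' (21%) the concentration is `c0`.
#'
#' @param gas_fraction Oxygen fraction of the gas phase, in (0, 1\].
#' @param params A [default_params()] object.
#' @return Concentration in mol/m^3.
#' @export
oxygen_source_concentration <- function(gas_fraction, params = default_params()) {
  if (any(gas_fraction <= 0) || any(gas_fraction > 1))
    stop("`gas_fraction` must lie in (0, 1]", call. = FALSE)
  params$c0 * gas_fraction / params$gas_fraction_ref
}

# reporting helpers -----------------------------------------------------

#' Convert mol/m^3 to micromolar
#' @param conc Concentration (mol/m^3).
#' @return Concentration in uM.
#' @export
to_uM <- function(conc) conc * 1000

#' Convert Pa to microPascal
#' @param tau Stress (Pa).
#' @return Stress in uPa.
#' @export
to_uPa <- function(tau) tau * 1e6
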