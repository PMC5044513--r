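#' Kozeny-Carman permeability estimate
#'
#' Homogenized permeability of a porous region from its porosity and a
#' characteristic pore (grain) size:
#' `kappa = d^2 * eps^3 / (180 * (1 - eps)^2)`. Strictly increasing in the
#' porosity `eps`.
#'
#' @param porosity Void fraction, strictly between 0 and 1.
#' @param pore_size Characteristic pore/grain diameter (m), positive.
#' @return Permeability in m^2.
#' @export
#' @examples
#' kozeny_permeability(0.3, 100e-6) # ~1.1e-12 m^2
kozeny_permeability <- function(porosity, pore_size) {
  if (!is.numeric(porosity) || any(porosity <= 0) || any(porosity >= 1))
    stop("`porosity` must lie strictly between 0 and 1", call. = FALSE)
  if (any(pore_size <= 0)) stop("`pore_size` must be positive", call. = FALSE)
  pore_size^2 * porosity^3 / (180 * (1 - porosity)^2)
}

#' Describe a homogenized porous region
#'
#' @param porosity Void fraction in (0, 1).
#' @param pore_size Characteristic pore/grain size (m).
#' @param permeability Optional permeability (m^2); defaults to the
#'   Kozeny-Carman estimate [kozeny_permeability()].
#' @return An object of class `porous_region`.
#' @export
porous_region <- function(porosity, pore_size,
                          permeability = kozeny_permeability(porosity, pore_size)) {
  if (permeability <= 0) stop("`permeability` must be positive", call. = FALSE)
  structure(list(porosity = porosity, pore_size = pore_size,
                 permeability = permeability),
            class = "porous_region")
}

new_chamber_geometry <- function(name, mode, dims, bbox, snap_x, snap_y,
                                 inside, region_of, boundary_tag, depth_at,
                                 porous, sink_region, port_ids, inlets,
                                 volume_target, volume, min_feature) {
  structure(list(name = name, mode = mode, dims = dims, bbox = bbox,
                 snap_x = snap_x, snap_y = snap_y, inside = inside,
                 region_of = region_of, boundary_tag = boundary_tag,
                 depth_at = depth_at, porous = porous,
                 sink_region = sink_region, port_ids = port_ids,
                 inlets = inlets, volume_target = volume_target,
                 volume = volume, min_feature = min_feature),
            class = "chamber_geometry")
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat("<chamber_geometry>", x$name, sprintf("(%s)\n", x$mode))
  cat("  bbox [m]: x", format(x$bbox[1:2]), " y", format(x$bbox[3:4]), "\n")
  cat("  reconstructed volume:", format(x$volume() * 1e6, digits = 4), "mL")
  if (is.finite(x$volume_target))
    cat(" (target", format(x$volume_target * 1e6, digits = 4), "mL)")
  cat("\n  regions:", paste(unique(c("lumen", names(x$porous))), collapse = ", "), "\n")
  invisible(x)
}

check_dims <- function(dims) {
  num <- vapply(dims, is.numeric, logical(1))
  bad <- names(dims)[num & vapply(dims, function(v) any(v <= 0), logical(1))]
  if (length(bad))
    stop("invalid geometry: non-positive dimension(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  dims
}

merge_overrides <- function(dims, overrides) {
  if (!length(overrides)) return(dims)
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop("`overrides` must be a named list", call. = FALSE)
  unknown <- setdiff(names(overrides), names(dims))
  if (length(unknown))
    stop("unknown dimension override(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  dims[names(overrides)] <- overrides
  dims
}

#' Scaffold-chamber bioreactor geometry (planar mid-plane section)
#'
#' Two media channels separated by a porous cell scaffold; each channel has
#' its own inlet (left) and outlet (right), and the outer channel walls are
#' gas-permeable membranes held at the gas-equilibrium oxygen concentration.
#' The extrusion depth is derived from the device's total volume (7.0 mL by
#' default), so a volumetric feed rate maps to a per-depth planar rate.
#'
#' Only volumes, port diameters and the scaffold thickness are device-stated;
#' channel heights and length are documented defaults, overridable here.
#'
#' @param overrides Named list of dimension overrides (see `dims` of the
#'   returned object; all lengths in meters). `inlet_split` gives the
#'   fraction of the feed routed to the bottom channel (default 0.5).
#' @return A `chamber_geometry`.
#' @export
#' @examples
#' g <- build_realbio()
#' g$volume() * 1e6 # ~7.0 mL
build_realbio <- function(overrides = list()) {
  dims <- list(
    length = 50e-3,            # channel length, documented default
    channel_height = 2e-3,     # each media channel, documented default
    scaffold_thickness = 1e-3, # device-stated
    port_width = 1e-3,         # 2D opening height = port ID
    inlet_id = 1e-3, outlet_id = 1e-3,
    volume = 7.0e-6,           # total device volume, m^3
    inlet_split = 0.5,         # fraction of feed to the bottom channel
    scaffold_porosity = 0.5,   # woven scaffold void fraction (assumed)
    scaffold_pore = 100e-6     # device-stated pore size
  )
  dims <- check_dims(merge_overrides(dims, overrides))
  if (dims$inlet_split >= 1)
    stop("invalid geometry: `inlet_split` must be < 1", call. = FALSE)
  ch <- dims$channel_height; sc <- dims$scaffold_thickness
  L <- dims$length; H <- 2 * ch + sc
  depth <- dims$volume / (H * L)
  pw <- dims$port_width
  if (pw > ch) stop("invalid geometry: port wider than channel", call. = FALSE)
  y_b <- c(ch / 2 - pw / 2, ch / 2 + pw / 2)           # bottom port span
  y_t <- ch + sc + c(ch / 2 - pw / 2, ch / 2 + pw / 2) # top port span
  eps <- 1e-12

  inside <- function(x, y) x >= -eps & x <= L + eps & y >= -eps & y <= H + eps
  region_of <- function(x, y)
    ifelse(y > ch & y < ch + sc, "scaffold", "lumen")
  in_span <- function(y, span) y > span[1] - eps & y < span[2] + eps
  boundary_tag <- function(x, y, nx, ny) {
    tag <- rep("wall", length(x))
    tag[ny != 0] <- "gas_membrane"                 # top/bottom outer walls
    port <- in_span(y, y_b) | in_span(y, y_t)
    tag[nx == -1 & port] <- "inlet"
    tag[nx == +1 & port] <- "outlet"
    tag
  }
  porous <- list(scaffold = porous_region(dims$scaffold_porosity,
                                          dims$scaffold_pore))
  new_chamber_geometry(
    name = "realbio", mode = "planar", dims = c(dims, list(depth = depth)),
    bbox = c(0, L, 0, H),
    snap_x = c(0, L),
    snap_y = sort(unique(c(0, y_b, ch, ch + sc, y_t, H))),
    inside = inside, region_of = region_of, boundary_tag = boundary_tag,
    depth_at = function(x) rep(depth, length(x)),
    porous = porous, sink_region = "scaffold",
    port_ids = c(inlet = dims$inlet_id, outlet = dims$outlet_id),
    inlets = list(split = c(dims$inlet_split, 1 - dims$inlet_split)),
    volume_target = 7.0e-6,
    volume = function() H * L * depth,
    min_feature = min(pw, sc)
  )
}

#' Fluidized-bed bioreactor geometry (width-averaged planar section)
#'
#' A vertical section along the flow path: a wedge-shaped lower distribution
#' chamber (tall at the inlet, tapering toward the far end), a horizontal
#' porous cell compartment (alginate-bead bed, porosity 0.3) bounded by two
#' thin filter layers, and a mirrored wedge-shaped upper collection chamber
#' (tapering toward the inlet end, tall at the outlet). The wedge profile is
#' the standard dead-volume-free design for tangential-flow modules: the
#' longitudinal sweep velocity stays roughly constant along the whole bed,
#' so no stagnant end pockets form. In plan view the chamber is a parabolic
#' (or elliptical) lens whose maximum width depends on the design variant;
#' the section carries the local plan-view width `w(x)` as a per-column
#' extrusion depth, so continuity and volumes follow the true shape. Feed
#' enters the lower chamber on the left end wall (1.5-mm ID) and leaves the
#' upper chamber on the right end wall (3-mm ID). All outer surfaces other
#' than the end walls are gas-permeable membranes.
#'
#' Wedge heights are set by the stated 4.8-mL total volume (original
#' variant) with a 45/55 inlet/outlet split; the bed thickness holds a
#' ~1 mL bead bed.
#'
#' @param width_variant One of `"original"` (27.3 mm maximum width,
#'   parabolic), `"narrow"` (22.2 mm, parabolic), `"oval"` (16.7 mm,
#'   elliptical plan profile).
#' @param overrides Named list of dimension overrides (meters).
#' @return A `chamber_geometry`.
#' @export
#' @examples
#' g <- build_fluidizedbed()
#' g$dims$max_width # 0.0273 m
build_fluidizedbed <- function(width_variant = c("original", "narrow", "oval"),
                               overrides = list()) {
  width_variant <- match.arg(width_variant)
  w_max <- switch(width_variant, original = 27.3e-3, narrow = 22.2e-3,
                  oval = 16.7e-3)
  shape <- if (width_variant == "oval") "ellipse" else "parabola"
  dims <- list(
    length = 40e-3,          # plan-view length along the flow path
    max_width = w_max,       # variant-stated
    min_width = 3e-3,        # clamp so the ports fit in the depth direction
    h_comp = 1.15e-3,        # bed height: 70e6 cells at 50% v/v, bed porosity 0.3
    h_filter = 100e-6,       # device-stated filter thickness
    wedge_split = 0.45,      # fraction of wedge height on the inlet side
    wedge_residual = 0.4e-3, # channel height kept at the tapered far end (m)
    inlet_width = 1.5e-3, outlet_width = 3e-3,
    inlet_id = 1.5e-3, outlet_id = 3e-3,
    volume = 4.8e-6,         # total device volume (original variant)
    porosity = 0.3,          # bead-bed porosity, device-stated
    bed_pore = 100e-6,       # drag length scale for the bed
    filter_porosity = 0.3, filter_pore = 100e-6
  )
  dims <- check_dims(merge_overrides(dims, overrides))
  if (dims$wedge_split >= 1)
    stop("invalid geometry: `wedge_split` must be < 1", call. = FALSE)
  L <- dims$length
  # Plan area of the original parabola fixes the heights from the stated
  # volume; the narrow/oval variants are "otherwise identical".
  A_plan <- 2 / 3 * 27.3e-3 * L
  h_res <- dims$wedge_residual
  h_sum <- 2 * (dims$volume / A_plan - dims$h_comp - 2 * dims$h_filter) -
    2 * h_res
  if (h_sum <= 0)
    stop("invalid geometry: compartment too tall for the stated volume",
         call. = FALSE)
  h_b <- dims$wedge_split * h_sum        # lower wedge height at the inlet end
  h_t <- (1 - dims$wedge_split) * h_sum  # upper wedge height at the outlet end
  if (h_b < dims$inlet_width)
    stop("invalid geometry: inlet taller than the lower chamber", call. = FALSE)
  if (h_t < dims$outlet_width)
    stop("invalid geometry: outlet taller than the upper chamber", call. = FALSE)
  y1 <- h_b; y2 <- y1 + dims$h_filter
  y3 <- y2 + dims$h_comp; y4 <- y3 + dims$h_filter
  H <- y4 + h_t
  yin <- c(0.25e-3, 0.25e-3 + dims$inlet_width)            # near the floor
  yout <- c(H - 0.25e-3 - dims$outlet_width, H - 0.25e-3)  # near the roof
  eps <- 1e-12

  width_at <- function(x) {
    xi <- pmin(pmax(x / L, 0), 1)
    w <- switch(shape,
      parabola = dims$max_width * 4 * xi * (1 - xi),
      ellipse  = dims$max_width * sqrt(pmax(4 * xi * (1 - xi), 0)))
    pmax(w, dims$min_width)
  }
  floor_at <- function(x) (y1 - h_res) * pmin(pmax(x / L, 0), 1)
  roof_at <- function(x) y4 + h_res + (h_t - h_res) * pmin(pmax(x / L, 0), 1)
  inside <- function(x, y) x >= -eps & x <= L + eps &
    y >= floor_at(x) - eps & y <= roof_at(x) + eps
  region_of <- function(x, y) {
    r <- rep("lumen", length(x))
    r[y > y1 & y <= y2] <- "filter"
    r[y > y2 & y <= y3] <- "porous_cell_compartment"
    r[y > y3 & y <= y4] <- "filter"
    r
  }
  in_span <- function(y, span) y > span[1] - eps & y < span[2] + eps
  boundary_tag <- function(x, y, nx, ny) {
    # end walls carry the ports; every other outer surface (the slanted
    # wedge floor/roof) is a gas-permeable membrane
    tag <- rep("gas_membrane", length(x))
    west <- x < eps & nx == -1
    east <- x > L - eps & nx == +1
    tag[west | east] <- "wall"
    tag[west & in_span(y, yin)] <- "inlet"
    tag[east & in_span(y, yout)] <- "outlet"
    tag
  }
  porous <- list(
    porous_cell_compartment = porous_region(dims$porosity, dims$bed_pore),
    filter = porous_region(dims$filter_porosity, dims$filter_pore))
  vol <- stats::integrate(function(x) width_at(x) * (roof_at(x) - floor_at(x)),
                          0, L, subdivisions = 500L)$value
  new_chamber_geometry(
    name = "fluidizedbed", mode = "planar",
    dims = c(dims, list(height = H, h_bottom = h_b, h_top = h_t,
                        variant = width_variant, shape = shape)),
    bbox = c(0, L, 0, H),
    snap_x = c(0, L),
    snap_y = sort(unique(c(0, yin, y1, y2, y3, y4, yout, H))),
    inside = inside, region_of = region_of, boundary_tag = boundary_tag,
    depth_at = width_at,
    porous = porous, sink_region = "porous_cell_compartment",
    port_ids = c(inlet = dims$inlet_id, outlet = dims$outlet_id),
    inlets = list(split = 1),
    volume_target = if (width_variant == "original") 4.8e-6 else NA_real_,
    volume = function() vol,
    min_feature = min(dims$inlet_width, 2 * h_res)
  )
}

#' Single-chamber bioreactor geometry (planar mid-plane section)
#'
#' One chamber with a slanted roof, a side inlet (1-mm ID) near the top of
#' the left wall, a lower offset outlet (2-mm ID) on the right wall, and a
#' thin bed of alginate beads resting on the chamber floor. There is no gas
#' membrane: oxygen enters only with the feed. The extrusion depth is set so
#' the section reconstructs the stated 4.0-mL chamber volume.
#'
#' @param overrides Named list of dimension overrides (meters).
#' @return A `chamber_geometry`.
#' @export
#' @examples
#' g <- build_quasivivo()
#' g$volume() * 1e6 # ~4.0 mL
build_quasivivo <- function(overrides = list()) {
  dims <- list(
    floor_length = 20e-3,    # chamber footprint along the section
    height_left = 12e-3,     # wall height at the inlet side
    height_right = 9e-3,     # wall height at the outlet side (slanted roof)
    bed_height = 0.6e-3,     # homogenized bead-bed layer on the floor
    inlet_width = 1e-3, outlet_width = 2e-3,
    inlet_id = 1e-3, outlet_id = 2e-3,
    inlet_center = 8e-3,     # height of the inlet axis
    outlet_center = 6.5e-3,  # height of the outlet axis (offset from inlet)
    volume = 4.0e-6,
    bed_porosity = 0.4,      # packed-bed void fraction (assumed)
    bead_diameter = 500e-6
  )
  dims <- check_dims(merge_overrides(dims, overrides))
  L <- dims$floor_length; hl <- dims$height_left; hr <- dims$height_right
  roof <- function(x) hl + (hr - hl) * x / L
  area <- L * (hl + hr) / 2
  depth <- dims$volume / area
  yin <- dims$inlet_center + c(-0.5, 0.5) * dims$inlet_width
  yout <- dims$outlet_center + c(-0.5, 0.5) * dims$outlet_width
  if (yin[2] > hl || yout[2] > hr)
    stop("invalid geometry: port lies above the roof", call. = FALSE)
  if (yout[1] <= dims$bed_height)
    stop("invalid geometry: outlet overlaps the bead bed", call. = FALSE)
  eps <- 1e-12

  inside <- function(x, y)
    x >= -eps & x <= L + eps & y >= -eps & y <= roof(x) + eps
  region_of <- function(x, y)
    ifelse(y <= dims$bed_height, "bead_bed", "lumen")
  in_span <- function(y, span) y > span[1] - eps & y < span[2] + eps
  boundary_tag <- function(x, y, nx, ny) {
    tag <- rep("wall", length(x))
    tag[nx == -1 & in_span(y, yin)] <- "inlet"
    tag[nx == +1 & in_span(y, yout)] <- "outlet"
    tag
  }
  porous <- list(bead_bed = porous_region(dims$bed_porosity,
                                          dims$bead_diameter))
  new_chamber_geometry(
    name = "quasivivo", mode = "planar", dims = c(dims, list(depth = depth)),
    bbox = c(0, L, 0, hl),
    snap_x = c(0, L),
    snap_y = sort(unique(c(0, dims$bed_height, yout, yin, hl))),
    inside = inside, region_of = region_of, boundary_tag = boundary_tag,
    depth_at = function(x) rep(depth, length(x)),
    porous = porous, sink_region = "bead_bed",
    port_ids = c(inlet = dims$inlet_id, outlet = dims$outlet_id),
    inlets = list(split = 1),
    volume_target = 4.0e-6,
    volume = function() area * depth,
    min_feature = dims$inlet_width
  )
}

#' Straight planar channel (verification geometry)
#'
#' Rectangular channel with a fully developed inlet on the whole left edge
#' and a zero-pressure outlet on the right; used to verify the flow and
#' transport solvers against closed-form laminar channel flow.
#'
#' @param length,height Channel dimensions (m).
#' @param depth Extrusion depth (m).
#' @return A `chamber_geometry`.
#' @export
build_channel <- function(length = 20e-3, height = 2e-3, depth = 10e-3) {
  stopifnot(length > 0, height > 0, depth > 0)
  eps <- 1e-12
  new_chamber_geometry(
    name = "channel", mode = "planar",
    dims = list(length = length, height = height, depth = depth,
                inlet_id = height, outlet_id = height),
    bbox = c(0, length, 0, height),
    snap_x = c(0, length), snap_y = c(0, height),
    inside = function(x, y) x >= -eps & x <= length + eps &
      y >= -eps & y <= height + eps,
    region_of = function(x, y) rep("lumen", base::length(x)),
    boundary_tag = function(x, y, nx, ny) {
      tag <- rep("wall", base::length(x))
      tag[nx == -1] <- "inlet"; tag[nx == +1] <- "outlet"
      tag
    },
    depth_at = function(x) rep(depth, base::length(x)),
    porous = list(), sink_region = NA_character_,
    port_ids = c(inlet = height, outlet = height),
    inlets = list(split = 1),
    volume_target = NA_real_,
    volume = function() length * height * depth,
    min_feature = height
  )
}

#' Straight circular pipe (axisymmetric verification geometry)
#'
#' Axisymmetric section (x = axial coordinate, y = radius) of a circular
#' pipe; the inlet spans the full cross-section and the outlet is at zero
#' pressure. Used to verify the axisymmetric solver against Poiseuille pipe
#' flow (peak speed `2 Q / A`).
#'
#' @param length Pipe length (m).
#' @param radius Pipe radius (m).
#' @return A `chamber_geometry`.
#' @export
build_pipe <- function(length = 10e-3, radius = 0.5e-3) {
  stopifnot(length > 0, radius > 0)
  eps <- 1e-12
  new_chamber_geometry(
    name = "pipe", mode = "axisymmetric",
    dims = list(length = length, radius = radius,
                inlet_id = 2 * radius, outlet_id = 2 * radius),
    bbox = c(0, length, 0, radius),
    snap_x = c(0, length), snap_y = c(0, radius),
    inside = function(x, y) x >= -eps & x <= length + eps &
      y >= -eps & y <= radius + eps,
    region_of = function(x, y) rep("lumen", base::length(x)),
    boundary_tag = function(x, y, nx, ny) {
      tag <- rep("wall", base::length(x))
      tag[ny == -1] <- "axis"
      tag[nx == -1] <- "inlet"; tag[nx == +1] <- "outlet"
      tag
    },
    depth_at = NULL,
    porous = list(), sink_region = NA_character_,
    port_ids = c(inlet = 2 * radius, outlet = 2 * radius),
    inlets = list(split = 1),
    volume_target = NA_real_,
    volume = function() pi * radius^2 * length,
    min_feature = radius
  )
}

#' Build a bioreactor geometry by name
#'
#' @param name One of `"realbio"`, `"fluidizedbed"`, `"quasivivo"`.
#' @param ... Passed to the specific builder.
#' @return A `chamber_geometry`.
#' @export
build_geometry <- function(name, ...) {
  switch(name,
         realbio = build_realbio(...),
         fluidizedbed = build_fluidizedbed(...),
         quasivivo = build_quasivivo(...),
         channel = build_channel(...),
         pipe = build_pipe(...),
         stop("unknown bioreactor name: ", name, call. = FALSE))
}
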