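# Steady incompressible laminar flow with Brinkman porous drag.
#
# Discretization: staggered (MAC) finite volumes on the structured mesh of
# generate_mesh(). Horizontal velocities u live on vertical faces, vertical
# velocities v on horizontal faces, pressure at cell centers. Viscous terms
# are central; at solid walls the viscous flux uses a one-sided quadratic
# ghost (exact for a parabolic profile, so plane and pipe Poiseuille flow
# are reproduced essentially to solver precision). Convection is
# first-order upwind, Picard-linearized around the previous iterate; it
# vanishes identically for developed channel flow, so it cannot pollute the
# Poiseuille oracle. Porous regions add a Darcy drag -mu/kappa * u
# (Brinkman closure). The coupled saddle-point system is solved with a
# sparse LU factorization each Picard sweep; the first sweep is a Stokes
# solve.
#
# Boundary conditions: no-slip on walls and gas membranes; Dirichlet normal
# velocity with zero tangential component on inlets (profile scaled so the
# discrete face fluxes sum exactly to the requested volumetric rate); zero
# pressure with zero normal-gradient velocity on outlets; symmetry on the
# axis of axisymmetric sections.

#' Flow boundary conditions
#'
#' @param flow_rate Total volumetric feed rate (m^3/s), non-negative. Split
#'   between multiple inlets according to the geometry's declared fractions.
#' @param profile Inlet velocity profile: fully developed `"parabolic"`
#'   (default) or `"plug"`.
#' @return An object of class `flow_bc`.
#' @export
#' @examples
#' flow_bc(1e-6 / 60) # 1 mL/min
flow_bc <- function(flow_rate, profile = c("parabolic", "plug")) {
  if (!is.numeric(flow_rate) || length(flow_rate) != 1L || flow_rate < 0)
    stop("`flow_rate` must be a non-negative volumetric rate", call. = FALSE)
  structure(list(flow_rate = flow_rate, profile = match.arg(profile)),
            class = "flow_bc")
}

tag_is_unknown <- function(tg) !is.na(tg) & (tg == "int" | tg == "outlet")
tag_is_dirichlet <- function(tg) !is.na(tg) & !(tg == "int" | tg == "outlet")

# inlet Dirichlet values for both face orientations (internal)
inlet_profile_values <- function(mesh, bc) {
  uval <- matrix(0, mesh$nx + 1L, mesh$ny)
  vval <- matrix(0, mesh$nx, mesh$ny + 1L)
  segs <- list()
  uf <- boundary_faces(mesh, "inlet", "u")
  if (nrow(uf)) {
    for (ii in unique(uf$i)) {
      js <- sort(uf$j[uf$i == ii])
      run <- cumsum(c(1L, diff(js) != 1L))
      for (r in unique(run))
        segs[[length(segs) + 1L]] <- list(orient = "u", i = ii, j = js[run == r])
    }
  }
  vf <- boundary_faces(mesh, "inlet", "v")
  if (nrow(vf)) {
    for (jj in unique(vf$j)) {
      is <- sort(vf$i[vf$j == jj])
      run <- cumsum(c(1L, diff(is) != 1L))
      for (r in unique(run))
        segs[[length(segs) + 1L]] <- list(orient = "v", j = jj, i = is[run == r])
    }
  }
  if (!length(segs)) stop("mesh has no inlet faces", call. = FALSE)
  pos <- vapply(segs, function(s)
    if (s$orient == "u") mean(mesh$yc[s$j]) else mean(mesh$xc[s$i]), numeric(1))
  segs <- segs[order(pos)]
  split <- mesh$geom$inlets$split
  if (length(split) != length(segs)) split <- rep(1, length(segs))
  split <- split / sum(split)

  for (k in seq_along(segs)) {
    s <- segs[[k]]
    if (s$orient == "u") {
      y0 <- mesh$Y[min(s$j)]; y1 <- mesh$Y[max(s$j) + 1L]
      tt <- (mesh$yc[s$j] - y0) / (y1 - y0)
      shape <- if (bc$profile != "parabolic") rep(1, length(tt))
      else if (mesh$mode == "axisymmetric" && y0 < 1e-12)
        1 - (mesh$yc[s$j] / y1)^2           # pipe parabola about the axis
      else 6 * tt * (1 - tt)
      A <- mesh$area_u[cbind(s$i, s$j)]
      sgn <- if (s$i <= mesh$nx && mesh$active[s$i, s$j[1]]) +1 else -1
      uval[cbind(s$i, s$j)] <- sgn * split[k] * bc$flow_rate * shape / sum(shape * A)
    } else {
      x0 <- mesh$X[min(s$i)]; x1 <- mesh$X[max(s$i) + 1L]
      tt <- (mesh$xc[s$i] - x0) / (x1 - x0)
      shape <- if (bc$profile == "parabolic") 6 * tt * (1 - tt) else rep(1, length(tt))
      A <- mesh$area_v[cbind(s$i, s$j)]
      sgn <- if (s$j <= mesh$ny && mesh$active[s$i[1], s$j]) +1 else -1
      vval[cbind(s$i, s$j)] <- sgn * split[k] * bc$flow_rate * shape / sum(shape * A)
    }
  }
  list(uval = uval, vval = vval)
}

mesh_weight_fun <- function(mesh) {
  if (mesh$mode == "axisymmetric") function(x, y) 2 * pi * y
  else function(x, y) mesh$geom$depth_at(x)
}

#' Solve steady laminar flow in a meshed bioreactor
#'
#' Solves the stationary incompressible momentum and continuity equations
#' with no-slip walls, Dirichlet inlets, zero-pressure outlets and Brinkman
#' drag in porous regions, using Picard iterations on the convective term.
#' Aborts if the inlet Reynolds number is outside the laminar regime
#' (> 2000).
#'
#' @param mesh A `hepaflow_mesh`.
#' @param fluid A [fluid_properties()] object.
#' @param bc A [flow_bc()] object.
#' @param porous Optional named list of [porous_region()] objects replacing,
#'   by region name, the permeabilities carried by the mesh.
#' @param maxit Maximum Picard iterations.
#' @param tol Relative nonlinear convergence tolerance on the velocity
#'   update between Picard sweeps.
#' @return An object of class `flow_solution` with velocity matrices `U`
#'   (`(nx+1) x ny`, on vertical faces) and `V` (`nx x (ny+1)`), pressure
#'   `P`, residual history and an inflow/outflow balance check.
#' @export
#' @examples
#' m <- generate_mesh(build_channel(), 0.25e-3)
#' sol <- solve_flow(m, bc = flow_bc(1e-6 / 60))
#' sol$flow_rate_check
solve_flow <- function(mesh, fluid = fluid_properties(), bc,
                       porous = NULL, maxit = 30L, tol = 1e-8) {
  stopifnot(inherits(mesh, "hepaflow_mesh"), inherits(bc, "flow_bc"))
  mu <- fluid$viscosity; rho <- fluid$density
  nx <- mesh$nx; ny <- mesh$ny
  X <- mesh$X; Y <- mesh$Y; dxv <- mesh$dx; dyv <- mesh$dy
  xc <- mesh$xc; yc <- mesh$yc
  active <- mesh$active
  utag <- mesh$utag; vtag <- mesh$vtag
  Wf <- mesh_weight_fun(mesh)

  diag_re <- inlet_reynolds(mesh$geom, fluid, bc$flow_rate)
  if (is.finite(diag_re) && diag_re > 2000)
    stop(sprintf("inlet Reynolds number %.0f exceeds the laminar limit (2000)",
                 diag_re), call. = FALSE)

  kappa <- mesh$kappa
  if (!is.null(porous)) {
    for (rn in names(porous)) {
      sel <- !is.na(mesh$region) & mesh$region == rn
      if (!any(sel)) stop("porous override for absent region: ", rn, call. = FALSE)
      kappa[sel] <- porous[[rn]]$permeability
    }
  }
  ikap <- 1 / kappa

  is_u_unknown <- tag_is_unknown(utag)
  is_v_unknown <- tag_is_unknown(vtag)
  uid <- matrix(0L, nx + 1L, ny); uid[is_u_unknown] <- seq_len(sum(is_u_unknown))
  nu <- sum(is_u_unknown)
  vid <- matrix(0L, nx, ny + 1L); vid[is_v_unknown] <- seq_len(sum(is_v_unknown))
  nv <- sum(is_v_unknown)
  pid <- matrix(0L, nx, ny); pid[active] <- seq_len(sum(active))
  np <- sum(active)
  N <- nu + nv + np
  voff <- nu; poff <- nu + nv

  prof <- inlet_profile_values(mesh, bc)
  uD <- prof$uval; vD <- prof$vval
  sel_in_u <- !is.na(utag) & utag == "inlet"
  sel_in_v <- !is.na(vtag) & vtag == "inlet"
  inflow <- sum(abs(uD[sel_in_u] * mesh$area_u[sel_in_u])) +
    sum(abs(vD[sel_in_v] * mesh$area_v[sel_in_v]))

  atM <- function(M, i, j, default) {
    ok <- i >= 1L & i <= nrow(M) & j >= 1L & j <= ncol(M)
    res <- rep(default, length(i))
    if (any(ok)) res[ok] <- M[cbind(i[ok], j[ok])]
    res
  }
  safe <- function(v, i) v[pmin(pmax(i, 1L), length(v))]

  TI <- TJ <- TX <- RR <- RV <- NULL
  reset_trip <- function() { TI <<- TJ <<- TX <<- RR <<- RV <<- list() }
  add <- function(r, c, x) {
    keep <- is.finite(x) & x != 0
    if (!any(keep)) return(invisible())
    TI[[length(TI) + 1L]] <<- r[keep]; TJ[[length(TJ) + 1L]] <<- c[keep]
    TX[[length(TX) + 1L]] <<- x[keep]
    invisible()
  }
  add_rhs <- function(r, v) {
    keep <- is.finite(v) & v != 0
    if (!any(keep)) return(invisible())
    RR[[length(RR) + 1L]] <<- r[keep]; RV[[length(RV) + 1L]] <<- v[keep]
    invisible()
  }

  # momentum assembly for one orientation ---------------------------------
  # 'a' indexes the face along its normal direction, 'b' the transverse
  # cell; accessor closures hide the u/v index layouts.
  assemble_momentum <- function(orient, Ustar, Vstar) {
    if (orient == "u") {
      TAG <- function(a, b) atM(utag, a, b, NA_character_)
      ID <- function(a, b) atM(uid, a, b, 0L)
      DVAL <- function(a, b) atM(uD, a, b, 0)
      ACT <- function(a, b) atM(active, a, b, FALSE)
      IK <- function(a, b) atM(ikap, a, b, 0)
      PID <- function(a, b) atM(pid, a, b, 0L)
      OTAG <- function(ncell, tline) atM(vtag, ncell, tline, NA_character_)
      SN <- function(a, b) if (is.null(Ustar)) 0 * a else atM(Ustar, a, b, 0)
      SO <- function(ncell, tline) if (is.null(Vstar)) 0 * ncell else
        atM(Vstar, ncell, tline, 0)
      dn <- dxv; dt <- dyv
      id_off <- 0L
      Wface <- function(a, b) Wf(X[a], yc[b])
      Wcell <- function(ac, b) Wf(safe(xc, ac), yc[b])
      Wline <- function(a, tl) Wf(X[a], Y[tl])
      radial <- FALSE
      fidx <- which(is_u_unknown)
      ij <- arrayInd(fidx, dim(uid)); fa <- ij[, 1]; fb <- ij[, 2]
      rows <- uid[fidx]
      r_face <- rep(1, length(fa))
    } else {
      TAG <- function(a, b) atM(vtag, b, a, NA_character_)
      ID <- function(a, b) atM(vid, b, a, 0L)
      DVAL <- function(a, b) atM(vD, b, a, 0)
      ACT <- function(a, b) atM(active, b, a, FALSE)
      IK <- function(a, b) atM(ikap, b, a, 0)
      PID <- function(a, b) atM(pid, b, a, 0L)
      OTAG <- function(ncell, tline) atM(utag, tline, ncell, NA_character_)
      SN <- function(a, b) if (is.null(Vstar)) 0 * a else atM(Vstar, b, a, 0)
      SO <- function(ncell, tline) if (is.null(Ustar)) 0 * ncell else
        atM(Ustar, tline, ncell, 0)
      dn <- dyv; dt <- dxv
      id_off <- voff
      Wface <- function(a, b) Wf(xc[b], Y[a])
      Wcell <- function(ac, b) Wf(xc[b], safe(yc, ac))
      Wline <- function(a, tl) Wf(X[tl], Y[a])
      radial <- mesh$mode == "axisymmetric"
      fidx <- which(is_v_unknown)
      ij <- arrayInd(fidx, dim(vid)); fa <- ij[, 2]; fb <- ij[, 1]
      rows <- vid[fidx] + voff
      r_face <- Y[fa]
    }
    nf <- length(rows)
    if (!nf) return(invisible())
    hasL <- ACT(fa - 1L, fb); hasR <- ACT(fa, fb)
    dnc <- ifelse(hasL, safe(dn, fa - 1L) / 2, 0) +
      ifelse(hasR, safe(dn, fa) / 2, 0)
    wt <- Wface(fa, fb)
    Vfc <- dnc * dt[fb] * wt
    Apc <- dt[fb] * wt
    dia <- numeric(nf)

    couple <- function(cc, a, b) {
      # adds cc * (value of same-orientation face (a,b)) to the row LHS;
      # returns TRUE where the face exists (unknown or Dirichlet)
      tg <- TAG(a, b)
      unk <- tag_is_unknown(tg) & cc != 0
      dir <- tag_is_dirichlet(tg) & cc != 0
      if (any(unk)) add(rows[unk], (ID(a, b) + id_off)[unk], cc[unk])
      if (any(dir)) add_rhs(rows[dir], -(cc * DVAL(a, b))[dir])
      !is.na(tg)
    }

    # --- viscous, normal direction ---------------------------------------
    ccR <- ifelse(hasR, mu * dt[fb] * Wcell(fa, fb) / safe(dn, fa), 0)
    useR <- couple(ccR, fa + 1L, fb)
    dia <- dia - ifelse(useR, ccR, 0)   # missing face beyond an edge outlet: zero-gradient
    ccL <- ifelse(hasL, mu * dt[fb] * Wcell(fa - 1L, fb) / safe(dn, fa - 1L), 0)
    useL <- couple(ccL, fa - 1L, fb)
    dia <- dia - ifelse(useL, ccL, 0)

    # --- viscous, transverse direction (+ wall/slip ghosts) --------------
    for (side in c(+1L, -1L)) {
      nbj <- fb + side
      tl <- if (side == 1L) fb + 1L else fb     # bounding line index
      An <- dnc * Wline(fa, tl)
      tg <- TAG(fa, nbj)
      have <- !is.na(tg)
      dctr <- dt[fb] / 2 + safe(dt, nbj) / 2
      cc <- ifelse(have, mu * An / dctr, 0)
      couple(cc, fa, nbj)
      dia <- dia - cc

      none <- !have
      if (any(none)) {
        o1 <- OTAG(ifelse(hasL, fa - 1L, fa), tl)
        o2 <- OTAG(ifelse(hasR, fa, fa - 1L), tl)
        slipish <- function(t_) !is.na(t_) & (t_ == "outlet" | t_ == "axis")
        slip <- none & (slipish(o1) | slipish(o2))
        wallg <- none & !slip
        if (any(wallg)) {
          # quadratic ghost: u = 0 at the wall, u(d1) = uK and u(d2) = u_far
          # sampled on the fluid side; viscous contribution
          # -mu*An*(c1*uK + c2*u_far), exact for parabolic profiles
          d1 <- dt[fb] / 2
          farb <- fb - side
          ftg <- TAG(fa, farb)
          usable <- wallg & !is.na(ftg)
          d2 <- d1 + dt[fb] / 2 + safe(dt, farb) / 2
          c1 <- d2 / (d1 * (d2 - d1))
          c2 <- -d1 / (d2 * (d2 - d1))
          couple(ifelse(usable, -mu * An * c2, 0), fa, farb)
          dia <- dia - ifelse(usable, mu * An * c1, 0)
          lin <- wallg & !usable    # single row of cells: linear ghost
          dia <- dia - ifelse(lin, mu * An / d1, 0)
        }
      }
    }

    # --- axisymmetric curvature for the radial component -----------------
    if (radial)
      dia <- dia - ifelse(r_face > 0, mu * Vfc / pmax(r_face, 1e-300)^2, 0)

    # --- Brinkman drag ---------------------------------------------------
    alph <- mu * (ifelse(hasL, safe(dn, fa - 1L) / 2 * IK(fa - 1L, fb), 0) +
                    ifelse(hasR, safe(dn, fa) / 2 * IK(fa, fb), 0)) /
      pmax(dnc, 1e-300)
    dia <- dia - alph * Vfc

    # --- pressure gradient: -(pR - pL) * A, ghost p = 0 beyond outlets ---
    if (any(hasR)) add(rows[hasR], (poff + PID(fa, fb))[hasR], -Apc[hasR])
    if (any(hasL)) add(rows[hasL], (poff + PID(fa - 1L, fb))[hasL], +Apc[hasL])

    # --- convection (Picard, first-order upwind) -------------------------
    if (!is.null(Ustar)) {
      ustar <- SN(fa, fb)
      o11 <- SO(fa - 1L, fb); o12 <- SO(fa - 1L, fb + 1L)
      o21 <- SO(fa, fb); o22 <- SO(fa, fb + 1L)
      vstar <- (hasL * (o11 + o12) + hasR * (o21 + o22)) /
        pmax(2 * (hasL + hasR), 1)

      # normal direction: upwind same-orientation neighbor at fa - s
      for (s in c(+1L, -1L)) {
        seld <- if (s == 1L) ustar > 0 else ustar < 0
        nbi <- fa - s
        d <- if (s == 1L) safe(dn, fa - 1L) else safe(dn, fa)
        tg <- TAG(nbi, fb)
        okn <- seld & !is.na(tg)
        ac <- ifelse(okn, rho * ustar * Vfc / d, 0)
        couple(s * ac, nbi, fb)
        dia <- dia - s * ac
      }
      # transverse direction: upwind neighbor at fb - s
      for (s in c(+1L, -1L)) {
        seld <- if (s == 1L) vstar > 0 else vstar < 0
        nbj <- fb - s
        tg <- TAG(fa, nbj)
        have <- seld & !is.na(tg)
        d <- cent_dist <- dt[fb] / 2 + safe(dt, nbj) / 2
        bcv <- ifelse(have, rho * vstar * Vfc / d, 0)
        couple(s * bcv, fa, nbj)
        dia <- dia - s * bcv
        # ghost beyond a wall: upwind value 0 half a cell away
        ghost <- seld & is.na(tg)
        if (any(ghost)) {
          tlg <- if (s == 1L) fb else fb + 1L
          o1 <- OTAG(ifelse(hasL, fa - 1L, fa), tlg)
          o2 <- OTAG(ifelse(hasR, fa, fa - 1L), tlg)
          slipish <- function(t_) !is.na(t_) & (t_ == "outlet" | t_ == "axis")
          wallg <- ghost & !(slipish(o1) | slipish(o2))
          bg <- ifelse(wallg, rho * vstar * Vfc / (dt[fb] / 2), 0)
          dia <- dia - s * bg
        }
      }
    }

    add(rows, rows, dia)
    invisible()
  }

  assemble_continuity <- function() {
    pfo <- which(active)
    pijm <- arrayInd(pfo, dim(pid))
    ci <- pijm[, 1]; cj <- pijm[, 2]
    rows <- poff + pid[pfo]
    for (f in c("E", "W", "N", "S")) {
      if (f %in% c("E", "W")) {
        ii <- if (f == "E") ci + 1L else ci
        A <- mesh$area_u[cbind(ii, cj)]
        tg <- utag[cbind(ii, cj)]
        id <- uid[cbind(ii, cj)]; off <- 0L
        dv <- uD[cbind(ii, cj)]
      } else {
        jj <- if (f == "N") cj + 1L else cj
        A <- mesh$area_v[cbind(ci, jj)]
        tg <- vtag[cbind(ci, jj)]
        id <- vid[cbind(ci, jj)]; off <- voff
        dv <- vD[cbind(ci, jj)]
      }
      s <- if (f %in% c("E", "N")) +1 else -1
      unk <- tag_is_unknown(tg)
      dir <- tag_is_dirichlet(tg)
      add(rows[unk], off + id[unk], s * A[unk])
      add_rhs(rows[dir], -s * A[dir] * dv[dir])
    }
    invisible()
  }

  solve_once <- function(Ustar, Vstar) {
    reset_trip()
    assemble_momentum("u", Ustar, Vstar)
    assemble_momentum("v", Ustar, Vstar)
    assemble_continuity()
    A <- Matrix::sparseMatrix(i = unlist(TI), j = unlist(TJ), x = unlist(TX),
                              dims = c(N, N))
    b <- numeric(N)
    if (length(RR)) {
      agg <- rowsum(unlist(RV), unlist(RR))
      b[as.integer(rownames(agg))] <- agg[, 1]
    }
    as.numeric(Matrix::solve(A, b))
  }

  Ucur <- uD; Vcur <- vD
  res_hist <- numeric(0)
  converged <- FALSE
  iters <- 0L
  z <- NULL
  for (it in seq_len(max(maxit, 1L))) {
    iters <- it
    z <- solve_once(if (it > 1L) Ucur else NULL,
                    if (it > 1L) Vcur else NULL)
    Unew <- uD; Vnew <- vD
    Unew[is_u_unknown] <- z[seq_len(nu)]
    Vnew[is_v_unknown] <- z[voff + seq_len(nv)]
    scale <- max(abs(Unew), abs(Vnew), 1e-300)
    res <- max(max(abs(Unew - Ucur)), max(abs(Vnew - Vcur))) / scale
    res_hist <- c(res_hist, res)
    Ucur <- Unew; Vcur <- Vnew
    if ((it > 1L || bc$flow_rate == 0) && res < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("flow solve: Picard iteration stopped at %d sweeps, last update %.2g",
                    iters, utils::tail(res_hist, 1)), call. = FALSE)
  P <- matrix(NA_real_, nx, ny)
  P[active] <- z[poff + seq_len(np)]

  out_u <- which(!is.na(utag) & utag == "outlet")
  out_v <- which(!is.na(vtag) & vtag == "outlet")
  outflow <- sum(abs(Ucur[out_u] * mesh$area_u[out_u])) +
    sum(abs(Vcur[out_v] * mesh$area_v[out_v]))
  pfo <- which(active); pijm <- arrayInd(pfo, dim(pid))
  ci <- pijm[, 1]; cj <- pijm[, 2]
  divg <- Ucur[cbind(ci + 1L, cj)] * mesh$area_u[cbind(ci + 1L, cj)] -
    Ucur[cbind(ci, cj)] * mesh$area_u[cbind(ci, cj)] +
    Vcur[cbind(ci, cj + 1L)] * mesh$area_v[cbind(ci, cj + 1L)] -
    Vcur[cbind(ci, cj)] * mesh$area_v[cbind(ci, cj)]
  div_max <- if (inflow > 0) max(abs(divg)) / inflow else max(abs(divg))

  structure(list(mesh = mesh, fluid = fluid, bc = bc,
                 U = Ucur, V = Vcur, P = P,
                 residuals = res_hist, iterations = iters,
                 converged = converged,
                 flow_rate_check = c(inflow = inflow, outflow = outflow),
                 div_max = div_max),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution>", x$mesh$geom$name, "\n")
  imb <- if (x$flow_rate_check[1] > 0)
    abs(diff(x$flow_rate_check)) / x$flow_rate_check[1] else 0
  cat(sprintf("  inflow %.4g, outflow %.4g m^3/s (imbalance %.2g%%)\n",
              x$flow_rate_check[1], x$flow_rate_check[2], 100 * imb))
  cat(sprintf("  Picard sweeps: %d (converged: %s), peak face speed %.3g m/s\n",
              x$iterations, x$converged, max(abs(x$U), abs(x$V))))
  invisible(x)
}

# cell-centered velocity components (internal)
cell_velocity <- function(sol) {
  m <- sol$mesh; nx <- m$nx; ny <- m$ny
  ub <- (sol$U[1:nx, , drop = FALSE] + sol$U[2:(nx + 1L), , drop = FALSE]) / 2
  vb <- (sol$V[, 1:ny, drop = FALSE] + sol$V[, 2:(ny + 1L), drop = FALSE]) / 2
  ub[!m$active] <- NA; vb[!m$active] <- NA
  list(u = ub, v = vb, speed = sqrt(ub^2 + vb^2))
}

at_mat <- function(M, i, j) {
  ok <- i >= 1L & i <= nrow(M) & j >= 1L & j <= ncol(M)
  res <- rep(NA_real_, length(i))
  if (any(ok)) res[ok] <- M[cbind(i[ok], j[ok])]
  res
}
at_vec <- function(v, i) {
  ok <- i >= 1L & i <= length(v)
  res <- rep(NA_real_, length(i))
  res[ok] <- v[i[ok]]
  res
}
one_sided_gradient <- function(v1, d1, v2, d2) {
  # slope at 0 of the quadratic through (0,0), (d1,v1), (d2,v2);
  # linear fallback when only one sample is available
  ifelse(is.na(v2), v1 / d1,
         (v1 * d2^2 - v2 * d1^2) / (d1 * d2 * (d2 - d1)))
}

#' Wall shear stress along a tagged boundary
#'
#' Shear stress `tau = mu * |d u_t / d n|` along all boundary faces carrying
#' the given tag, evaluated from a one-sided quadratic fit through the two
#' nearest cell-centered tangential velocities (exact for a parabolic
#' profile). The magnitude convention is used, so `tau >= 0`.
#'
#' @param sol A `flow_solution`.
#' @param boundary Boundary tag (e.g. `"wall"`, `"gas_membrane"`).
#' @param fluid Optional [fluid_properties()]; defaults to the one used for
#'   the solve.
#' @return A data frame with face coordinates `x`, `y`, an arclength along
#'   the boundary and the shear stress `tau` (Pa).
#' @export
wall_shear <- function(sol, boundary = "wall", fluid = sol$fluid) {
  stopifnot(inherits(sol, "flow_solution"))
  m <- sol$mesh; mu <- fluid$viscosity
  cv <- cell_velocity(sol)
  out <- list()
  bf <- boundary_faces(m, boundary, "u")
  if (nrow(bf)) {
    fluid_right <- bf$i <= m$nx & at_mat(m$active * 1, bf$i, bf$j) > 0
    i1 <- ifelse(fluid_right, bf$i, bf$i - 1L)
    s <- ifelse(fluid_right, +1L, -1L)
    i2 <- i1 + s
    v1 <- cv$v[cbind(i1, bf$j)]
    d1 <- m$dx[i1] / 2
    v2 <- at_mat(cv$v, i2, bf$j)
    d2 <- d1 + m$dx[i1] / 2 + at_vec(m$dx, i2) / 2
    tau <- mu * abs(one_sided_gradient(v1, d1, v2, d2))
    out[[length(out) + 1L]] <- data.frame(
      boundary = boundary, x = m$X[bf$i], y = m$yc[bf$j],
      arclength = m$yc[bf$j], tau = tau)
  }
  bf <- boundary_faces(m, boundary, "v")
  if (nrow(bf)) {
    fluid_up <- bf$j <= m$ny & at_mat(m$active * 1, bf$i, bf$j) > 0
    j1 <- ifelse(fluid_up, bf$j, bf$j - 1L)
    s <- ifelse(fluid_up, +1L, -1L)
    j2 <- j1 + s
    u1 <- cv$u[cbind(bf$i, j1)]
    d1 <- m$dy[j1] / 2
    u2 <- at_mat(cv$u, bf$i, j2)
    d2 <- d1 + m$dy[j1] / 2 + at_vec(m$dy, j2) / 2
    tau <- mu * abs(one_sided_gradient(u1, d1, u2, d2))
    out[[length(out) + 1L]] <- data.frame(
      boundary = boundary, x = m$xc[bf$i], y = m$Y[bf$j],
      arclength = m$xc[bf$i], tau = tau)
  }
  if (!length(out))
    stop("no boundary faces with tag: ", boundary, call. = FALSE)
  res <- do.call(rbind, out)
  res <- res[is.finite(res$tau), , drop = FALSE]
  res[order(res$arclength), , drop = FALSE]
}

#' Shear stress on the surface of a mesh region
#'
#' Evaluates `mu * |tangential velocity jump| / distance` across every face
#' separating the region from neighboring fluid, a homogenized measure of
#' the shear experienced at a scaffold or bead-bed surface.
#'
#' @param sol A `flow_solution`.
#' @param region Region name (e.g. `"scaffold"`, `"bead_bed"`,
#'   `"porous_cell_compartment"`).
#' @return A data frame with face coordinates and `tau` (Pa).
#' @export
region_surface_shear <- function(sol, region) {
  m <- sol$mesh
  inreg <- !is.na(m$region) & m$region == region
  if (!any(inreg)) stop("region not present: ", region, call. = FALSE)
  mu <- sol$fluid$viscosity
  cv <- cell_velocity(sol)
  out <- list()
  iL <- which(inreg[-m$nx, , drop = FALSE] != inreg[-1, , drop = FALSE] &
                m$active[-m$nx, , drop = FALSE] & m$active[-1, , drop = FALSE],
              arr.ind = TRUE)
  if (nrow(iL)) {
    i <- iL[, 1]; j <- iL[, 2]
    d <- (m$dx[i] + m$dx[i + 1L]) / 2
    tau <- mu * abs(cv$v[cbind(i + 1L, j)] - cv$v[cbind(i, j)]) / d
    out[[length(out) + 1L]] <- data.frame(x = m$X[i + 1L], y = m$yc[j], tau = tau)
  }
  jL <- which(inreg[, -m$ny, drop = FALSE] != inreg[, -1, drop = FALSE] &
                m$active[, -m$ny, drop = FALSE] & m$active[, -1, drop = FALSE],
              arr.ind = TRUE)
  if (nrow(jL)) {
    i <- jL[, 1]; j <- jL[, 2]
    d <- (m$dy[j] + m$dy[j + 1L]) / 2
    tau <- mu * abs(cv$u[cbind(i, j + 1L)] - cv$u[cbind(i, j)]) / d
    out[[length(out) + 1L]] <- data.frame(x = m$xc[i], y = m$Y[j + 1L], tau = tau)
  }
  if (!length(out))
    stop("region has no interface with surrounding fluid: ", region,
         call. = FALSE)
  res <- do.call(rbind, out)
  res[is.finite(res$tau), , drop = FALSE]
}

#' Inlet Reynolds number of a geometry at a feed rate
#'
#' `Re = rho * v_mean * ID / mu` with the mean speed taken through the
#' circular inlet port of the device.
#'
#' @param geom A `chamber_geometry`.
#' @param fluid A [fluid_properties()].
#' @param flow_rate Feed rate (m^3/s).
#' @return Dimensionless Reynolds number.
#' @export
#' @examples
#' inlet_reynolds(build_quasivivo(), fluid_properties(), 0.5e-6 / 60) # ~10.6
inlet_reynolds <- function(geom, fluid, flow_rate) {
  id <- unname(geom$port_ids["inlet"])
  if (!is.finite(id)) return(NA_real_)
  area <- pi * id^2 / 4
  fluid$density * (flow_rate / area) * id / fluid$viscosity
}

#' Flow diagnostics: Reynolds number, peak speed, recirculation
#'
#' The recirculation fraction is the volume fraction of the fluid domain in
#' which the velocity projects negatively onto the mean inlet-to-outlet
#' direction — a coarse indicator of closed recirculation zones.
#'
#' @param sol A `flow_solution`.
#' @param geom Optional geometry (defaults to the meshed one).
#' @return A list with `reynolds_inlet`, `peak_speed` (m/s) and
#'   `recirculation_fraction`.
#' @export
flow_diagnostics <- function(sol, geom = sol$mesh$geom) {
  m <- sol$mesh
  cv <- cell_velocity(sol)
  re <- inlet_reynolds(geom, sol$fluid, sol$bc$flow_rate)
  peak <- max(cv$speed, na.rm = TRUE)
  cen <- function(tag) {
    fu <- boundary_faces(m, tag, "u"); fv <- boundary_faces(m, tag, "v")
    xs <- c(m$X[fu$i], m$xc[fv$i]); ys <- c(m$yc[fu$j], m$Y[fv$j])
    c(mean(xs), mean(ys))
  }
  dirv <- cen("outlet") - cen("inlet")
  nrm <- sqrt(sum(dirv^2)); dirv <- if (nrm > 0) dirv / nrm else c(1, 0)
  proj <- cv$u * dirv[1] + cv$v * dirv[2]
  act <- m$active & !is.na(proj)
  rec <- if (peak > 0)
    sum(m$vol[act & proj < -1e-9 * peak]) / sum(m$vol[act]) else 0
  list(reynolds_inlet = re, peak_speed = peak, recirculation_fraction = rec)
}

#' Summary shear stress experienced at cell level in a compartment
#'
#' Combines two homogenized estimates: (i) the tangential-jump surface shear
#' across the compartment boundary ([region_surface_shear()]), which
#' dominates when medium flows over the compartment (scaffold chamber,
#' bead bed under a tangential stream), and (ii) a pore-scale estimate
#' `mu * (|u|/porosity) / (pore_size/2)` inside the compartment, which
#' dominates when medium is forced through it (fluidized bed). The reported
#' level is the larger of the two medians.
#'
#' @param sol A `flow_solution`.
#' @param region Cell-compartment region name.
#' @return A list with `tau_surface` and `tau_pore` (median values, Pa) and
#'   `level = max(tau_surface, tau_pore)`.
#' @export
cell_shear_level <- function(sol, region) {
  m <- sol$mesh
  p <- m$geom$porous[[region]]
  if (is.null(p)) stop("not a porous cell compartment: ", region, call. = FALSE)
  surf <- stats::median(region_surface_shear(sol, region)$tau)
  cv <- cell_velocity(sol)
  sel <- !is.na(m$region) & m$region == region
  sp <- cv$speed[sel]
  pore <- stats::median(sol$fluid$viscosity * (sp / p$porosity) /
                          (p$pore_size / 2))
  list(tau_surface = surf, tau_pore = pore, level = max(surf, pore))
}
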