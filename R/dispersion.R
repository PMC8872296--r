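# Sparse 5-point Neumann Laplacian assembly helpers ------------------------

# linear index, column-major: l = (j-1)*nr + i
.face_pairs <- function(nr, nc) {
  # horizontal faces (between rows i, i+1) and vertical faces (cols j, j+1)
  ih <- rep(seq_len(nr - 1), nc)
  jh <- rep(seq_len(nc), each = nr - 1)
  iv <- rep(seq_len(nr), nc - 1)
  jv <- rep(seq_len(nc - 1), each = nr)
  list(h_from = (jh - 1) * nr + ih, h_to = (jh - 1) * nr + ih + 1,
       v_from = (jv - 1) * nr + iv, v_to = jv * nr + iv)
}

#' Prescribed airflow field for one floor and airflow state
#'
#' Stand-in for the CFD airflow stage: a potential-flow (discrete Laplace)
#' problem driven by volumetric injections at supply outlets, extractions at
#' return outlets, and state-signed fluxes at portals. With the PSDs closed
#' the surplus leaves the concourse through the exits and rises from the
#' platform through the stairway; with PSDs open (one platform side), outdoor
#' air enters the concourse exits, descends the stairway and leaves through
#' the open PSD segments. Global mass balance is closed by construction.
#'
#' @param grid a `grid2d` for one floor (from [rasterize()]).
#' @param geometry a [station_geometry()].
#' @param state an airflow-state label valid for the grid's floor, see
#'   [airflow_states()].
#' @param bc a [boundary_conditions()] (supplies outlet velocities).
#' @param return_fraction fraction of the supply flow removed through return
#'   outlets (the rest leaves through portals). Default 0.5.
#' @param q_psd volumetric flow drawn through the open PSD side into the
#'   tunnel, m3/s. Default 8.
#' @return An object of class `flow_field`: `grid`, `state`, `phi`
#'   (potential), `b` (net injected flux per cell, m3/s, positive into the
#'   floor), `u`, `v` (cell-centre velocities, m/s) and the flux `budget`.
#' @export
build_flow <- function(grid, geometry, state, bc = boundary_conditions(),
                       return_fraction = 0.5, q_psd = 8) {
  stopifnot(inherits(grid, "grid2d"))
  if (!state %in% airflow_states(grid$floor))
    stop("state ", state, " not valid for floor ", grid$floor)
  nr <- grid$nrow; nc <- grid$ncol; n <- nr * nc
  H <- grid$height

  ou <- geometry$outlets[geometry$outlets$floor == grid$floor, ]
  v_out <- if (grid$floor == "concourse") bc$v_c else bc$v_p
  Q_sup <- v_out * sum(ou$w[ou$type == "supply"] * ou$h[ou$type == "supply"])
  Q_ret <- return_fraction * Q_sup
  Q_sup_other <- if (grid$floor == "concourse") {
    op <- geometry$outlets[geometry$outlets$floor == "platform", ]
    bc$v_p * sum(op$w[op$type == "supply"] * op$h[op$type == "supply"])
  } else {
    oc <- geometry$outlets[geometry$outlets$floor == "concourse", ]
    bc$v_c * sum(oc$w[oc$type == "supply"] * oc$h[oc$type == "supply"])
  }

  b <- numeric(n)
  put <- function(b, cells, Q) {
    if (!length(cells)) {
      if (abs(Q) > 0) stop("flux assigned to a feature with no grid cells")
      return(b)
    }
    b[cells] <- b[cells] + Q / length(cells)
    b
  }
  sup_cells <- label_cells(grid, "supply")
  ret_cells <- label_cells(grid, "return")
  stair_cells <- c(portal_cells(grid, if (grid$floor == "concourse") "stair_c" else "stair_p"),
                   portal_cells(grid, if (grid$floor == "concourse") "esc_c" else "esc_p"))
  b <- put(b, sup_cells, Q_sup)
  b <- put(b, ret_cells, -Q_ret)

  budget <- list(Q_sup = Q_sup, Q_ret = Q_ret)
  if (grid$floor == "concourse") {
    Q_stair_closed <- Q_sup_other * (1 - return_fraction)   # platform surplus rising
    Q_stair_open <- q_psd - Q_sup_other * (1 - return_fraction) # drawn down to platform
    exit_ids <- geometry$portals$id[geometry$portals$role == "exit"]
    if (state == "CLOSED") {
      b <- put(b, stair_cells, Q_stair_closed)
      Q_exit <- Q_sup - Q_ret + Q_stair_closed
      for (e in exit_ids) b <- put(b, portal_cells(grid, e), -Q_exit / length(exit_ids))
      budget <- c(budget, Q_stair = Q_stair_closed, Q_exit_out = Q_exit)
    } else { # OPEN
      b <- put(b, stair_cells, -Q_stair_open)
      Q_exit_in <- Q_ret + Q_stair_open - Q_sup
      if (Q_exit_in < 0) stop("open-state flux budget requires q_psd large enough ",
                              "for inflow at the exits")
      for (e in exit_ids) b <- put(b, portal_cells(grid, e), Q_exit_in / length(exit_ids))
      budget <- c(budget, Q_stair = -Q_stair_open, Q_exit_in = Q_exit_in)
    }
  } else { # platform
    if (state == "CLOSED") {
      b <- put(b, stair_cells, -(Q_sup - Q_ret))
      budget <- c(budget, Q_stair = -(Q_sup - Q_ret))
    } else {
      side <- if (state == "AB_OPEN") "psd_ab" else "psd_cd"
      psd <- geometry$portals$id[geometry$portals$role == side]
      psd_cells <- unlist(lapply(psd, portal_cells, grid = grid))
      Q_stair_in <- q_psd - (Q_sup - Q_ret)
      if (Q_stair_in < 0) stop("open-state flux budget requires q_psd >= supply surplus")
      b <- put(b, stair_cells, Q_stair_in)
      b <- put(b, psd_cells, -q_psd)
      budget <- c(budget, Q_stair = Q_stair_in, Q_psd_out = q_psd)
    }
  }
  if (abs(sum(b)) > 1e-6 * max(abs(b)))
    stop("flow flux budget failed to close; check portal rasterization")
  b[sup_cells[1]] <- b[sup_cells[1]] - sum(b)  # machine-precision residue

  fp <- .face_pairs(nr, nc)
  from <- c(fp$h_from, fp$v_from); to <- c(fp$h_to, fp$v_to)
  ii <- c(from, to, from, to)
  jj <- c(from, to, to, from)
  xx <- c(rep(1, 2 * length(from)), rep(-1, 2 * length(from)))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  # anchor the potential at cell 1 (pure-Neumann problem is defined up to a
  # constant; b sums to zero so the anchored system is consistent)
  A[1, ] <- 0; A[1, 1] <- 1
  rhs <- b; rhs[1] <- 0
  phi <- as.numeric(Matrix::solve(A, rhs))

  Fh <- matrix(0, nr - 1, nc); Fv <- matrix(0, nr, nc - 1)
  pm <- matrix(phi, nr, nc)
  Fh[] <- pm[-nr, ] - pm[-1, ]
  Fv[] <- pm[, -nc] - pm[, -1]
  u <- matrix(0, nr, nc); vv <- matrix(0, nr, nc)
  u[-nr, ] <- u[-nr, ] + Fh / 2; u[-1, ] <- u[-1, ] + Fh / 2
  vv[, -nc] <- vv[, -nc] + Fv / 2; vv[, -1] <- vv[, -1] + Fv / 2
  u <- u / (grid$cell * H); vv <- vv / (grid$cell * H)

  structure(list(grid = grid, state = state, phi = pm,
                 b = matrix(b, nr, nc), Fh = Fh, Fv = Fv,
                 u = u, v = vv, budget = budget),
            class = "flow_field")
}

#' Net outward volumetric flux through a portal
#'
#' @param flow a `flow_field`.
#' @param id portal id.
#' @return Outward-positive flux, m3/s.
#' @export
portal_flux <- function(flow, id) {
  cells <- portal_cells(flow$grid, id)
  -sum(flow$b[cells])
}

#' Discrete divergence of a flow field
#'
#' Net face outflow minus prescribed injection per cell; by construction this
#' is at solver precision everywhere, and exactly the face imbalance in cells
#' with no injection.
#'
#' @param flow a `flow_field`.
#' @return Matrix of the same shape as the grid.
#' @export
flow_divergence <- function(flow) {
  nr <- flow$grid$nrow; nc <- flow$grid$ncol
  div <- matrix(0, nr, nc)
  div[-nr, ] <- div[-nr, ] + flow$Fh
  div[-1, ] <- div[-1, ] - flow$Fh
  div[, -nc] <- div[, -nc] + flow$Fv
  div[, -1] <- div[, -1] - flow$Fv
  div - flow$b
}

#' Steady PM2.5 concentration field
#'
#' First-order upwind finite-volume discretization of depth-averaged steady
#' advection-diffusion, \eqn{u \cdot \nabla C = D_{eff} \nabla^2 C + S/(A h)},
#' on the face fluxes of a [build_flow()] field. Inflow cells take Dirichlet
#' concentrations (supply outlets at `mu_sup`; portal inflows per the
#' `dirichlet` map, e.g. exits at `mu_out` in the open state); outflow is
#' zero-gradient (advective). The scheme is monotone: with no interior
#' sources the solution stays within the range of the inflow concentrations.
#'
#' @param flow a `flow_field`.
#' @param sources data frame of point sources `x_m, y_m, floor,
#'   rate_mg_per_h` (e.g. from [derive_sources()]); rows on other floors are
#'   ignored. May be `NULL`.
#' @param bc a [boundary_conditions()].
#' @param diffusivity effective (turbulent) diffusivity, m2/s; default 0.1.
#' @param dirichlet named vector mapping cell labels (`"supply"`,
#'   `"portal:<id>"`) to inflow concentrations, ug/m3. Supply cells default
#'   to `bc$mu_sup` when not listed.
#' @param extra_source optional matrix of additional volumetric sources,
#'   ug/s per cell (e.g. equipment emissions).
#' @param source_radius footprint radius over which each point source is
#'   spread uniformly, m; a crowd emits over its standing area rather than a
#'   single cell. Default 1.5.
#' @return An object of class `concentration_field`: `grid`, `state`,
#'   `values` (ug/m3), `residual`.
#' @export
solve_steady <- function(flow, sources = NULL, bc = boundary_conditions(),
                         diffusivity = 0.1, dirichlet = NULL,
                         extra_source = NULL, source_radius = 1.5) {
  stopifnot(inherits(flow, "flow_field"))
  if (diffusivity <= 0) stop("diffusivity must be positive")
  grid <- flow$grid
  nr <- grid$nrow; nc <- grid$ncol; n <- nr * nc
  H <- grid$height; h <- grid$cell

  dir_map <- c(supply = bc$mu_sup)
  if (!is.null(dirichlet)) dir_map[names(dirichlet)] <- dirichlet

  bvec <- as.numeric(flow$b)
  labs <- as.character(grid$labels)
  dir_val <- rep(NA_real_, n)
  for (lab in names(dir_map)) dir_val[labs == lab] <- dir_map[[lab]]
  inflow <- bvec > 1e-12
  if (any(inflow & is.na(dir_val)))
    stop("inflow cells without a Dirichlet concentration: labels ",
         paste(unique(labs[inflow & is.na(dir_val)]), collapse = ", "))
  # any labelled cell with a mapped value is pinned (inflow cells must be)
  is_dir <- !is.na(dir_val)

  S <- numeric(n)
  if (!is.null(sources) && nrow(sources)) {
    src <- sources[sources$floor == grid$floor, , drop = FALSE]
    if (nrow(src)) {
      rate_ugs <- src$rate_mg_per_h * 1000 / 3600
      ri <- max(0L, ceiling(source_radius / h))
      for (k in seq_len(nrow(src))) {
        ij <- grid_index(grid, src$x_m[k], src$y_m[k])
        ii <- max(1L, ij[1] - ri):min(nr, ij[1] + ri)
        jj <- max(1L, ij[2] - ri):min(nc, ij[2] + ri)
        cells <- as.matrix(expand.grid(i = ii, j = jj))
        ctr <- cell_center(grid, cells[, 1], cells[, 2])
        d <- sqrt((ctr[, 1] - src$x_m[k])^2 + (ctr[, 2] - src$y_m[k])^2)
        keep <- d <= max(source_radius, h / 2)
        l <- (cells[keep, 2] - 1L) * nr + cells[keep, 1]
        S[l] <- S[l] + rate_ugs[k] / length(l)
      }
    }
  }
  if (!is.null(extra_source)) S <- S + as.numeric(extra_source)

  fp <- .face_pairs(nr, nc)
  from <- c(fp$h_from, fp$v_from); to <- c(fp$h_to, fp$v_to)
  Ff <- c(as.numeric(flow$Fh), as.numeric(flow$Fv))  # flux from -> to, m3/s
  Dc <- diffusivity * H                               # diffusive conductance

  # per-face contributions: advection (upwind) + diffusion
  ii <- c(from, to, from, to)
  jj <- c(from, to, to, from)
  xx <- c(pmax(Ff, 0) + Dc,    # diag of 'from'
          pmax(-Ff, 0) + Dc,   # diag of 'to'
          pmin(Ff, 0) - Dc,    # from row, to column
          -pmax(Ff, 0) - Dc)   # to row, from column
  # extraction cells: advective removal of cell concentration
  ii <- c(ii, seq_len(n)); jj <- c(jj, seq_len(n))
  xx <- c(xx, pmax(-bvec, 0))
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  rhs <- S

  dcells <- which(is_dir)
  if (length(dcells)) {
    A[dcells, ] <- 0
    A <- A + Matrix::sparseMatrix(i = dcells, j = dcells, x = 1, dims = c(n, n))
    rhs[dcells] <- dir_val[dcells]
  }

  conc <- as.numeric(Matrix::solve(A, rhs))
  resid <- max(abs(A %*% conc - rhs))
  if (min(conc) < -1e-6)
    stop("negative concentration after solve (min ", min(conc),
         "); scheme expected to be monotone")
  conc[conc < 0] <- 0
  structure(list(grid = grid, state = flow$state,
                 values = matrix(conc, nr, nc), residual = resid,
                 diffusivity = diffusivity),
            class = "concentration_field")
}

#' Mean concentration over a floor (or masked region)
#'
#' @param field a `concentration_field`.
#' @param mask optional logical matrix selecting cells; default all cells.
#' @return Arithmetic mean, ug/m3.
#' @export
floor_mean <- function(field, mask = NULL) {
  stopifnot(inherits(field, "concentration_field"))
  v <- if (is.null(mask)) field$values else field$values[mask]
  if (!length(v)) stop("empty mask")
  mean(v)
}

#' Solve all per-state concentration fields for the station
#'
#' Convenience wrapper running [build_flow()] and [solve_steady()] for every
#' airflow state on both floors, with the cross-floor stairway coupling
#' resolved sequentially: the platform closed-state solution supplies the
#' stairway inflow concentration of the concourse closed state, and the
#' concourse open-state solution supplies the stairway inflow of the two
#' platform open states. Equipment emissions (`bc$r_eq`) are spread uniformly
#' over the concourse gate and vending cells.
#'
#' @param geometry a [station_geometry()].
#' @param grids per-floor grids from [rasterize()].
#' @param bc a [boundary_conditions()].
#' @param sources pedestrian particulate sources (see [derive_sources()]).
#' @param diffusivity,return_fraction,q_psd passed to the solvers.
#' @return Nested list `fields[[floor]][[state]]` of `concentration_field`s.
#' @export
solve_station_fields <- function(geometry, grids, bc = boundary_conditions(),
                                 sources = NULL, diffusivity = 0.1,
                                 return_fraction = 0.5, q_psd = 8) {
  gc_ <- grids$concourse; gp <- grids$platform
  eq <- matrix(0, gc_$nrow, gc_$ncol)
  eq_cells <- c(portal_cells(gc_, "gate_in"), portal_cells(gc_, "gate_out"),
                portal_cells(gc_, "vend_w"), portal_cells(gc_, "vend_e"))
  if (length(eq_cells)) eq[eq_cells] <- bc$r_eq * 1e9 / length(eq_cells)  # kg/s -> ug/s

  stair_conc <- function(field, ids) {
    cells <- unlist(lapply(ids, portal_cells, grid = field$grid))
    mean(field$values[cells])
  }
  exit_ids <- geometry$portals$id[geometry$portals$role == "exit"]

  # platform CLOSED (stair is outflow there)
  f_p_cl <- build_flow(gp, geometry, "CLOSED", bc, return_fraction, q_psd)
  c_p_cl <- solve_steady(f_p_cl, sources, bc, diffusivity)

  # concourse CLOSED: stairway carries platform air upward
  f_c_cl <- build_flow(gc_, geometry, "CLOSED", bc, return_fraction, q_psd)
  d_cl <- setNames(rep(stair_conc(c_p_cl, c("stair_p", "esc_p")), 2),
                   c("portal:stair_c", "portal:esc_c"))
  c_c_cl <- solve_steady(f_c_cl, sources, bc, diffusivity, d_cl, eq)

  # concourse OPEN: outdoor air enters the exits, stairway is outflow
  f_c_op <- build_flow(gc_, geometry, "OPEN", bc, return_fraction, q_psd)
  d_op <- setNames(rep(bc$mu_out, length(exit_ids)), paste0("portal:", exit_ids))
  c_c_op <- solve_steady(f_c_op, sources, bc, diffusivity, d_op, eq)

  # platform open states: stairway carries concourse air downward
  mu_stair <- stair_conc(c_c_op, c("stair_c", "esc_c"))
  d_ps <- setNames(rep(mu_stair, 2), c("portal:stair_p", "portal:esc_p"))
  f_p_ab <- build_flow(gp, geometry, "AB_OPEN", bc, return_fraction, q_psd)
  c_p_ab <- solve_steady(f_p_ab, sources, bc, diffusivity, d_ps)
  f_p_cd <- build_flow(gp, geometry, "CD_OPEN", bc, return_fraction, q_psd)
  c_p_cd <- solve_steady(f_p_cd, sources, bc, diffusivity, d_ps)

  list(concourse = list(CLOSED = c_c_cl, OPEN = c_c_op),
       platform = list(CLOSED = c_p_cl, AB_OPEN = c_p_ab, CD_OPEN = c_p_cd))
}
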