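#' Spatial blend model linking state fields to the measured field
#'
#' The "true" time-averaged field a fixed instrument sees lies between the
#' per-state steady fields: over one train headway the PSDs are open for
#' `dwell` seconds, so the open-state weight is `dwell/headway` in the floor
#' interior, but rises smoothly towards 1 where outdoor air dominates
#' whenever the doors cycle. On the concourse that zone is marked by the
#' open-state field itself (exit jets spill around passageway corners, so a
#' purely geometric marker misses them): the open weight is a logistic in
#' the open-state concentration, high where the open-state field approaches
#' the outdoor level (passageways and exit mouths), at its base value in the
#' supply-dominated interior. On the platform the tunnel-draw zones are not
#' marked by the fields, so geometric logistic ramps from each PSD side's
#' footprint are used. Weights are non-negative and sum to 1 in every cell.
#'
#' @param geometry a [station_geometry()].
#' @param grids per-floor grids from [rasterize()].
#' @param fields per-floor, per-state concentration fields
#'   ([solve_station_fields()]); the concourse `OPEN` field drives the
#'   concourse weight.
#' @param headway_s train headway, s.
#' @param dwell_s PSD-open seconds per headway; must satisfy
#'   `0 < dwell_s < headway_s`.
#' @param conc_midpoint,conc_width midpoint and width (ug/m3) of the
#'   concourse logistic in the open-state concentration.
#' @param platform_ramp_distance,platform_ramp_width same for the platform
#'   PSD-side ramps, m.
#' @param gamma smooth nonlinearity exponent of the mixing rule (0 gives a
#'   pure convex combination).
#' @param noise_sd multiplicative instrument noise standard deviation
#'   (fraction of the value).
#' @param quantization instrument resolution, ug/m3 (default 0.1).
#' @return An object of class `blend_model` with per-floor, per-state weight
#'   matrices.
#' @export
default_blend <- function(geometry, grids, fields, headway_s = 360,
                          dwell_s = 30,
                          conc_midpoint = 52, conc_width = 5,
                          platform_ramp_distance = 2.5, platform_ramp_width = 1,
                          gamma = 0, noise_sd = 0.05, quantization = 0.1) {
  if (dwell_s <= 0 || dwell_s >= headway_s)
    stop("dwell must satisfy 0 < dwell < headway")
  b <- dwell_s / headway_s

  rect_dist <- function(x, y, r)
    sqrt(pmax(0, pmax(r$xmin - x, x - r$xmax))^2 +
         pmax(0, pmax(r$ymin - y, y - r$ymax))^2)
  min_dist <- function(grid, rects) {
    ij <- expand.grid(i = seq_len(grid$nrow), j = seq_len(grid$ncol))
    ctr <- cell_center(grid, ij$i, ij$j)
    d <- rep(Inf, nrow(ctr))
    for (r in seq_len(nrow(rects)))
      d <- pmin(d, rect_dist(ctr[, 1], ctr[, 2], rects[r, ]))
    matrix(d, grid$nrow, grid$ncol)
  }

  c_open <- fields$concourse$OPEN
  if (is.null(c_open)) stop("fields must contain the concourse OPEN state")
  w_open <- b + (1 - b) *
    stats::plogis((c_open$values - conc_midpoint) / conc_width)
  conc_w <- list(CLOSED = 1 - w_open, OPEN = w_open)

  gp <- grids$platform
  d_ab <- min_dist(gp, geometry$portals[geometry$portals$role == "psd_ab", ])
  d_cd <- min_dist(gp, geometry$portals[geometry$portals$role == "psd_cd", ])
  ramp <- function(d) stats::plogis((platform_ramp_distance - d) / platform_ramp_width)
  v_ab <- b + (1 - b) * ramp(d_ab)
  v_cd <- b + (1 - b) * ramp(d_cd)
  v_cl <- matrix(1 - 2 * b, gp$nrow, gp$ncol)
  tot <- v_cl + v_ab + v_cd
  plat_w <- list(CLOSED = v_cl / tot, AB_OPEN = v_ab / tot, CD_OPEN = v_cd / tot)

  structure(list(weights = list(concourse = conc_w, platform = plat_w),
                 grids = grids, gamma = gamma, noise_sd = noise_sd,
                 quantization = quantization,
                 headway_s = headway_s, dwell_s = dwell_s),
            class = "blend_model")
}

# deterministic blended field (no noise, no quantization) for one floor
blended_truth <- function(fields, blend, floor) {
  w <- blend$weights[[floor]]
  ff <- fields[[floor]]
  if (is.null(w) || is.null(ff)) stop("unknown floor: ", floor)
  missing_states <- setdiff(names(w), names(ff))
  if (length(missing_states))
    stop("missing state field(s): ", paste(missing_states, collapse = ", "))
  g <- blend$gamma
  acc <- 0
  for (s in names(w)) acc <- acc + w[[s]] * ff[[s]]$values^(1 + g)
  acc^(1 / (1 + g))
}

#' Synthesize instrument readings at a location
#'
#' One-second readings of the synthetic instrument: the spatially weighted
#' power-mean blend of the per-state fields at the location, perturbed by
#' multiplicative Gaussian noise, quantized to the instrument resolution and
#' clipped at zero. Uses the current RNG state; seed with `set.seed()`.
#'
#' @param fields nested per-floor, per-state `concentration_field` list, as
#'   from [solve_station_fields()].
#' @param blend a [default_blend()] model.
#' @param x,y location, m.
#' @param floor `"concourse"` or `"platform"`.
#' @param n number of 1-s readings to draw.
#' @return Numeric vector of `n` readings, ug/m3.
#' @export
synthesize_measured <- function(fields, blend, x, y, floor, n = 1) {
  stopifnot(inherits(blend, "blend_model"))
  w <- blend$weights[[floor]]
  ff <- fields[[floor]]
  if (is.null(ff)) stop("no fields for floor ", floor)
  missing_states <- setdiff(names(w), names(ff))
  if (length(missing_states))
    stop("missing state field(s): ", paste(missing_states, collapse = ", "))
  grid <- blend$grids[[floor]]
  ij <- grid_index(grid, x, y)
  l <- (ij[, 2] - 1L) * grid$nrow + ij[, 1]
  g <- blend$gamma
  base <- 0
  for (s in names(w)) base <- base + w[[s]][l] * ff[[s]]$values[l]^(1 + g)
  base <- base^(1 / (1 + g))
  val <- base * (1 + rnorm(n * length(base), 0, blend$noise_sd))
  val <- round(val / blend$quantization) * blend$quantization
  pmax(0, val)
}

#' Synthesize the measurement-point sample table
#'
#' For every plan point, the measured output is the mean of `n_draws`
#' one-second synthetic readings (a ten-minute occupation at 1 Hz by
#' default), and the inputs are the per-state simulated concentrations at the
#' point. Concourse rows carry two inputs, platform rows three.
#'
#' @param plan a [design_station_samples()] plan.
#' @param fields per-floor, per-state fields ([solve_station_fields()]).
#' @param blend a [default_blend()] model.
#' @param n_draws readings averaged per point; default 600.
#' @return Named list of data frames (`concourse`, `platform`) with columns
#'   `point_id, floor, zone, x_m, y_m, sim_<state>..., measured`.
#' @export
synthesize_sample_table <- function(plan, fields, blend, n_draws = 600) {
  out <- lapply(c("concourse", "platform"), function(fl) {
    p <- plan[plan$floor == fl, , drop = FALSE]
    if (!nrow(p)) return(NULL)
    grid <- blend$grids[[fl]]
    ij <- grid_index(grid, p$x_m, p$y_m)
    l <- (ij[, 2] - 1L) * grid$nrow + ij[, 1]
    sims <- lapply(fields[[fl]], function(f) f$values[l])
    names(sims) <- paste0("sim_", tolower(names(sims)))
    measured <- vapply(seq_len(nrow(p)), function(k)
      mean(synthesize_measured(fields, blend, p$x_m[k], p$y_m[k], fl, n_draws)),
      numeric(1))
    cbind(p[, c("point_id", "floor", "zone", "x_m", "y_m")],
          as.data.frame(sims), measured = measured)
  })
  names(out) <- c("concourse", "platform")
  out[!vapply(out, is.null, logical(1))]
}

#' Synthesize a mobile 1-s sampling curve along a trajectory
#'
#' Emulates a hand-carried instrument logging once per second while its
#' bearer walks through the station: one synthetic reading per trajectory
#' second at the current position.
#'
#' @param trajectory data frame for one pedestrian (`ped_id, t, floor, x,
#'   y`).
#' @param fields,blend as in [synthesize_measured()].
#' @return Data frame `ped_id, t_s, conc_ugm3`, one row per second.
#' @export
synthesize_mobile_curve <- function(trajectory, fields, blend) {
  if (!nrow(trajectory))
    return(data.frame(ped_id = integer(), t_s = numeric(), conc_ugm3 = numeric()))
  conc <- numeric(nrow(trajectory))
  for (fl in unique(trajectory$floor)) {
    ix <- which(trajectory$floor == fl)
    conc[ix] <- synthesize_measured(fields, blend, trajectory$x[ix],
                                    trajectory$y[ix], fl, n = 1)
  }
  data.frame(ped_id = trajectory$ped_id, t_s = trajectory$t, conc_ugm3 = conc)
}
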