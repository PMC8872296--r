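#' Ventilation and particulate boundary conditions
#'
#' Boundary-condition set for the dispersion stage. Defaults describe the
#' bundled station during the non-air-conditioning season: untreated but
#' filtered outdoor air is supplied to both floors and all return air is
#' discharged outdoors.
#'
#' @param v_c concourse supply-air outlet velocity, m/s.
#' @param v_p platform supply-air outlet velocity, m/s.
#' @param W_l lighting load, W/m2 (carried for configuration fidelity; unused
#'   by the depth-averaged solver).
#' @param rho_p particle material density, kg/m3 (carried; unused).
#' @param D_p particle diameter, m (carried; unused).
#' @param mu_out outdoor PM2.5 concentration, ug/m3.
#' @param mu_sup supply-air PM2.5 concentration, ug/m3. Kept as an independent
#'   printed value rather than recomputed from `mu_out` and the filter pass
#'   fraction (which would give 24.6).
#' @param r_per per-person particulate generation rate, mg/(person h).
#' @param r_eq equipment particulate generation rate, kg/s.
#' @param filtration_efficiency fraction associated with the ventilation
#'   system's primary filter (0.40 by default). Stored alongside `mu_sup`;
#'   note that `mu_out * 0.40` is approximately `mu_sup`, i.e. the number
#'   behaves as a pass fraction, and the configuration stores both values
#'   without resolving the semantics.
#' @return An object of class `boundary_conditions` (a named list).
#' @examples
#' bc <- boundary_conditions()
#' bc$mu_out
#' @export
boundary_conditions <- function(v_c = 2.3, v_p = 1.9, W_l = 20,
                                rho_p = 1050, D_p = 2.5e-6,
                                mu_out = 61.5, mu_sup = 24.4,
                                r_per = 10, r_eq = 3.78e-9,
                                filtration_efficiency = 0.40) {
  bc <- list(v_c = v_c, v_p = v_p, W_l = W_l, rho_p = rho_p, D_p = D_p,
             mu_out = mu_out, mu_sup = mu_sup, r_per = r_per, r_eq = r_eq,
             filtration_efficiency = filtration_efficiency)
  bad <- vapply(bc, function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x < 0, logical(1))
  if (any(bad))
    stop("boundary conditions must be single non-negative numbers: ",
         paste(names(bc)[bad], collapse = ", "))
  class(bc) <- "boundary_conditions"
  bc
}

#' Construct a station geometry
#'
#' Low-level constructor; most users call [build_default_station()].
#'
#' @param floors named list (`concourse`, `platform`), each with `length`,
#'   `width`, `height` in metres. Coordinates are metric, origin at each
#'   floor's south-west corner, x along the length.
#' @param portals data frame with columns `id`, `floor`, `role`, `xmin`,
#'   `xmax`, `ymin`, `ymax` (axis-aligned footprints).
#' @param outlets data frame with columns `floor`, `type` (`"supply"` or
#'   `"return"`), `x`, `y` (centre) and `w`, `h` (outlet size, m).
#' @return An object of class `station_geometry`.
#' @export
station_geometry <- function(floors, portals, outlets) {
  stopifnot(all(c("concourse", "platform") %in% names(floors)))
  for (fl in names(floors))
    stopifnot(all(c("length", "width", "height") %in% names(floors[[fl]])))
  portals <- as.data.frame(portals)
  outlets <- as.data.frame(outlets)
  for (k in seq_len(nrow(portals))) {
    p <- portals[k, ]
    f <- floors[[p$floor]]
    if (is.null(f)) stop("portal ", p$id, " references unknown floor ", p$floor)
    if (p$xmin < 0 || p$ymin < 0 || p$xmax > f$length || p$ymax > f$width)
      stop("portal ", p$id, " footprint lies outside its floor")
  }
  if (any(portals$role == "exit" & portals$floor != "concourse"))
    stop("exits may only be placed on the concourse")
  if (any(grepl("^psd", portals$role) & portals$floor != "platform"))
    stop("PSD segments may only be placed on the platform")
  structure(list(floors = floors, portals = portals, outlets = outlets),
            class = "station_geometry")
}

#' Bundled default station
#'
#' Two-floor underground island-platform station with platform screen doors:
#' a 90.4 m x 20 m x 3.5 m concourse with four street exits (A-D) and their
#' passageways, security checkpoint, inbound/outbound gate arrays, ticket and
#' vending machines, and a stair/escalator pair down to a 110 m x 12.8 m x 3 m
#' island platform with six PSD segments per side (AB side north, CD side
#' south). Supply and return outlets are uniformly spaced arrays matching the
#' standard outlet sizes (300 x 300 mm concourse, 600 x 500 mm platform).
#'
#' @return A [station_geometry()] object.
#' @examples
#' geo <- build_default_station()
#' with(geo$floors$concourse, length * width)  # public plan area, m2
#' @export
build_default_station <- function() {
  floors <- list(
    concourse = list(length = 90.4, width = 20,   height = 3.5),
    platform  = list(length = 110,  width = 12.8, height = 3))

  p <- function(id, floor, role, xmin, xmax, ymin, ymax)
    data.frame(id = id, floor = floor, role = role,
               xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)

  psd_x <- c(15, 30, 45, 60, 75, 90)
  portals <- rbind(
    p("A", "concourse", "exit", 0,    0.4,  12, 16),
    p("B", "concourse", "exit", 0,    0.4,  4,  8),
    p("C", "concourse", "exit", 90.0, 90.4, 4,  8),
    p("D", "concourse", "exit", 90.0, 90.4, 12, 16),
    p("pw_A", "concourse", "passageway", 0.4, 10,   12, 16),
    p("pw_B", "concourse", "passageway", 0.4, 10,   4,  8),
    p("pw_C", "concourse", "passageway", 80.8, 90.0, 4,  8),
    p("pw_D", "concourse", "passageway", 80.8, 90.0, 12, 16),
    p("ticket_w", "concourse", "ticket", 14,   16,   17, 19.5),
    p("ticket_e", "concourse", "ticket", 74.4, 76.4, 17, 19.5),
    p("vend_w", "concourse", "vending", 14,   16,   0.5, 3),
    p("vend_e", "concourse", "vending", 74.4, 76.4, 0.5, 3),
    p("security", "concourse", "security", 24, 28, 8, 12),
    p("gate_in",  "concourse", "gate_in",  36, 38, 6, 14),
    p("gate_out", "concourse", "gate_out", 54, 56, 6, 14),
    p("stair_c", "concourse", "stair",     43, 46, 6.5, 9.5),
    p("esc_c",   "concourse", "escalator", 43, 46, 10.5, 13.5),
    p("stair_p", "platform", "stair",     52, 55, 4.9, 7.9),
    p("esc_p",   "platform", "escalator", 57, 60, 4.9, 7.9),
    do.call(rbind, lapply(seq_along(psd_x), function(i)
      p(sprintf("psd_cd_%d", i), "platform", "psd_cd",
        psd_x[i] - 1, psd_x[i] + 1, 0, 0.4))),
    do.call(rbind, lapply(seq_along(psd_x), function(i)
      p(sprintf("psd_ab_%d", i), "platform", "psd_ab",
        psd_x[i] - 1, psd_x[i] + 1, 12.4, 12.8))))

  outlets <- rbind(
    expand.grid(floor = "concourse", type = "supply",
                x = seq(12, 78.4, length.out = 8), y = c(5, 15),
                w = 0.3, h = 0.3, stringsAsFactors = FALSE),
    data.frame(floor = "concourse", type = "return",
               x = seq(20, 70.4, length.out = 8), y = 18.5,
               w = 0.3, h = 0.3),
    data.frame(floor = "platform", type = "supply",
               x = seq(10, 100, by = 10), y = 9.4, w = 0.6, h = 0.5),
    data.frame(floor = "platform", type = "return",
               x = seq(15, 95, by = 16), y = 3.4, w = 0.6, h = 0.5))

  station_geometry(floors, portals, outlets)
}

#' Airflow-organization states of a floor
#'
#' The PSD system yields discrete ventilation regimes: on the concourse the
#' PSDs are either closed (station air leaves through the exits) or open
#' (outdoor air enters through the exits); on the island platform either all
#' PSDs are closed or those on one side (AB or CD) are open while a train
#' dwells.
#'
#' @param floor `"concourse"` or `"platform"`.
#' @return Character vector of state labels.
#' @examples
#' airflow_states("concourse")
#' airflow_states("platform")
#' @export
airflow_states <- function(floor) {
  switch(as.character(floor),
         concourse = c("CLOSED", "OPEN"),
         platform  = c("CLOSED", "AB_OPEN", "CD_OPEN"),
         stop("unknown floor: ", floor))
}

#' Rasterize a station geometry onto per-floor grids
#'
#' Cells are half-open squares `[i*h, (i+1)*h)`; indices are 1-based
#' row-major with rows along the floor length (x) and columns along the width
#' (y). A cell takes the label of the portal covering its centre
#' (`"portal:<id>"`), else `"supply"`/`"return"` if an outlet covers it, else
#' `"walkable"`. Every portal is guaranteed at least one cell (the cell
#' containing its footprint centre).
#'
#' @param geometry a [station_geometry()].
#' @param cell_size grid spacing h, m; must be positive and no larger than the
#'   smallest floor dimension.
#' @return Named list of `grid2d` objects, one per floor.
#' @examples
#' g <- rasterize(build_default_station(), 0.4)
#' dim(g$concourse$labels)  # 226 x 50
#' @export
rasterize <- function(geometry, cell_size) {
  stopifnot(inherits(geometry, "station_geometry"))
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive number")
  mindim <- min(unlist(lapply(geometry$floors, function(f) c(f$length, f$width))))
  if (cell_size > mindim)
    stop("cell_size exceeds the smallest floor dimension")
  out <- lapply(names(geometry$floors), function(fl) {
    f <- geometry$floors[[fl]]
    nr <- ceiling(f$length / cell_size)
    nc <- ceiling(f$width / cell_size)
    labels <- matrix("walkable", nr, nc)
    xc <- (seq_len(nr) - 0.5) * cell_size
    yc <- (seq_len(nc) - 0.5) * cell_size
    ou <- geometry$outlets[geometry$outlets$floor == fl, , drop = FALSE]
    for (k in seq_len(nrow(ou))) {
      o <- ou[k, ]
      ii <- which(xc >= o$x - o$w / 2 & xc < o$x + o$w / 2)
      jj <- which(yc >= o$y - o$h / 2 & yc < o$y + o$h / 2)
      if (!length(ii)) ii <- pmin(nr, pmax(1L, floor(o$x / cell_size) + 1L))
      if (!length(jj)) jj <- pmin(nc, pmax(1L, floor(o$y / cell_size) + 1L))
      labels[ii, jj] <- o$type
    }
    po <- geometry$portals[geometry$portals$floor == fl, , drop = FALSE]
    # rasterize larger footprints first so small portals (e.g. exits) are
    # never shadowed by an overlapping/adjacent larger zone at coarse cells
    po <- po[order(-(po$xmax - po$xmin) * (po$ymax - po$ymin)), , drop = FALSE]
    for (k in seq_len(nrow(po))) {
      pt <- po[k, ]
      ii <- which(xc >= pt$xmin & xc < pt$xmax)
      jj <- which(yc >= pt$ymin & yc < pt$ymax)
      if (!length(ii)) ii <- pmin(nr, pmax(1L, floor((pt$xmin + pt$xmax) / 2 / cell_size) + 1L))
      if (!length(jj)) jj <- pmin(nc, pmax(1L, floor((pt$ymin + pt$ymax) / 2 / cell_size) + 1L))
      labels[ii, jj] <- paste0("portal:", pt$id)
    }
    structure(list(floor = fl, cell = cell_size, nrow = nr, ncol = nc,
                   length = f$length, width = f$width, height = f$height,
                   origin = c(0, 0), labels = labels),
              class = "grid2d")
  })
  names(out) <- names(geometry$floors)
  out
}

#' @method print grid2d
#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("grid2d: %s, %d x %d cells of %.2f m (%.1f x %.1f m)\n",
              x$floor, x$nrow, x$ncol, x$cell, x$length, x$width))
  invisible(x)
}

# row/col of the cell containing (x, y), clamped to the grid
grid_index <- function(grid, x, y) {
  i <- pmin(grid$nrow, pmax(1L, floor(x / grid$cell) + 1L))
  j <- pmin(grid$ncol, pmax(1L, floor(y / grid$cell) + 1L))
  cbind(i, j)
}

# centre coordinates of cells given row/col indices
cell_center <- function(grid, i, j) {
  cbind((i - 0.5) * grid$cell, (j - 0.5) * grid$cell)
}

# linear indices of cells carrying a given label
label_cells <- function(grid, label) which(grid$labels == label)

# linear indices of a portal's cells
portal_cells <- function(grid, id) label_cells(grid, paste0("portal:", id))

# centre point of a portal footprint
portal_center <- function(geometry, id) {
  p <- geometry$portals[geometry$portals$id == id, ]
  if (nrow(p) != 1L) stop("unknown portal: ", id)
  c((p$xmin + p$xmax) / 2, (p$ymin + p$ymax) / 2)
}

#' Write and read a station configuration
#'
#' Serializes geometry and boundary conditions to YAML or JSON (chosen by file
#' extension). Values round-trip unchanged.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @param geometry a [station_geometry()].
#' @param bc a [boundary_conditions()] object.
#' @return `write_station_config()` returns `path` invisibly;
#'   `read_station_config()` returns `list(geometry, bc)`.
#' @export
write_station_config <- function(path, geometry = build_default_station(),
                                 bc = boundary_conditions()) {
  cfg <- list(floors = geometry$floors,
              portals = geometry$portals,
              outlets = geometry$outlets,
              boundary_conditions = unclass(bc))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    cfg$portals <- lapply(seq_len(nrow(geometry$portals)),
                          function(k) as.list(geometry$portals[k, ]))
    cfg$outlets <- lapply(seq_len(nrow(geometry$outlets)),
                          function(k) as.list(geometry$outlets[k, ]))
    yaml::write_yaml(cfg, path)
  } else if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported config extension: ", ext)
  invisible(path)
}

#' @rdname write_station_config
#' @export
read_station_config <- function(path) {
  if (!file.exists(path)) stop("station config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config extension: ", ext)
  portals <- cfg$portals
  outlets <- cfg$outlets
  if (!is.data.frame(portals))
    portals <- do.call(rbind, lapply(portals, as.data.frame))
  if (!is.data.frame(outlets))
    outlets <- do.call(rbind, lapply(outlets, as.data.frame))
  bc <- do.call(boundary_conditions, cfg$boundary_conditions)
  list(geometry = station_geometry(cfg$floors, portals, outlets), bc = bc)
}
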