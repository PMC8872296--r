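# Shared fixtures, built once per test run.

# hand-built 1-D channel flow on an n x 1 grid: constant face flux f (m3/s)
# from cell 1 to cell n, inflow at cell 1 (labelled portal:in), outflow at n
channel_flow <- function(n = 50, f = 1, cell = 1, height = 1) {
  labels <- matrix("walkable", n, 1)
  labels[1, 1] <- "portal:in"
  grid <- structure(list(floor = "concourse", cell = cell, nrow = n, ncol = 1,
                         length = n * cell, width = cell, height = height,
                         origin = c(0, 0), labels = labels),
                    class = "grid2d")
  b <- matrix(0, n, 1); b[1, 1] <- f; b[n, 1] <- -f
  structure(list(grid = grid, state = "CLOSED", phi = matrix(0, n, 1),
                 b = b, Fh = matrix(f, n - 1, 1),
                 Fv = matrix(0, n, 0),
                 u = matrix(f / (cell * height), n, 1),
                 v = matrix(0, n, 1), budget = list()),
            class = "flow_field")
}

# quiescent 1-D strip with both end cells labelled for Dirichlet pinning
still_strip <- function(n = 21, cell = 1) {
  labels <- matrix("walkable", n, 1)
  labels[1, 1] <- "portal:west"
  labels[n, 1] <- "portal:east"
  grid <- structure(list(floor = "concourse", cell = cell, nrow = n, ncol = 1,
                         length = n * cell, width = cell, height = 1,
                         origin = c(0, 0), labels = labels),
                    class = "grid2d")
  structure(list(grid = grid, state = "CLOSED", phi = matrix(0, n, 1),
                 b = matrix(0, n, 1), Fh = matrix(0, n - 1, 1),
                 Fv = matrix(0, n, 0), u = matrix(0, n, 1),
                 v = matrix(0, n, 1), budget = list()),
            class = "flow_field")
}

# memoized default-station objects shared across test files
.fixture_env <- new.env(parent = emptyenv())

default_geometry <- function() {
  if (is.null(.fixture_env$geo)) .fixture_env$geo <- build_default_station()
  .fixture_env$geo
}

default_grids <- function(cell = 0.8) {
  key <- paste0("grids_", cell)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- rasterize(default_geometry(), cell)
  .fixture_env[[key]]
}

# the canonical full pipeline run (default configuration, master seed 1)
shared_run <- function() {
  if (is.null(.fixture_env$run))
    .fixture_env$run <- run_full(seed = 1, quiet = TRUE)
  .fixture_env$run
}

# straight-corridor trajectory at fixed speed for kinematics checks
straight_trajectory <- function(length_m = 50, speed = 1.25,
                                floor = "concourse", y = 10) {
  tt <- 0:floor(length_m / speed)
  data.frame(ped_id = 1L, direction = "boarding", t = tt, floor = floor,
             x = pmin(length_m, speed * tt), y = y)
}
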