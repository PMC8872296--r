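test_that("flow budgets close and portal fluxes carry the state's sign", {
  geo <- default_geometry()
  g <- default_grids()
  bc <- boundary_conditions()
  for (fl in names(g)) for (st in airflow_states(fl)) {
    flow <- build_flow(g[[fl]], geo, st, bc)
    # net injection balances to machine precision
    expect_lt(abs(sum(flow$b)), 1e-9)
    # discrete divergence vanishes everywhere (face fluxes match injections)
    expect_lt(max(abs(flow_divergence(flow))), 1e-8)
  }
  closed <- build_flow(g$concourse, geo, "CLOSED", bc)
  open <- build_flow(g$concourse, geo, "OPEN", bc)
  for (e in c("A", "B", "C", "D")) {
    expect_gt(portal_flux(closed, e), 0)  # outward when PSDs closed
    expect_lt(portal_flux(open, e), 0)    # inward when PSDs opened
  }
  ab <- build_flow(g$platform, geo, "AB_OPEN", bc)
  psd_out <- sum(vapply(sprintf("psd_ab_%d", 1:6), portal_flux,
                        numeric(1), flow = ab))
  expect_equal(psd_out, 8, tolerance = 1e-9)
  expect_error(build_flow(g$concourse, geo, "AB_OPEN", bc), "not valid")
})

test_that("uniform inflow produces the constant solution", {
  geo <- default_geometry()
  g <- default_grids()
  bc <- boundary_conditions()
  flow <- build_flow(g$concourse, geo, "CLOSED", bc)
  c0 <- 46.67
  dir <- c(supply = c0, "portal:stair_c" = c0, "portal:esc_c" = c0)
  f <- solve_steady(flow, NULL, bc, dirichlet = dir)
  expect_lt(max(abs(f$values - c0)), 1e-8)
  expect_equal(floor_mean(f), c0, tolerance = 1e-9)
})

test_that("pure diffusion between two pinned walls gives the linear profile", {
  flow <- still_strip(21)
  f <- solve_steady(flow, NULL, boundary_conditions(), diffusivity = 0.5,
                    dirichlet = c("portal:west" = 0, "portal:east" = 100))
  prof <- as.numeric(f$values)
  expect_equal(prof[11], 50, tolerance = 1e-8)            # midpoint
  expect_equal(prof, seq(0, 100, length.out = 21), tolerance = 1e-8)
})

test_that("1-D advection with a uniform source matches the closed form", {
  n <- 60; f_flux <- 2; h <- 0.5; H <- 1
  flow <- channel_flow(n, f = f_flux, cell = h, height = H)
  c0 <- 10
  s_cell <- 0.4  # ug/s injected per cell
  S <- matrix(s_cell, n, 1); S[1, 1] <- 0
  sol <- solve_steady(flow, NULL, boundary_conditions(), diffusivity = 1e-9,
                      dirichlet = c("portal:in" = c0), extra_source = S)
  # advection-dominated limit: c grows linearly, c_i = c0 + (i-1) s/f
  expected <- c0 + (seq_len(n) - 1) * s_cell / f_flux
  expect_equal(as.numeric(sol$values), expected, tolerance = 1e-6)
})

test_that("solution is linear in source strength with zero inflow", {
  geo <- default_geometry()
  g <- default_grids()
  bc <- boundary_conditions()
  flow <- build_flow(g$concourse, geo, "CLOSED", bc)
  src <- data.frame(x_m = c(26, 60), y_m = c(10, 11), floor = "concourse",
                    rate_mg_per_h = c(40, 25))
  dir0 <- c(supply = 0, "portal:stair_c" = 0, "portal:esc_c" = 0)
  f1 <- solve_steady(flow, src, bc, dirichlet = dir0)
  src3 <- transform(src, rate_mg_per_h = 3 * rate_mg_per_h)
  f3 <- solve_steady(flow, src3, bc, dirichlet = dir0)
  expect_equal(f3$values, 3 * f1$values, tolerance = 1e-8)
})

test_that("maximum principle holds without interior sources", {
  geo <- default_geometry()
  g <- default_grids()
  bc <- boundary_conditions()
  flow <- build_flow(g$concourse, geo, "OPEN", bc)
  dir <- c(supply = 24.4, "portal:A" = 61.5, "portal:B" = 58,
           "portal:C" = 65, "portal:D" = 61.5)
  f <- solve_steady(flow, NULL, bc, dirichlet = dir)
  expect_gte(min(f$values), 24.4 - 1e-9)
  expect_lte(max(f$values), 65 + 1e-9)
})

test_that("floor mean equals the direct-sum oracle and validates masks", {
  g <- default_grids()$platform
  vals <- matrix(runif(g$nrow * g$ncol, 20, 80), g$nrow, g$ncol)
  f <- structure(list(grid = g, state = "CLOSED", values = vals, residual = 0),
                 class = "concentration_field")
  expect_equal(floor_mean(f), sum(vals) / length(vals))
  mask <- vals > 50
  expect_equal(floor_mean(f, mask), mean(vals[vals > 50]))
  expect_error(floor_mean(f, matrix(FALSE, g$nrow, g$ncol)), "empty")
  two <- structure(list(grid = g, state = "CLOSED",
                        values = matrix(c(40, 60), 2, 1), residual = 0),
                   class = "concentration_field")
  expect_equal(floor_mean(two), 50)
})

test_that("refining the mesh changes floor means by less than 5%", {
  geo <- default_geometry()
  bc <- boundary_conditions()
  src <- data.frame(x_m = c(26, 37), y_m = c(10, 10), floor = "concourse",
                    rate_mg_per_h = c(60, 40))
  means <- vapply(c(0.8, 0.4), function(h) {
    fields <- solve_station_fields(geo, rasterize(geo, h), bc, src)
    floor_mean(fields$concourse$CLOSED)
  }, numeric(1))
  expect_lt(abs(means[2] - means[1]) / means[1], 0.05)
})

test_that("concentration maxima co-locate with sources or return outlets", {
  run <- shared_run()
  f <- run$fields$concourse$CLOSED
  g <- run$grids$concourse
  peak <- arrayInd(which.max(f$values), dim(f$values))
  pk <- metropm:::cell_center(g, peak[1], peak[2])
  src <- run$sources[run$sources$floor == "concourse", ]
  d_src <- if (nrow(src)) min(sqrt((src$x_m - pk[1])^2 + (src$y_m - pk[2])^2)) else Inf
  ret <- run$geometry$outlets
  ret <- ret[ret$floor == "concourse" & ret$type == "return", ]
  d_ret <- min(sqrt((ret$x - pk[1])^2 + (ret$y - pk[2])^2))
  expect_lt(min(d_src, d_ret), 5)
})
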