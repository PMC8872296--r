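test_that("walking speeds follow the truncated normal model", {
  expect_equal(sample_speed(speed_model(spread = 0), 5), rep(1.25, 5))
  set.seed(1)
  sp <- sample_speed(speed_model(), 1e5)
  expect_true(all(sp > 0))
  expect_true(all(sp >= 0.3 & sp <= 2.5))
  se <- 0.2 / sqrt(1e5)
  expect_lt(abs(mean(sp) - 1.25), 3 * se + 1e-3)  # truncation shifts ~0
  expect_error(speed_model(mean = -1), "positive")
  # literal-variance reading is wider
  expect_gt(sd(sample_speed(speed_model(spread_is = "variance"), 1e4)), 0.3)
})

test_that("route cost combines distance, queue and component terms", {
  expect_equal(route_cost(50, 1.25, 30, 10), 80)
  expect_equal(route_cost(50, 1.25, 30, 10,
                          route_cost_weights(W_q = 0, W_L = 0)), 40)
  expect_error(route_cost(50, 0, 0, 0), "positive")
  # monotone in queue time
  q <- seq(0, 60, by = 10)
  costs <- vapply(q, function(qi) route_cost(50, 1.25, qi, 10), numeric(1))
  expect_true(all(diff(costs) >= 0))
})

test_that("demand spec validates and normalizes the exit ratio", {
  d <- demand_spec()
  expect_equal(sum(d$exit_ratio), 1)
  expect_equal(unname(d$exit_ratio["A"] / d$exit_ratio["C"]), 3.5)
  expect_error(demand_spec(boarding_up = -1), "non-negative")
  expect_error(demand_spec(card_fraction = 1.5), "card_fraction")
})

test_that("simulation conserves agents and respects kinematics and FIFO", {
  sim <- simulate_trajectories(duration = 720, seed = 11)
  ag <- sim$agents
  # conservation: every spawned agent completes or is recorded as dropped
  expect_equal(sum(ag$completed) + length(sim$dropped), nrow(ag))
  # determinism
  sim2 <- simulate_trajectories(duration = 720, seed = 11)
  expect_identical(sim$trajectories, sim2$trajectories)
  # 1-s speed cap: no displacement above the truncation bound
  tr <- sim$trajectories
  for (d in split(tr, tr$ped_id)) {
    if (nrow(d) < 2) next
    step <- sqrt(diff(d$x)^2 + diff(d$y)^2) / diff(d$t)
    expect_lte(max(step), 2.5 + 1e-9)
    expect_true(all(diff(d$t) == 1))
  }
  # positions stay inside the walkable floor rectangles
  geo <- default_geometry()
  for (fl in unique(tr$floor)) {
    f <- geo$floors[[fl]]
    sel <- tr$floor == fl
    expect_true(all(tr$x[sel] >= 0 & tr$x[sel] <= f$length))
    expect_true(all(tr$y[sel] >= 0 & tr$y[sel] <= f$width))
  }
})

test_that("FIFO queue recursion never allows overtaking", {
  arr <- c(0, 1, 2, 2.5, 10)
  sv <- metropm:::serve_fifo(arr, 2, 3)
  # service starts ordered like arrivals within the facility
  expect_true(all(diff(sv$start[order(arr)]) >= 0))
  expect_true(all(sv$wait >= 0))
  # single server, saturated: departures spaced by the service time
  sv1 <- metropm:::serve_fifo(c(0, 0, 0, 0), 1, 2)
  expect_equal(sort(sv1$depart), c(2, 4, 6, 8))
})

test_that("density map matches a direct person-second count", {
  g <- default_grids()$concourse
  # one stationary agent in one cell for the whole window
  tr <- data.frame(ped_id = 1, direction = "boarding", t = 0:99,
                   floor = "concourse", x = 10.1, y = 10.1)
  dm <- density_map(tr, g, c(0, 100))
  ij <- metropm:::grid_index(g, 10.1, 10.1)
  expect_equal(dm$values[ij[1], ij[2]], 1 / g$cell^2)  # 1 person per cell area
  expect_equal(sum(dm$values > 0), 1)
  # doubling identical trajectories doubles every cell
  tr2 <- rbind(tr, transform(tr, ped_id = 2))
  dm2 <- density_map(tr2, g, c(0, 100))
  expect_equal(dm2$values, 2 * dm$values)
  # integral over the floor equals the time-average head count
  sim <- simulate_trajectories(duration = 720, seed = 3)
  win <- c(200, 500)
  dmc <- density_map(sim$trajectories, g, win)
  inwin <- sim$trajectories$floor == "concourse" &
    sim$trajectories$t >= win[1] & sim$trajectories$t < win[2]
  expect_equal(sum(dmc$values) * g$cell^2,
               sum(inwin) / diff(win))
  expect_error(density_map(tr, g, c(50, 50)), "empty")
})

test_that("service levels follow the waiting level-of-service thresholds", {
  expect_equal(service_level(0.370), "A")
  expect_equal(service_level(0.371), "B")
  expect_equal(service_level(0.5), "C")
  expect_equal(service_level(0.667), "D")
  expect_equal(service_level(1.2), "F")
  expect_equal(service_level(c(0, 0.435, 1)), c("A", "B", "E"))
  expect_error(service_level(-0.1), "non-negative")
})

test_that("particulate sources form at congested regions with r_per scaling", {
  g <- default_grids()$concourse
  vals <- matrix(0, g$nrow, g$ncol)
  vals[10:12, 10:12] <- 5 / (9 * g$cell^2)  # 5 persons in a 3x3 block
  dens <- structure(list(grid = g, values = vals, window = c(0, 1)),
                    class = "density_field")
  src <- derive_sources(dens, boundary_conditions())
  expect_equal(nrow(src), 1)
  expect_equal(src$persons, 5, tolerance = 1e-12)
  expect_equal(src$rate_mg_per_h, 50)  # 5 persons x 10 mg/(person h)
  ctr <- metropm:::cell_center(g, 11, 11)
  expect_equal(c(src$x_m, src$y_m), c(ctr[1], ctr[2]))
  # uniformly level-A floor yields no sources
  quiet <- structure(list(grid = g, values = matrix(0.1, g$nrow, g$ncol),
                          window = c(0, 1)), class = "density_field")
  expect_equal(nrow(derive_sources(quiet, boundary_conditions())), 0)
  # out-of-range per-person rate warns
  expect_warning(derive_sources(dens, boundary_conditions(r_per = 20)),
                 "6.5-15.2")
})

test_that("residence statistics reduce to the direct average", {
  ag <- data.frame(ped_id = 1:3, direction = "boarding",
                   entry_time = c(0, 0, 0), exit_time = c(50, 100, 150),
                   completed = TRUE)
  rs <- residence_stats(ag)
  expect_equal(c(rs$min_s, rs$max_s, rs$mean_s), c(50, 150, 100))
  one <- residence_stats(ag[1, ])
  expect_equal(one$min_s, one$max_s)
  expect_equal(one$min_s, one$mean_s)
  expect_error(residence_stats(ag[0, ]), "no")
})
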