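test_that("blend weights sum to one and follow the open-air pattern", {
  run <- shared_run()
  blend <- run$blend
  expect_equal(blend$dwell_s / blend$headway_s, 1 / 12)
  for (fl in c("concourse", "platform")) {
    w <- blend$weights[[fl]]
    tot <- Reduce(`+`, w)
    expect_lt(max(abs(tot - 1)), 1e-12)
    for (m in w) expect_gte(min(m), 0)
  }
  # passageway cells carry a higher open-state weight than the interior
  g <- run$grids$concourse
  pw <- metropm:::portal_cells(g, "pw_A")
  interior <- metropm:::grid_index(g, 45, 10)
  w_open <- blend$weights$concourse$OPEN
  expect_gt(mean(w_open[pw]), w_open[interior[1], interior[2]])
  # interior open weight sits near the dwell fraction
  expect_lt(w_open[interior[1], interior[2]], 0.3)
  # platform: cells at a PSD side weight that side's open state higher
  gp <- run$grids$platform
  near_ab <- metropm:::grid_index(gp, 45, 12.6)
  mid <- metropm:::grid_index(gp, 45, 6.4)
  w_ab <- blend$weights$platform$AB_OPEN
  expect_gt(w_ab[near_ab[1], near_ab[2]], w_ab[mid[1], mid[2]])
  expect_error(default_blend(run$geometry, run$grids, run$fields,
                             dwell_s = 360, headway_s = 360), "dwell")
})

test_that("synthesized readings reduce to hand arithmetic in special cases", {
  run <- shared_run()
  # all states equal c*: blend returns c* regardless of weights (sd = 0)
  fields_const <- run$fields
  for (fl in names(fields_const))
    for (s in names(fields_const[[fl]]))
      fields_const[[fl]][[s]]$values[] <- 46.6
  blend0 <- default_blend(run$geometry, run$grids, run$fields, noise_sd = 0)
  v <- synthesize_measured(fields_const, blend0, 45, 10, "concourse")
  expect_equal(v, 46.6, tolerance = 1e-9)
  # w = (1, 0): returns the first state's value after quantization
  blend1 <- blend0
  blend1$weights$concourse$CLOSED[] <- 1
  blend1$weights$concourse$OPEN[] <- 0
  g <- run$grids$concourse
  ij <- metropm:::grid_index(g, 30, 10)
  truth <- run$fields$concourse$CLOSED$values[ij[1], ij[2]]
  expect_equal(synthesize_measured(run$fields, blend1, 30, 10, "concourse"),
               round(truth, 1), tolerance = 1e-9)
  # w = (0.5, 0.5) on states (40, 60) -> 50
  fields_ab <- run$fields
  fields_ab$concourse$CLOSED$values[] <- 40
  fields_ab$concourse$OPEN$values[] <- 60
  blend5 <- blend0
  blend5$weights$concourse$CLOSED[] <- 0.5
  blend5$weights$concourse$OPEN[] <- 0.5
  expect_equal(synthesize_measured(fields_ab, blend5, 30, 10, "concourse"), 50)
  # missing state field errors
  broken <- run$fields
  broken$concourse$OPEN <- NULL
  expect_error(synthesize_measured(broken, blend0, 30, 10, "concourse"),
               "missing state")
})

test_that("zero-noise synthesis is a convex combination of the state fields", {
  run <- shared_run()
  blend0 <- default_blend(run$geometry, run$grids, run$fields, noise_sd = 0)
  set.seed(42)
  pts <- cbind(runif(50, 1, 89), runif(50, 1, 19))
  g <- run$grids$concourse
  for (k in seq_len(nrow(pts))) {
    v <- synthesize_measured(run$fields, blend0, pts[k, 1], pts[k, 2],
                             "concourse")
    ij <- metropm:::grid_index(g, pts[k, 1], pts[k, 2])
    lo <- min(run$fields$concourse$CLOSED$values[ij[1], ij[2]],
              run$fields$concourse$OPEN$values[ij[1], ij[2]])
    hi <- max(run$fields$concourse$CLOSED$values[ij[1], ij[2]],
              run$fields$concourse$OPEN$values[ij[1], ij[2]])
    expect_gte(v, lo - 0.05 - 1e-9)  # half a quantization step
    expect_lte(v, hi + 0.05 + 1e-9)
  }
})

test_that("sample tables carry per-floor input columns and CLT-scale noise", {
  run <- shared_run()
  expect_equal(sim_cols <- grep("^sim_", names(run$tables$concourse), value = TRUE),
               c("sim_closed", "sim_open"))
  expect_equal(grep("^sim_", names(run$tables$platform), value = TRUE),
               c("sim_closed", "sim_ab_open", "sim_cd_open"))
  expect_true(all(run$tables$concourse$measured >= 0))
  # sd = 0: the table equals a single-draw synthesis
  blend0 <- default_blend(run$geometry, run$grids, run$fields, noise_sd = 0)
  t1 <- synthesize_sample_table(run$plan, run$fields, blend0, n_draws = 1)
  t2 <- synthesize_sample_table(run$plan, run$fields, blend0, n_draws = 17)
  expect_equal(t1$concourse$measured, t2$concourse$measured, tolerance = 1e-9)
  # sd = 0.05: spread of repeated 600-draw means matches the CLT scale
  p1 <- run$plan[run$plan$floor == "concourse", ][1, ]
  reps <- replicate(40, {
    mean(synthesize_measured(run$fields, run$blend, p1$x_m, p1$y_m,
                             "concourse", n = 600))
  })
  v <- mean(reps)
  se_expected <- v * 0.05 / sqrt(600)
  expect_gt(sd(reps), se_expected / 2)
  expect_lt(sd(reps), se_expected * 2)
})

test_that("mobile curves align with trajectories and integrate consistently", {
  run <- shared_run()
  blend0 <- default_blend(run$geometry, run$grids, run$fields, noise_sd = 0)
  id <- run$cohort$results$ped_id[1]
  tr <- run$sim$trajectories[run$sim$trajectories$ped_id == id, ]
  curve <- synthesize_mobile_curve(tr, run$fields, blend0)
  expect_equal(nrow(curve), nrow(tr))          # one reading per second
  expect_equal(curve$t_s, tr$t)
  # constant-position trajectory at sd = 0 gives a constant series
  still <- data.frame(ped_id = 9L, direction = "boarding", t = 0:30,
                      floor = "concourse", x = 45, y = 10)
  cs <- synthesize_mobile_curve(still, run$fields, blend0)
  expect_equal(length(unique(cs$conc_ugm3)), 1)
  # integrating the sd = 0 curve equals integrating the blended truth
  truth <- metropm:::blended_truth(run$fields, blend0, "concourse")
  g <- run$grids$concourse
  trc <- tr[tr$floor == "concourse", ]
  ij <- metropm:::grid_index(g, trc$x, trc$y)
  E_truth <- sum(truth[(ij[, 2] - 1) * g$nrow + ij[, 1]])
  E_curve <- sum(curve$conc_ugm3[tr$floor == "concourse"])
  expect_lt(abs(E_curve - E_truth), 0.051 * nrow(trc))  # quantization bound
})
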