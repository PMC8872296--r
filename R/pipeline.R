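#' Run the full synthetic exposure study
#'
#' One-call orchestration of every stage: pedestrian simulation, density and
#' source derivation, per-state concentration fields, measurement-point
#' design, synthetic sampling, surrogate training, cohort exposure
#' integration, a mobile-sampling validation cohort, the microenvironment
#' averaging method, and the method comparison. All randomness derives from
#' `seed`; two runs with the same arguments give identical results.
#'
#' @param seed master integer seed.
#' @param out_dir optional directory for artifacts (CSV/JSON); created if
#'   needed. `NULL` writes nothing.
#' @param config optional path to a station config (see
#'   [read_station_config()]); default is the bundled station.
#' @param cell_size solver grid spacing, m.
#' @param duration simulated span, s.
#' @param n_sample pedestrians integrated per direction.
#' @param n_mobile mobile validation curves per direction.
#' @param demand,service,blend_args,diffusivity stage parameters (see
#'   [demand_spec()], [service_spec()], [default_blend()],
#'   [solve_station_fields()]).
#' @param swarm,iters PSO controls for surrogate tuning.
#' @param quiet suppress per-stage messages.
#' @return A list with all stage outputs: `sim`, `sources`, `fields`,
#'   `plan`, `blend`, `tables`, `bank`, `map`, `cohort`, `mobile`,
#'   `average`, `report`, `headline`, `residence`, `manifest`.
#' @export
run_full <- function(seed = 1, out_dir = NULL, config = NULL,
                     cell_size = 0.8, duration = 1080,
                     n_sample = 50, n_mobile = 20,
                     demand = demand_spec(), service = service_spec(),
                     blend_args = list(), diffusivity = 0.1,
                     swarm = 12, iters = 15, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  if (!is.null(config)) {
    cfg <- read_station_config(config)
    geometry <- cfg$geometry; bc <- cfg$bc
  } else {
    geometry <- build_default_station(); bc <- boundary_conditions()
  }
  grids <- rasterize(geometry, cell_size)

  say("stage 1/7: pedestrian flow (%d s span)", duration)
  sim <- simulate_trajectories(demand, geometry, route_cost_weights(),
                               speed_model(), duration, seed = seed + 1,
                               service = service)

  say("stage 2/7: density and particulate sources")
  window <- c(duration / 4, duration)  # skip the fill-in transient
  sources <- do.call(rbind, lapply(grids, function(g)
    derive_sources(density_map(sim$trajectories, g, window), bc)))

  say("stage 3/7: per-state concentration fields")
  fields <- solve_station_fields(geometry, grids, bc, sources,
                                 diffusivity = diffusivity)

  say("stage 4/7: sampling design and synthetic measurement")
  plan <- design_station_samples(geometry, seed = seed + 2)
  blend <- do.call(default_blend, c(list(geometry = geometry, grids = grids,
                                         fields = fields,
                                         headway_s = demand$headway_s,
                                         dwell_s = service$dwell_s),
                                    blend_args))
  set.seed(seed + 3)
  tables <- synthesize_sample_table(plan, fields, blend)

  say("stage 5/7: surrogate bank (K-means + PSO-tuned SVR)")
  bank <- build_surrogate_bank(tables, seed = seed + 4,
                               swarm = swarm, iters = iters)
  map <- build_region_map(grids, plan,
                          labels = bank$labels)

  say("stage 6/7: exposure integration (%d per direction)", n_sample)
  cohort <- cohort_exposure(sim, bank, map, fields, n_sample, seed = seed + 5)

  say("stage 7/7: validation cohort and method comparison")
  ag <- sim$agents[sim$agents$completed, ]
  set.seed(seed + 6)
  mobile_ids <- unlist(lapply(split(ag$ped_id, ag$direction), function(ids)
    sample(ids, min(n_mobile, length(ids)))))
  truth <- list(concourse = blended_truth(fields, blend, "concourse"),
                platform = blended_truth(fields, blend, "platform"))
  mobile <- lapply(mobile_ids, function(id) {
    tr <- sim$trajectories[sim$trajectories$ped_id == id, ]
    curve <- synthesize_mobile_curve(tr, fields, blend)
    data.frame(ped_id = id, direction = tr$direction[1],
               E = sum(curve$conc_ugm3), time_s = nrow(curve))
  })
  mobile <- do.call(rbind, mobile)
  measured_ref <- tapply(mobile$E, mobile$direction, mean)

  # averaging method: state-mean concentration per floor, cohort mean times
  avg_conc <- vapply(fields, function(ff)
    mean(vapply(ff, floor_mean, numeric(1))), numeric(1))
  cs <- cohort$summary
  avg_E <- setNames(vapply(cs$direction, function(d) {
    r <- cs[cs$direction == d, ]
    average_method(avg_conc,
                   c(concourse = r$mean_t_concourse,
                     platform = r$mean_t_platform))$E_total
  }, numeric(1)), cs$direction)
  int_E <- setNames(cs$mean_E, cs$direction)
  report <- compare_methods(measured_ref[names(int_E)], int_E, avg_E)

  # headline property: per-pedestrian error of each method against the
  # noise-free blended truth
  head_res <- lapply(split(cohort$results, cohort$results$ped_id), function(r) {
    tr <- sim$trajectories[sim$trajectories$ped_id == r$ped_id, ]
    E_truth <- 0
    for (fl in unique(tr$floor)) {
      ix <- tr$floor == fl
      g <- grids[[fl]]
      ij <- grid_index(g, tr$x[ix], tr$y[ix])
      E_truth <- E_truth + sum(truth[[fl]][(ij[, 2] - 1L) * g$nrow + ij[, 1]])
    }
    E_avg <- average_method(avg_conc,
                            c(concourse = r$t_concourse,
                              platform = r$t_platform))$E_total
    data.frame(ped_id = r$ped_id, direction = r$direction,
               E_truth = E_truth, E_integration = r$E_total, E_average = E_avg,
               int_wins = abs(r$E_total - E_truth) <= abs(E_avg - E_truth))
  })
  head_res <- do.call(rbind, head_res)
  headline <- list(results = head_res,
                   win_fraction = mean(head_res$int_wins))

  residence <- residence_stats(sim)
  manifest <- list(seed = seed, cell_size = cell_size, duration = duration,
                   n_sample = n_sample, n_mobile = n_mobile,
                   package_version = as.character(utils::packageVersion("metropm")),
                   elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))

  out <- list(geometry = geometry, bc = bc, grids = grids, sim = sim,
              sources = sources, fields = fields, plan = plan, blend = blend,
              tables = tables, bank = bank, map = map, cohort = cohort,
              mobile = mobile, measured_ref = measured_ref,
              average_E = avg_E, report = report, headline = headline,
              residence = residence, manifest = manifest)
  if (!is.null(out_dir)) write_run_artifacts(out, out_dir)
  out
}

# write the text artifacts of a run and a manifest with file hashes
write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    path
  }
  files <- c(
    w(run$sim$trajectories, "trajectories.csv"),
    w(run$sources, "sources.csv"),
    w(as.data.frame(run$plan), "sample_plan.csv"),
    w(run$tables$concourse, "samples_concourse.csv"),
    w(run$tables$platform, "samples_platform.csv"),
    w(run$bank$metrics, "surrogate_metrics.csv"),
    w(run$cohort$results, "cohort_results.csv"),
    w(run$mobile, "mobile_validation.csv"),
    w(run$residence, "residence_stats.csv"),
    w(run$report$table, "comparison.csv"))
  jsonlite::write_json(
    list(manifest = run$manifest,
         error_ratio = as.list(run$report$error_ratio),
         headline_win_fraction = run$headline$win_fraction,
         surrogate_test_r2 = as.list(setNames(run$bank$metrics$r2_test,
                                              run$bank$metrics$region)),
         file_md5 = as.list(tools::md5sum(files))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
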