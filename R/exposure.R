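#' Trajectory-integrated exposure (integration method)
#'
#' Implements the 1-s exposure integral \eqn{E = \int_T C(t) dt}: for every
#' trajectory second the per-state simulated concentrations at the current
#' position are fused into one concentration by the surrogate of the region
#' containing the position, that value is taken as the exposure concentration
#' for the second, and the results are accumulated (Delta t = 1 s, no
#' interpolation between seconds).
#'
#' @param trajectory data frame for one pedestrian (`ped_id, direction, t,
#'   floor, x, y`, one row per second).
#' @param bank a [build_surrogate_bank()] (or named list of
#'   `surrogate_model`s).
#' @param map a [build_region_map()].
#' @param fields per-floor, per-state fields ([solve_station_fields()]).
#' @return List of class `exposure_result`: `ped_id`, `direction`, `method`,
#'   `E_total` (ug s/m3), `E_concourse`, `E_platform`, `t_concourse`,
#'   `t_platform` (s), and the per-second `series`.
#' @export
integrate_exposure <- function(trajectory, bank, map, fields) {
  models <- if (inherits(bank, "surrogate_bank")) bank$models else bank
  n <- nrow(trajectory)
  if (!n)
    return(structure(list(ped_id = NA_integer_, direction = NA_character_,
                          method = "integration", E_total = 0,
                          E_concourse = 0, E_platform = 0,
                          t_concourse = 0, t_platform = 0,
                          series = numeric(0)),
                     class = "exposure_result"))
  conc <- numeric(n)
  for (fl in unique(trajectory$floor)) {
    ix <- which(trajectory$floor == fl)
    grid <- map$grids[[fl]]
    ij <- grid_index(grid, trajectory$x[ix], trajectory$y[ix])
    l <- (ij[, 2] - 1L) * grid$nrow + ij[, 1]
    sims <- vapply(fields[[fl]], function(f) f$values[l], numeric(length(l)))
    sims <- matrix(sims, nrow = length(l))
    regs <- region_at(map, trajectory$x[ix], trajectory$y[ix], fl)
    for (r in unique(regs)) {
      model <- models[[r]]
      if (is.null(model)) stop("unlabeled region: ", r)
      sel <- regs == r
      if (ncol(sims) != model$d)
        stop("state count ", ncol(sims), " does not match region ", r)
      conc[ix[sel]] <- pmax(0, predict(model, sims[sel, , drop = FALSE]))
    }
  }
  on_c <- trajectory$floor == "concourse"
  structure(list(ped_id = trajectory$ped_id[1],
                 direction = trajectory$direction[1] %||% NA_character_,
                 method = "integration",
                 E_total = sum(conc),
                 E_concourse = sum(conc[on_c]),
                 E_platform = sum(conc[!on_c]),
                 t_concourse = sum(on_c), t_platform = sum(!on_c),
                 series = conc),
            class = "exposure_result")
}

#' Microenvironment average-concentration exposure (averaging method)
#'
#' Implements \eqn{E = \sum_i avg(C_i) T_i}: one average concentration per
#' microenvironment (concourse, platform; passageways count as concourse)
#' multiplied by the residence time in it.
#'
#' @param mean_conc_by_env named numeric vector, ug/m3.
#' @param residence_by_env named numeric vector, s; names must match
#'   `mean_conc_by_env`.
#' @return An `exposure_result` (method `"average"`).
#' @examples
#' average_method(c(concourse = 53.2), c(concourse = 104.84))$E_total  # 5577.5
#' @export
average_method <- function(mean_conc_by_env, residence_by_env) {
  if (!setequal(names(mean_conc_by_env), names(residence_by_env)))
    stop("microenvironment keys differ between concentrations and times")
  residence_by_env <- residence_by_env[names(mean_conc_by_env)]
  E <- mean_conc_by_env * residence_by_env
  structure(list(ped_id = NA_integer_, direction = NA_character_,
                 method = "average",
                 E_total = sum(E),
                 E_concourse = sum(E[names(E) == "concourse"]),
                 E_platform = sum(E[names(E) == "platform"]),
                 t_concourse = sum(residence_by_env[names(E) == "concourse"]),
                 t_platform = sum(residence_by_env[names(E) == "platform"]),
                 by_env = E),
            class = "exposure_result")
}

#' Relative error in percent
#'
#' @param calculated calculated value(s).
#' @param measured reference value(s); must be positive.
#' @return `|calculated - measured| / measured * 100`.
#' @examples
#' relative_error(9985.74, 10601.3)  # 5.80
#' @export
relative_error <- function(calculated, measured) {
  if (any(measured <= 0)) stop("measured reference must be positive")
  abs(calculated - measured) / measured * 100
}

#' Cohort exposure summary
#'
#' Randomly samples `n_sample` completed pedestrians per direction and
#' integrates each one's exposure with the surrogate bank.
#'
#' @param sim a `ped_sim` from [simulate_trajectories()].
#' @param bank,map,fields as in [integrate_exposure()].
#' @param n_sample pedestrians per direction; default 50.
#' @param seed integer seed for the sampling.
#' @return List of class `cohort_exposure`: `results` (per-pedestrian data
#'   frame) and `summary` (per-direction mean/sd of E and mean per-floor
#'   decomposition).
#' @export
cohort_exposure <- function(sim, bank, map, fields, n_sample = 50, seed = 1) {
  ag <- sim$agents[sim$agents$completed, , drop = FALSE]
  set.seed(seed)
  picked <- unlist(lapply(split(ag$ped_id, ag$direction), function(ids) {
    if (length(ids) < n_sample)
      stop("fewer than ", n_sample, " completed trajectories in a direction")
    sample(ids, n_sample)
  }))
  tr <- sim$trajectories[sim$trajectories$ped_id %in% picked, , drop = FALSE]
  res <- lapply(split(tr, tr$ped_id), integrate_exposure,
                bank = bank, map = map, fields = fields)
  results <- do.call(rbind, lapply(res, function(r)
    data.frame(ped_id = r$ped_id, direction = r$direction,
               E_total = r$E_total, E_concourse = r$E_concourse,
               E_platform = r$E_platform, t_concourse = r$t_concourse,
               t_platform = r$t_platform)))
  summ <- do.call(rbind, lapply(split(results, results$direction), function(d)
    data.frame(direction = d$direction[1], n = nrow(d),
               mean_E = mean(d$E_total), sd_E = sd(d$E_total),
               mean_E_concourse = mean(d$E_concourse),
               mean_E_platform = mean(d$E_platform),
               mean_t_concourse = mean(d$t_concourse),
               mean_t_platform = mean(d$t_platform))))
  rownames(results) <- rownames(summ) <- NULL
  structure(list(results = results, summary = summ, n_sample = n_sample),
            class = "cohort_exposure")
}

#' Compare the integration and averaging methods against a reference
#'
#' Relative errors of each method per direction, and the error ratio
#' (averaging error divided by integration error).
#'
#' @param measured_ref named vector (`boarding`, `alighting`) of reference
#'   exposures, ug s/m3.
#' @param integration_results,average_results named vectors of calculated
#'   exposures, same names.
#' @return List of class `comparison_report`: `table` (exposures and errors)
#'   and `error_ratio` per direction.
#' @examples
#' compare_methods(c(boarding = 10601.3, alighting = 6057.8),
#'                 c(boarding = 9985.7, alighting = 5761.5),
#'                 c(boarding = 8954.8, alighting = 5373.1))
#' @export
compare_methods <- function(measured_ref, integration_results,
                            average_results) {
  dirs <- names(measured_ref)
  if (!setequal(dirs, names(integration_results)) ||
      !setequal(dirs, names(average_results)))
    stop("all three inputs must cover the same directions")
  integration_results <- integration_results[dirs]
  average_results <- average_results[dirs]
  err_int <- relative_error(integration_results, measured_ref)
  err_avg <- relative_error(average_results, measured_ref)
  tab <- data.frame(direction = dirs,
                    measured = as.numeric(measured_ref),
                    integration = as.numeric(integration_results),
                    average = as.numeric(average_results),
                    err_integration_pct = as.numeric(err_int),
                    err_average_pct = as.numeric(err_avg))
  structure(list(table = tab,
                 error_ratio = setNames(as.numeric(err_avg / err_int), dirs)),
            class = "comparison_report")
}

#' @method print comparison_report
#' @export
print.comparison_report <- function(x, ...) {
  cat("Exposure comparison (ug s/m3; errors vs measured reference)\n")
  print(format(x$table, digits = 5), row.names = FALSE)
  cat("error ratio (average / integration):",
      paste(sprintf("%s %.2f", names(x$error_ratio), x$error_ratio),
            collapse = ", "), "\n")
  invisible(x)
}
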