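#' Time-averaged pedestrian density map
#'
#' Per grid cell, person-seconds spent in the cell during the window divided
#' by window length and cell area: the average number of pedestrians per unit
#' time and unit area, persons/m2.
#'
#' @param trajectories trajectory data frame (`ped_id, t, floor, x, y`), e.g.
#'   `sim$trajectories` from [simulate_trajectories()].
#' @param grid a `grid2d` from [rasterize()]; only rows on its floor count.
#' @param window numeric `c(t0, t1)`, seconds; half-open `[t0, t1)`, must be
#'   non-empty.
#' @return An object of class `density_field`: list with `grid`, `values`
#'   (matrix, persons/m2) and `window`.
#' @export
density_map <- function(trajectories, grid, window) {
  stopifnot(inherits(grid, "grid2d"), length(window) == 2L)
  if (window[2] <= window[1]) stop("empty density window")
  tr <- trajectories[trajectories$floor == grid$floor &
                       trajectories$t >= window[1] &
                       trajectories$t < window[2], , drop = FALSE]
  vals <- matrix(0, grid$nrow, grid$ncol)
  if (nrow(tr)) {
    ij <- grid_index(grid, tr$x, tr$y)
    tab <- table(factor((ij[, 2] - 1L) * grid$nrow + ij[, 1],
                        levels = seq_len(grid$nrow * grid$ncol)))
    vals[] <- as.numeric(tab)
  }
  vals <- vals / (diff(window) * grid$cell^2)
  structure(list(grid = grid, values = vals, window = window),
            class = "density_field")
}

#' Pedestrian level of service from density
#'
#' Letter grade per the waiting level-of-service table used for transit
#' spaces: A for densities up to 0.370 persons/m2, then B (<= 0.435),
#' C (<= 0.526), D (<= 0.667), E (<= 1) and F above 1. Upper bounds are
#' closed.
#'
#' @param density persons/m2; vectorized; must be non-negative.
#' @return Character vector of levels `"A"`-`"F"`.
#' @examples
#' service_level(c(0.370, 0.5, 1.2))  # "A" "C" "F"
#' @export
service_level <- function(density) {
  if (any(density < 0)) stop("density must be non-negative")
  br <- c(-Inf, 0.370, 0.435, 0.526, 0.667, 1, Inf)
  as.character(cut(density, br, labels = LETTERS[1:6], right = TRUE))
}

# lower density bound of each service level (exclusive)
.level_lower <- c(A = -Inf, B = 0.370, C = 0.435, D = 0.526, E = 0.667, F = 1)

#' Derive pedestrian particulate sources from a density map
#'
#' Connected regions (4-neighbour) whose density is at or worse than the
#' given service level become point sources at the region centroid; the
#' source strength is the mean person count present in the region times the
#' per-person generation rate.
#'
#' @param density a `density_field` from [density_map()].
#' @param bc a [boundary_conditions()]; supplies `r_per` (mg/(person h)).
#'   A warning is issued when `r_per` falls outside the literature range of
#'   6.5-15.2 mg/h for a person in an enclosed space.
#' @param level_threshold worst acceptable level; cells strictly denser than
#'   its lower bound are source candidates. Default `"C"`.
#' @return Data frame `x_m, y_m, floor, persons, rate_mg_per_h` (possibly
#'   empty).
#' @export
derive_sources <- function(density, bc = boundary_conditions(),
                           level_threshold = "C") {
  stopifnot(inherits(density, "density_field"))
  if (!level_threshold %in% names(.level_lower))
    stop("unknown service level: ", level_threshold)
  if (bc$r_per < 6.5 || bc$r_per > 15.2)
    warning("per-person generation rate ", bc$r_per,
            " mg/h outside the reported 6.5-15.2 mg/h range")
  g <- density$grid
  hot <- density$values > .level_lower[[level_threshold]]
  lab <- matrix(0L, g$nrow, g$ncol)
  comp <- 0L
  for (start in which(hot)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    stack <- start
    while (length(stack)) {
      c0 <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[c0] != 0L) next
      lab[c0] <- comp
      i <- (c0 - 1L) %% g$nrow + 1L
      j <- (c0 - 1L) %/% g$nrow + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] < 1L || nb[1] > g$nrow || nb[2] < 1L || nb[2] > g$ncol) next
        l <- (nb[2] - 1L) * g$nrow + nb[1]
        if (hot[l] && lab[l] == 0L) stack <- c(stack, l)
      }
    }
  }
  if (comp == 0L)
    return(data.frame(x_m = numeric(), y_m = numeric(), floor = character(),
                      persons = numeric(), rate_mg_per_h = numeric()))
  out <- lapply(seq_len(comp), function(cc) {
    cells <- which(lab == cc)
    i <- (cells - 1L) %% g$nrow + 1L
    j <- (cells - 1L) %/% g$nrow + 1L
    ctr <- cell_center(g, i, j)
    persons <- sum(density$values[cells]) * g$cell^2
    data.frame(x_m = mean(ctr[, 1]), y_m = mean(ctr[, 2]), floor = g$floor,
               persons = persons, rate_mg_per_h = persons * bc$r_per)
  })
  do.call(rbind, out)
}
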