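#' Optimal (maximin) Latin hypercube sample
#'
#' Centred Latin hypercube design: each axis is cut into `n` equal strata and
#' each stratum holds exactly one point (at its centre), so the design fills
#' the range of every coordinate. The initial random permutation is improved
#' by random within-column swaps, accepting only swaps that increase the
#' minimum pairwise Euclidean distance (maximin criterion); the score is
#' therefore non-decreasing over iterations.
#'
#' @param n number of points, >= 1.
#' @param bounds 2 x d matrix (rows: lower, upper) or list with `lower`,
#'   `upper`; bounds must be non-degenerate.
#' @param iterations swap iterations; default 200.
#' @param seed integer seed; the design is deterministic per seed.
#' @return Matrix `n x d` of points, with attributes `maximin` (the achieved
#'   minimum pairwise distance) and `score_trace`.
#' @examples
#' olhs(1, rbind(c(0, 0), c(1, 1)))  # the domain centre
#' @export
olhs <- function(n, bounds, iterations = 200, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (is.list(bounds)) bounds <- rbind(bounds$lower, bounds$upper)
  d <- ncol(bounds)
  if (any(bounds[2, ] <= bounds[1, ])) stop("degenerate bounds")
  set.seed(seed)
  # one point per stratum, at stratum centres, in [0,1]^d
  U <- vapply(seq_len(d), function(k) (sample.int(n) - 0.5) / n, numeric(n))
  U <- matrix(U, n, d)
  score <- function(U) if (n < 2) Inf else min(dist(U))
  s <- score(U)
  trace <- s
  if (n >= 2) {
    for (it in seq_len(iterations)) {
      k <- sample.int(d, 1)
      ij <- sample.int(n, 2)
      U2 <- U
      U2[ij, k] <- U2[rev(ij), k]
      s2 <- score(U2)
      if (s2 > s) { U <- U2; s <- s2 }
      trace <- c(trace, s)
    }
  }
  pts <- sweep(sweep(U, 2, bounds[2, ] - bounds[1, ], "*"), 2, bounds[1, ], "+")
  attr(pts, "maximin") <- s
  attr(pts, "score_trace") <- trace
  pts
}

#' Station measurement-point plan
#'
#' Reproduces the structure of the sampling campaign: each floor is split
#' into two lengthwise halves with an independent maximin Latin hypercube of
#' `n_half` points per half, plus `n_passageway` points in each of the four
#' concourse passageways. An exclusion step then drops the points closest to
#' station infrastructure (gates, security, ticket/vending machines, stairs,
#' PSD segments) until the per-floor target counts are met, standing in for
#' points that are impractical to occupy with an instrument; by default this
#' yields 47 concourse and 29 platform points.
#'
#' @param geometry a [station_geometry()].
#' @param n_half Latin hypercube points per lengthwise half; default 20.
#' @param n_passageway points per passageway; default 3.
#' @param target named vector of retained points per floor; default
#'   `c(concourse = 47, platform = 29)`. Use `NA` to keep all raw points.
#' @param margin inset from the floor boundary, m.
#' @param seed integer seed.
#' @return Data frame of class `sample_plan`: `point_id, floor, zone, x_m,
#'   y_m`.
#' @export
design_station_samples <- function(geometry = build_default_station(),
                                   n_half = 20, n_passageway = 3,
                                   target = c(concourse = 47, platform = 29),
                                   margin = 0.5, seed = 1) {
  pts <- list()
  sub_seed <- function(k) seed * 101 + k
  k <- 0
  for (fl in c("concourse", "platform")) {
    f <- geometry$floors[[fl]]
    halves <- list(c(margin, f$length / 2), c(f$length / 2, f$length - margin))
    for (hh in 1:2) {
      k <- k + 1
      b <- rbind(c(halves[[hh]][1], margin), c(halves[[hh]][2], f$width - margin))
      p <- olhs(n_half, b, seed = sub_seed(k))
      pts[[length(pts) + 1L]] <- data.frame(
        floor = fl, zone = sprintf("half-%d", hh), x_m = p[, 1], y_m = p[, 2])
    }
  }
  pw <- geometry$portals[geometry$portals$role == "passageway", ]
  for (r in seq_len(nrow(pw))) {
    k <- k + 1
    b <- rbind(c(pw$xmin[r] + 0.2, pw$ymin[r] + 0.2),
               c(pw$xmax[r] - 0.2, pw$ymax[r] - 0.2))
    p <- olhs(n_passageway, b, seed = sub_seed(k))
    pts[[length(pts) + 1L]] <- data.frame(
      floor = pw$floor[r], zone = paste0("passageway-", sub("pw_", "", pw$id[r])),
      x_m = p[, 1], y_m = p[, 2])
  }
  plan <- do.call(rbind, pts)

  # exclusion: drop points nearest to infrastructure footprints until the
  # per-floor targets are met
  infra_roles <- c("gate_in", "gate_out", "security", "ticket", "vending",
                   "stair", "escalator", "psd_ab", "psd_cd")
  infra <- geometry$portals[geometry$portals$role %in% infra_roles, ]
  rect_dist <- function(x, y, r)
    sqrt(pmax(0, pmax(r$xmin - x, x - r$xmax))^2 +
         pmax(0, pmax(r$ymin - y, y - r$ymax))^2)
  keep <- rep(TRUE, nrow(plan))
  for (fl in names(target)) {
    tgt <- target[[fl]]
    if (is.na(tgt)) next
    idx <- which(plan$floor == fl)
    if (length(idx) < tgt)
      stop("requested ", tgt, " points on ", fl, " but only ",
           length(idx), " candidates")
    infra_f <- infra[infra$floor == fl, ]
    dmin <- rep(Inf, length(idx))
    for (r in seq_len(nrow(infra_f)))
      dmin <- pmin(dmin, rect_dist(plan$x_m[idx], plan$y_m[idx], infra_f[r, ]))
    drop_n <- length(idx) - tgt
    if (drop_n > 0) keep[idx[order(dmin)[seq_len(drop_n)]]] <- FALSE
  }
  plan <- plan[keep, , drop = FALSE]
  plan <- data.frame(point_id = seq_len(nrow(plan)), plan, row.names = NULL)
  class(plan) <- c("sample_plan", "data.frame")
  plan
}
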