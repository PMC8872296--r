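#' Pedestrian walking-speed model
#'
#' Free walking speeds are drawn from a truncated normal distribution. The
#' default mean is 1.25 m/s with a spread parameter of 0.2, interpreted as a
#' standard deviation (0.2 m/s); a literal-variance reading (sd = sqrt(0.2),
#' about 0.45 m/s) is implausibly wide for station walking but is available
#' via `spread_is = "variance"`.
#'
#' @param mean mean free speed, m/s; must be positive.
#' @param spread spread parameter (see `spread_is`).
#' @param spread_is `"sd"` (default) or `"variance"`.
#' @param bounds truncation bounds, m/s.
#' @return An object of class `speed_model`.
#' @export
speed_model <- function(mean = 1.25, spread = 0.2, spread_is = c("sd", "variance"),
                        bounds = c(0.3, 2.5)) {
  spread_is <- match.arg(spread_is)
  if (!is.numeric(mean) || mean <= 0) stop("mean speed must be positive")
  if (spread < 0) stop("spread must be non-negative")
  sd <- if (spread_is == "sd") spread else sqrt(spread)
  stopifnot(length(bounds) == 2L, bounds[1] > 0, bounds[2] > bounds[1])
  structure(list(mean = mean, sd = sd, bounds = bounds), class = "speed_model")
}

#' Draw pedestrian walking speeds
#'
#' Inverse-CDF sampling from the truncated normal of a [speed_model()]; with
#' zero spread every draw equals the mean.
#'
#' @param model a [speed_model()].
#' @param n number of draws.
#' @return Numeric vector of speeds, m/s, all positive.
#' @export
sample_speed <- function(model, n = 1) {
  stopifnot(inherits(model, "speed_model"))
  if (model$sd == 0) return(rep(model$mean, n))
  lo <- stats::pnorm(model$bounds[1], model$mean, model$sd)
  hi <- stats::pnorm(model$bounds[2], model$mean, model$sd)
  stats::qnorm(runif(n, lo, hi), model$mean, model$sd)
}

#' Route-cost weights
#'
#' Weights of the perceived route cost
#' \eqn{Cost = W_D (D_G / V) + W_q Q + W_L L}: distance term (time to walk the
#' remaining distance), expected queueing time, and a geometric component cost
#' (stairs vs escalator). All weights default to 1.
#'
#' @param W_D,W_q,W_L non-negative weights.
#' @return An object of class `route_cost_weights`.
#' @export
route_cost_weights <- function(W_D = 1, W_q = 1, W_L = 1) {
  w <- c(W_D = W_D, W_q = W_q, W_L = W_L)
  if (any(w < 0)) stop("route-cost weights must be non-negative")
  structure(as.list(w), class = "route_cost_weights")
}

#' Perceived route cost
#'
#' @param distance_to_goal remaining distance D_G, m.
#' @param speed walking speed V, m/s; must be positive.
#' @param queue_time expected queueing time Q, s.
#' @param component_cost geometric component cost L, s.
#' @param weights a [route_cost_weights()].
#' @return Cost in seconds.
#' @examples
#' route_cost(50, 1.25, 30, 10)  # 40 + 30 + 10 = 80 s
#' @export
route_cost <- function(distance_to_goal, speed, queue_time, component_cost,
                       weights = route_cost_weights()) {
  if (any(speed <= 0)) stop("speed must be positive")
  if (any(c(distance_to_goal, queue_time, component_cost) < 0))
    stop("route-cost inputs must be non-negative")
  weights$W_D * (distance_to_goal / speed) +
    weights$W_q * queue_time +
    weights$W_L * component_cost
}

#' Passenger demand specification
#'
#' Off-peak hourly demand for the bundled station: per-train boarding and
#' alighting counts by direction (upward trains serve the CD side of the
#' island platform, downward trains the AB side), the share of passengers
#' entering on a stored-value card versus buying a ticket, the exit-choice
#' ratio and the train headway.
#'
#' @param boarding_up,boarding_down,alighting_up,alighting_down passengers per
#'   hour by direction.
#' @param card_fraction share entering directly with a card (the rest visit a
#'   ticket machine first).
#' @param exit_ratio named relative weights for exits A-D.
#' @param headway_s interval between trains of one direction, s.
#' @return An object of class `demand_spec`.
#' @export
demand_spec <- function(boarding_up = 2143, boarding_down = 789,
                        alighting_up = 951, alighting_down = 918,
                        card_fraction = 0.80,
                        exit_ratio = c(A = 3.5, B = 2, C = 1, D = 3.5),
                        headway_s = 360) {
  counts <- c(boarding_up, boarding_down, alighting_up, alighting_down)
  if (any(counts < 0)) stop("demand counts must be non-negative")
  if (card_fraction < 0 || card_fraction > 1)
    stop("card_fraction must lie in [0, 1]")
  if (any(exit_ratio < 0) || sum(exit_ratio) <= 0) stop("invalid exit ratio")
  structure(list(boarding_up = boarding_up, boarding_down = boarding_down,
                 alighting_up = alighting_up, alighting_down = alighting_down,
                 card_fraction = card_fraction,
                 exit_ratio = exit_ratio / sum(exit_ratio),
                 headway_s = headway_s),
            class = "demand_spec")
}

#' Facility service parameters
#'
#' Server counts and deterministic per-person service times of the queueing
#' facilities, plus the geometric component costs (traversal times, also the
#' L term of the route cost) of stairs and escalators. Defaults were chosen
#' once so that, under the default demand, mean residence times fall near the
#' reference values (157.2 s boarding, 92.3 s alighting).
#'
#' @param security,gate_in,gate_out,ticket lists with `n` servers and
#'   `service` seconds.
#' @param escalator_headway seconds between consecutive riders stepping on.
#' @param L_stair,L_escalator traversal/component costs, s.
#' @param board_rate passengers boarding per second per door.
#' @param dwell_s PSD-open (train dwell) duration per stop, s.
#' @param lead_time boarding passengers aim to reach the platform uniformly
#'   within this many seconds (range) before their train's arrival
#'   (timetable-aware arrivals; off-peak passengers know the headway).
#' @param queue_allowance extra seconds passengers budget for queues when
#'   predicting their own concourse transit time.
#' @return An object of class `service_spec`.
#' @export
service_spec <- function(security = list(n = 4, service = 2),
                         gate_in = list(n = 4, service = 2),
                         gate_out = list(n = 4, service = 2),
                         ticket = list(n = 4, service = 15),
                         escalator_headway = 1,
                         L_stair = 25, L_escalator = 18,
                         board_rate = 2, dwell_s = 30,
                         lead_time = c(5, 75), queue_allowance = 15) {
  structure(list(security = security, gate_in = gate_in, gate_out = gate_out,
                 ticket = ticket, escalator_headway = escalator_headway,
                 L_stair = L_stair, L_escalator = L_escalator,
                 board_rate = board_rate, dwell_s = dwell_s,
                 lead_time = lead_time, queue_allowance = queue_allowance),
            class = "service_spec")
}

# FIFO multi-server queue: serve in arrival order, earliest-free server.
# Returns start/depart/wait vectors aligned with `arrivals`.
serve_fifo <- function(arrivals, n_servers, service) {
  n <- length(arrivals)
  start <- depart <- numeric(n)
  free <- rep(-Inf, n_servers)
  ord <- order(arrivals)
  for (k in ord) {
    s <- which.min(free)
    start[k] <- max(arrivals[k], free[s])
    free[s] <- start[k] + service
    depart[k] <- free[s]
  }
  list(start = start, depart = depart, wait = start - arrivals)
}

# Route choice among parallel server points by perceived cost, then FIFO
# service at the chosen server. Processed in arrival order so no overtaking
# occurs within any one server queue.
choose_and_serve <- function(arrivals, from_xy, server_xy, service, speeds,
                             weights, L = 0) {
  n <- length(arrivals)
  m <- nrow(server_xy)
  free <- rep(-Inf, m)
  choice <- integer(n); start <- depart <- arrive_at <- numeric(n)
  L <- rep_len(L, m)
  ord <- order(arrivals)
  for (k in ord) {
    d <- sqrt((server_xy[, 1] - from_xy[k, 1])^2 +
              (server_xy[, 2] - from_xy[k, 2])^2)
    eta <- arrivals[k] + d / speeds[k]
    q <- pmax(0, free - eta)
    cost <- route_cost(d, speeds[k], q, L, weights)
    g <- which.min(cost)
    choice[k] <- g
    arrive_at[k] <- eta[g]
    start[k] <- max(arrive_at[k], free[g])
    free[g] <- start[k] + service
    depart[k] <- free[g]
  }
  list(choice = choice, arrive = arrive_at, start = start, depart = depart)
}

# sample positions of one agent's node itinerary at whole seconds
trace_nodes <- function(times, xs, ys, floors) {
  t0 <- ceiling(times[1]); t1 <- floor(times[length(times)])
  if (t1 < t0) return(NULL)
  tt <- seq(t0, t1)
  x <- stats::approx(times, xs, tt, ties = "ordered")$y
  y <- stats::approx(times, ys, tt, ties = "ordered")$y
  # floor of the latest node at or before each sampled second
  fl <- floors[findInterval(tt, times, rightmost.closed = TRUE)]
  data.frame(t = tt, floor = fl, x = x, y = y)
}

#' Simulate pedestrian trajectories through the station
#'
#' Stage-based queueing waypoint simulator. Boarding passengers enter at an
#' exit (choice by the demand ratio), buy a ticket if they are not card
#' holders, pass the security checkpoint and an inbound gate (gate chosen by
#' perceived route cost), descend by stairs or escalator (chosen by route
#' cost including the geometric component term), walk to a platform screen
#' door on their train's side and board when the train dwells. Alighting
#' passengers emerge from the doors at train arrival, ascend, pass an
#' outbound gate and leave by an exit. All queues are FIFO with deterministic
#' service times; positions are reported once per second.
#'
#' Boarding entry times are drawn uniformly within `service$arrival_window`
#' seconds before the target train (timetable-aware arrivals); trains of the
#' two directions alternate every half headway.
#'
#' @param demand a [demand_spec()].
#' @param geometry a [station_geometry()].
#' @param weights a [route_cost_weights()].
#' @param speed a [speed_model()].
#' @param duration simulated span, s; must be positive.
#' @param seed integer seed; fully determines the output.
#' @param service a [service_spec()].
#' @return A list of class `ped_sim` with elements `trajectories` (data frame
#'   `ped_id, direction, t, floor, x, y`, one row per second), `agents`
#'   (per-agent metadata incl. entry/exit times and completion flag),
#'   `dropped` (ids not completing within `duration`) and `trains`.
#' @export
simulate_trajectories <- function(demand = demand_spec(),
                                  geometry = build_default_station(),
                                  weights = route_cost_weights(),
                                  speed = speed_model(),
                                  duration = 1080, seed = 1,
                                  service = service_spec()) {
  stopifnot(inherits(demand, "demand_spec"), inherits(geometry, "station_geometry"))
  if (duration <= 0) stop("duration must be positive")
  set.seed(seed)

  hw <- demand$headway_s
  trains_cd <- seq(hw / 3, duration, by = hw)          # upward, CD side
  trains_ab <- seq(hw / 3 + hw / 2, duration, by = hw) # downward, AB side
  if (!length(trains_cd)) trains_cd <- duration
  trains <- rbind(data.frame(side = "CD", time = trains_cd),
                  if (length(trains_ab)) data.frame(side = "AB", time = trains_ab))

  # waypoints (metric coordinates)
  exits <- c("A", "B", "C", "D")
  exit_xy <- t(vapply(exits, function(e) portal_center(geometry, e), numeric(2)))
  ticket_xy <- rbind(portal_center(geometry, "ticket_w"),
                     portal_center(geometry, "ticket_e"))
  sec_xy <- cbind(rep(26, service$security$n),
                  seq(8.7, 11.3, length.out = service$security$n))
  gin_xy <- cbind(rep(37, service$gate_in$n),
                  seq(7, 13, length.out = service$gate_in$n))
  gout_xy <- cbind(rep(55, service$gate_out$n),
                   seq(7, 13, length.out = service$gate_out$n))
  stair_c <- portal_center(geometry, "stair_c")
  esc_c <- portal_center(geometry, "esc_c")
  stair_p <- portal_center(geometry, "stair_p")
  esc_p <- portal_center(geometry, "esc_p")
  psd_x <- c(15, 30, 45, 60, 75, 90)
  door_cd <- cbind(psd_x, 1.5)    # waiting point in front of CD doors
  door_ab <- cbind(psd_x, 11.3)

  # hourly counts spread over the trains serving one hour -> per-train loads
  trains_per_h <- 3600 / hw
  per_train_board <- c(CD = demand$boarding_up, AB = demand$boarding_down) / trains_per_h
  per_train_alight <- c(CD = demand$alighting_up, AB = demand$alighting_down) / trains_per_h

  agents <- list(); traj <- list(); id <- 0L

  ## ---- boarding ----
  b_rows <- list()
  for (side in c("CD", "AB")) {
    tr <- trains$time[trains$side == side]
    # skip trains too early for anyone to reach from the street
    elig <- tr[tr >= 180]
    if (!length(elig)) elig <- tr
    nb <- round(per_train_board[[side]] * length(elig))
    if (nb == 0) next
    target <- elig[1 + (seq_len(nb) - 1L) %% length(elig)]
    b_rows[[side]] <- data.frame(side = side, target = target)
  }
  board <- do.call(rbind, b_rows)
  if (!is.null(board) && nrow(board)) {
    nb <- nrow(board)
    board$ped_id <- seq_len(nb)
    board$exit <- sample(exits, nb, replace = TRUE, prob = demand$exit_ratio)
    board$card <- runif(nb) < demand$card_fraction
    board$speed <- sample_speed(speed, nb)

    # timetable-aware entry: each passenger predicts their own concourse
    # transit (walk legs at their speed, nominal services, a queue allowance)
    # and enters so as to reach the platform `lead_time` seconds early
    sec_pt0 <- colMeans(sec_xy)
    gate_pt0 <- colMeans(gin_xy)
    d_walk <- sqrt(rowSums((exit_xy[board$exit, , drop = FALSE] -
                              matrix(sec_pt0, nb, 2, byrow = TRUE))^2)) +
      sqrt(sum((gate_pt0 - sec_pt0)^2)) +
      sqrt(sum((esc_c - gate_pt0)^2)) + 20
    t_pred <- d_walk / board$speed +
      service$security$service + service$gate_in$service +
      ifelse(board$card, 0, service$ticket$service + 15) +
      service$L_escalator + service$queue_allowance
    lead <- runif(nb, service$lead_time[1], service$lead_time[2])
    board$entry <- pmax(0, board$target - t_pred - lead)

    pos <- exit_xy[board$exit, , drop = FALSE]
    tnow <- board$entry
    nodes <- lapply(seq_len(nb), function(k)
      list(t = tnow[k], x = pos[k, 1], y = pos[k, 2], f = "concourse"))

    walk_to <- function(k, xy, tcur, pcur) {
      d <- sqrt(sum((xy - pcur)^2))
      tcur + d / board$speed[k]
    }
    add_node <- function(nodes, k, t, xy, f = "concourse") {
      nd <- nodes[[k]]
      nodes[[k]] <- list(t = c(nd$t, t), x = c(nd$x, xy[1]),
                         y = c(nd$y, xy[2]), f = c(nd$f, f))
      nodes
    }

    # ticket machines for non-card holders (nearest of the two banks,
    # service$ticket$n machines split across banks, FIFO per bank)
    need <- which(!board$card)
    if (length(need)) {
      bank <- ifelse(pos[need, 1] < geometry$floors$concourse$length / 2, 1L, 2L)
      for (b in 1:2) {
        kk <- need[bank == b]
        if (!length(kk)) next
        arr <- vapply(kk, function(k) walk_to(k, ticket_xy[b, ], tnow[k], pos[k, ]),
                      numeric(1))
        sv <- serve_fifo(arr, max(1L, service$ticket$n %/% 2L), service$ticket$service)
        for (i in seq_along(kk)) {
          k <- kk[i]
          nodes <- add_node(nodes, k, arr[i], ticket_xy[b, ])
          nodes <- add_node(nodes, k, sv$depart[i], ticket_xy[b, ])
          tnow[k] <- sv$depart[i]; pos[k, ] <- ticket_xy[b, ]
        }
      }
    }

    # security checkpoint (bank of identical lanes, FIFO)
    sec_pt <- colMeans(sec_xy)
    arr <- vapply(seq_len(nb), function(k) walk_to(k, sec_pt, tnow[k], pos[k, ]),
                  numeric(1))
    sv <- serve_fifo(arr, service$security$n, service$security$service)
    for (k in seq_len(nb)) {
      nodes <- add_node(nodes, k, arr[k], sec_pt)
      nodes <- add_node(nodes, k, sv$depart[k], sec_pt)
      tnow[k] <- sv$depart[k]; pos[k, ] <- matrix(sec_pt, 1)
    }

    # inbound gates: route-cost choice among channels
    cs <- choose_and_serve(tnow, pos, gin_xy, service$gate_in$service,
                           board$speed, weights)
    for (k in seq_len(nb)) {
      g <- cs$choice[k]
      nodes <- add_node(nodes, k, cs$arrive[k], gin_xy[g, ])
      nodes <- add_node(nodes, k, cs$depart[k], gin_xy[g, ])
      tnow[k] <- cs$depart[k]; pos[k, ] <- gin_xy[g, , drop = FALSE]
    }

    # stairs vs escalator down: route cost with component term; the
    # escalator is a single-file device with a boarding headway.
    esc_free <- -Inf
    dev_choice <- character(nb)
    ord <- order(tnow)
    for (k in ord) {
      d_st <- sqrt(sum((stair_c - pos[k, ])^2))
      d_es <- sqrt(sum((esc_c - pos[k, ])^2))
      eta_es <- tnow[k] + d_es / board$speed[k]
      q_es <- max(0, esc_free - eta_es)
      c_st <- route_cost(d_st, board$speed[k], 0, service$L_stair, weights)
      c_es <- route_cost(d_es, board$speed[k], q_es, service$L_escalator, weights)
      if (c_es <= c_st) {
        dev_choice[k] <- "escalator"
        start <- max(eta_es, esc_free)
        esc_free <- start + service$escalator_headway
        nodes <- add_node(nodes, k, eta_es, esc_c)
        nodes <- add_node(nodes, k, start, esc_c)
        nodes <- add_node(nodes, k, start + service$L_escalator, esc_p, "platform")
        tnow[k] <- start + service$L_escalator
        pos[k, ] <- matrix(esc_p, 1)
      } else {
        dev_choice[k] <- "stair"
        eta <- tnow[k] + d_st / board$speed[k]
        nodes <- add_node(nodes, k, eta, stair_c)
        nodes <- add_node(nodes, k, eta + service$L_stair, stair_p, "platform")
        tnow[k] <- eta + service$L_stair
        pos[k, ] <- matrix(stair_p, 1)
      }
    }

    # walk to a door on the train side, wait, board during the dwell
    doors <- list(CD = door_cd, AB = door_ab)
    door_id <- sample.int(nrow(door_cd), nb, replace = TRUE)
    board_time <- rep(NA_real_, nb)
    for (side in c("CD", "AB")) {
      kk <- which(board$side == side)
      if (!length(kk)) next
      tr <- trains$time[trains$side == side]
      dxy <- doors[[side]]
      arr <- numeric(length(kk))
      for (i in seq_along(kk)) {
        k <- kk[i]
        xy <- dxy[door_id[k], ]
        arr[i] <- walk_to(k, xy, tnow[k], pos[k, ])
        nodes <- add_node(nodes, k, arr[i], xy, "platform")
        pos[k, ] <- matrix(xy, 1)
      }
      # FIFO boarding per door at board_rate passengers/s during the dwell
      for (d in seq_len(nrow(dxy))) {
        idx <- kk[door_id[kk] == d]
        if (!length(idx)) next
        a <- arr[match(idx, kk)]
        o <- idx[order(a)]
        free <- -Inf
        for (k in o) {
          ak <- arr[match(k, kk)]
          tt <- suppressWarnings(min(tr[tr + service$dwell_s >=
                                          max(ak, free + 1 / service$board_rate)]))
          if (!is.finite(tt)) { board_time[k] <- NA_real_; next }
          bstart <- max(tt, ak, free + 1 / service$board_rate)
          if (bstart > tt + service$dwell_s) { board_time[k] <- NA_real_; next }
          free <- bstart
          board_time[k] <- bstart
          nodes <- add_node(nodes, k, bstart, pos[k, ], "platform")
        }
      }
    }

    for (k in seq_len(nb)) {
      id <- id + 1L
      done <- is.finite(board_time[k]) && board_time[k] <= duration
      nd <- nodes[[k]]
      tr_k <- trace_nodes(nd$t, nd$x, nd$y, nd$f)
      if (!is.null(tr_k) && nrow(tr_k)) {
        tr_k <- tr_k[tr_k$t <= duration, , drop = FALSE]
        if (nrow(tr_k)) {
          tr_k$ped_id <- id; tr_k$direction <- "boarding"
          traj[[length(traj) + 1L]] <- tr_k
        }
      }
      agents[[length(agents) + 1L]] <- data.frame(
        ped_id = id, direction = "boarding", side = board$side[k],
        portal = board$exit[k], device = dev_choice[k],
        entry_time = board$entry[k],
        exit_time = if (done) board_time[k] else NA_real_,
        completed = done)
    }
  }

  ## ---- alighting ----
  a_rows <- list()
  for (side in c("CD", "AB")) {
    tr <- trains$time[trains$side == side]
    na_ <- round(per_train_alight[[side]] * length(tr))
    if (na_ == 0) next
    per <- table(factor(1 + (seq_len(na_) - 1L) %% length(tr), levels = seq_along(tr)))
    for (j in seq_along(tr)) {
      m <- as.integer(per[j])
      if (!m) next
      door <- sample.int(6L, m, replace = TRUE)
      # passengers leave each door in single file
      stag <- stats::ave(seq_len(m), door, FUN = seq_along) / 2
      a_rows[[length(a_rows) + 1L]] <-
        data.frame(side = side, spawn = tr[j] + stag, door = door)
    }
  }
  alight <- do.call(rbind, a_rows)
  if (!is.null(alight) && nrow(alight)) {
    na_ <- nrow(alight)
    alight$speed <- sample_speed(speed, na_)
    alight$exit <- sample(exits, na_, replace = TRUE, prob = demand$exit_ratio)
    doors <- list(CD = door_cd, AB = door_ab)
    pos <- t(vapply(seq_len(na_), function(k)
      doors[[alight$side[k]]][alight$door[k], ], numeric(2)))
    tnow <- alight$spawn
    nodes <- lapply(seq_len(na_), function(k)
      list(t = tnow[k], x = pos[k, 1], y = pos[k, 2], f = "platform"))
    add_node <- function(nodes, k, t, xy, f) {
      nd <- nodes[[k]]
      nodes[[k]] <- list(t = c(nd$t, t), x = c(nd$x, xy[1]),
                         y = c(nd$y, xy[2]), f = c(nd$f, f))
      nodes
    }

    # up by stairs or escalator
    esc_free <- -Inf
    ord <- order(tnow)
    for (k in ord) {
      d_st <- sqrt(sum((stair_p - pos[k, ])^2))
      d_es <- sqrt(sum((esc_p - pos[k, ])^2))
      eta_es <- tnow[k] + d_es / alight$speed[k]
      q_es <- max(0, esc_free - eta_es)
      c_st <- route_cost(d_st, alight$speed[k], 0, service$L_stair, weights)
      c_es <- route_cost(d_es, alight$speed[k], q_es, service$L_escalator, weights)
      if (c_es <= c_st) {
        start <- max(eta_es, esc_free)
        esc_free <- start + service$escalator_headway
        nodes <- add_node(nodes, k, eta_es, esc_p, "platform")
        nodes <- add_node(nodes, k, start, esc_p, "platform")
        nodes <- add_node(nodes, k, start + service$L_escalator, esc_c, "concourse")
        tnow[k] <- start + service$L_escalator
        pos[k, ] <- matrix(esc_c, 1)
      } else {
        eta <- tnow[k] + d_st / alight$speed[k]
        nodes <- add_node(nodes, k, eta, stair_p, "platform")
        nodes <- add_node(nodes, k, eta + service$L_stair, stair_c, "concourse")
        tnow[k] <- eta + service$L_stair
        pos[k, ] <- matrix(stair_c, 1)
      }
    }

    # outbound gates, then walk to the chosen exit
    cs <- choose_and_serve(tnow, pos, gout_xy, service$gate_out$service,
                           alight$speed, weights)
    leave <- numeric(na_)
    for (k in seq_len(na_)) {
      g <- cs$choice[k]
      nodes <- add_node(nodes, k, cs$arrive[k], gout_xy[g, ], "concourse")
      nodes <- add_node(nodes, k, cs$depart[k], gout_xy[g, ], "concourse")
      xy <- exit_xy[alight$exit[k], ]
      d <- sqrt(sum((xy - gout_xy[g, ])^2))
      leave[k] <- cs$depart[k] + d / alight$speed[k]
      nodes <- add_node(nodes, k, leave[k], xy, "concourse")
    }

    for (k in seq_len(na_)) {
      id <- id + 1L
      done <- leave[k] <= duration
      nd <- nodes[[k]]
      tr_k <- trace_nodes(nd$t, nd$x, nd$y, nd$f)
      if (!is.null(tr_k) && nrow(tr_k)) {
        tr_k <- tr_k[tr_k$t <= duration, , drop = FALSE]
        if (nrow(tr_k)) {
          tr_k$ped_id <- id; tr_k$direction <- "alighting"
          traj[[length(traj) + 1L]] <- tr_k
        }
      }
      agents[[length(agents) + 1L]] <- data.frame(
        ped_id = id, direction = "alighting", side = alight$side[k],
        portal = alight$exit[k], device = NA_character_,
        entry_time = alight$spawn[k],
        exit_time = if (done) leave[k] else NA_real_,
        completed = done)
    }
  }

  trajectories <- if (length(traj)) {
    df <- do.call(rbind, traj)
    df[, c("ped_id", "direction", "t", "floor", "x", "y")]
  } else data.frame(ped_id = integer(), direction = character(),
                    t = numeric(), floor = character(),
                    x = numeric(), y = numeric())
  agents <- if (length(agents)) do.call(rbind, agents) else NULL
  structure(list(trajectories = trajectories, agents = agents,
                 dropped = agents$ped_id[!agents$completed],
                 trains = trains, seed = seed, duration = duration),
            class = "ped_sim")
}

#' Residence-time statistics
#'
#' Minimum, maximum and mean time in the station per direction, computed from
#' agent entry/exit times, plus the mean per-floor split from the 1-s
#' trajectory rows.
#'
#' @param sim a `ped_sim` from [simulate_trajectories()], or an agents data
#'   frame with `direction`, `entry_time`, `exit_time`.
#' @param completed_only drop agents that never finished (default TRUE).
#' @return Data frame with one row per direction: `n`, `min_s`, `max_s`,
#'   `mean_s`, `mean_concourse_s`, `mean_platform_s`.
#' @export
residence_stats <- function(sim, completed_only = TRUE) {
  ag <- if (inherits(sim, "ped_sim")) sim$agents else sim
  if (is.null(ag) || !nrow(ag)) stop("no trajectories to summarize")
  if (completed_only) ag <- ag[ag$completed %||% TRUE, , drop = FALSE]
  if (!nrow(ag)) stop("no completed trajectories")
  dur <- ag$exit_time - ag$entry_time
  out <- do.call(rbind, lapply(split(seq_len(nrow(ag)), ag$direction), function(ix) {
    data.frame(direction = ag$direction[ix[1]], n = length(ix),
               min_s = min(dur[ix]), max_s = max(dur[ix]),
               mean_s = mean(dur[ix]))
  }))
  if (inherits(sim, "ped_sim") && nrow(sim$trajectories)) {
    tr <- sim$trajectories[sim$trajectories$ped_id %in% ag$ped_id, ]
    fl <- tapply(tr$floor == "concourse", list(tr$direction), mean)
    out$mean_concourse_s <- out$mean_s * as.numeric(fl[out$direction])
    out$mean_platform_s <- out$mean_s - out$mean_concourse_s
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
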