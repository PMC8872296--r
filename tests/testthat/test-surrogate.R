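test_that("R-squared follows its defining identity", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_lt(r_squared(c(1, 2, 3), c(5, 5, 5)), 0)
  expect_error(r_squared(c(1, 1), c(1, 2)), "zero total variance")
  expect_error(r_squared(1, 1), "length")
})

test_that("train/test splits are disjoint with the reference sizes", {
  tab <- data.frame(x = 1:23, measured = rnorm(23))
  sp <- split_train_test(tab, 3, seed = 2)
  expect_equal(nrow(sp$train), 20)  # 23-point region -> 20 train / 3 test
  expect_length(intersect(sp$train$x, sp$test$x), 0)
  expect_setequal(c(sp$train$x, sp$test$x), tab$x)
  sp29 <- split_train_test(data.frame(x = 1:29), 4, seed = 2)
  expect_equal(nrow(sp29$train), 25)
  expect_error(split_train_test(tab, 23), "n_test")
  expect_error(split_train_test(tab, 0), "n_test")
})

test_that("K-means partition recovers separated clusters and the WCSS optimum", {
  set.seed(5)
  tab <- data.frame(
    sim_closed = c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1)),
    sim_open = c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1)),
    measured = c(rnorm(10, 0, 0.1), rnorm(10, 5, 0.1)))
  lab <- kmeans_partition(tab, 2, seed = 1)
  expect_length(unique(lab[1:10]), 1)
  expect_length(unique(lab[11:20]), 1)
  expect_false(lab[1] == lab[11])
  # brute-force WCSS oracle on n <= 8
  set.seed(7)
  small <- data.frame(sim_closed = rnorm(8), sim_open = rnorm(8),
                      measured = rnorm(8))
  lab8 <- kmeans_partition(small, 2, seed = 3, nstart = 25)
  feats <- scale(as.matrix(small))
  wcss_of <- function(grp) {
    sum(vapply(unique(grp), function(g) {
      m <- feats[grp == g, , drop = FALSE]
      sum(sweep(m, 2, colMeans(m))^2)
    }, numeric(1)))
  }
  best <- Inf
  for (code in 1:(2^7 - 1)) {
    grp <- c(0, as.integer(intToBits(code))[1:7])
    if (length(unique(grp)) == 2) best <- min(best, wcss_of(grp))
  }
  expect_equal(attr(lab8, "wcss"), best, tolerance = 1e-8)
  expect_error(kmeans_partition(small, 9), "exceeds")
  expect_error(kmeans_partition(small, 1), ">= 2")
})

test_that("SVR fits constants within the tube and validates inputs", {
  x <- matrix(seq(0, 1, length.out = 8))
  m <- train_svr(x, rep(5, 8), lambda = 10, sigma = 1, epsilon = 0.1)
  expect_lt(max(abs(predict(m, x) - 5)), 0.1 + 1e-9)
  expect_error(train_svr(x, rep(5, 8), lambda = -1, sigma = 1), "lambda")
  expect_error(predict(m, matrix(1, 1, 3)), "dimension")
})

test_that("libSVM solution matches the projected-gradient dual oracle", {
  set.seed(11)
  x <- matrix(c(0.0, 0.3, 0.9, 1.7, 2.2, 3.1), ncol = 1)
  y <- c(0.1, 0.5, 1.4, 1.1, 0.3, -0.6)
  C <- 2; sigma <- 0.8; eps <- 0.05
  m <- train_svr(x, y, C, sigma, eps)
  xs <- sweep(sweep(x, 2, m$x_center), 2, m$x_scale, "/")
  # full dual coefficient vector of the libSVM solution
  beta_fit <- rep(0, nrow(x))
  for (k in seq_len(nrow(m$sv))) {
    row <- which(apply(xs, 1, function(r) all(abs(r - m$sv[k, ]) < 1e-10)))
    beta_fit[row] <- m$coefs[k]
  }
  orc <- svr_dual_oracle(xs, y, C, sigma, eps)
  J_fit <- svr_primal_objective(orc$K, beta_fit, -m$rho, y, C, eps)
  J_orc <- svr_oracle_objective(orc, y, C, eps)
  expect_lt(abs(J_fit - J_orc), 1e-5 * max(1, abs(J_orc)))
  # predictions agree pointwise as well
  f_orc <- as.numeric(orc$K %*% orc$beta) + orc$b
  expect_lt(max(abs(predict(m, x) - f_orc)), 0.05)
})

test_that("predictions are invariant to input standardization round-trip", {
  set.seed(3)
  x <- matrix(rnorm(40, 50, 10), ncol = 2)
  y <- sin(x[, 1] / 10) + 0.1 * x[, 2]
  m_raw <- train_svr(x, y, 10, 0.5, 0.01)
  xs <- scale(x)
  m_std <- train_svr(xs, y, 10, 0.5, 0.01)
  xnew <- matrix(rnorm(20, 50, 10), ncol = 2)
  xnew_s <- sweep(sweep(xnew, 2, attr(xs, "scaled:center")), 2,
                  attr(xs, "scaled:scale"), "/")
  expect_lt(max(abs(predict(m_raw, xnew) - predict(m_std, xnew_s))), 1e-8)
})

test_that("PSO tuning is deterministic, monotone, and competitive with a grid", {
  set.seed(21)
  x <- matrix(runif(30, 0, 4))
  y <- exp(-(x[, 1] - 2)^2) + 0.05 * x[, 1]
  one <- pso_tune(x, y, swarm = 1, iters = 0, seed = 8)
  expect_length(one$trace, 1)  # the initial sampled position is returned
  expect_true(one$lambda >= 1e-2 && one$lambda <= 1e4)
  expect_true(one$sigma >= 1e-3 && one$sigma <= 1e2)
  expect_identical(pso_tune(x, y, swarm = 6, iters = 5, seed = 9),
                   pso_tune(x, y, swarm = 6, iters = 5, seed = 9))
  tuned <- pso_tune(x, y, swarm = 10, iters = 10, seed = 2)
  expect_true(all(diff(tuned$trace) >= 0))  # global best never degrades
  # dense log-grid oracle under the same CV objective
  ix <- seq_len(24)
  xtr <- x[ix, , drop = FALSE]; ytr <- y[ix]
  xte <- x[-ix, , drop = FALSE]; yte <- y[-ix]
  tuned <- pso_tune(xtr, ytr, swarm = 10, iters = 10, seed = 2)
  m_pso <- train_svr(xtr, ytr, tuned$lambda, tuned$sigma)
  r2_pso <- r_squared(yte, predict(m_pso, xte))
  grid <- expand.grid(l = seq(-2, 4, length.out = 20),
                      s = seq(-3, 2, length.out = 20))
  fold <- rep_len(1:4, length(ytr))
  cv_r2 <- function(lam, sig) {
    pred <- numeric(length(ytr))
    for (f in 1:4) {
      m <- train_svr(xtr[fold != f, , drop = FALSE], ytr[fold != f], lam, sig)
      pred[fold == f] <- predict(m, xtr[fold == f, , drop = FALSE])
    }
    r_squared(ytr, pred)
  }
  best <- -Inf; best_par <- NULL
  for (k in seq_len(nrow(grid))) {
    sc <- cv_r2(10^grid$l[k], 10^grid$s[k])
    if (sc > best) { best <- sc; best_par <- grid[k, ] }
  }
  m_grid <- train_svr(xtr, ytr, 10^best_par$l, 10^best_par$s)
  r2_grid <- r_squared(yte, predict(m_grid, xte))
  expect_gte(r2_pso, r2_grid - 0.02)
  expect_error(pso_tune(x, y, bounds_log_lambda = c(2, 2)), "degenerate")
})

test_that("region map matches the exhaustive nearest-neighbour oracle", {
  run <- shared_run()
  plan <- run$plan
  labels <- run$bank$labels
  map <- build_region_map(run$grids, plan, labels)
  pc <- plan[plan$floor == "concourse", ]
  g <- run$grids$concourse
  set.seed(4)
  for (k in 1:25) {
    x <- runif(1, 0, g$length); y <- runif(1, 0, g$width)
    ij <- metropm:::grid_index(g, x, y)
    ctr <- metropm:::cell_center(g, ij[1], ij[2])
    d <- sqrt((pc$x_m - ctr[1])^2 + (pc$y_m - ctr[2])^2)
    expect_equal(map$concourse[ij[1], ij[2]], labels[which.min(d)])
  }
  # single labelled point covers the whole floor
  map1 <- build_region_map(run$grids, pc[1, , drop = FALSE], "A")
  expect_true(all(map1$concourse == "A"))
  # a cell coincident with a labelled point takes that label
  ij1 <- metropm:::grid_index(g, pc$x_m[5], pc$y_m[5])
  expect_equal(map$concourse[ij1[1], ij1[2]], labels[5])
  expect_error(build_region_map(run$grids, pc[0, ], character(0)), "no labelled")
})

test_that("prediction routing respects regions and input dimensions", {
  run <- shared_run()
  bank <- run$bank$models
  map <- run$map
  # platform locations demand three state values
  expect_error(predict_concentration(bank, map, 50, 6, "platform", c(40, 50)),
               "length 2")
  v <- predict_concentration(bank, map, 50, 6, "platform", c(40, 50, 45))
  expect_gte(v, 0)
  # routing equals direct evaluation of the region's model
  reg <- metropm:::region_at(map, 45, 10, "concourse")
  direct <- max(0, predict(bank[[reg]], matrix(c(40, 50), 1)))
  expect_equal(predict_concentration(bank, map, 45, 10, "concourse",
                                     c(40, 50)), direct)
})
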