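# input (simulated-state) column names of a sample table
sim_cols <- function(table) grep("^sim_", names(table), value = TRUE)

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar y)^2}. May be
#' negative for predictions worse than the mean.
#'
#' @param measured,predicted equal-length numeric vectors, length >= 2.
#' @return Scalar R-squared.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 2)
    stop("measured and predicted must be equal-length vectors of length >= 2")
  sst <- sum((measured - mean(measured))^2)
  if (sst == 0) stop("zero total variance in measured values")
  1 - sum((measured - predicted)^2) / sst
}

#' Partition concourse sample points by K-means
#'
#' Clusters the standardized per-point feature vectors (simulated state
#' inputs plus the measured output) with Lloyd's algorithm (k-means++-style
#' multiple restarts via `nstart`), splitting the concourse points into an
#' interior, supply-dominated type (A) and an exit-proximal, outdoor-
#' dominated type (B). For `k = 2` the cluster with the smaller mean
#' open-state simulated value is labelled `"A"`.
#'
#' @param table concourse sample-table data frame (`sim_*` columns and
#'   `measured`).
#' @param k number of clusters, >= 2 and <= rows.
#' @param seed integer seed (restarts make the result deterministic per
#'   seed).
#' @param nstart random restarts; best by within-cluster sum of squares.
#' @return Character vector of labels, one per row, with attribute `wcss`.
#' @export
kmeans_partition <- function(table, k = 2, seed = 1, nstart = 10) {
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(table)) stop("k exceeds the number of points")
  feats <- scale(as.matrix(table[, c(sim_cols(table), "measured")]))
  feats[, attr(feats, "scaled:scale") == 0] <- 0
  set.seed(seed)
  km <- kmeans(feats, centers = k, nstart = nstart, iter.max = 100)
  labels <- as.character(km$cluster)
  if (k == 2) {
    open_col <- intersect(c("sim_open", "sim_cd_open"), names(table))[1]
    m <- tapply(table[[open_col]], km$cluster, mean)
    a_first <- names(sort(m))  # ascending: interior cluster first
    labels <- c("A", "B")[match(km$cluster, as.integer(a_first))]
  }
  attr(labels, "wcss") <- km$tot.withinss
  labels
}

#' Random train/test split of a sample table
#'
#' @param table data frame.
#' @param n_test held-out rows, `0 < n_test < nrow(table)`.
#' @param seed integer seed.
#' @return List `train`, `test` (disjoint, union = table).
#' @export
split_train_test <- function(table, n_test, seed = 1) {
  n <- nrow(table)
  if (n_test <= 0 || n_test >= n) stop("n_test must satisfy 0 < n_test < n")
  set.seed(seed)
  ix <- sample.int(n, n_test)
  list(train = table[-ix, , drop = FALSE], test = table[ix, , drop = FALSE])
}

#' Train an epsilon-SVR surrogate
#'
#' Solves the epsilon-insensitive support vector regression with RBF kernel
#' \eqn{\kappa(x_i, x_k) = \exp(-\sigma \|x_i - x_k\|^2)} and slack weight
#' `lambda`, i.e. minimizing \eqn{\tfrac12\|\omega\|^2 + \lambda \sum_i
#' (\xi_i + \xi_i^*)} subject to the epsilon tube constraints, via the
#' libSVM SMO solver. Inputs are standardized internally (constants stored in
#' the model); the output stays in physical units, so `epsilon` is in ug/m3.
#'
#' @param x numeric matrix of inputs (rows = points).
#' @param y numeric response vector.
#' @param lambda slack-penalty weight, > 0.
#' @param sigma RBF kernel width, > 0.
#' @param epsilon insensitivity tube half-width, >= 0; default 0.1 ug/m3
#'   (the instrument resolution).
#' @param region optional region id stored in the model.
#' @return An object of class `surrogate_model` holding the support vectors,
#'   dual coefficients and bias; `predict()` evaluates
#'   \eqn{f(x) = \sum_i \alpha_i \kappa(x_i, x) + b} directly from them.
#' @export
train_svr <- function(x, y, lambda, sigma, epsilon = 0.1, region = NULL) {
  x <- as.matrix(x)
  if (lambda <= 0 || sigma <= 0 || epsilon < 0)
    stop("require lambda > 0, sigma > 0, epsilon >= 0")
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  degenerate <- function()
    structure(list(region = region, lambda = lambda, sigma = sigma,
                   epsilon = epsilon, d = ncol(x),
                   sv = matrix(0, 1, ncol(x)), coefs = 0, rho = -mean(y),
                   x_center = ctr, x_scale = scl, n_train = nrow(x)),
              class = "surrogate_model")
  # constant response fits inside the tube with no support vectors
  if (sd(y) == 0) return(degenerate())
  fit <- tryCatch(
    e1071::svm(xs, y, type = "eps-regression", kernel = "radial",
               gamma = sigma, cost = lambda, epsilon = epsilon,
               tolerance = 1e-8, scale = FALSE),
    error = function(e) {
      if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL
      else stop(e)
    })
  if (is.null(fit) || !length(fit$coefs)) return(degenerate())
  structure(list(region = region, lambda = lambda, sigma = sigma,
                 epsilon = epsilon, d = ncol(x),
                 sv = as.matrix(fit$SV), coefs = as.numeric(fit$coefs),
                 rho = fit$rho, x_center = ctr, x_scale = scl,
                 n_train = nrow(x)),
            class = "surrogate_model")
}

#' @rdname train_svr
#' @param object a `surrogate_model`.
#' @param newdata matrix (or vector) of raw inputs.
#' @param ... unused.
#' @export
predict.surrogate_model <- function(object, newdata, ...) {
  nd <- if (is.null(dim(newdata))) matrix(newdata, ncol = object$d)
        else as.matrix(newdata)
  if (ncol(nd) != object$d)
    stop("input dimension ", ncol(nd), " does not match model dimension ",
         object$d)
  nds <- sweep(sweep(nd, 2, object$x_center), 2, object$x_scale, "/")
  # squared distances to support vectors
  d2 <- outer(rowSums(nds^2), rowSums(object$sv^2), "+") -
    2 * nds %*% t(object$sv)
  as.numeric(exp(-object$sigma * pmax(d2, 0)) %*% object$coefs - object$rho)
}

#' Tune SVR hyperparameters by particle swarm optimization
#'
#' Global-best PSO (inertia 0.7, cognitive and social coefficients 1.5) over
#' `log10(lambda)` and `log10(sigma)`, maximizing the pooled k-fold
#' cross-validation R-squared on the training set. The incumbent best score
#' is non-decreasing over iterations; with a single particle and zero
#' iterations the initial sampled position is returned.
#'
#' @param x,y training inputs and response.
#' @param epsilon SVR tube half-width.
#' @param bounds_log_lambda,bounds_log_sigma search intervals in log10 units.
#' @param swarm particles, >= 1.
#' @param iters PSO iterations, >= 0.
#' @param folds cross-validation folds.
#' @param seed integer seed.
#' @return List `lambda`, `sigma`, `score` (CV R-squared), `trace`
#'   (best score per iteration).
#' @export
pso_tune <- function(x, y, epsilon = 0.1,
                     bounds_log_lambda = c(-2, 4), bounds_log_sigma = c(-3, 2),
                     swarm = 12, iters = 15, folds = 5, seed = 1) {
  x <- as.matrix(x)
  if (swarm < 1) stop("swarm must be >= 1")
  if (diff(bounds_log_lambda) <= 0 || diff(bounds_log_sigma) <= 0)
    stop("degenerate hyperparameter bounds")
  set.seed(seed)
  n <- nrow(x)
  folds <- min(folds, n)
  fold_id <- sample(rep_len(seq_len(folds), n))
  objective <- function(z) {
    lam <- 10^z[1]; sig <- 10^z[2]
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- try(train_svr(x[tr, , drop = FALSE], y[tr], lam, sig, epsilon),
               silent = TRUE)
      if (inherits(m, "try-error")) return(-Inf)
      pred[!tr] <- predict(m, x[!tr, , drop = FALSE])
    }
    if (sd(y) == 0) return(-sum((y - pred)^2))
    r_squared(y, pred)
  }

  lo <- c(bounds_log_lambda[1], bounds_log_sigma[1])
  hi <- c(bounds_log_lambda[2], bounds_log_sigma[2])
  pos <- cbind(runif(swarm, lo[1], hi[1]), runif(swarm, lo[2], hi[2]))
  vel <- matrix(0, swarm, 2)
  pbest <- pos
  pscore <- apply(pos, 1, objective)
  gi <- which.max(pscore)
  gbest <- pbest[gi, ]; gscore <- pscore[gi]
  trace <- gscore
  w <- 0.7; c1 <- 1.5; c2 <- 1.5
  for (it in seq_len(iters)) {
    r1 <- matrix(runif(swarm * 2), swarm, 2)
    r2 <- matrix(runif(swarm * 2), swarm, 2)
    vel <- w * vel + c1 * r1 * (pbest - pos) +
      c2 * r2 * (matrix(gbest, swarm, 2, byrow = TRUE) - pos)
    pos <- pos + vel
    pos[, 1] <- pmin(hi[1], pmax(lo[1], pos[, 1]))
    pos[, 2] <- pmin(hi[2], pmax(lo[2], pos[, 2]))
    sc <- apply(pos, 1, objective)
    upd <- sc > pscore
    pbest[upd, ] <- pos[upd, , drop = FALSE]
    pscore[upd] <- sc[upd]
    gi <- which.max(pscore)
    if (pscore[gi] > gscore) { gbest <- pbest[gi, ]; gscore <- pscore[gi] }
    trace <- c(trace, gscore)
  }
  list(lambda = 10^gbest[1], sigma = 10^gbest[2], score = gscore,
       trace = trace)
}

#' Region map for surrogate routing
#'
#' Labels every concourse grid cell with the type (A/B) of its nearest
#' classified sample point (a Voronoi assignment), and the whole platform as
#' `"platform"`: exposure integration then routes each trajectory position to
#' the surrogate trained for that region.
#'
#' @param grids per-floor grids from [rasterize()].
#' @param plan a [design_station_samples()] plan.
#' @param labels character labels aligned with the concourse rows of `plan`.
#' @return An object of class `region_map` with a concourse label matrix.
#' @export
build_region_map <- function(grids, plan, labels) {
  pc <- plan[plan$floor == "concourse", , drop = FALSE]
  if (!nrow(pc) || !length(labels)) stop("no labelled concourse points")
  if (nrow(pc) != length(labels))
    stop("labels must align with the concourse plan points")
  g <- grids$concourse
  ij <- expand.grid(i = seq_len(g$nrow), j = seq_len(g$ncol))
  ctr <- cell_center(g, ij$i, ij$j)
  d2 <- outer(rowSums(ctr^2), rowSums(cbind(pc$x_m, pc$y_m)^2), "+") -
    2 * ctr %*% t(cbind(pc$x_m, pc$y_m))
  nearest <- max.col(-d2, ties.method = "first")
  structure(list(concourse = matrix(labels[nearest], g$nrow, g$ncol),
                 grids = grids),
            class = "region_map")
}

# region label(s) for positions on a floor
region_at <- function(map, x, y, floor) {
  if (floor == "platform") return(rep("platform", length(x)))
  g <- map$grids$concourse
  ij <- grid_index(g, x, y)
  map$concourse[(ij[, 2] - 1L) * g$nrow + ij[, 1]]
}

#' Predict the measured concentration at a location
#'
#' Routes the per-state simulated values to the surrogate model of the region
#' containing the location and clips the prediction at zero.
#'
#' @param bank named list of `surrogate_model`s (regions `A`, `B`,
#'   `platform`), e.g. from [build_surrogate_bank()].
#' @param map a [build_region_map()] object.
#' @param x,y location, m.
#' @param floor floor name.
#' @param sim_values numeric vector of per-state simulated concentrations
#'   (length 2 on the concourse, 3 on the platform).
#' @return Predicted concentration, ug/m3.
#' @export
predict_concentration <- function(bank, map, x, y, floor, sim_values) {
  region <- region_at(map, x, y, floor)[1]
  model <- bank[[region]]
  if (is.null(model)) stop("no surrogate for region ", region)
  if (length(sim_values) != model$d)
    stop("sim_values has length ", length(sim_values),
         " but region ", region, " expects ", model$d)
  max(0, predict(model, matrix(sim_values, 1)))
}

#' Cluster, tune and train the full surrogate bank
#'
#' Runs the fusion stage end-to-end on a synthesized sample table: K-means
#' partition of the concourse points into types A and B, a random train/test
#' split per region (about 15% held out, matching the reference splits
#' 20/3, 20/4 and 25/4 at the default point counts), PSO hyperparameter
#' tuning by cross-validation on the training set only, final fits, and
#' train/test R-squared bookkeeping.
#'
#' @param tables named list (`concourse`, `platform`) from
#'   [synthesize_sample_table()].
#' @param epsilon SVR tube half-width, ug/m3.
#' @param test_fraction held-out share per region.
#' @param seed integer seed driving clustering, splits and PSO.
#' @param swarm,iters PSO controls.
#' @return List of class `surrogate_bank`: `models` (named list),
#'   `labels` (concourse point types), `metrics` (per-region data frame with
#'   hyperparameters and R-squared values).
#' @export
build_surrogate_bank <- function(tables, epsilon = 0.1, test_fraction = 0.15,
                                 seed = 1, swarm = 12, iters = 15) {
  labels <- kmeans_partition(tables$concourse, k = 2, seed = seed)
  regions <- list(
    A = tables$concourse[labels == "A", , drop = FALSE],
    B = tables$concourse[labels == "B", , drop = FALSE],
    platform = tables$platform)
  models <- list(); metrics <- list()
  for (r in names(regions)) {
    tab <- regions[[r]]
    cols <- sim_cols(tab)
    n_test <- max(1L, round(test_fraction * nrow(tab)))
    sp <- split_train_test(tab, n_test, seed = seed + match(r, names(regions)))
    xtr <- as.matrix(sp$train[, cols]); ytr <- sp$train$measured
    xte <- as.matrix(sp$test[, cols]);  yte <- sp$test$measured
    tune <- pso_tune(xtr, ytr, epsilon, swarm = swarm, iters = iters,
                     seed = seed + 10 * match(r, names(regions)))
    m <- train_svr(xtr, ytr, tune$lambda, tune$sigma, epsilon, region = r)
    pred_te <- predict(m, xte)
    r2_tr <- r_squared(ytr, predict(m, xtr))
    r2_te <- if (nrow(xte) >= 2 && sd(yte) > 0)
      r_squared(yte, pred_te) else NA_real_
    holdout <- data.frame(region = r, measured = yte, predicted = pred_te)
    models[[r]] <- m
    metrics[[r]] <- list(df = data.frame(region = r, n_train = nrow(xtr),
                                         n_test = nrow(xte),
                                         lambda = tune$lambda, sigma = tune$sigma,
                                         cv_r2 = tune$score,
                                         r2_train = r2_tr, r2_test = r2_te),
                         holdout = holdout)
  }
  hold <- do.call(rbind, lapply(metrics, `[[`, "holdout"))
  rownames(hold) <- NULL
  structure(list(models = models, labels = labels,
                 metrics = do.call(rbind, lapply(metrics, `[[`, "df")),
                 holdout = hold,
                 r2_test_pooled = r_squared(hold$measured, hold$predicted)),
            class = "surrogate_bank")
}
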