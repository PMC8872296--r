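# Independent dense-QP oracle for the epsilon-SVR dual on standardized
# inputs: box-constrained L-BFGS-B on (alpha, alpha*) with the equality
# constraint sum(alpha - alpha*) = 0 enforced by a quadratic penalty,
# followed by an exact KKT polish on the identified active set.
svr_dual_oracle <- function(xs, y, C, sigma, eps, mu = 1e8) {
  n <- nrow(xs)
  K <- exp(-sigma * as.matrix(dist(xs))^2)
  obj <- function(th) {
    a <- th[1:n]; s <- th[(n + 1):(2 * n)]
    beta <- a - s
    0.5 * sum(beta * (K %*% beta)) + eps * sum(a + s) - sum(y * beta) +
      mu * sum(beta)^2
  }
  grad <- function(th) {
    a <- th[1:n]; s <- th[(n + 1):(2 * n)]
    beta <- a - s
    Kb <- as.numeric(K %*% beta) + 2 * mu * sum(beta)
    c(Kb + eps - y, -Kb + eps + y)
  }
  fit <- stats::optim(rep(C / 4, 2 * n), obj, grad, method = "L-BFGS-B",
                      lower = rep(0, 2 * n), upper = rep(C, 2 * n),
                      control = list(maxit = 20000, factr = 1))
  a <- fit$par[1:n]; s <- fit$par[(n + 1):(2 * n)]
  beta <- a - s
  b_of <- function(beta) stats::optimize(function(b)
    svr_primal_objective(K, beta, b, y, C, eps),
    interval = range(y) + c(-5, 5), tol = 1e-12)$minimum
  out <- list(beta = beta, K = K, b = b_of(beta))

  # KKT polish: fix variables at the box faces, solve the equality-
  # constrained QP exactly on the remaining free set
  tol <- 1e-5 * C
  at_hi <- beta > C - tol
  at_lo <- beta < -C + tol
  free <- !at_hi & !at_lo & abs(beta) > tol
  if (any(free)) {
    beta_p <- numeric(n)
    beta_p[at_hi] <- C
    beta_p[at_lo] <- -C
    Fi <- which(free); Bi <- which(at_hi | at_lo)
    sgn <- sign(beta[Fi])
    A <- rbind(cbind(K[Fi, Fi, drop = FALSE], 1),
               c(rep(1, length(Fi)), 0))
    rhs <- c(y[Fi] - eps * sgn -
               if (length(Bi)) as.numeric(K[Fi, Bi, drop = FALSE] %*%
                                            beta_p[Bi]) else 0,
             -sum(beta_p[Bi]))
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (!is.null(sol)) {
      beta_p[Fi] <- sol[seq_along(Fi)]
      b_p <- sol[length(sol)]
      ok <- all(abs(beta_p) <= C + tol)
      if (ok && svr_primal_objective(K, beta_p, b_p, y, C, eps) <
            svr_primal_objective(K, out$beta, out$b, y, C, eps)) {
        out$beta <- beta_p
        out$b <- b_p
      }
    }
  }
  out
}

# primal objective 0.5 b'Kb + C * sum of epsilon-insensitive losses
svr_primal_objective <- function(K, beta, b, y, C, eps) {
  f <- as.numeric(K %*% beta) + b
  0.5 * sum(beta * (K %*% beta)) + C * sum(pmax(0, abs(y - f) - eps))
}

# primal objective of the oracle's solution at its own bias
svr_oracle_objective <- function(orc, y, C, eps) {
  svr_primal_objective(orc$K, orc$beta, orc$b, y, C, eps)
}
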