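# Independent convex-QP oracle for the fused-lasso objectives.
#
# Solves  min_z  z' P z - 2 q' z + r0 + lam * sum_j t_j
#         s.t.   -t_j <= (D z)_j <= t_j
# with a log-barrier interior-point method (Newton steps on the barrier
# objective, t eliminated by block Schur complement).  This is the generic
# auxiliary-absolute-value QP formulation and shares no code or algorithm
# with the package's dynamic-programming solver; the returned objective is
# evaluated at the (strictly feasible) final iterate and is therefore an
# upper bound on the optimum that converges to it as mu -> 0.

qp_oracle <- function(P, q, r0, D, lam, z0, rel_tol = 1e-9) {
  stopifnot(lam > 0)
  m <- nrow(D)
  z <- z0
  t <- abs(as.vector(D %*% z)) + 1
  f_true <- function(z) {
    drop(crossprod(z, P %*% z)) - 2 * sum(q * z) + r0 +
      lam * sum(abs(as.vector(D %*% z)))
  }
  phi <- function(z, t, mu) {
    dz <- as.vector(D %*% z)
    u <- t - dz
    v <- t + dz
    if (any(u <= 0) || any(v <= 0)) return(Inf)
    drop(crossprod(z, P %*% z)) - 2 * sum(q * z) + r0 + lam * sum(t) -
      mu * sum(log(u) + log(v))
  }
  mu <- max(1, abs(f_true(z0))) / (2 * m)
  repeat {
    for (newton in 1:60) {
      dz <- as.vector(D %*% z)
      u <- t - dz
      v <- t + dz
      gz <- as.vector(2 * (P %*% z) - 2 * q + crossprod(D, mu * (1 / u - 1 / v)))
      gt <- lam - mu * (1 / u + 1 / v)
      A <- mu * (1 / u^2 + 1 / v^2)
      B <- mu * (1 / v^2 - 1 / u^2)
      geff <- (A^2 - B^2) / A
      S <- 2 * P + crossprod(D, geff * D)
      rhs <- -gz + as.vector(crossprod(D, (B / A) * gt))
      step_z <- tryCatch(solve(S, rhs), error = function(e) NULL)
      if (is.null(step_z)) break
      step_t <- (-gt - B * as.vector(D %*% step_z)) / A
      dec <- -(sum(gz * step_z) + sum(gt * step_t))
      if (!is.finite(dec) || dec < mu * 1e-10) break
      # backtracking line search keeping u, v > 0
      alpha <- 1
      phi0 <- phi(z, t, mu)
      repeat {
        zn <- z + alpha * step_z
        tn <- t + alpha * step_t
        if (phi(zn, tn, mu) <= phi0 - 0.25 * alpha * dec + 1e-12) break
        alpha <- alpha / 2
        if (alpha < 1e-12) break
      }
      if (alpha < 1e-12) break
      z <- z + alpha * step_z
      t <- t + alpha * step_t
    }
    if (2 * m * mu <= rel_tol * max(1, abs(f_true(z)))) break
    mu <- mu / 10
  }
  list(z = z, objective = f_true(z))
}

diff_matrix <- function(n) {
  if (n < 2) return(matrix(0, 0, n))
  D <- matrix(0, n - 1, n)
  D[cbind(seq_len(n - 1), seq_len(n - 1))] <- -1
  D[cbind(seq_len(n - 1), 2:n)] <- 1
  D
}

# oracle for the single-condition weighted fused lasso
qp_fused_oracle <- function(y, w, lam, rel_tol = 1e-9) {
  n <- length(y)
  P <- diag(w, n)
  q <- w * y
  r0 <- sum(w * y^2)
  z0 <- rep(sum(w * y) / sum(w), n)
  qp_oracle(P, q, r0, diff_matrix(n), lam, z0, rel_tol)
}

# oracle for the coupled two-condition objective; takes one chromosome
# entry of a condition_matrix (meth_a/cov_a, meth_b/cov_b matrices)
qp_two_condition_oracle <- function(entry, lam, rel_tol = 1e-9) {
  n <- length(entry$pos)
  ca <- rowSums(entry$cov_a)
  cb <- rowSums(entry$cov_b)
  ma <- rowSums(entry$meth_a)
  mb <- rowSums(entry$meth_b)
  P <- matrix(0, 2 * n, 2 * n)
  diag(P)[1:n] <- ca + cb
  diag(P)[(n + 1):(2 * n)] <- cb
  P[cbind(1:n, (n + 1):(2 * n))] <- cb
  P[cbind((n + 1):(2 * n), 1:n)] <- cb
  q <- c(ma + mb, mb)
  r0 <- 0
  for (j in seq_len(ncol(entry$cov_a))) {
    cv <- entry$cov_a[, j]
    r0 <- r0 + sum(ifelse(cv > 0, entry$meth_a[, j]^2 / cv, 0))
  }
  for (j in seq_len(ncol(entry$cov_b))) {
    cv <- entry$cov_b[, j]
    r0 <- r0 + sum(ifelse(cv > 0, entry$meth_b[, j]^2 / cv, 0))
  }
  D1 <- diff_matrix(n)
  D <- rbind(cbind(D1, matrix(0, n - 1, n)),
             cbind(matrix(0, n - 1, n), D1))
  z0 <- c(rep(sum(ma + mb) / max(sum(ca + cb), 1), n), rep(0, n))
  qp_oracle(P, q, r0, D, lam, z0, rel_tol)
}
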