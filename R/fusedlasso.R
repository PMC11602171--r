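#' Exact weighted 1D fused-lasso fit
#'
#' Computes the global minimizer of the coverage-weighted, fusion-penalized
#' least squares objective
#' \deqn{\sum_i c_i (y_i - \beta_i)^2 + \lambda_2 \sum_{i \ge 2} |\beta_i - \beta_{i-1}|}
#' by exact dynamic programming over piecewise-quadratic value functions.
#' The solution is piecewise constant; `lambda2` sets the fusion strength
#' (0 reproduces `y`; very large values return the coverage-weighted mean).
#'
#' Zero-weight sites contribute nothing to the least-squares term and never
#' break a fusion: they are assigned the level of the plateau immediately
#' to their left (or the first plateau, at a chromosome start), which is
#' always optimal because total variation across a run of weightless sites
#' telescopes.
#'
#' @param y observed values (methylation fractions or differences).
#' @param w non-negative weights (coverages); at least one must be > 0.
#' @param lambda2 fusion strength, >= 0.
#' @return A `fused_fit` list: `beta` (fitted values), `lambda2`, and
#'   `objective` (penalized weighted least squares at `beta`).
#' @export
solve_fused_lasso_1d <- function(y, w, lambda2) {
  stopifnot(length(y) == length(w), lambda2 >= 0, all(w >= 0))
  n <- length(y)
  if (n == 0) {
    return(structure(list(beta = numeric(0), lambda2 = lambda2,
                          objective = 0), class = "fused_fit"))
  }
  if (all(w == 0)) stop("all weights are zero; nothing to fit")
  pos_w <- which(w > 0)
  ys <- y[pos_w]
  ws <- w[pos_w]

  # saturation cap: for lambda2 at or above the largest absolute prefix of
  # the centered weighted residuals, the minimizer is exactly the weighted
  # mean; solving with the capped lambda2 avoids catastrophic cancellation
  # at huge penalties (e.g. 1e9) without changing the solution.
  mu <- sum(ws * ys) / sum(ws)
  lam_sat <- max(abs(cumsum(2 * ws * (ys - mu))))
  lam_eff <- min(lambda2, lam_sat)
  if (lam_eff >= lam_sat) {
    beta_s <- rep(mu, length(ys))
  } else {
    beta_s <- fused_dp_weighted(ys, ws, lam_eff)
  }

  beta <- rep(NA_real_, n)
  beta[pos_w] <- beta_s
  if (length(pos_w) < n) {
    # fill weightless sites with the level of the plateau to their left
    filled <- beta
    last <- beta_s[1]
    for (i in seq_len(n)) {
      if (is.na(filled[i])) filled[i] <- last else last <- filled[i]
    }
    beta <- filled
  }
  structure(
    list(beta = beta, lambda2 = lambda2,
         objective = fused_objective(y, w, beta, lambda2)),
    class = "fused_fit"
  )
}

#' Penalized weighted least-squares objective of a fit
#'
#' @param y,w data and weights as in [solve_fused_lasso_1d()].
#' @param beta fitted values.
#' @param lambda2 fusion strength.
#' @return The objective value.
#' @export
fused_objective <- function(y, w, beta, lambda2) {
  r <- y - beta
  r[w == 0] <- 0
  sum(w * r^2) + lambda2 * sum(abs(diff(beta)))
}

#' @export
print.fused_fit <- function(x, ...) {
  lev <- fused_runs(x$beta)
  cat(sprintf(
    "fused_fit: %d sites, %d plateau(s), lambda2 = %g, objective = %g\n",
    length(x$beta), nrow(lev), x$lambda2, x$objective
  ))
  invisible(x)
}

#' Extract maximal constant runs from a fitted vector
#'
#' Successive values within `tol` of each other are treated as fused
#' (guards float noise in the solver output).
#'
#' @param beta numeric vector.
#' @param tol plateau equality tolerance.
#' @return data.table with columns `first`, `last` (indices) and `level`.
#' @export
fused_runs <- function(beta, tol = 1e-8) {
  n <- length(beta)
  if (n == 0) {
    return(data.table(first = integer(), last = integer(), level = numeric()))
  }
  brk <- which(abs(diff(beta)) > tol)
  first <- c(1L, brk + 1L)
  last <- c(brk, n)
  data.table(first = first, last = last,
             level = vapply(seq_along(first), function(k) {
               mean(beta[first[k]:last[k]])
             }, numeric(1)))
}

#' Coupled two-condition fused-lasso fit
#'
#' With two conditions, one coefficient vector `beta_ref` carries the
#' methylation of the reference condition and a second vector `beta_diff`
#' carries the difference of the other condition to the reference; both are
#' fusion-penalized with the same `lambda2`:
#' \deqn{\sum_r \sum_i c^{A,r}_i (y^{A,r}_i - \beta^{ref}_i)^2 +
#'       \sum_r \sum_i c^{B,r}_i (y^{B,r}_i - \beta^{ref}_i - \beta^{diff}_i)^2 +
#'       \lambda_2 \sum_{c} \sum_i |\beta^c_i - \beta^c_{i-1}|}
#'
#' Optimized by block coordinate descent alternating exact 1D solves: each
#' block subproblem is itself a weighted fused lasso (see the methods
#' vignette); the fusion penalty separates across blocks, so the descent
#' converges to the joint optimum.
#'
#' @param cmat a two-condition [build_condition_matrix()] result.
#' @param lambda2 fusion strength (default 25, the methylation-scale value).
#' @param tol convergence tolerance on the max absolute change of either
#'   coefficient vector.
#' @param max_iter iteration cap.
#' @return A `two_condition_fit`: per-chromosome list with `pos`,
#'   `beta_ref`, `beta_diff`, `objective`, `iterations`.
#' @export
solve_two_condition <- function(cmat, lambda2 = 25, tol = 1e-6,
                                max_iter = 100L) {
  stopifnot(inherits(cmat, "condition_matrix"))
  if (length(cmat$n_reps) < 2 || cmat$n_reps[2] == 0) {
    stop("second condition absent; use solve_fused_lasso_1d for one condition")
  }
  fits <- lapply(cmat$chroms, function(entry) {
    solve_two_condition_chrom(entry, lambda2, tol, max_iter)
  })
  structure(list(chroms = fits, lambda2 = lambda2),
            class = "two_condition_fit")
}

solve_two_condition_chrom <- function(entry, lambda2, tol, max_iter) {
  ca <- rowSums(entry$cov_a)
  cb <- rowSums(entry$cov_b)
  ma <- rowSums(entry$meth_a)
  mb <- rowSums(entry$meth_b)
  ya <- ifelse(ca > 0, ma / ca, 0)
  yb <- ifelse(cb > 0, mb / cb, 0)
  n <- length(ca)

  beta_diff <- numeric(n)
  beta_ref <- numeric(n)
  it <- 0L
  repeat {
    it <- it + 1L
    # beta_ref block: weighted fused lasso on pooled residuals
    w_ref <- ca + cb
    y_ref <- ifelse(w_ref > 0, (ca * ya + cb * (yb - beta_diff)) / w_ref, 0)
    new_ref <- solve_fused_lasso_1d(y_ref, w_ref, lambda2)$beta
    # beta_diff block: weighted fused lasso on second-condition residuals
    y_diff <- yb - new_ref
    new_diff <- if (all(cb == 0)) {
      numeric(n)
    } else {
      solve_fused_lasso_1d(y_diff, cb, lambda2)$beta
    }
    delta <- max(abs(new_ref - beta_ref), abs(new_diff - beta_diff))
    beta_ref <- new_ref
    beta_diff <- new_diff
    if (delta < tol || it >= max_iter) break
  }
  obj <- two_condition_objective(entry, beta_ref, beta_diff, lambda2)
  list(pos = entry$pos, beta_ref = beta_ref, beta_diff = beta_diff,
       objective = obj, iterations = it)
}

#' Objective of the coupled two-condition model
#'
#' @param entry one chromosome entry of a two-condition matrix.
#' @param beta_ref,beta_diff coefficient vectors.
#' @param lambda2 fusion strength.
#' @return The objective value, summing per-replicate least squares and the
#'   fusion penalties of both coefficient vectors.
#' @export
two_condition_objective <- function(entry, beta_ref, beta_diff, lambda2) {
  obj <- 0
  for (j in seq_len(ncol(entry$cov_a))) {
    cv <- entry$cov_a[, j]
    yv <- ifelse(cv > 0, entry$meth_a[, j] / cv, 0)
    obj <- obj + sum(cv * (yv - beta_ref)^2)
  }
  for (j in seq_len(ncol(entry$cov_b))) {
    cv <- entry$cov_b[, j]
    yv <- ifelse(cv > 0, entry$meth_b[, j] / cv, 0)
    obj <- obj + sum(cv * (yv - beta_ref - beta_diff)^2)
  }
  obj + lambda2 * (sum(abs(diff(beta_ref))) + sum(abs(diff(beta_diff))))
}
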