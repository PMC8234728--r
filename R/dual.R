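#' Solve the soft-margin minimum enclosing ball dual
#'
#' Finds the dual weights of the soft-margin minimum enclosing ball (support
#' vector data description) problem
#' \deqn{\min_\alpha \; \alpha^T K \alpha - \sum_i \alpha_i K_{ii}
#'       \quad \text{s.t.} \quad \sum_i \alpha_i = 1,\; 0 \le \alpha_i \le C.}
#' This is a convex quadratic program over the simplex intersected with a
#' box.  It is solved by pairwise coordinate descent (sequential minimal
#' optimization): starting from the uniform feasible point, weight is moved
#' between the most KKT-violating pair of coordinates until the gradient gap
#' falls below tolerance.  Each pairwise step is solved in closed form, so
#' the iteration is exact, deterministic and monotone; for this convex
#' problem it converges to the global optimum.  A ridge of `1e-10` is added
#' to the Gram diagonal so that among equivalent optima (e.g. duplicated
#' training genes) the minimum-norm solution is returned.
#'
#' @param K Symmetric kernel (Gram) matrix of the training genes.
#' @param C Box constraint (penalty) in `(0, Inf)`; the problem is feasible
#'   only when `nrow(K) * C >= 1`.
#' @return List with components `alpha` (the dual weights) and `objective`
#'   (the dual objective value at `alpha`).
#' @seealso [meb_fit()] which calls this and recovers the ball radius.
#' @export
solve_meb_dual <- function(K, C) {
  K <- as.matrix(K)
  n <- nrow(K)
  if (n == 0L) stop("empty kernel matrix", call. = FALSE)
  if (ncol(K) != n || max(abs(K - t(K))) > 1e-8)
    stop("'K' must be a symmetric square matrix", call. = FALSE)
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0)
    stop("'C' must be a single positive number", call. = FALSE)
  if (n * C < 1 - 1e-12)
    stop("infeasible dual: n * C < 1; with C = ", C,
         " the training set must contain at least ", ceiling(1 / C),
         " genes (it has ", n, ")", call. = FALSE)
  if (n == 1L) {
    alpha <- 1
    return(list(alpha = alpha, objective = meb_dual_objective(alpha, K)))
  }
  Kr <- K
  diag(Kr) <- diag(Kr) + 1e-10
  d <- diag(Kr)
  Cb <- min(C, 1)  # alpha_i <= 1 is implied by the simplex constraint
  alpha <- rep(1 / n, n)
  g <- 2 * drop(Kr %*% alpha) - d
  tol <- 1e-10 * max(1, max(abs(d)))
  maxit <- 200000L
  converged <- FALSE
  for (it in seq_len(maxit)) {
    up <- which(alpha < Cb - 1e-15)  # room to grow
    dn <- which(alpha > 1e-15)       # room to shrink
    if (length(up) == 0L || length(dn) == 0L) { converged <- TRUE; break }
    i <- up[which.min(g[up])]
    j <- dn[which.max(g[dn])]
    gap <- g[j] - g[i]
    if (gap < tol) { converged <- TRUE; break }
    eta <- Kr[i, i] + Kr[j, j] - 2 * Kr[i, j]
    t_step <- min(if (eta > 0) gap / (2 * eta) else Inf,
                  Cb - alpha[i], alpha[j])
    alpha[i] <- alpha[i] + t_step
    alpha[j] <- alpha[j] - t_step
    g <- g + (2 * t_step) * (Kr[, i] - Kr[, j])
  }
  if (!converged)
    warning("dual solver stopped after ", maxit,
            " pairwise updates before reaching tolerance", call. = FALSE)
  alpha[alpha < 1e-15] <- 0
  list(alpha = alpha, objective = meb_dual_objective(alpha, K))
}

meb_dual_objective <- function(alpha, K) {
  drop(crossprod(alpha, K %*% alpha)) - sum(alpha * diag(K))
}

# Squared radius from the KKT conditions: distance to the center for the
# boundary support vectors (sv_tol < alpha < C - sv_tol), averaged for
# numerical stability.  Returns r_squared and the boundary index set.
meb_radius <- function(K, alpha, C, sv_tol = 1e-7 * C) {
  n <- length(alpha)
  if (n == 1L) return(list(r_squared = 0, boundary_sv = 1L))
  quad <- drop(crossprod(alpha, K %*% alpha))
  boundary <- which(alpha > sv_tol & alpha < C - sv_tol)
  if (length(boundary) == 0L)
    stop("no boundary support vector (all dual weights at their bounds); ",
         "refit with a different kernel scale 'nu' or penalty 'C'",
         call. = FALSE)
  d2 <- diag(K)[boundary] - 2 * drop(K[boundary, , drop = FALSE] %*% alpha) + quad
  r2 <- mean(d2)
  if (r2 < 0) {
    if (r2 < -1e-10)
      warning("squared radius ", r2, " clamped to 0", call. = FALSE)
    r2 <- 0
  }
  list(r_squared = r2, boundary_sv = boundary)
}
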