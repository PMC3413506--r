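#' Solve a bounded-variable linear program
#'
#' Maximizes (or minimizes) \code{obj \%*\% x} subject to \code{A x = b}
#' and \code{lb <= x <= ub}, using a dense two-phase primal simplex with
#' bounded variables. Infinite bounds are handled natively (no
#' large-number substitution). Redundant constraint rows are tolerated:
#' phase-1 artificial variables that remain basic at zero are frozen for
#' phase 2. Pivoting uses Dantzig's rule with ties broken by smallest
#' index, switching to Bland's rule after a fixed number of iterations so
#' termination is guaranteed under degeneracy; this makes the returned
#' basis deterministic for a given problem.
#'
#' This is the numerical engine behind [fba()], [fva()] and
#' [geometric_fba()]. Problem sizes in this package are small (tens to a
#' few hundred reactions), for which a dense simplex with a fresh basis
#' factorization per iteration is robust and fast enough.
#'
#' @param obj objective coefficients (length n).
#' @param A constraint matrix (m x n); may have any rank.
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds; \code{-Inf}/\code{Inf} allowed.
#' @param maximize direction; \code{FALSE} minimizes.
#' @param tol feasibility/optimality tolerance (absolute).
#' @param max_iter iteration cap per phase.
#' @return list with \code{status} ("optimal", "infeasible", "unbounded"),
#'   \code{objective} and \code{x} (length n, NA unless optimal).
#' @export
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  n <- length(obj)
  A <- as.matrix(A)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  cvec <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  if (m == 0L) {
    # pure box problem
    x <- ifelse(cvec > tol, ub, ifelse(cvec < -tol, lb, pmax(lb, pmin(ub, 0))))
    if (any(is.infinite(x))) {
      return(list(status = "unbounded", objective = NA_real_,
                  x = rep(NA_real_, n)))
    }
    z <- sum(cvec * x)
    return(list(status = "optimal",
                objective = if (maximize) z else -z, x = x))
  }

  # initial nonbasic values: finite bound nearest zero, else 0 for free vars
  x0 <- numeric(n)
  for (j in seq_len(n)) {
    if (is.finite(lb[j]) && is.finite(ub[j])) {
      x0[j] <- if (abs(lb[j]) <= abs(ub[j])) lb[j] else ub[j]
    } else if (is.finite(lb[j])) x0[j] <- lb[j]
    else if (is.finite(ub[j])) x0[j] <- ub[j]
    else x0[j] <- 0
  }
  r <- b - as.numeric(A %*% x0)
  art_sign <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(art_sign, nrow = m))
  N <- n + m
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  x <- c(x0, abs(r))
  basis <- n + seq_len(m)

  # phase 1: minimize sum of artificials == maximize -sum
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- simplex_iterate(c1, Aext, b, lbe, ube, x, basis, tol, max_iter)
  if (p1$status == "iteration_limit") {
    stop("LP solver: iteration limit reached in phase 1")
  }
  x <- p1$x; basis <- p1$basis
  if (sum(x[(n + 1):N]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  # freeze artificials (redundant rows keep theirs basic at zero)
  lbe[(n + 1):N] <- 0
  ube[(n + 1):N] <- 0
  x[(n + 1):N] <- 0

  c2 <- c(cvec, rep(0, m))
  p2 <- simplex_iterate(c2, Aext, b, lbe, ube, x, basis, tol, max_iter)
  if (p2$status == "iteration_limit") {
    stop("LP solver: iteration limit reached in phase 2")
  }
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  xopt <- p2$x[seq_len(n)]
  z <- sum(cvec * xopt)
  list(status = "optimal", objective = if (maximize) z else -z, x = xopt)
}

# One simplex run (maximization) from a feasible basic solution.
# Returns status "optimal", "unbounded" or "iteration_limit".
simplex_iterate <- function(cvec, A, b, lb, ub, x, basis, tol, max_iter) {
  m <- nrow(A); N <- ncol(A)
  bland_after <- 3L * (N + m)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      return(list(status = "iteration_limit", x = x, basis = basis))
    }
    AB <- A[, basis, drop = FALSE]
    # refresh basic values against accumulated round-off
    nonbasic <- setdiff(seq_len(N), basis)
    rhs <- b - if (length(nonbasic))
      as.numeric(A[, nonbasic, drop = FALSE] %*% x[nonbasic]) else 0
    x[basis] <- solve(AB, rhs)
    y <- solve(t(AB), cvec[basis])
    d <- cvec[nonbasic] - as.numeric(crossprod(A[, nonbasic, drop = FALSE], y))

    at_lb <- abs(x[nonbasic] - lb[nonbasic]) <= 1e-7
    at_ub <- abs(x[nonbasic] - ub[nonbasic]) <= 1e-7
    fixed <- lb[nonbasic] >= ub[nonbasic] - 1e-12
    # candidate may increase (from lb or free) when d > tol,
    # or decrease (from ub or free) when d < -tol
    can_up <- !fixed & d > tol & (at_lb | (!at_lb & !at_ub))
    can_dn <- !fixed & d < -tol & (at_ub | (!at_lb & !at_ub))
    cand <- which(can_up | can_dn)
    if (!length(cand)) {
      return(list(status = "optimal", x = x, basis = basis))
    }
    if (iter > bland_after) {
      k <- cand[which.min(nonbasic[cand])]
    } else {
      k <- cand[which.max(abs(d[cand]))]
    }
    j <- nonbasic[k]
    dir <- if (can_up[k]) 1 else -1

    w <- solve(AB, A[, j])
    # ratio test: how far can x_j move in direction dir?
    step_own <- if (dir > 0) ub[j] - x[j] else x[j] - lb[j]
    best_step <- step_own
    leave <- 0L          # 0: bound flip
    leave_to <- NA_real_
    for (i in seq_len(m)) {
      wi <- dir * w[i]
      bi <- basis[i]
      if (wi > tol) {
        lim <- (x[bi] - lb[bi]) / wi
        tgt <- lb[bi]
      } else if (wi < -tol) {
        lim <- (x[bi] - ub[bi]) / wi
        tgt <- ub[bi]
      } else next
      if (is.nan(lim)) lim <- 0
      if (lim < best_step - 1e-12 ||
          (lim < best_step + 1e-12 && leave > 0L && bi < basis[leave])) {
        best_step <- lim
        leave <- i
        leave_to <- tgt
      }
    }
    if (is.infinite(best_step)) {
      return(list(status = "unbounded", x = x, basis = basis))
    }
    best_step <- max(best_step, 0)
    x[j] <- x[j] + dir * best_step
    x[basis] <- x[basis] - dir * best_step * w
    if (leave > 0L) {
      x[basis[leave]] <- leave_to   # snap exactly to its bound
      basis[leave] <- j
    }
    # else: bound flip, basis unchanged
  }
}
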