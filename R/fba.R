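#' Flux balance analysis
#'
#' Solves the linear program max (or min) \eqn{v_{obj}} subject to the
#' steady-state mass balance \eqn{S v = 0} and the flux bounds
#' \eqn{lb \le v \le ub}, where S is the stoichiometric matrix over
#' non-boundary species. The objective is the flux of a single reaction,
#' conventionally the biomass exchange. A model that cannot grow but
#' admits the zero flux vector is reported as \code{status = "optimal"}
#' with objective 0 (not infeasible), so deletion screens can compare
#' against a viability threshold; infeasibility is reported faithfully
#' when no feasible flux vector exists at all.
#'
#' @param model a \code{metab_model}.
#' @param objective reaction id to optimize; defaults to the model's
#'   objective.
#' @param maximize direction (default TRUE).
#' @param tol solver feasibility/optimality tolerance.
#' @return an object of class \code{fba_solution}: \code{status},
#'   \code{objective} (optimal flux value), \code{fluxes} (named vector,
#'   one entry per reaction).
#' @examples
#' m <- chain_model(3, uptake_bound = 10)
#' sol <- fba(m)
#' sol$objective   # 10: limited by the uptake bound
#' @export
fba <- function(model, objective = model$objective_id, maximize = TRUE,
                tol = 1e-9) {
  stopifnot(inherits(model, "metab_model"))
  if (is.null(objective)) stop("no objective reaction given and model has none")
  if (!objective %in% names(model$reactions)) {
    stop("objective reaction '", objective, "' not in model")
  }
  S <- stoich_matrix(model)
  bounds <- flux_bounds(model)
  n <- ncol(S)
  cvec <- as.numeric(colnames(S) == objective)
  res <- lp_solve(cvec, S, rep(0, nrow(S)), bounds[, "lb"], bounds[, "ub"],
                  maximize = maximize, tol = tol)
  fluxes <- res$x
  names(fluxes) <- colnames(S)
  structure(list(status = res$status, objective = res$objective,
                 fluxes = fluxes, objective_id = objective,
                 maximize = maximize, model_id = model$id),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("<fba_solution> ", x$model_id, ", objective '", x$objective_id, "' (",
      if (x$maximize) "max" else "min", ")\n", sep = "")
  cat("  status:    ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat("  objective: ", format(x$objective, digits = 6), "\n", sep = "")
    nz <- sum(abs(x$fluxes) > 1e-9)
    cat("  fluxes:    ", length(x$fluxes), " reactions (", nz,
        " carrying flux)\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.fba_solution <- function(object, ...) object$fluxes

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux subject
#' to the steady-state constraint, the model bounds, and (when
#' \code{fraction > 0}) the requirement that the objective flux stays at
#' or above \code{fraction} times its FBA optimum. \code{fraction = 0}
#' leaves the objective unconstrained, the regime used for blocked-
#' reaction detection.
#'
#' @param model a \code{metab_model}.
#' @param reactions reaction ids to scan (default: all).
#' @param fraction required fraction of the FBA optimum, in [0, 1].
#' @param objective objective reaction id.
#' @param tol solver tolerance.
#' @return data.frame with columns \code{reaction}, \code{min},
#'   \code{max}; ranges may be infinite for unbounded directions.
#' @export
fva <- function(model, reactions = NULL, fraction = 1.0,
                objective = model$objective_id, tol = 1e-9) {
  stopifnot(inherits(model, "metab_model"), fraction >= 0, fraction <= 1)
  S <- stoich_matrix(model)
  bounds <- flux_bounds(model)
  if (is.null(reactions)) reactions <- colnames(S)
  stopifnot(all(reactions %in% colnames(S)))
  if (fraction > 0) {
    if (is.null(objective)) stop("objective required when fraction > 0")
    base <- fba(model, objective = objective)
    if (base$status != "optimal") {
      stop("base FBA problem is ", base$status, "; cannot run FVA")
    }
    j <- match(objective, colnames(S))
    bounds[j, "lb"] <- max(bounds[j, "lb"], fraction * base$objective)
  }
  mins <- maxs <- numeric(length(reactions))
  zero <- rep(0, nrow(S))
  for (k in seq_along(reactions)) {
    cvec <- as.numeric(colnames(S) == reactions[k])
    lo <- lp_solve(cvec, S, zero, bounds[, "lb"], bounds[, "ub"],
                   maximize = FALSE, tol = tol)
    hi <- lp_solve(cvec, S, zero, bounds[, "lb"], bounds[, "ub"],
                   maximize = TRUE, tol = tol)
    if (lo$status == "infeasible" || hi$status == "infeasible") {
      stop("FVA subproblem infeasible for reaction '", reactions[k], "'")
    }
    mins[k] <- if (lo$status == "unbounded") -Inf else lo$objective
    maxs[k] <- if (hi$status == "unbounded") Inf else hi$objective
  }
  data.frame(reaction = reactions, min = mins, max = maxs,
             stringsAsFactors = FALSE)
}

#' Geometric flux balance analysis
#'
#' Selects a unique, central flux distribution among the alternate
#' optima of FBA. The objective flux is fixed at its optimum; then,
#' iteratively, flux variability ranges delimit the current optimal box,
#' and the summed absolute deviation from the range midpoints is
#' minimized; the constraint that this total deviation stays at its
#' minimum is added, and the process repeats until the bounding box
#' contracts below \code{tol}. The feasible set at every step is defined
#' by the problem data alone, so the result is invariant under reaction
#' reordering and solver restarts (to within \code{tol}).
#'
#' @param model a \code{metab_model}.
#' @param objective objective reaction id.
#' @param tol convergence tolerance on the maximal range width.
#' @param max_iter iteration cap.
#' @return an \code{fba_solution} whose fluxes are the centered optimum;
#'   carries attribute \code{iterations}.
#' @export
geometric_fba <- function(model, objective = model$objective_id,
                          tol = 1e-6, max_iter = 50L) {
  stopifnot(inherits(model, "metab_model"))
  base <- fba(model, objective = objective)
  if (base$status == "unbounded") {
    stop("FBA optimum is unbounded; tighten exchange bounds before geometric FBA")
  }
  if (base$status != "optimal") stop("FBA problem is ", base$status)

  S <- stoich_matrix(model)
  n <- ncol(S); m <- nrow(S)
  rxns <- colnames(S)
  bounds <- flux_bounds(model)
  j <- match(objective, rxns)
  bounds[j, ] <- c(base$objective, base$objective)

  # growing constraint system over variables (v, t_1..t_K blocks)
  # rows: S v = 0; per block k: v - t_k <= p_k, v + t_k >= p_k, sum(t_k) <= D_k
  Aeq <- S
  beq <- rep(0, m)
  lb <- bounds[, "lb"]; ub <- bounds[, "ub"]
  v_cur <- base$fluxes
  iter <- 0L
  repeat {
    iter <- iter + 1L
    rng <- fva_box(Aeq, beq, lb, ub, n, tol = 1e-9)
    if (any(!is.finite(rng))) {
      stop("optimal face is unbounded; tighten bounds before geometric FBA")
    }
    lb[seq_len(n)] <- rng[, 1]
    ub[seq_len(n)] <- rng[, 2]
    width <- max(rng[, 2] - rng[, 1])
    if (width < tol || iter > max_iter) break

    p <- (rng[, 1] + rng[, 2]) / 2
    nv <- length(lb)
    # append t block: t_i >= |v_i - p_i| via two slack-completed rows each
    # v_i - t_i + s1_i = p_i ; v_i + t_i - s2_i = p_i ; s1, s2 >= 0
    Zt <- matrix(0, nrow(Aeq), 2 * n)
    A1 <- cbind(Aeq, Zt, matrix(0, nrow(Aeq), n))
    row1 <- cbind(diag_sub(nv, n), -diag(n), diag(n), matrix(0, n, n))
    row2 <- cbind(diag_sub(nv, n), diag(n), matrix(0, n, n), -diag(n))
    Aeq2 <- rbind(A1, row1, row2)
    beq2 <- c(beq, p, p)
    lb2 <- c(lb, rep(0, 3 * n))
    ub2 <- c(ub, rep(Inf, 3 * n))
    cdev <- c(rep(0, nv), rep(1, n), rep(0, 2 * n))
    sol <- lp_solve(cdev, Aeq2, beq2, lb2, ub2, maximize = FALSE)
    if (sol$status != "optimal") {
      stop("geometric FBA centering LP returned status ", sol$status)
    }
    Dk <- sol$objective
    v_cur <- sol$x[seq_len(n)]
    names(v_cur) <- rxns
    # keep the block, frozen at total deviation <= Dk (one extra row with slack)
    Aeq <- cbind(Aeq2, 0)
    Aeq <- rbind(Aeq, c(rep(0, nv), rep(1, n), rep(0, 2 * n), 1))
    beq <- c(beq2, Dk + 0.5 * tol)     # slack against round-off
    lb <- c(lb2, 0)
    ub <- c(ub2, Inf)
  }
  out <- structure(list(status = "optimal", objective = base$objective,
                        fluxes = v_cur, objective_id = objective,
                        maximize = base$maximize, model_id = model$id),
                   class = "fba_solution")
  attr(out, "iterations") <- iter
  out
}

# min/max each of the first n variables subject to Aeq x = beq, lb<=x<=ub
fva_box <- function(Aeq, beq, lb, ub, n, tol = 1e-9) {
  out <- matrix(NA_real_, n, 2)
  nv <- length(lb)
  for (k in seq_len(n)) {
    if (ub[k] - lb[k] < 1e-12) { out[k, ] <- c(lb[k], ub[k]); next }
    cvec <- numeric(nv); cvec[k] <- 1
    lo <- lp_solve(cvec, Aeq, beq, lb, ub, maximize = FALSE, tol = tol)
    hi <- lp_solve(cvec, Aeq, beq, lb, ub, maximize = TRUE, tol = tol)
    out[k, 1] <- if (lo$status == "unbounded") -Inf else lo$objective
    out[k, 2] <- if (hi$status == "unbounded") Inf else hi$objective
    if (lo$status == "infeasible" || hi$status == "infeasible") {
      stop("variability subproblem infeasible (variable ", k, ")")
    }
  }
  # guard against crossing from round-off
  bad <- out[, 1] > out[, 2]
  if (any(bad)) {
    mid <- (out[bad, 1] + out[bad, 2]) / 2
    out[bad, 1] <- mid; out[bad, 2] <- mid
  }
  out
}

# identity on the first n of nv columns
diag_sub <- function(nv, n) {
  M <- matrix(0, n, nv)
  M[cbind(seq_len(n), seq_len(n))] <- 1
  M
}
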