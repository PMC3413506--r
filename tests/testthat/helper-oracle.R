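# Independent brute-force LP oracle: enumerates all basic solutions
# (choose a full-rank basis of size rank(A); every non-basic variable sits
# at a finite bound), keeps the feasible ones, and returns the best
# objective. Exponential, so only for problems with ~<= 12 variables and
# finite bounds on all non-basic candidates. Deliberately shares no code
# with the package's simplex.
enumerate_lp_optimum <- function(cvec, A, b, lb, ub, maximize = TRUE,
                                 tol = 1e-7) {
  n <- length(cvec)
  A <- as.matrix(A)
  qrA <- qr(A)
  r <- qrA$rank
  best <- -Inf
  best_x <- NULL
  finite_both <- is.finite(lb) & is.finite(ub)
  must_basic <- which(!is.finite(lb) & !is.finite(ub))
  basis_sets <- utils::combn(n, r, simplify = FALSE)
  for (J in basis_sets) {
    if (length(setdiff(must_basic, J))) next
    AJ <- A[, J, drop = FALSE]
    if (qr(AJ)$rank < r) next
    N <- setdiff(seq_len(n), J)
    # each nonbasic var at one of its finite bounds
    choices <- lapply(N, function(j) {
      v <- c(if (is.finite(lb[j])) lb[j], if (is.finite(ub[j])) ub[j])
      unique(v)
    })
    if (any(lengths(choices) == 0)) next
    grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
    for (gi in seq_len(max(1L, nrow(grid)))) {
      x <- numeric(n)
      if (length(N)) x[N] <- as.numeric(grid[gi, ])
      rhs <- b - if (length(N)) as.numeric(A[, N, drop = FALSE] %*% x[N]) else b * 0
      xJ <- tryCatch(qr.solve(AJ, rhs), error = function(e) NULL)
      if (is.null(xJ)) next
      x[J] <- xJ
      if (max(abs(A %*% x - b)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      z <- sum(cvec * x)
      zz <- if (maximize) z else -z
      if (zz > best) { best <- zz; best_x <- x }
    }
  }
  if (is.null(best_x)) return(list(feasible = FALSE, objective = NA_real_))
  list(feasible = TRUE,
       objective = if (maximize) best else -best, x = best_x)
}

# Oracle FBA of a metab_model via enumeration (finite-bound models only).
enumerate_fba_optimum <- function(model, objective = model$objective_id) {
  S <- stoich_matrix(model)
  bounds <- flux_bounds(model)
  cvec <- as.numeric(colnames(S) == objective)
  enumerate_lp_optimum(cvec, S, rep(0, nrow(S)),
                       bounds[, "lb"], bounds[, "ub"], maximize = TRUE)
}

# truth table of a GPR over all deletion subsets of its genes
gpr_truth_table <- function(g) {
  genes <- sort(gpr_genes(g))
  if (!length(genes)) return(gpr_eval(g, character()))
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(genes)))
  apply(subsets, 1, function(del) gpr_eval(g, genes[as.logical(del)]))
}
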