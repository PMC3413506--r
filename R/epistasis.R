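#' Multiplicative epistasis
#'
#' The nonscaled multiplicative definition: epsilon = W_xy - W_x W_y,
#' where W_x and W_y are single-perturbation fitnesses and W_xy the
#' double-perturbation fitness. Any epsilon different from 0 (beyond a
#' tolerance) indicates a genetic interaction under the assumption that
#' the two genes contribute independently and multiplicatively to
#' fitness; epsilon > 0 is alleviating (positive) epistasis, epsilon < 0
#' aggravating (negative).
#'
#' @param w_x,w_y,w_xy fitnesses in [0, 1] (vectorized).
#' @return numeric epsilon values (always in [-1, 1]).
#' @examples
#' epsilon(0.5, 0.5, 0.25)  # 0: perfectly multiplicative
#' epsilon(0.5, 0.5, 0.1)   # -0.15: aggravating interaction
#' @export
epsilon <- function(w_x, w_y, w_xy) {
  vals <- c(w_x, w_y, w_xy)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("fitness values must lie in [0, 1]")
  }
  w_xy - w_x * w_y
}

#' FBA fitness of a perturbed model
#'
#' Fitness is the maximal biomass production rate of the perturbed model
#' relative to the wild type: deletions are applied through GPR logic and
#' flux restrictions through [restrict_gene_flux()] against the reference
#' solution, then one FBA is run and the objective divided by
#' \code{wild_type}. The ratio is clamped to [0, 1] at solver tolerance;
#' an infeasible perturbed problem scores fitness 0 (with attribute
#' \code{infeasible = TRUE}).
#'
#' @param model a \code{metab_model} (unperturbed).
#' @param deleted character vector of genes to delete.
#' @param restrict named numeric vector: gene id -> restriction fraction
#'   in [0, 1] of the reference flux.
#' @param reference an \code{fba_solution} of the unperturbed model
#'   (geometric FBA recommended: it is unique); required when
#'   \code{restrict} is non-empty.
#' @param wild_type wild-type objective (> 0); defaults to the
#'   reference's objective.
#' @param sign_preserving passed to [restrict_gene_flux()].
#' @return fitness in [0, 1].
#' @export
fba_fitness <- function(model, deleted = character(), restrict = NULL,
                        reference = NULL, wild_type = NULL,
                        sign_preserving = FALSE) {
  stopifnot(inherits(model, "metab_model"))
  if (is.null(wild_type)) {
    if (is.null(reference)) stop("supply wild_type or reference")
    wild_type <- reference$objective
  }
  stopifnot(wild_type > 0)
  if (length(deleted)) model <- apply_deletions(model, deleted)
  if (length(restrict)) {
    stopifnot(!is.null(names(restrict)), !is.null(reference))
    for (g in names(restrict)) {
      model <- restrict_gene_flux(model, g, restrict[[g]], reference,
                                  sign_preserving = sign_preserving)
    }
  }
  sol <- fba(model)
  if (sol$status != "optimal") {
    out <- 0
    attr(out, "infeasible") <- TRUE
    return(out)
  }
  max(0, min(1, sol$objective / wild_type))
}

#' Pairwise epistasis screen under fractional flux restriction
#'
#' Computes the wild-type geometric FBA reference once; restricts each
#' gene's reactions to \code{fraction} of their reference flux to obtain
#' single fitnesses W; then, for every unordered gene pair, restricts
#' both genes' reaction sets simultaneously (a reaction annotated to
#' both genes is capped once -- bounds are set, not compounded) to obtain
#' W_xy and epsilon = W_xy - W_x W_y. Pairs with |epsilon| above
#' \code{tolerance} count as interactions. Because the interaction count
#' depends on that cutoff, counts at tolerance/10 and tolerance*10 are
#' reported alongside.
#'
#' Optional checkpointing: with a \code{checkpoint} file path, completed
#' pairs are saved every \code{checkpoint_every} pairs in the (fixed,
#' deterministic) enumeration order, and an interrupted screen resumes
#' from the file.
#'
#' @param model a \code{metab_model}.
#' @param fraction flux-restriction fraction in [0, 1].
#' @param tolerance interaction cutoff on |epsilon| (default 1e-4).
#' @param genes genes to screen (default: all; sorted for determinism).
#' @param reference optional precomputed geometric FBA solution.
#' @param sign_preserving passed to [restrict_gene_flux()].
#' @param checkpoint optional RDS path for resumable screening.
#' @param checkpoint_every pairs between checkpoint writes.
#' @return an object of class \code{epistasis_result}: the restriction
#'   fraction, wild-type objective, per-gene fitness vector \code{W},
#'   per-pair data.frame \code{pairs} (gene_x, gene_y, w_x, w_y, w_xy,
#'   epsilon), interaction \code{counts}, and
#'   \code{counts_by_tolerance}.
#' @export
pairwise_screen <- function(model, fraction = 0.5, tolerance = 1e-4,
                            genes = NULL, reference = NULL,
                            sign_preserving = FALSE,
                            checkpoint = NULL, checkpoint_every = 200L) {
  stopifnot(inherits(model, "metab_model"), fraction >= 0, fraction <= 1)
  if (is.null(reference)) reference <- geometric_fba(model)
  wt <- reference$objective
  stopifnot(wt > 0)
  genes <- if (is.null(genes)) model_genes(model) else sort(unique(genes))
  if (length(genes) < 2L) stop("need at least two genes for a pairwise screen")

  W <- vapply(genes, function(g) {
    fba_fitness(model, restrict = stats::setNames(fraction, g),
                reference = reference, wild_type = wt,
                sign_preserving = sign_preserving)
  }, numeric(1))

  pair_idx <- utils::combn(length(genes), 2L)
  n_pairs <- ncol(pair_idx)
  w_xy <- rep(NA_real_, n_pairs)
  start <- 1L
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    ck <- readRDS(checkpoint)
    if (identical(ck$genes, genes) && identical(ck$fraction, fraction)) {
      w_xy <- ck$w_xy
      start <- ck$next_pair
    }
  }
  if (start <= n_pairs) {
    for (p in start:n_pairs) {
      gx <- genes[pair_idx[1L, p]]; gy <- genes[pair_idx[2L, p]]
      w_xy[p] <- fba_fitness(model,
                             restrict = stats::setNames(c(fraction, fraction),
                                                        c(gx, gy)),
                             reference = reference, wild_type = wt,
                             sign_preserving = sign_preserving)
      if (!is.null(checkpoint) &&
          (p %% checkpoint_every == 0L || p == n_pairs)) {
        saveRDS(list(genes = genes, fraction = fraction, w_xy = w_xy,
                     next_pair = p + 1L), checkpoint)
      }
    }
  }
  pairs <- data.frame(gene_x = genes[pair_idx[1L, ]],
                      gene_y = genes[pair_idx[2L, ]],
                      w_x = unname(W[pair_idx[1L, ]]),
                      w_y = unname(W[pair_idx[2L, ]]),
                      w_xy = w_xy, stringsAsFactors = FALSE)
  pairs$epsilon <- pairs$w_xy - pairs$w_x * pairs$w_y
  count_at <- function(tol) {
    c(total = sum(abs(pairs$epsilon) > tol),
      positive = sum(pairs$epsilon > tol),
      negative = sum(pairs$epsilon < -tol))
  }
  counts <- count_at(tolerance)
  tols <- c(tolerance / 10, tolerance, tolerance * 10)
  sens <- data.frame(tolerance = tols,
                     t(vapply(tols, count_at, numeric(3))))
  structure(list(fraction = fraction, tolerance = tolerance,
                 wild_type = wt, genes = genes, W = W, pairs = pairs,
                 counts = as.list(counts),
                 fraction_interacting = counts[["total"]] / n_pairs,
                 counts_by_tolerance = sens),
            class = "epistasis_result")
}

#' @export
print.epistasis_result <- function(x, ...) {
  cat("<epistasis_result> restriction fraction ", x$fraction,
      ", ", length(x$genes), " genes, ", nrow(x$pairs), " pairs\n", sep = "")
  cat(sprintf("  interactions (|epsilon| > %g): %d  (%d positive, %d negative; %.1f%% of pairs)\n",
              x$tolerance, x$counts$total, x$counts$positive,
              x$counts$negative, 100 * x$fraction_interacting))
  invisible(x)
}

#' Epistasis across a grid of restriction fractions
#'
#' Runs one full [pairwise_screen()] per fraction (default: 0 to 90
#' percent of wild-type flux in 10-percent steps) and tabulates the
#' interaction counts per level.
#'
#' @param model a \code{metab_model}.
#' @param fractions restriction fractions to scan.
#' @param tolerance interaction cutoff.
#' @param genes genes to screen.
#' @return list of class \code{restriction_profile}: \code{summary}
#'   data.frame (fraction, total, positive, negative,
#'   fraction_interacting) and \code{screens}, the per-fraction results.
#' @export
restriction_profile <- function(model, fractions = seq(0, 0.9, by = 0.1),
                                tolerance = 1e-4, genes = NULL) {
  stopifnot(inherits(model, "metab_model"))
  reference <- geometric_fba(model)
  screens <- lapply(fractions, function(f) {
    pairwise_screen(model, fraction = f, tolerance = tolerance,
                    genes = genes, reference = reference)
  })
  summary <- data.frame(
    fraction = fractions,
    total = vapply(screens, function(s) s$counts$total, numeric(1)),
    positive = vapply(screens, function(s) s$counts$positive, numeric(1)),
    negative = vapply(screens, function(s) s$counts$negative, numeric(1)),
    fraction_interacting = vapply(screens, `[[`, numeric(1),
                                  "fraction_interacting"))
  structure(list(summary = summary, screens = screens,
                 tolerance = tolerance),
            class = "restriction_profile")
}

#' @export
print.restriction_profile <- function(x, ...) {
  cat("<restriction_profile> interaction counts by flux-restriction level\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write per-pair and summary epistasis TSVs
#'
#' @param result an \code{epistasis_result}.
#' @param pairs_path,summary_path output TSV paths (either may be NULL).
#' @return invisibly, the paths written.
#' @export
write_epistasis_tsv <- function(result, pairs_path = NULL, summary_path = NULL) {
  stopifnot(inherits(result, "epistasis_result"))
  if (!is.null(pairs_path)) {
    utils::write.table(result$pairs, pairs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    utils::write.table(result$counts_by_tolerance, summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(pairs_path, summary_path))
}
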