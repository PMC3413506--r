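#' Read a gene list file
#'
#' One ORF name per line; \code{#} starts a comment; blank lines and
#' surrounding whitespace ignored. Matching elsewhere in the package is
#' by exact, case-sensitive name.
#'
#' @param path text file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Single-gene deletion screen
#'
#' Deletes each gene in turn (via GPR logic) and records the maximal
#' biomass objective. The wild type is solved once; a deletion is called
#' viable when its objective exceeds \code{threshold} times the
#' wild-type objective. Genes whose deletion disables no reaction are
#' scored at the wild-type objective without re-solving.
#'
#' @param model a \code{metab_model}.
#' @param medium optional \code{medium_spec} applied first.
#' @param genes genes to screen (default: all model genes).
#' @param threshold relative viability threshold (default 1e-6).
#' @return data.frame of class \code{deletion_screen} with columns
#'   \code{gene}, \code{objective}, \code{viable}; attribute
#'   \code{wild_type} holds the wild-type objective.
#' @export
single_deletion_screen <- function(model, medium = NULL, genes = NULL,
                                   threshold = 1e-6) {
  stopifnot(inherits(model, "metab_model"))
  if (!is.null(medium)) model <- apply_medium(model, medium)
  genes <- if (is.null(genes)) model_genes(model) else sort(unique(genes))
  if (!length(genes)) stop("model has no genes to screen")
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective <= 0) {
    stop("wild type does not grow in this medium (status ", wt$status,
         ", objective ", wt$objective, "); screen is meaningless")
  }
  objective <- vapply(genes, function(g) {
    affected <- vapply(model$reactions, function(r) {
      r$gpr$kind != "none" && !gpr_eval(r$gpr, g)
    }, logical(1))
    if (!any(affected)) return(wt$objective)
    sol <- fba(apply_deletions(model, g))
    if (sol$status == "optimal") sol$objective else 0
  }, numeric(1))
  out <- data.frame(gene = genes, objective = unname(objective),
                    viable = unname(objective) > threshold * wt$objective,
                    stringsAsFactors = FALSE)
  attr(out, "wild_type") <- wt$objective
  attr(out, "threshold") <- threshold
  class(out) <- c("deletion_screen", "data.frame")
  out
}

#' Score essentiality predictions against gene lists
#'
#' Follows the screening convention in which "positive" means the model
#' predicts growth: a gene on neither list (considered inessential) whose
#' deletion still grows is a true positive; a listed gene (essential or
#' auxotroph-inducing, i.e. expected not to grow on minimal medium) whose
#' deletion does not grow is a true negative. Derived metrics:
#' sensitivity tp/(tp+fn), specificity tn/(tn+fp), positive and negative
#' predictive values, and \code{combined_accuracy}, the product
#' sensitivity x specificity (the literature sometimes labels this
#' product a "geometric mean"; the printed values follow the product).
#'
#' @param screen a \code{deletion_screen}.
#' @param essential character vector of essential gene ids.
#' @param auxotroph character vector of auxotroph-inducing gene ids
#'   (counted as condition-negative together with \code{essential}).
#' @return an object of class \code{confusion_matrix}.
#' @export
score_essentiality <- function(screen, essential, auxotroph = character()) {
  stopifnot(inherits(screen, "deletion_screen"))
  listed <- union(essential, auxotroph)
  unmatched <- setdiff(listed, screen$gene)
  neg <- screen$gene %in% listed
  pos_pred <- screen$viable
  cm <- confusion_matrix(tp = sum(pos_pred & !neg),
                         fn = sum(!pos_pred & !neg),
                         fp = sum(pos_pred & neg),
                         tn = sum(!pos_pred & neg))
  attr(cm, "unmatched_list_genes") <- unmatched
  cm
}

#' @rdname score_essentiality
#' @param tp,fn,fp,tn non-negative integer counts (see above for the
#'   screening semantics).
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn)),
            class = "confusion_matrix")
}

#' Predictive metrics of a confusion matrix
#'
#' @param x a \code{confusion_matrix}.
#' @return named numeric vector: \code{sensitivity}, \code{specificity},
#'   \code{ppv}, \code{npv}, \code{combined_accuracy} (the product of
#'   sensitivity and specificity).
#' @export
confusion_metrics <- function(x) {
  stopifnot(inherits(x, "confusion_matrix"))
  sens <- x$tp / (x$tp + x$fn)
  spec <- x$tn / (x$tn + x$fp)
  c(sensitivity = sens, specificity = spec,
    ppv = x$tp / (x$tp + x$fp), npv = x$tn / (x$tn + x$fn),
    combined_accuracy = sens * spec)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (positive = predicted growth)\n")
  cat(sprintf("  TP %5d   FN %5d\n  FP %5d   TN %5d\n", x$tp, x$fn, x$fp, x$tn))
  m <- confusion_metrics(x)
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  ppv %.1f%%  npv %.1f%%\n",
              100 * m["sensitivity"], 100 * m["specificity"],
              100 * m["ppv"], 100 * m["npv"]))
  cat(sprintf("  combined accuracy (sens x spec) %.2f%%\n",
              100 * m["combined_accuracy"]))
  invisible(x)
}

#' Auxotrophy screen
#'
#' For each gene, runs one deletion FBA on the minimal medium and one on
#' the supplemented medium and classifies: no growth on minimal but
#' growth on supplemented is the expected auxotroph behaviour
#' (\code{"auxotroph_confirmed"}); growth on minimal contradicts the
#' auxotrophic phenotype (\code{"viable_in_minimal"}); growth in neither
#' means the model wrongly predicts the deletion cannot be rescued by
#' supplementation (\code{"inviable_in_supplemented"}).
#'
#' @param model a \code{metab_model}.
#' @param genes genes to screen (typically the auxotroph-inducing list
#'   intersected with the model's genes).
#' @param minimal,supplemented \code{medium_spec}s; the wild type must
#'   grow in both.
#' @param threshold relative viability threshold.
#' @return data.frame of class \code{auxotrophy_screen} with columns
#'   \code{gene}, \code{objective_minimal}, \code{objective_supplemented},
#'   \code{category}.
#' @export
auxotrophy_screen <- function(model, genes, minimal, supplemented,
                              threshold = 1e-6) {
  s_min <- single_deletion_screen(model, medium = minimal, genes = genes,
                                  threshold = threshold)
  s_sup <- single_deletion_screen(model, medium = supplemented, genes = genes,
                                  threshold = threshold)
  stopifnot(identical(s_min$gene, s_sup$gene))
  category <- ifelse(s_min$viable, "viable_in_minimal",
                     ifelse(s_sup$viable, "auxotroph_confirmed",
                            "inviable_in_supplemented"))
  out <- data.frame(gene = s_min$gene,
                    objective_minimal = s_min$objective,
                    objective_supplemented = s_sup$objective,
                    category = category, stringsAsFactors = FALSE)
  class(out) <- c("auxotrophy_screen", "data.frame")
  out
}

#' Compare several models in one table
#'
#' Emits per-model census counts and, when gene lists and media are
#' supplied, viability and auxotrophy metrics. A model whose screen
#' fails contributes a row of NAs with a warning; the table is still
#' emitted for the rest.
#'
#' @param models named list of \code{metab_model}s.
#' @param essential,auxotroph gene lists (optional; enable the viability
#'   block).
#' @param minimal,supplemented either a single \code{medium_spec} used
#'   for every model or a named list parallel to \code{models}
#'   (optional; \code{supplemented} enables the auxotrophy block).
#' @param blocked logical: also compute the blocked-reaction fraction
#'   (all exchanges open); off by default as it runs one FVA per model.
#' @return data.frame, one row per model.
#' @export
compare_models <- function(models, essential = NULL, auxotroph = NULL,
                           minimal = NULL, supplemented = NULL,
                           blocked = FALSE) {
  stopifnot(is.list(models), length(models) >= 1)
  if (is.null(names(models))) {
    names(models) <- vapply(models, `[[`, character(1), "id")
  }
  pick <- function(x, nm) {
    if (is.null(x) || inherits(x, "medium_spec")) x else x[[nm]]
  }
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    row <- data.frame(model = nm,
                      metabolites = nrow(m$species),
                      reactions = length(m$reactions),
                      genes = length(model_genes(m)),
                      exchange = length(exchange_reactions(m)),
                      isa = length(isa_reactions(m)),
                      blocked_fraction = NA_real_,
                      sensitivity = NA_real_, specificity = NA_real_,
                      ppv = NA_real_, npv = NA_real_,
                      combined_accuracy = NA_real_,
                      auxotroph_confirmed = NA_integer_,
                      viable_in_minimal = NA_integer_,
                      inviable_in_supplemented = NA_integer_,
                      stringsAsFactors = FALSE)
    tryCatch({
      if (blocked) {
        row$blocked_fraction <- blocked_reactions(m)$fraction
      }
      if (!is.null(essential)) {
        scr <- single_deletion_screen(m, medium = pick(minimal, nm))
        met <- confusion_metrics(score_essentiality(scr, essential, auxotroph))
        row[names(met)] <- as.list(met)
      }
      if (!is.null(auxotroph) && !is.null(supplemented)) {
        aux_genes <- intersect(auxotroph, model_genes(m))
        if (length(aux_genes)) {
          aux <- auxotrophy_screen(m, aux_genes, pick(minimal, nm),
                                   pick(supplemented, nm))
          tab <- table(factor(aux$category,
                              levels = c("auxotroph_confirmed",
                                         "viable_in_minimal",
                                         "inviable_in_supplemented")))
          row$auxotroph_confirmed <- tab[["auxotroph_confirmed"]]
          row$viable_in_minimal <- tab[["viable_in_minimal"]]
          row$inviable_in_supplemented <- tab[["inviable_in_supplemented"]]
        }
      }
      row
    }, error = function(e) {
      warning("model '", nm, "' failed: ", conditionMessage(e))
      row
    })
  })
  do.call(rbind, rows)
}
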