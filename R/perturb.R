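#' Growth-medium specifications
#'
#' A medium is a table of exchange-reaction bounds. Applying it replaces
#' the listed exchange bounds and closes every unlisted exchange reaction
#' to uptake (lower bound 0) while leaving it open to export, so the
#' medium fully determines what the simulation may import. Under the
#' exchange sign convention, uptake is negative flux: a lower bound of
#' \code{-10} allows uptake at rate up to 10.
#'
#' @param reactions character vector of exchange reaction ids.
#' @param lb,ub numeric bounds, recycled to \code{length(reactions)}.
#' @param name tag for reports.
#' @return a data.frame of class \code{medium_spec} with columns
#'   \code{reaction}, \code{lb}, \code{ub}.
#' @examples
#' m <- chain_model(3, 10)
#' med <- medium_spec("EX_nutrient", lb = -5)
#' fba(apply_medium(m, med))$objective  # 5
#' @export
medium_spec <- function(reactions, lb = -Inf, ub = Inf, name = "medium") {
  out <- data.frame(reaction = as.character(reactions),
                    lb = rep_len(as.numeric(lb), length(reactions)),
                    ub = rep_len(as.numeric(ub), length(reactions)),
                    stringsAsFactors = FALSE)
  attr(out, "medium_name") <- name
  class(out) <- c("medium_spec", "data.frame")
  out
}

#' @rdname medium_spec
#' @param model a \code{metab_model} (for \code{open_medium}: the model
#'   whose exchange reactions are all opened to uptake, the package's
#'   operationalization of a "supplemented" or maximal medium).
#' @param uptake uptake magnitude for every exchange reaction.
#' @export
open_medium <- function(model, uptake = Inf) {
  ex <- exchange_reactions(model)
  medium_spec(ex, lb = -abs(uptake), ub = Inf, name = "supplemented")
}

#' @rdname medium_spec
#' @param path TSV file with columns \code{reaction}, \code{lb},
#'   \code{ub} (header required; \code{Inf}/\code{-Inf} accepted).
#' @export
read_medium_tsv <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("reaction", "lb", "ub") %in% names(df)))
  medium_spec(df$reaction, df$lb, df$ub, name = name)
}

#' @rdname medium_spec
#' @export
write_medium_tsv <- function(medium, path) {
  utils::write.table(as.data.frame(medium)[, c("reaction", "lb", "ub")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply a medium to a model
#'
#' @param model a \code{metab_model}.
#' @param medium a \code{medium_spec}.
#' @return a new \code{metab_model}; the input is not modified.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(model, "metab_model"), inherits(medium, "medium_spec"))
  ex <- exchange_reactions(model)
  bad <- setdiff(medium$reaction, ex)
  if (length(bad)) {
    stop("medium lists non-exchange (or unknown) reactions: ",
         paste(bad, collapse = ", "))
  }
  for (rid in setdiff(ex, medium$reaction)) {
    model$reactions[[rid]]$lb <- max(model$reactions[[rid]]$lb, 0)
  }
  for (k in seq_len(nrow(medium))) {
    model <- set_bounds(model, medium$reaction[k],
                        lb = medium$lb[k], ub = medium$ub[k])
  }
  model
}

#' Delete genes from a model via GPR logic
#'
#' Every reaction whose GPR rule evaluates FALSE under the deletion set
#' gets bounds (0, 0); all other reactions are untouched. Unknown gene
#' ids produce a warning, not an error.
#'
#' @param model a \code{metab_model}.
#' @param genes character vector of gene ids to delete.
#' @return a new \code{metab_model}.
#' @export
apply_deletions <- function(model, genes) {
  stopifnot(inherits(model, "metab_model"))
  genes <- unique(as.character(genes))
  unknown <- setdiff(genes, model_genes(model))
  if (length(unknown)) {
    warning("genes not in model (ignored): ", paste(unknown, collapse = ", "))
  }
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    if (r$gpr$kind != "none" && !gpr_eval(r$gpr, genes)) {
      model$reactions[[rid]]$lb <- 0
      model$reactions[[rid]]$ub <- 0
    }
  }
  model
}

#' Anaerobic transform
#'
#' Reconfigures a model for anaerobic growth simulation: closes the
#' oxygen exchange to uptake, opens the supplement exchanges (in yeast:
#' ergosterol, lanosterol, zymosterol and phosphatidate, reflecting the
#' sterol and fatty-acid requirement of anaerobically grown cultures),
#' disables the aerobic lipid pseudoreaction and enables the anaerobic
#' variant, thereby switching the biomass definition to the
#' sterol-reduced one.
#'
#' @param model a \code{metab_model}.
#' @param oxygen_exchange id of the oxygen exchange reaction.
#' @param supplement_exchanges ids of supplement exchange reactions to
#'   open to uptake.
#' @param aerobic_lipid,anaerobic_lipid ids of the two lipid
#'   pseudoreactions.
#' @param uptake supplement uptake magnitude (bound is \code{-uptake}).
#' @param anaerobic_bounds bounds given to the enabled anaerobic lipid
#'   pseudoreaction.
#' @return a new \code{metab_model}.
#' @export
anaerobic_transform <- function(model, oxygen_exchange, supplement_exchanges,
                                aerobic_lipid, anaerobic_lipid,
                                uptake = Inf, anaerobic_bounds = c(0, Inf)) {
  stopifnot(inherits(model, "metab_model"))
  need <- c(oxygen_exchange, supplement_exchanges, aerobic_lipid, anaerobic_lipid)
  missing <- setdiff(need, names(model$reactions))
  if (length(missing)) {
    stop("anaerobic transform: reactions not found in model: ",
         paste(missing, collapse = ", "))
  }
  model$reactions[[oxygen_exchange]]$lb <-
    max(model$reactions[[oxygen_exchange]]$lb, 0)
  for (rid in supplement_exchanges) {
    model$reactions[[rid]]$lb <- -abs(uptake)
  }
  model <- set_bounds(model, aerobic_lipid, lb = 0, ub = 0)
  model <- set_bounds(model, anaerobic_lipid,
                      lb = anaerobic_bounds[1], ub = anaerobic_bounds[2])
  model
}

#' Restrict flux through a gene's reactions to a fraction of reference
#'
#' Every reaction whose GPR rule contains the gene as a leaf has its
#' bounds intersected with \code{[-f |v*|, +f |v*|]}, where \code{v*} is
#' the reaction's flux in the reference solution (a geometric-FBA
#' solution of the unperturbed model, so \code{v*} is well defined).
#' With \code{sign_preserving = TRUE} the restriction is
#' \code{[0, f v*]} (or \code{[f v*, 0]} for negative reference flux)
#' instead. Fraction 0 is equivalent to deleting every reaction the gene
#' touches; fraction 1 never relaxes an existing bound.
#'
#' @param model a \code{metab_model}.
#' @param gene a single gene id; if absent from the model a warning is
#'   given and the model returned unchanged.
#' @param fraction fraction of reference flux in [0, 1].
#' @param reference an \code{fba_solution} for the unperturbed model.
#' @param sign_preserving see above; default FALSE (symmetric about 0).
#' @return a new \code{metab_model}.
#' @export
restrict_gene_flux <- function(model, gene, fraction, reference,
                               sign_preserving = FALSE) {
  stopifnot(inherits(model, "metab_model"), inherits(reference, "fba_solution"),
            fraction >= 0, fraction <= 1, length(gene) == 1L)
  if (!gene %in% model_genes(model)) {
    warning("gene '", gene, "' not in model; no restriction applied")
    return(model)
  }
  for (rid in gene_reactions(model, gene)) {
    vref <- reference$fluxes[[rid]]
    r <- model$reactions[[rid]]
    if (sign_preserving) {
      lo <- min(0, fraction * vref); hi <- max(0, fraction * vref)
    } else {
      cap <- fraction * abs(vref)
      lo <- -cap; hi <- cap
    }
    model$reactions[[rid]]$lb <- max(r$lb, lo)
    model$reactions[[rid]]$ub <- min(r$ub, hi)
    if (model$reactions[[rid]]$lb > model$reactions[[rid]]$ub) {
      # can happen when original bounds exclude 0 and cap is small; clamp
      model$reactions[[rid]]$ub <- model$reactions[[rid]]$lb
    }
  }
  model
}

#' Reactions associated with a gene
#'
#' @param model a \code{metab_model}.
#' @param gene a gene id.
#' @return character vector of reaction ids whose GPR contains the gene.
#' @export
gene_reactions <- function(model, gene) {
  hits <- vapply(model$reactions, function(r) gene %in% gpr_genes(r$gpr),
                 logical(1))
  names(model$reactions)[hits]
}
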