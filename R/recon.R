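#' Derive an evidence-only reconstruction from a model
#'
#' Separates the knowledge base (GENRE) from the modelling assumptions
#' (GEM): removes every reaction annotated SBO 395 ("encapsulating
#' process", the irreversible "isa" class mappings) or SBO 397 ("omitted
#' process": biomass and lipid pseudoreactions, hypothetical transport,
#' exchanges), removes all flux bounds from the surviving reactions
#' (bounds are modelling constraints, not biochemical evidence), and
#' prunes species -- boundary placeholders, "biomass" and any other
#' orphan -- that no longer participate in any reaction. The surviving
#' gene set is recomputed from the surviving GPR rules. Deriving an
#' already-derived reconstruction is the identity, so the operation is
#' idempotent.
#'
#' @param model a \code{metab_model} carrying SBO annotations; a model
#'   with no SBO term on any reaction is rejected (derivation would be
#'   the identity, almost surely by mistake).
#' @return a \code{metab_model} with \code{is_reconstruction = TRUE}.
#' @export
derive_reconstruction <- function(model) {
  stopifnot(inherits(model, "metab_model"))
  if (model$is_reconstruction) return(model)
  sbo <- vapply(model$reactions, function(r)
    if (is.na(r$sbo)) NA_integer_ else r$sbo, integer(1))
  if (all(is.na(sbo))) {
    stop("model carries no SBO annotation on any reaction; cannot derive a reconstruction")
  }
  keep <- is.na(sbo) | !(sbo %in% c(395L, 397L))
  reactions <- model$reactions[keep]
  reactions <- lapply(reactions, function(r) {
    r$lb <- -Inf; r$ub <- Inf; r
  })
  used <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  species <- model$species[model$species$id %in% used, , drop = FALSE]
  rownames(species) <- NULL
  obj <- model$objective_id
  if (!is.null(obj) && !obj %in% names(reactions)) obj <- NULL
  metab_model(species, reactions, objective_id = obj, id = model$id,
              name = model$name, is_reconstruction = TRUE)
}

#' Detect blocked reactions
#'
#' A reaction is blocked when it cannot carry nonzero flux under any
#' feasible steady state for a given exchange regime: its flux
#' variability range, computed with the objective unconstrained, is
#' (0, 0). The default regime opens every exchange reaction in both
#' directions ("all-open"), the most permissive setting, so the blocked
#' set reflects structural gaps rather than medium choices; a
#' \code{medium_spec} may be supplied instead, and the regime used is
#' recorded on the result.
#'
#' @param model a \code{metab_model}.
#' @param medium \code{"all-open"} (default) or a \code{medium_spec}.
#' @param tol flux magnitude below which a range endpoint counts as 0.
#' @return list with \code{blocked} (reaction ids), \code{fraction}
#'   (blocked / total reactions) and \code{medium} (regime tag).
#' @export
blocked_reactions <- function(model, medium = "all-open", tol = 1e-6) {
  stopifnot(inherits(model, "metab_model"))
  if (inherits(medium, "medium_spec")) {
    model <- apply_medium(model, medium)
    regime <- attr(medium, "medium_name")
  } else if (identical(medium, "all-open")) {
    for (rid in exchange_reactions(model)) {
      model$reactions[[rid]]$lb <- -Inf
      model$reactions[[rid]]$ub <- Inf
    }
    regime <- "all-open"
  } else {
    stop("medium must be \"all-open\" or a medium_spec")
  }
  rng <- fva(model, fraction = 0)
  blocked <- rng$reaction[abs(rng$min) <= tol & abs(rng$max) <= tol]
  list(blocked = blocked,
       fraction = length(blocked) / length(model$reactions),
       medium = regime)
}
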