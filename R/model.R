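#' Construct a stoichiometrically constrained metabolic model
#'
#' The in-memory container used throughout the package. A model is a set
#' of species, a set of bounded reactions with optional GPR rules and SBO
#' annotations, and an objective reaction (conventionally the biomass
#' exchange). Boundary placeholder species (COBRA convention: identifier
#' suffix \code{"_b"} or SBML \code{boundaryCondition="true"}) are kept in
#' the document but never enter the stoichiometric matrix handed to the
#' solver.
#'
#' @param species data.frame with columns \code{id}, and optionally
#'   \code{name}, \code{compartment}, \code{chebi}, \code{sbo} (integer),
#'   \code{boundary} (logical). Missing optional columns are filled.
#' @param reactions list of reactions built with [reaction()].
#' @param objective_id id of the objective reaction.
#' @param id,name model identifier and display name.
#' @param is_reconstruction logical flag: TRUE for an evidence-only
#'   reconstruction derived with [derive_reconstruction()].
#' @return an object of class \code{metab_model}.
#' @seealso [reaction()], [read_sbml()], [fba()]
#' @export
metab_model <- function(species, reactions, objective_id = NULL,
                        id = "model", name = id, is_reconstruction = FALSE) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(species))
  defaults <- list(name = species$id, compartment = "c",
                   chebi = NA_character_, sbo = NA_integer_, boundary = FALSE)
  for (col in names(defaults)) {
    if (!col %in% names(species)) species[[col]] <- defaults[[col]]
  }
  # "_b" suffix is itself the boundary convention
  species$boundary <- species$boundary | grepl("_b$", species$id)
  if (anyDuplicated(species$id)) {
    stop("duplicate species ids: ",
         paste(unique(species$id[duplicated(species$id)]), collapse = ", "))
  }
  if (is.null(names(reactions))) {
    names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  }
  if (anyDuplicated(names(reactions))) {
    stop("duplicate reaction ids: ",
         paste(unique(names(reactions)[duplicated(names(reactions))]), collapse = ", "))
  }
  for (r in reactions) {
    unknown <- setdiff(names(r$stoich), species$id)
    if (length(unknown)) {
      stop("reaction '", r$id, "' references unknown species: ",
           paste(unknown, collapse = ", "))
    }
    if (r$lb > r$ub) stop("reaction '", r$id, "': lower bound exceeds upper bound")
  }
  if (!is.null(objective_id) && !objective_id %in% names(reactions)) {
    stop("objective reaction '", objective_id, "' not in model")
  }
  structure(list(id = id, name = name, species = species,
                 reactions = reactions, objective_id = objective_id,
                 is_reconstruction = is_reconstruction),
            class = "metab_model")
}

#' Construct a reaction record
#'
#' @param id reaction identifier (unique within a model).
#' @param stoich named numeric vector mapping species id to signed
#'   stoichiometric coefficient; negative = consumed, positive = produced.
#' @param lb,ub flux bounds (model units); \code{-Inf}/\code{Inf} allowed
#'   and kept explicit (a large-number substitute is applied only at
#'   solver hand-off).
#' @param name display name.
#' @param gpr a \code{gpr} object or a COBRA rule string.
#' @param sbo optional integer SBO term (395 = encapsulating "isa"
#'   process, 397 = omitted process such as biomass or hypothetical
#'   transport).
#' @param pubmed character vector of PubMed ids supporting the reaction.
#' @return a list of class \code{metab_reaction}.
#' @export
reaction <- function(id, stoich, lb = -Inf, ub = Inf, name = id,
                     gpr = gpr_none(), sbo = NA_integer_,
                     pubmed = character()) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  stopifnot(inherits(gpr, "gpr"), is.numeric(stoich), !is.null(names(stoich)))
  if (anyDuplicated(names(stoich))) {
    stoich <- tapply(stoich, names(stoich), sum)
    stoich <- stats::setNames(as.numeric(stoich), names(stoich))
  }
  stoich <- stoich[stoich != 0]
  structure(list(id = id, name = name, stoich = stoich,
                 lb = as.numeric(lb), ub = as.numeric(ub), gpr = gpr,
                 sbo = as.integer(sbo), pubmed = as.character(pubmed)),
            class = "metab_reaction")
}

#' @export
print.metab_reaction <- function(x, ...) {
  lhs <- x$stoich[x$stoich < 0]
  rhs <- x$stoich[x$stoich > 0]
  fmt <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(abs(v) == 1, names(v), paste(abs(v), names(v))), collapse = " + ")
  }
  arrow <- if (x$lb < 0 && x$ub > 0) "<=>" else "->"
  cat("<reaction> ", x$id, ": ", fmt(lhs), " ", arrow, " ", fmt(rhs),
      "  [", x$lb, ", ", x$ub, "]\n", sep = "")
  invisible(x)
}

#' Model accessors
#'
#' \code{model_genes} returns the distinct genes appearing as leaves in
#' any GPR rule. \code{reaction_ids} and \code{species_ids} list
#' identifiers. \code{exchange_reactions} returns ids of reactions that
#' involve exactly one non-boundary species (the "reactant ->"
#' convention: positive flux exports the internal species, negative flux
#' imports it). \code{isa_reactions} and \code{omitted_reactions} select
#' by SBO term 395 and 397.
#'
#' @param model a \code{metab_model}.
#' @return character vectors of identifiers.
#' @export
model_genes <- function(model) {
  stopifnot(inherits(model, "metab_model"))
  sort(unique(unlist(lapply(model$reactions, function(r) gpr_genes(r$gpr)))))
}

#' @rdname model_genes
#' @export
reaction_ids <- function(model) names(model$reactions)

#' @rdname model_genes
#' @export
species_ids <- function(model) model$species$id

boundary_species <- function(model) model$species$id[model$species$boundary]

#' @rdname model_genes
#' @export
exchange_reactions <- function(model) {
  bnd <- boundary_species(model)
  is_ex <- vapply(model$reactions, function(r) {
    sum(!(names(r$stoich) %in% bnd)) == 1L
  }, logical(1))
  names(model$reactions)[is_ex]
}

#' @rdname model_genes
#' @export
isa_reactions <- function(model) {
  names(model$reactions)[vapply(model$reactions, function(r)
    isTRUE(r$sbo == 395L), logical(1))]
}

#' @rdname model_genes
#' @export
omitted_reactions <- function(model) {
  names(model$reactions)[vapply(model$reactions, function(r)
    isTRUE(r$sbo == 397L), logical(1))]
}

#' Stoichiometric matrix
#'
#' Builds the matrix S (rows: non-boundary species, columns: reactions)
#' from the reaction records alone. Boundary placeholder species are
#' excluded, so exchange reactions appear as columns with a single entry
#' of -1 on their internal species: positive flux produces/exports,
#' negative flux consumes/imports.
#'
#' @param model a \code{metab_model}.
#' @return a dense numeric matrix with dimnames (species, reactions).
#' @export
stoich_matrix <- function(model) {
  stopifnot(inherits(model, "metab_model"))
  internal <- model$species$id[!model$species$boundary]
  S <- matrix(0, nrow = length(internal), ncol = length(model$reactions),
              dimnames = list(internal, names(model$reactions)))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    st <- st[names(st) %in% internal]
    if (length(st)) S[names(st), j] <- st
  }
  S
}

#' Flux bounds of all reactions
#'
#' @param model a \code{metab_model}.
#' @return a two-column matrix (lb, ub) with reaction ids as rownames.
#' @export
flux_bounds <- function(model) {
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  cbind(lb = lb, ub = ub)
}

set_bounds <- function(model, rxn_id, lb = NULL, ub = NULL) {
  stopifnot(rxn_id %in% names(model$reactions))
  if (!is.null(lb)) model$reactions[[rxn_id]]$lb <- as.numeric(lb)
  if (!is.null(ub)) model$reactions[[rxn_id]]$ub <- as.numeric(ub)
  model
}

#' @export
print.metab_model <- function(x, ...) {
  nb <- sum(!x$species$boundary)
  cat("<metab_model> ", x$id,
      if (x$is_reconstruction) " (reconstruction)" else "", "\n", sep = "")
  cat("  species:   ", nrow(x$species), " (", nb, " internal)\n", sep = "")
  cat("  reactions: ", length(x$reactions),
      " (", length(exchange_reactions(x)), " exchange, ",
      length(isa_reactions(x)), " isa)\n", sep = "")
  cat("  genes:     ", length(model_genes(x)), "\n", sep = "")
  if (!is.null(x$objective_id))
    cat("  objective: ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' @export
summary.metab_model <- function(object, ...) {
  out <- list(
    id = object$id,
    n_species = nrow(object$species),
    n_internal_species = sum(!object$species$boundary),
    n_reactions = length(object$reactions),
    n_exchange = length(exchange_reactions(object)),
    n_isa = length(isa_reactions(object)),
    n_genes = length(model_genes(object)),
    objective = object$objective_id,
    is_reconstruction = object$is_reconstruction
  )
  class(out) <- "summary.metab_model"
  out
}

#' @export
print.summary.metab_model <- function(x, ...) {
  cat("Model census for '", x$id, "'\n", sep = "")
  cat("  metabolites (all/internal): ", x$n_species, "/", x$n_internal_species, "\n", sep = "")
  cat("  reactions: ", x$n_reactions, "  exchange: ", x$n_exchange,
      "  isa: ", x$n_isa, "\n", sep = "")
  cat("  genes: ", x$n_genes, "\n", sep = "")
  invisible(x)
}

#' Check a model against the encoding conventions
#'
#' Reports, without failing: (i) reversible "isa" reactions (SBO 395 with
#' a negative lower bound; the convention requires irreversibility so
#' generic class species act only as sinks), (ii) reactions touching a
#' boundary placeholder species that are not of the single-internal-
#' species exchange form, and (iii) the complete absence of SBO
#' annotation, which blocks reconstruction derivation.
#'
#' @param model a \code{metab_model}.
#' @return data.frame with columns \code{type}, \code{id},
#'   \code{message}; zero rows for a conforming model.
#' @export
validate_conventions <- function(model) {
  stopifnot(inherits(model, "metab_model"))
  out <- list()
  add <- function(type, id, message) {
    out[[length(out) + 1L]] <<- data.frame(type = type, id = id,
                                           message = message,
                                           stringsAsFactors = FALSE)
  }
  bnd <- boundary_species(model)
  for (r in model$reactions) {
    if (isTRUE(r$sbo == 395L) && r$lb < 0) {
      add("isa_reversible", r$id,
          sprintf("isa reaction has lower bound %g; must be >= 0", r$lb))
    }
    touches_bnd <- any(names(r$stoich) %in% bnd)
    n_internal <- sum(!(names(r$stoich) %in% bnd))
    if (touches_bnd && n_internal != 1L) {
      add("malformed_exchange", r$id,
          sprintf("involves a boundary species but %d internal species (exchange form requires exactly 1)",
                  n_internal))
    }
  }
  has_sbo <- any(vapply(model$reactions, function(r) !is.na(r$sbo), logical(1)))
  if (!has_sbo && length(model$reactions)) {
    add("no_sbo_terms", model$id,
        "no reaction carries an SBO term; reconstruction derivation would be blocked")
  }
  if (!length(out)) {
    return(data.frame(type = character(), id = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
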