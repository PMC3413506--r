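#' Read an SBML metabolic model
#'
#' Parses SBML Level 2 (COBRA dialect: bounds as \code{LOWER_BOUND} /
#' \code{UPPER_BOUND} kinetic-law parameters, gene rules in a
#' \code{GENE_ASSOCIATION} notes line, objective via
#' \code{OBJECTIVE_COEFFICIENT}) and SBML Level 3 with the \code{fbc}
#' package (flux-bound parameters, structured
#' \code{geneProductAssociation}, active objective). When both encodings
#' are present the structured fbc form takes precedence over the notes
#' text. SBO terms and ChEBI / PubMed annotations (identifiers.org MIRIAM
#' URIs) are preserved. Species carrying the boundary-placeholder
#' convention (identifier suffix \code{"_b"} or
#' \code{boundaryCondition="true"}) are flagged and excluded from the
#' stoichiometric matrix.
#'
#' @param path path to an SBML file.
#' @return a \code{metab_model}.
#' @seealso [write_sbml()], [validate_conventions()]
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file '", path,
                                           "': ", conditionMessage(e)))
  root <- doc
  if (xml2::xml_name(root) != "sbml") stop("not an SBML document: ", path)
  model_node <- xml_find1(root, "model")
  if (is.null(model_node)) stop("SBML document has no <model>: ", path)
  attrs <- xml2::xml_attrs(model_node)
  model_id <- attr_or(attrs, "id", "model")
  model_name <- attr_or(attrs, "name", model_id)

  # fbc global tables (L3)
  params <- sbml_parameters(model_node)
  gene_labels <- sbml_gene_products(model_node)
  active_obj <- sbml_active_objective(model_node)

  sp_nodes <- xml_findall(model_node, "listOfSpecies/species")
  species <- do.call(rbind, lapply(sp_nodes, function(nd) {
    a <- xml2::xml_attrs(nd)
    data.frame(id = attr_or(a, "id", NA_character_),
               name = attr_or(a, "name", attr_or(a, "id", "")),
               compartment = attr_or(a, "compartment", "c"),
               chebi = sbml_miriam(nd, "chebi"),
               sbo = sbo_int(attr_or(a, "sboTerm", NA_character_)),
               boundary = identical(attr_or(a, "boundaryCondition", "false"), "true"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(species) || !nrow(species)) stop("SBML model has no species: ", path)

  rx_nodes <- xml_findall(model_node, "listOfReactions/reaction")
  objective_id <- active_obj
  reactions <- lapply(rx_nodes, function(nd) {
    a <- xml2::xml_attrs(nd)
    rid <- attr_or(a, "id", NA_character_)
    stoich <- c(sbml_stoich(nd, "listOfReactants", -1),
                sbml_stoich(nd, "listOfProducts", +1))
    stoich <- tapply(stoich, names(stoich), sum)   # merge duplicates
    stoich <- stats::setNames(as.numeric(stoich), names(stoich))
    unknown <- setdiff(names(stoich), species$id)
    if (length(unknown)) {
      stop("reaction '", rid, "' references unknown species: ",
           paste(unknown, collapse = ", "))
    }
    reversible <- !identical(attr_or(a, "reversible", "true"), "false")
    bnds <- sbml_bounds(nd, a, params, reversible)
    if (!is.null(bnds$objective) && bnds$objective != 0 && is.null(objective_id)) {
      objective_id <<- rid
    }
    gpr <- sbml_gpr(nd, gene_labels)
    reaction(id = rid, name = attr_or(a, "name", rid), stoich = stoich,
             lb = bnds$lb, ub = bnds$ub, gpr = gpr,
             sbo = sbo_int(attr_or(a, "sboTerm", NA_character_)),
             pubmed = sbml_miriam_all(nd, "pubmed"))
  })
  metab_model(species, reactions, objective_id = objective_id,
              id = model_id, name = model_name)
}

# -- reader helpers (namespace-agnostic via local-name()) ---------------------

xml_findall <- function(node, relpath) {
  steps <- strsplit(relpath, "/", fixed = TRUE)[[1]]
  xp <- paste0(".", paste0("/*[local-name()='", steps, "']", collapse = ""))
  xml2::xml_find_all(node, xp)
}

xml_find1 <- function(node, relpath) {
  r <- xml_findall(node, relpath)
  if (length(r)) r[[1]] else NULL
}

attr_or <- function(attrs, name, default) {
  hit <- which(sub("^.*:", "", names(attrs)) == name)
  if (length(hit)) attrs[[hit[1]]] else default
}

sbo_int <- function(x) {
  if (is.na(x)) return(NA_integer_)
  as.integer(sub("^SBO:0*", "", x))
}

sbml_double <- function(x) {
  if (is.na(x)) return(NA_real_)
  if (x %in% c("INF", "inf", "Inf")) return(Inf)
  if (x %in% c("-INF", "-inf", "-Inf")) return(-Inf)
  as.numeric(x)
}

sbml_stoich <- function(rx_node, listname, sign) {
  refs <- xml_findall(rx_node, paste0(listname, "/speciesReference"))
  if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
  ids <- vapply(refs, function(r) attr_or(xml2::xml_attrs(r), "species",
                                          NA_character_), character(1))
  st <- vapply(refs, function(r) {
    v <- sbml_double(attr_or(xml2::xml_attrs(r), "stoichiometry", "1"))
    if (is.na(v)) 1 else v
  }, numeric(1))
  stats::setNames(sign * st, ids)
}

# global listOfParameters (used by fbc flux bounds)
sbml_parameters <- function(model_node) {
  nodes <- xml_findall(model_node, "listOfParameters/parameter")
  if (!length(nodes)) return(stats::setNames(numeric(0), character(0)))
  ids <- vapply(nodes, function(n) attr_or(xml2::xml_attrs(n), "id",
                                           NA_character_), character(1))
  vals <- vapply(nodes, function(n) sbml_double(attr_or(xml2::xml_attrs(n),
                                                        "value", NA_character_)),
                 numeric(1))
  stats::setNames(vals, ids)
}

sbml_gene_products <- function(model_node) {
  nodes <- xml_findall(model_node, "listOfGeneProducts/geneProduct")
  if (!length(nodes)) return(stats::setNames(character(0), character(0)))
  ids <- vapply(nodes, function(n) attr_or(xml2::xml_attrs(n), "id",
                                           NA_character_), character(1))
  labels <- vapply(nodes, function(n) {
    a <- xml2::xml_attrs(n)
    attr_or(a, "label", attr_or(a, "id", NA_character_))
  }, character(1))
  stats::setNames(labels, ids)
}

sbml_active_objective <- function(model_node) {
  objs <- xml_findall(model_node, "listOfObjectives/objective")
  if (!length(objs)) return(NULL)
  fo <- xml_findall(objs[[1]], "listOfFluxObjectives/fluxObjective")
  if (!length(fo)) return(NULL)
  attr_or(xml2::xml_attrs(fo[[1]]), "reaction", NULL)
}

sbml_bounds <- function(rx_node, attrs, params, reversible) {
  # L3/fbc: attribute points at a global parameter
  lbp <- attr_or(attrs, "lowerFluxBound", NA_character_)
  ubp <- attr_or(attrs, "upperFluxBound", NA_character_)
  if (!is.na(lbp) || !is.na(ubp)) {
    lb <- if (!is.na(lbp) && lbp %in% names(params)) params[[lbp]] else -Inf
    ub <- if (!is.na(ubp) && ubp %in% names(params)) params[[ubp]] else Inf
    return(list(lb = lb, ub = ub, objective = NULL))
  }
  # L2/COBRA: kineticLaw parameters
  pn <- xml_findall(rx_node, "kineticLaw/listOfParameters/parameter")
  lb <- ub <- NA_real_; objc <- NULL
  for (p in pn) {
    a <- xml2::xml_attrs(p)
    pid <- attr_or(a, "id", "")
    val <- sbml_double(attr_or(a, "value", NA_character_))
    if (pid == "LOWER_BOUND") lb <- val
    if (pid == "UPPER_BOUND") ub <- val
    if (pid == "OBJECTIVE_COEFFICIENT") objc <- val
  }
  if (is.na(lb)) lb <- if (reversible) -Inf else 0
  if (is.na(ub)) ub <- Inf
  list(lb = lb, ub = ub, objective = objc)
}

sbml_gpr <- function(rx_node, gene_labels) {
  # structured fbc association takes precedence
  assoc <- xml_find1(rx_node, "geneProductAssociation")
  if (!is.null(assoc)) {
    kids <- xml2::xml_children(assoc)
    if (length(kids)) return(fbc_assoc_tree(kids[[1]], gene_labels))
  }
  # fall back to notes text
  notes <- xml_find1(rx_node, "notes")
  if (!is.null(notes)) {
    txt <- xml2::xml_text(
      xml2::xml_find_all(notes, ".//*[contains(text(), 'GENE_ASSOCIATION')]"))
    if (length(txt)) {
      rule <- sub("^.*GENE_ASSOCIATION:\\s*", "", txt[[1]])
      return(parse_gpr(rule))
    }
  }
  gpr_none()
}

fbc_assoc_tree <- function(node, gene_labels) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- attr_or(xml2::xml_attrs(node), "geneProduct", NA_character_)
    lab <- if (ref %in% names(gene_labels)) gene_labels[[ref]] else ref
    return(structure(list(kind = "gene", gene = lab), class = "gpr"))
  }
  kids <- lapply(xml2::xml_children(node), fbc_assoc_tree,
                 gene_labels = gene_labels)
  if (nm == "and") return(gpr_node("and", kids))
  if (nm == "or") return(gpr_node("or", kids))
  stop("unsupported geneProductAssociation node: ", nm)
}

sbml_miriam <- function(node, db) {
  hits <- sbml_miriam_all(node, db)
  if (length(hits)) hits[[1]] else NA_character_
}

sbml_miriam_all <- function(node, db) {
  lis <- xml2::xml_find_all(node, ".//*[local-name()='li']")
  if (!length(lis)) return(character())
  res <- vapply(lis, function(li) attr_or(xml2::xml_attrs(li), "resource",
                                          NA_character_), character(1))
  pat <- paste0("identifiers\\.org/", db, "/")
  hits <- res[!is.na(res) & grepl(pat, res)]
  sub(paste0(".*", pat), "", hits)
}

# -- writer -------------------------------------------------------------------

#' Write a model as SBML
#'
#' Emits SBML Level 2 Version 4 in the COBRA dialect the Yeast-consensus
#' era models use: flux bounds as \code{LOWER_BOUND}/\code{UPPER_BOUND}
#' kinetic-law parameters (infinite bounds encoded as \code{INF} /
#' \code{-INF} and recovered as such), the objective via
#' \code{OBJECTIVE_COEFFICIENT}, GPR rules as a \code{GENE_ASSOCIATION}
#' notes line, SBO terms as \code{sboTerm} attributes, and ChEBI / PubMed
#' annotations as identifiers.org MIRIAM URIs. A written file re-reads to
#' an equivalent document.
#'
#' @param model a \code{metab_model} passing its invariants.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "metab_model"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  num <- function(v) {
    if (is.infinite(v)) (if (v > 0) "INF" else "-INF")
    else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }
  sbo_attr <- function(s) {
    if (is.na(s)) "" else sprintf(' sboTerm="SBO:%07d"', s)
  }
  rdf_block <- function(about, qualifier, uris) {
    if (!length(uris)) return(character())
    c("      <annotation>",
      '        <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">',
      sprintf('          <rdf:Description rdf:about="#%s">', esc(about)),
      sprintf("            <bqbiol:%s>", qualifier),
      "              <rdf:Bag>",
      sprintf('                <rdf:li rdf:resource="%s"/>', esc(uris)),
      "              </rdf:Bag>",
      sprintf("            </bqbiol:%s>", qualifier),
      "          </rdf:Description>",
      "        </rdf:RDF>",
      "      </annotation>")
  }

  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
             sprintf('  <model id="%s" name="%s">', esc(model$id), esc(model$name)))
  comps <- unique(model$species$compartment)
  lines <- c(lines, "    <listOfCompartments>",
             sprintf('      <compartment id="%s" size="1"/>', esc(comps)),
             "    </listOfCompartments>",
             "    <listOfSpecies>")
  for (i in seq_len(nrow(model$species))) {
    sp <- model$species[i, ]
    chebi <- if (!is.na(sp$chebi) && nzchar(sp$chebi))
      paste0("http://identifiers.org/chebi/", sp$chebi) else character()
    open_tag <- sprintf('      <species id="%s" name="%s" compartment="%s" boundaryCondition="%s"%s%s>',
                        esc(sp$id), esc(sp$name), esc(sp$compartment),
                        if (sp$boundary) "true" else "false",
                        sbo_attr(sp$sbo), if (length(chebi)) "" else "")
    if (length(chebi)) {
      lines <- c(lines, open_tag, rdf_block(sp$id, "is", chebi),
                 "      </species>")
    } else {
      lines <- c(lines, sub(">$", "/>", open_tag))
    }
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfReactions>")
  for (r in model$reactions) {
    rev <- r$lb < 0
    lines <- c(lines, sprintf('      <reaction id="%s" name="%s" reversible="%s"%s>',
                              esc(r$id), esc(r$name),
                              if (rev) "true" else "false", sbo_attr(r$sbo)))
    gtxt <- gpr_to_text(r$gpr)
    lines <- c(lines,
               "        <notes>",
               '          <body xmlns="http://www.w3.org/1999/xhtml">',
               sprintf("            <p>GENE_ASSOCIATION: %s</p>", esc(gtxt)),
               "          </body>",
               "        </notes>")
    if (length(r$pubmed)) {
      blk <- rdf_block(r$id, "isDescribedBy",
                       paste0("http://identifiers.org/pubmed/", r$pubmed))
      lines <- c(lines, sub("^      ", "        ", blk))
    }
    reactants <- r$stoich[r$stoich < 0]
    products <- r$stoich[r$stoich > 0]
    if (length(reactants)) {
      lines <- c(lines, "        <listOfReactants>",
                 sprintf('          <speciesReference species="%s" stoichiometry="%s"/>',
                         esc(names(reactants)),
                         vapply(-reactants, num, character(1))),
                 "        </listOfReactants>")
    }
    if (length(products)) {
      lines <- c(lines, "        <listOfProducts>",
                 sprintf('          <speciesReference species="%s" stoichiometry="%s"/>',
                         esc(names(products)),
                         vapply(products, num, character(1))),
                 "        </listOfProducts>")
    }
    objc <- if (!is.null(model$objective_id) &&
                identical(r$id, model$objective_id)) 1 else 0
    lines <- c(lines,
               "        <kineticLaw>",
               '          <math xmlns="http://www.w3.org/1998/Math/MathML"><ci> FLUX_VALUE </ci></math>',
               "          <listOfParameters>",
               sprintf('            <parameter id="LOWER_BOUND" value="%s"/>', num(r$lb)),
               sprintf('            <parameter id="UPPER_BOUND" value="%s"/>', num(r$ub)),
               sprintf('            <parameter id="OBJECTIVE_COEFFICIENT" value="%s"/>', num(objc)),
               "          </listOfParameters>",
               "        </kineticLaw>",
               "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
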