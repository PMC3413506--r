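#' Gene-protein-reaction (GPR) boolean expressions
#'
#' A GPR rule links a reaction to the genes whose products catalyse it:
#' AND joins subunits of a complex (all required), OR joins isoenzymes
#' (any suffices). Rules are stored as a small tree of nodes of kind
#' \code{"gene"}, \code{"and"}, \code{"or"} or \code{"none"} (no gene
#' association; the reaction is unaffected by any deletion).
#'
#' @param text a rule in the COBRA text dialect, e.g.
#'   \code{"(YAL001C and YBR002W) or YCL003C"}. \code{NA}, \code{""} and
#'   whitespace-only strings give the \code{"none"} rule. Operators may be
#'   written \code{and}/\code{AND}/\code{&}/\code{&&} and
#'   \code{or}/\code{OR}/\code{|}/\code{||}.
#' @return an object of class \code{gpr}.
#' @examples
#' g <- parse_gpr("(A and B) or C")
#' gpr_eval(g, deleted = c("A"))   # TRUE: C still present
#' gpr_genes(g)
#' @export
parse_gpr <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    return(gpr_none())
  }
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  node <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed GPR rule near '", st$toks[st$pos], "': ", text)
  }
  node
}

gpr_tokenize <- function(text) {
  text <- gsub("&&", " & ", text, fixed = TRUE)
  text <- gsub("||", " | ", text, fixed = TRUE)
  text <- gsub("(", " ( ", text, fixed = TRUE)
  text <- gsub(")", " ) ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_is_op <- function(tok, which) {
  !is.na(tok) && tolower(tok) %in% which
}

gpr_parse_or <- function(st) {
  children <- list(gpr_parse_and(st))
  while (gpr_is_op(gpr_peek(st), c("or", "|"))) {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_and(st)))
  }
  if (length(children) == 1L) children[[1]] else gpr_node("or", children)
}

gpr_parse_and <- function(st) {
  children <- list(gpr_parse_atom(st))
  while (gpr_is_op(gpr_peek(st), c("and", "&"))) {
    st$pos <- st$pos + 1L
    children <- c(children, list(gpr_parse_atom(st)))
  }
  if (length(children) == 1L) children[[1]] else gpr_node("and", children)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("malformed GPR rule: unexpected end of input")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    node <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) stop("malformed GPR rule: missing ')'")
    st$pos <- st$pos + 1L
    return(node)
  }
  if (tok == ")" || gpr_is_op(tok, c("and", "&", "or", "|"))) {
    stop("malformed GPR rule: unexpected '", tok, "'")
  }
  st$pos <- st$pos + 1L
  gpr_gene(tok)
}

# Flatten nested nodes of the same kind so AND/OR always have >= 2 children.
gpr_node <- function(kind, children) {
  flat <- list()
  for (ch in children) {
    if (ch$kind == kind) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  structure(list(kind = kind, children = flat), class = "gpr")
}

gpr_gene <- function(id) structure(list(kind = "gene", gene = id), class = "gpr")

#' @rdname parse_gpr
#' @export
gpr_none <- function() structure(list(kind = "none"), class = "gpr")

#' Evaluate a GPR rule under a set of deleted genes
#'
#' A \code{"gene"} leaf is FALSE iff its gene is deleted; \code{"and"} and
#' \code{"or"} follow boolean semantics; the \code{"none"} rule is always
#' TRUE, so reactions without gene association survive every deletion.
#'
#' @param gpr a \code{gpr} object.
#' @param deleted character vector of deleted gene identifiers.
#' @return a single logical: can the reaction still be catalysed?
#' @export
gpr_eval <- function(gpr, deleted = character()) {
  stopifnot(inherits(gpr, "gpr"))
  switch(gpr$kind,
    none = TRUE,
    gene = !(gpr$gene %in% deleted),
    and  = all(vapply(gpr$children, gpr_eval, logical(1), deleted = deleted)),
    or   = any(vapply(gpr$children, gpr_eval, logical(1), deleted = deleted)),
    stop("unknown GPR node kind: ", gpr$kind)
  )
}

#' @rdname gpr_eval
#' @description \code{evaluate_gpr} is an alias for \code{gpr_eval}.
#' @export
evaluate_gpr <- gpr_eval

#' Genes referenced by a GPR rule
#'
#' @param gpr a \code{gpr} object.
#' @return character vector of distinct gene identifiers (empty for the
#'   \code{"none"} rule).
#' @export
gpr_genes <- function(gpr) {
  stopifnot(inherits(gpr, "gpr"))
  switch(gpr$kind,
    none = character(),
    gene = gpr$gene,
    unique(unlist(lapply(gpr$children, gpr_genes)))
  )
}

#' Render a GPR rule as COBRA-style text
#'
#' @param gpr a \code{gpr} object.
#' @return a single string; \code{""} for the \code{"none"} rule.
#' @export
gpr_to_text <- function(gpr) {
  stopifnot(inherits(gpr, "gpr"))
  render <- function(node, parent_kind) {
    switch(node$kind,
      none = "",
      gene = node$gene,
      {
        op <- if (node$kind == "and") " and " else " or "
        body <- paste(vapply(node$children, render, character(1),
                             parent_kind = node$kind), collapse = op)
        # parenthesise unless already at top level of same precedence
        if (is.na(parent_kind) || parent_kind == node$kind) body
        else paste0("(", body, ")")
      }
    )
  }
  render(gpr, NA_character_)
}

#' @export
print.gpr <- function(x, ...) {
  txt <- gpr_to_text(x)
  cat("<gpr> ", if (nzchar(txt)) txt else "(no gene association)", "\n", sep = "")
  invisible(x)
}
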