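#' Linear-chain test model
#'
#' A nutrient-to-biomass chain with unit stoichiometry and one gene per
#' internal reaction: exchange \code{EX_nutrient} (uptake bounded at
#' \code{uptake_bound}), reactions \code{r1 ... rL} converting the
#' nutrient stepwise into biomass, and the biomass exchange
#' \code{EX_biomass} as objective. Analytically, the FBA optimum equals
#' \code{uptake_bound}; deleting any single gene drops it to 0; and
#' restricting any gene to fraction f of the (unique) wild-type flux
#' scales the optimum, hence fitness, to exactly f.
#'
#' @param length number of gene-bearing internal reactions (>= 2).
#' @param uptake_bound nutrient uptake bound (flux units).
#' @return a \code{metab_model} with genes \code{g1 ... gL}.
#' @export
chain_model <- function(length = 3L, uptake_bound = 10) {
  stopifnot(length >= 2L, uptake_bound > 0)
  L <- as.integer(length)
  mets <- c("nutrient", if (L > 1) paste0("M", seq_len(L - 1L)), "biomass")
  species <- data.frame(id = c(mets, "nutrient_b", "biomass_b"),
                        stringsAsFactors = FALSE)
  rxns <- list(reaction("EX_nutrient",
                        c(nutrient = -1, nutrient_b = 1),
                        lb = -uptake_bound, ub = Inf, sbo = 397L))
  for (i in seq_len(L)) {
    from <- mets[i]; to <- mets[i + 1L]
    st <- stats::setNames(c(-1, 1), c(from, to))
    rxns <- c(rxns, list(reaction(paste0("r", i), st, lb = 0, ub = Inf,
                                  gpr = paste0("g", i),
                                  sbo = if (i == L) 397L else 176L)))
  }
  rxns <- c(rxns, list(reaction("EX_biomass",
                                c(biomass = -1, biomass_b = 1),
                                lb = 0, ub = Inf, sbo = 397L)))
  metab_model(species, rxns, objective_id = "EX_biomass",
              id = sprintf("chain%d", L))
}

#' Branched test model with GPR logic and two biomass variants
#'
#' A small network exercising every perturbation pathway the package
#' models: two parallel isoenzyme branches (\code{gA} OR \code{gB}), an
#' AND-gated step requiring a complex (\code{gC and gD}) plus a cofactor
#' regeneration loop (\code{gE}), an oxygen-dependent sterol synthesis
#' step (\code{gF}), two lipid pseudoreactions (aerobic consuming sterol,
#' anaerobic not; the anaerobic one ships disabled), "isa" reactions
#' (SBO 395) mapping each specific lipid into the generic \code{lip}
#' species consumed by biomass, and exchanges for glucose, oxygen,
#' sterol and biomass (SBO 397). The aerobic FBA optimum is 5 (half the
#' glucose uptake, because sterol synthesis consumes half the carbon);
#' after [anaerobic_transform()] with sterol supplementation it is 10.
#'
#' Ground truth on glucose minimal medium: \code{gC}, \code{gD},
#' \code{gE} are essential; \code{gF} is auxotroph-inducing (rescued by
#' opening the sterol exchange); \code{gA}, \code{gB} are redundant.
#'
#' @return a \code{metab_model}.
#' @export
branched_model <- function() {
  species <- data.frame(
    id = c("glc", "P", "Q", "cof_ox", "cof_red", "o2", "sterol",
           "lipA", "lipB", "lip", "biomass",
           "glc_b", "o2_b", "sterol_b", "biomass_b"),
    stringsAsFactors = FALSE)
  species$chebi <- NA_character_
  species$chebi[species$id == "glc"] <- "CHEBI:17234"
  rxns <- list(
    reaction("EX_glc", c(glc = -1, glc_b = 1), lb = -10, ub = Inf, sbo = 397L),
    reaction("EX_o2", c(o2 = -1, o2_b = 1), lb = -Inf, ub = Inf, sbo = 397L),
    reaction("EX_sterol", c(sterol = -1, sterol_b = 1), lb = 0, ub = Inf,
             sbo = 397L),
    reaction("EX_biomass", c(biomass = -1, biomass_b = 1), lb = 0, ub = Inf,
             sbo = 397L),
    reaction("r_brA", c(glc = -1, P = 1), lb = 0, ub = Inf, gpr = "gA",
             sbo = 176L, pubmed = "100001"),
    reaction("r_brB", c(glc = -1, P = 1), lb = 0, ub = Inf, gpr = "gB",
             sbo = 176L),
    reaction("r_cof", c(P = -1, cof_ox = -1, Q = 1, cof_red = 1),
             lb = 0, ub = Inf, gpr = "gC and gD", sbo = 176L),
    reaction("r_regen", c(cof_red = -1, cof_ox = 1), lb = 0, ub = Inf,
             gpr = "gE", sbo = 176L),
    reaction("r_sterol", c(Q = -1, o2 = -1, sterol = 1), lb = 0, ub = Inf,
             gpr = "gF", sbo = 176L),
    reaction("r_lipA", c(Q = -1, sterol = -1, lipA = 1), lb = 0, ub = Inf,
             sbo = 397L),
    reaction("r_lipB", c(Q = -1, lipB = 1), lb = 0, ub = 0, sbo = 397L),
    reaction("isa_lipA", c(lipA = -1, lip = 1), lb = 0, ub = Inf, sbo = 395L),
    reaction("isa_lipB", c(lipB = -1, lip = 1), lb = 0, ub = Inf, sbo = 395L),
    reaction("r_bio", c(lip = -1, biomass = 1), lb = 0, ub = Inf, sbo = 397L)
  )
  metab_model(species, rxns, objective_id = "EX_biomass", id = "branched")
}

#' Glucose-limited minimal medium for the branched fixture
#'
#' Glucose uptake bounded at \code{glucose}; oxygen unconstrained;
#' sterol exchange closed to uptake.
#'
#' @param glucose glucose uptake magnitude.
#' @return a \code{medium_spec}.
#' @export
branched_minimal_medium <- function(glucose = 10) {
  medium_spec(c("EX_glc", "EX_o2"), lb = c(-abs(glucose), -Inf), ub = Inf,
              name = "minimal_aerobic")
}

#' Random feasible test model
#'
#' Constructs a small flow network (species = nodes, unit-stoichiometry
#' reactions = edges) around a strictly feasible flux vector chosen
#' first, so the FBA optimum is guaranteed positive: a random increasing
#' path from the source species to the sink species carries flow f > 0,
#' bounds are drawn to admit it with slack, and extra random edges (some
#' reversible) create alternate routes and degenerate optima. One gene
#' per internal reaction. All bounds are finite so brute-force vertex
#' enumeration is well defined. Fully reproducible from \code{seed}; the
#' global RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param n_species number of internal species (>= 2).
#' @param n_reactions total reactions including the two exchanges
#'   (3 <= n_reactions <= 12 keeps oracle enumeration tractable).
#' @return a \code{metab_model}; attribute \code{feasible_flow} records
#'   the construction flow.
#' @export
random_feasible_model <- function(seed, n_species = 5L, n_reactions = 8L) {
  stopifnot(n_species >= 2L, n_reactions >= 3L, n_reactions <= 12L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  k <- as.integer(n_species)
  ids <- paste0("s", seq_len(k))
  species <- data.frame(id = c(ids, "src_b", "snk_b"), stringsAsFactors = FALSE)
  f <- round(stats::runif(1, 1, 5), 3)

  # increasing path 1 -> ... -> k
  n_internal <- n_reactions - 2L
  path_nodes <- sort(unique(c(1L, k, sample(seq_len(k), min(k, 3L)))))
  path_edges <- cbind(utils::head(path_nodes, -1), utils::tail(path_nodes, -1))
  n_extra <- n_internal - nrow(path_edges)
  if (n_extra < 0) {
    path_edges <- cbind(1L, k)   # degenerate path if too few reactions
    n_extra <- n_internal - 1L
  }
  extra <- NULL
  if (n_extra > 0) {
    for (e in seq_len(n_extra)) {
      i <- sample.int(k - 1L, 1L)
      downstream <- (i + 1L):k
      j <- downstream[sample.int(length(downstream), 1L)]
      extra <- rbind(extra, c(i, j))
    }
  }
  edges <- rbind(path_edges, extra)
  on_path <- c(rep(TRUE, nrow(path_edges)), rep(FALSE, if (is.null(extra)) 0 else nrow(extra)))

  rxns <- list(reaction("EX_in", c(stats::setNames(-1, ids[1]), src_b = 1),
                        lb = -f * stats::runif(1, 1.05, 1.6), ub = 0,
                        sbo = 397L))
  for (e in seq_len(nrow(edges))) {
    st <- stats::setNames(c(-1, 1), ids[edges[e, ]])
    if (on_path[e]) {
      lb <- 0
      ub <- f * stats::runif(1, 1.05, 2)
    } else {
      lb <- if (stats::runif(1) < 0.3) -round(stats::runif(1, 0.5, 2), 3) else 0
      ub <- round(stats::runif(1, 0.5, 3), 3)
    }
    rxns <- c(rxns, list(reaction(paste0("v", e), st, lb = lb, ub = ub,
                                  gpr = paste0("g", e), sbo = 176L)))
  }
  rxns <- c(rxns, list(reaction("EX_out", c(stats::setNames(-1, ids[k]), snk_b = 1),
                                lb = 0, ub = 10 * f, sbo = 397L)))
  m <- metab_model(species, rxns, objective_id = "EX_out",
                   id = sprintf("rand%d", seed))
  attr(m, "feasible_flow") <- f
  m
}

#' Named fixture registry
#'
#' Addressable small models for demos and the command line:
#' \code{"chain"} ([chain_model()] with length 3, uptake 10),
#' \code{"branched"} ([branched_model()]), and \code{"random<seed>"}
#' (e.g. \code{"random42"}, [random_feasible_model()] defaults).
#'
#' @param name fixture name.
#' @return a \code{metab_model}.
#' @export
fixture_model <- function(name) {
  if (name == "chain") return(chain_model(3L, 10))
  if (name == "branched") return(branched_model())
  if (grepl("^random[0-9]+$", name)) {
    return(random_feasible_model(as.integer(sub("^random", "", name))))
  }
  stop("unknown fixture '", name, "'; available: chain, branched, random<seed>")
}
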