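# shared in-code fixtures for the test suite

# three species, two reactions; minimal hand-written document for IO tests
tiny_model <- function() {
  metab_model(
    species = data.frame(id = c("A", "B", "A_b"), stringsAsFactors = FALSE),
    reactions = list(
      reaction("EX_A", c(A = -1, A_b = 1), lb = -5, ub = Inf, sbo = 397L),
      reaction("r1", c(A = -1, B = 1), lb = 0, ub = 10, gpr = "gX",
               sbo = 176L)
    ),
    objective_id = "r1", id = "tiny")
}

# compare two models field by field (order-insensitive on species rows)
expect_models_equal <- function(m1, m2) {
  expect_setequal(m1$species$id, m2$species$id)
  s1 <- m1$species[order(m1$species$id), ]
  s2 <- m2$species[order(m2$species$id), ]
  expect_equal(s1$boundary, s2$boundary)
  expect_equal(s1$compartment, s2$compartment)
  expect_equal(s1$chebi, s2$chebi)
  expect_identical(sort(names(m1$reactions)), sort(names(m2$reactions)))
  for (rid in names(m1$reactions)) {
    r1 <- m1$reactions[[rid]]; r2 <- m2$reactions[[rid]]
    expect_equal(sort(names(r1$stoich)), sort(names(r2$stoich)),
                 info = rid)
    expect_equal(r1$stoich[sort(names(r1$stoich))],
                 r2$stoich[sort(names(r2$stoich))], info = rid)
    expect_equal(r1$lb, r2$lb, info = rid)
    expect_equal(r1$ub, r2$ub, info = rid)
    expect_equal(r1$sbo, r2$sbo, info = rid)
    expect_setequal(r1$pubmed, r2$pubmed)
    expect_identical(gpr_truth_table(r1$gpr), gpr_truth_table(r2$gpr),
                     info = rid)
  }
  expect_identical(m1$objective_id, m2$objective_id)
}

# a multi-module network: n_modules parallel 3-gene chains, biomass
# consuming one precursor from each (AND across modules via stoichiometry)
modular_model <- function(n_modules = 5L, uptake = 6) {
  species <- c(unlist(lapply(seq_len(n_modules), function(k)
    paste0(c("n", "a", "p"), k))), "biomass")
  bnd <- c(paste0("n", seq_len(n_modules), "_b"), "biomass_b")
  rxns <- list()
  for (k in seq_len(n_modules)) {
    nk <- paste0("n", k); ak <- paste0("a", k); pk <- paste0("p", k)
    rxns <- c(rxns, list(
      reaction(paste0("EX_", nk),
               stats::setNames(c(-1, 1), c(nk, paste0(nk, "_b"))),
               lb = -uptake, ub = Inf, sbo = 397L),
      reaction(paste0("m", k, "r1"), stats::setNames(c(-1, 1), c(nk, ak)),
               lb = 0, ub = Inf, gpr = paste0("m", k, "g1"), sbo = 176L),
      reaction(paste0("m", k, "r2"), stats::setNames(c(-1, 1), c(ak, pk)),
               lb = 0, ub = Inf, gpr = paste0("m", k, "g2"), sbo = 176L)))
  }
  bio_st <- stats::setNames(c(rep(-1, n_modules), 1),
                            c(paste0("p", seq_len(n_modules)), "biomass"))
  rxns <- c(rxns, list(
    reaction("r_bio", bio_st, lb = 0, ub = Inf, sbo = 397L),
    reaction("EX_biomass", c(biomass = -1, biomass_b = 1), lb = 0, ub = Inf,
             sbo = 397L)))
  metab_model(data.frame(id = c(species, bnd), stringsAsFactors = FALSE),
              rxns, objective_id = "EX_biomass",
              id = sprintf("modular%d", n_modules))
}
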