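test_that("write -> read round trip is a fixed point", {
  for (m in list(tiny_model(), chain_model(4, 8), branched_model(),
                 random_feasible_model(11))) {
    f <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, f)
    m2 <- read_sbml(f)
    expect_models_equal(m, m2)
    # a second round trip reproduces the file byte for byte
    f2 <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m2, f2)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("infinite bounds are encoded and recovered as unbounded", {
  m <- tiny_model()
  m$reactions$EX_A$lb <- -Inf
  m$reactions$EX_A$ub <- Inf
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_identical(m2$reactions$EX_A$lb, -Inf)
  expect_identical(m2$reactions$EX_A$ub, Inf)
})

test_that("AND/OR gene rules survive the round trip with identical truth tables", {
  m <- tiny_model()
  m$reactions$r1$gpr <- parse_gpr("(gA and gB) or (gC and gD)")
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_identical(gpr_truth_table(m$reactions$r1$gpr),
                   gpr_truth_table(m2$reactions$r1$gpr))
})

test_that("Level 3 fbc documents are read (structured rules take precedence)", {
  fbc <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1" fbc:required="false">',
    '  <model id="l3toy">',
    '    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="A" compartment="c" boundaryCondition="false" constant="false"/>',
    '      <species id="B" compartment="c" boundaryCondition="false" constant="false"/>',
    '      <species id="A_b" compartment="c" boundaryCondition="true" constant="false"/>',
    '    </listOfSpecies>',
    '    <listOfParameters>',
    '      <parameter id="lb_m10" value="-10" constant="true"/>',
    '      <parameter id="ub_inf" value="INF" constant="true"/>',
    '      <parameter id="lb_0" value="0" constant="true"/>',
    '    </listOfParameters>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj1">',
    '      <fbc:objective fbc:id="obj1" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    '          <fbc:fluxObjective fbc:reaction="r1" fbc:coefficient="1"/>',
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '    <fbc:listOfGeneProducts>',
    '      <fbc:geneProduct fbc:id="G_gA" fbc:label="gA"/>',
    '      <fbc:geneProduct fbc:id="G_gB" fbc:label="gB"/>',
    '      <fbc:geneProduct fbc:id="G_gC" fbc:label="gC"/>',
    '    </fbc:listOfGeneProducts>',
    '    <listOfReactions>',
    '      <reaction id="EX_A" reversible="true" fast="false"',
    '                fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="ub_inf">',
    '        <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="A_b" stoichiometry="1" constant="true"/></listOfProducts>',
    '      </reaction>',
    '      <reaction id="r1" reversible="false" fast="false" sboTerm="SBO:0000176"',
    '                fbc:lowerFluxBound="lb_0" fbc:upperFluxBound="ub_inf">',
    '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '          <p>GENE_ASSOCIATION: gWRONG</p>',
    '        </body></notes>',
    '        <fbc:geneProductAssociation>',
    '          <fbc:or>',
    '            <fbc:and>',
    '              <fbc:geneProductRef fbc:geneProduct="G_gA"/>',
    '              <fbc:geneProductRef fbc:geneProduct="G_gB"/>',
    '            </fbc:and>',
    '            <fbc:geneProductRef fbc:geneProduct="G_gC"/>',
    '          </fbc:or>',
    '        </fbc:geneProductAssociation>',
    '        <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>',
    '        <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(fbc, f)
  m <- read_sbml(f)
  expect_equal(m$reactions$EX_A$lb, -10)
  expect_identical(m$reactions$EX_A$ub, Inf)
  expect_identical(m$objective_id, "r1")
  expect_equal(m$reactions$r1$sbo, 176L)
  # structured fbc rule wins over the notes text
  expect_setequal(gpr_genes(m$reactions$r1$gpr), c("gA", "gB", "gC"))
  expect_true(m$species$boundary[m$species$id == "A_b"])
  expect_true(gpr_eval(m$reactions$r1$gpr, deleted = "gA"))     # gC rescues
  expect_false(gpr_eval(m$reactions$r1$gpr, deleted = c("gA", "gC")))
})

test_that("reader errors on broken input", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("this is not XML <", f)
  expect_error(read_sbml(f), "cannot parse")
  writeLines("<notsbml/>", f)
  expect_error(read_sbml(f), "not an SBML")
  # reaction referencing an unknown species -> integrity error
  bad <- readLines({
    g <- withr::local_tempfile(fileext = ".xml")
    write_sbml(tiny_model(), g); g
  })
  bad <- sub('species="B"', 'species="GHOST"', bad)
  writeLines(bad, f)
  expect_error(read_sbml(f), "unknown species")
})

test_that("stoichiometric matrix excludes boundary species and tracks reactions", {
  m <- branched_model()
  S <- stoich_matrix(m)
  expect_equal(ncol(S), length(m$reactions))
  expect_equal(nrow(S), sum(!m$species$boundary))
  expect_false(any(grepl("_b$", rownames(S))))
  # exchange columns carry -1 on the internal species: positive flux exports
  expect_equal(S["glc", "EX_glc"], -1)
  # gene set invariant under reaction reordering
  m2 <- m
  m2$reactions <- rev(m2$reactions)
  expect_identical(model_genes(m), model_genes(m2))
})

test_that("convention validation flags the paper-convention violations", {
  expect_equal(nrow(validate_conventions(branched_model())), 0)
  expect_equal(nrow(validate_conventions(chain_model(3, 10))), 0)

  m <- branched_model()
  m$reactions$isa_lipA$lb <- -10        # reversible isa: forbidden
  rep1 <- validate_conventions(m)
  expect_equal(rep1$type, "isa_reversible")
  expect_equal(rep1$id, "isa_lipA")

  m2 <- tiny_model()
  m2$reactions$EX_A$stoich <- c(A = -1, B = -1, A_b = 1)  # 2 internal species
  rep2 <- validate_conventions(m2)
  expect_true("malformed_exchange" %in% rep2$type)

  m3 <- tiny_model()
  m3$reactions <- lapply(m3$reactions, function(r) { r$sbo <- NA_integer_; r })
  rep3 <- validate_conventions(m3)
  expect_true("no_sbo_terms" %in% rep3$type)
})

test_that("model constructor enforces document invariants", {
  sp <- data.frame(id = c("A", "A"), stringsAsFactors = FALSE)
  expect_error(metab_model(sp, list()), "duplicate species")
  sp <- data.frame(id = "A", stringsAsFactors = FALSE)
  expect_error(
    metab_model(sp, list(reaction("r", c(Z = 1)))), "unknown species")
  expect_error(
    metab_model(sp, list(reaction("r", c(A = 1), lb = 5, ub = 1))),
    "lower bound exceeds")
  expect_error(
    metab_model(sp, list(reaction("r", c(A = 1))), objective_id = "nope"),
    "not in model")
})
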