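test_that("gene deletion via GPR logic disables the right reactions", {
  b <- branched_model()
  # deleting a gene absent from all rules leaves the objective unchanged
  expect_warning(d <- apply_deletions(b, "gZZ"), "not in model")
  expect_equal(fba(d)$objective, fba(b)$objective)
  # isoenzyme branch survives a single deletion; AND complex does not
  expect_equal(fba(apply_deletions(b, "gA"))$objective, 5, tolerance = 1e-6)
  expect_equal(fba(apply_deletions(b, c("gA", "gB")))$objective, 0)
  expect_equal(fba(apply_deletions(b, "gC"))$objective, 0)
  # sole gene of the only biomass-feeding step in a chain
  m <- chain_model(3, 10)
  expect_equal(fba(apply_deletions(m, "g2"))$objective, 0)
  # the input model is untouched
  expect_equal(fba(b)$objective, 5, tolerance = 1e-6)
})

test_that("sequential deletions compose like the union deletion", {
  b <- branched_model()
  combos <- list(c("gA", "gC"), c("gB", "gF"), c("gA", "gB"), c("gD", "gE"))
  for (gs in combos) {
    seq_del <- apply_deletions(apply_deletions(b, gs[1]), gs[2])
    union_del <- apply_deletions(b, gs)
    expect_equal(fba(seq_del)$objective, fba(union_del)$objective,
                 tolerance = 1e-9, info = paste(gs, collapse = "+"))
  }
})

test_that("media replace listed bounds and close unlisted uptake", {
  b <- branched_model()
  med <- branched_minimal_medium(glucose = 4)
  bm <- apply_medium(b, med)
  expect_equal(bm$reactions$EX_glc$lb, -4)
  expect_equal(bm$reactions$EX_sterol$lb, 0)    # unlisted: no uptake
  expect_identical(bm$reactions$EX_sterol$ub, Inf)  # still open to export
  expect_equal(fba(bm)$objective, 2, tolerance = 1e-6)  # half carbon to sterol
  # idempotence
  bm2 <- apply_medium(bm, med)
  expect_equal(flux_bounds(bm2), flux_bounds(bm))
  # closing all uptake kills growth
  closed <- medium_spec(exchange_reactions(b), lb = 0, ub = Inf)
  expect_equal(fba(apply_medium(b, closed))$objective, 0)
  # non-exchange ids are rejected
  expect_error(apply_medium(b, medium_spec("r_cof", -1, 1)), "non-exchange")
})

test_that("medium TSV round trips", {
  med <- medium_spec(c("EX_glc", "EX_o2"), lb = c(-10, -Inf), ub = Inf)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_medium_tsv(med, f)
  med2 <- read_medium_tsv(f)
  expect_equal(med$reaction, med2$reaction)
  expect_equal(med$lb, med2$lb)
  expect_equal(med$ub, med2$ub)
})

test_that("supplementing the missing precursor rescues growth", {
  b <- branched_model()
  # gF blocks sterol synthesis: no growth on minimal medium
  bdel <- apply_deletions(b, "gF")
  expect_equal(fba(bdel)$objective, 0)
  # opening the sterol exchange to uptake is the unique rescue
  rescued <- apply_medium(bdel, medium_spec(c("EX_glc", "EX_o2", "EX_sterol"),
                                            lb = c(-10, -Inf, -10), ub = Inf))
  expect_gt(fba(rescued)$objective, 1)
})

test_that("anaerobic transform closes oxygen, opens supplements, swaps lipid", {
  b <- branched_model()
  # closing oxygen alone (aerobic biomass still active) blocks growth
  b_noO2 <- apply_medium(b, medium_spec(c("EX_glc", "EX_o2"),
                                        lb = c(-10, 0), ub = Inf))
  expect_equal(fba(b_noO2)$objective, 0)
  # the full transform restores growth through the anaerobic lipid variant
  ba <- anaerobic_transform(b, "EX_o2", "EX_sterol", "r_lipA", "r_lipB",
                            uptake = 10)
  expect_gt(fba(ba)$objective, 0)
  expect_gte(ba$reactions$EX_o2$lb, 0)
  # aerobic lipid pseudoreaction carries zero flux in any optimum
  rng <- fva(ba, "r_lipA", fraction = 1.0)
  expect_equal(rng$min, 0, tolerance = 1e-9)
  expect_equal(rng$max, 0, tolerance = 1e-9)
  # missing reaction ids are reported by name
  expect_error(anaerobic_transform(b, "EX_o2", "EX_nope", "r_lipA", "r_lipB"),
               "EX_nope")
})

test_that("fractional flux restriction interpolates between deletion and wild type", {
  m <- chain_model(3, 10)
  ref <- geometric_fba(m)
  # fraction 0 == deletion of every reaction the gene touches
  r0 <- fba(restrict_gene_flux(m, "g1", 0, ref))$objective
  expect_equal(r0, fba(apply_deletions(m, "g1"))$objective)
  # fraction 1 recovers the wild type
  expect_equal(fba(restrict_gene_flux(m, "g1", 1, ref))$objective, 10)
  # sole-pathway gene at fraction 0.5: fitness exactly 0.5
  expect_equal(fba(restrict_gene_flux(m, "g2", 0.5, ref))$objective, 5)
  # unknown gene: warning, identity transform
  expect_warning(m2 <- restrict_gene_flux(m, "gZZ", 0.5, ref), "not in model")
  expect_equal(flux_bounds(m2), flux_bounds(m))
})

test_that("sign-preserving restriction keeps the reference direction", {
  sp <- data.frame(id = c("A", "B", "A_b", "B_b"), stringsAsFactors = FALSE)
  rx <- list(
    reaction("EX_A", c(A = -1, A_b = 1), lb = -10, ub = Inf, sbo = 397L),
    reaction("rrev", c(A = -1, B = 1), lb = -Inf, ub = Inf, gpr = "g1",
             sbo = 176L),
    reaction("EX_B", c(B = -1, B_b = 1), lb = 0, ub = 8, sbo = 397L))
  m <- metab_model(sp, rx, objective_id = "EX_B", id = "signed")
  ref <- geometric_fba(m)
  expect_equal(unname(ref$fluxes["rrev"]), 8, tolerance = 1e-6)
  sym <- restrict_gene_flux(m, "g1", 0.5, ref)
  expect_equal(sym$reactions$rrev$lb, -4)   # symmetric about zero
  expect_equal(sym$reactions$rrev$ub, 4)
  sgn <- restrict_gene_flux(m, "g1", 0.5, ref, sign_preserving = TRUE)
  expect_equal(sgn$reactions$rrev$lb, 0)    # forward-only
  expect_equal(sgn$reactions$rrev$ub, 4)
})

test_that("restriction never raises fitness above one", {
  m <- random_feasible_model(31)
  ref <- geometric_fba(m)
  for (g in model_genes(m)) {
    for (f in c(0, 0.4, 0.8, 1)) {
      fit <- fba_fitness(m, restrict = stats::setNames(f, g), reference = ref)
      expect_lte(fit, 1)
      expect_gte(fit, 0)
    }
  }
})
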