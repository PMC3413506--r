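test_that("single-deletion screen separates essential from redundant genes", {
  b <- branched_model()
  scr <- single_deletion_screen(b, medium = branched_minimal_medium())
  expect_setequal(scr$gene, c("gA", "gB", "gC", "gD", "gE", "gF"))
  expect_true(all(scr$viable[scr$gene %in% c("gA", "gB")]))
  expect_false(any(scr$viable[scr$gene %in% c("gC", "gD", "gE", "gF")]))
  # counts sum to screened genes whatever the lists say
  cm <- score_essentiality(scr, essential = c("gC", "gD", "gE"),
                           auxotroph = "gF")
  expect_equal(cm$tp + cm$fn + cm$fp + cm$tn, nrow(scr))
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(2L, 0L, 0L, 4L))
  met <- confusion_metrics(cm)
  expect_equal(unname(met["sensitivity"]), 1)
  expect_equal(unname(met["specificity"]), 1)
  # OR-pair genes deleted one at a time are each viable
  expect_true(all(scr$viable[scr$gene %in% c("gA", "gB")]))
})

test_that("screen refuses a medium in which the wild type cannot grow", {
  b <- branched_model()
  dead <- medium_spec(exchange_reactions(b), lb = 0, ub = Inf)
  expect_error(single_deletion_screen(b, medium = dead), "wild type")
})

test_that("screen results are invariant under gene order permutation", {
  b <- branched_model()
  s1 <- single_deletion_screen(b, genes = c("gA", "gC", "gF"))
  s2 <- single_deletion_screen(b, genes = c("gF", "gA", "gC"))
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})

test_that("confusion metrics reproduce the published screening arithmetic", {
  # counts as printed for the yeast consensus model's 918-gene screen
  cm <- confusion_matrix(tp = 684, fn = 20, fp = 113, tn = 101)
  met <- confusion_metrics(cm)
  expect_equal(unname(met["sensitivity"]), 684 / 704)
  expect_equal(round(100 * unname(met["sensitivity"]), 1), 97.2)
  expect_equal(round(100 * unname(met["npv"]), 1), 83.5)
  expect_equal(round(100 * unname(met["ppv"]), 0), 86)
  expect_equal(round(100 * unname(met["specificity"]), 0), 47)
  expect_equal(unname(met["combined_accuracy"]), (684 / 704) * (101 / 214))
  # within 0.1 percentage point of the printed 45.88 (rounded inputs)
  expect_lt(abs(100 * unname(met["combined_accuracy"]) - 45.88), 0.1)
  # the printed 45.88% arises from the pre-rounded percentages
  expect_equal(round(97.2 * 47.2 / 100, 2), 45.88)
  expect_true(all(met >= 0 & met <= 1))
})

test_that("moving a gene between lists shifts columns, not row sums", {
  b <- branched_model()
  scr <- single_deletion_screen(b, medium = branched_minimal_medium())
  cm1 <- score_essentiality(scr, essential = c("gC", "gD", "gE", "gF"))
  cm2 <- score_essentiality(scr, essential = c("gC", "gD", "gE"),
                            auxotroph = "gF")
  expect_equal(c(cm1$tp, cm1$fn, cm1$fp, cm1$tn),
               c(cm2$tp, cm2$fn, cm2$fp, cm2$tn))
  # dropping gF from both lists moves it from TN to FN; row sum constant
  cm3 <- score_essentiality(scr, essential = c("gC", "gD", "gE"))
  expect_equal(cm3$tn, cm2$tn - 1L)
  expect_equal(cm3$fn, cm2$fn + 1L)
  expect_equal(cm3$tp + cm3$fn + cm3$fp + cm3$tn,
               cm2$tp + cm2$fn + cm2$fp + cm2$tn)
})

test_that("auxotrophy screen classifies rescue, leak and non-rescue", {
  b <- branched_model()
  minimal <- branched_minimal_medium()
  supplemented <- open_medium(b, uptake = 10)
  aux <- auxotrophy_screen(b, c("gF", "gA", "gC"), minimal, supplemented)
  cat_of <- function(g) aux$category[aux$gene == g]
  # gF: dead on minimal, rescued by sterol uptake -- the auxotroph signature
  expect_identical(cat_of("gF"), "auxotroph_confirmed")
  # gA: grows on minimal (isoenzyme) -- not an auxotroph in the model
  expect_identical(cat_of("gA"), "viable_in_minimal")
  # gC: complex subunit, no medium can rescue it
  expect_identical(cat_of("gC"), "inviable_in_supplemented")
  # categories are mutually exclusive and exhaustive
  expect_true(all(aux$category %in% c("auxotroph_confirmed",
                                      "viable_in_minimal",
                                      "inviable_in_supplemented")))
})

test_that("gene list files are parsed with comments and blanks", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# essential genes", "gC", "gD  ", "", "gE # complex",
               "gC"), f)
  expect_identical(read_gene_list(f), c("gC", "gD", "gE"))
})

test_that("model comparison emits one row per model, surviving failures", {
  b <- branched_model()
  m <- chain_model(3, 10)
  tab <- compare_models(list(two = b, one = b),
                        essential = c("gC", "gD", "gE"), auxotroph = "gF",
                        minimal = branched_minimal_medium(),
                        supplemented = open_medium(b, uptake = 10))
  expect_equal(nrow(tab), 2)
  # identical inputs give identical rows (modulo the name column)
  expect_equal(tab[1, -1], tab[2, -1], ignore_attr = TRUE)
  expect_equal(tab$genes[1], 6)
  expect_equal(tab$auxotroph_confirmed[1], 1L)
  # census-only call works without lists
  census <- compare_models(list(chain = m))
  expect_equal(census$reactions, 5)
  expect_equal(census$exchange, 2)
  # a failing model still leaves the others' rows intact
  dead <- apply_deletions(b, c("gA", "gB"))
  expect_warning(
    tab2 <- compare_models(list(ok = b, dead = dead),
                           essential = "gC",
                           minimal = branched_minimal_medium()),
    "failed")
  expect_equal(nrow(tab2), 2)
  expect_false(is.na(tab2$sensitivity[1]))
  expect_true(is.na(tab2$sensitivity[2]))
})
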