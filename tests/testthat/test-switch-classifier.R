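# Four-category mutant classification and common-induced-gene detection.

obs <- function(genotype = "x", infected = TRUE, it = infected,
                cell = "differentiated", bact = if (infected) TRUE else NA,
                w1 = FALSE, w2 = FALSE, fix = FALSE) {
  mutantObservation(genotype, infected, it, cell, bact, w1, w2, fix)
}

test_that("the archetypal evidence patterns map to their categories", {
  # V1 / exoY: empty uninfected nodules, root-like transcriptome
  r <- classifyMutant(obs("V1", infected = FALSE, it = FALSE,
                          cell = "undifferentiated", bact = NA))
  expect_equal(r$category, "cat4_empty_uninfected")
  expect_true(r$consistent)
  # bacA: infected, differentiated cells, undifferentiated bacteroids,
  # first wave only
  r <- classifyMutant(obs("bacA", cell = "differentiated", bact = FALSE,
                          w1 = TRUE, w2 = FALSE))
  expect_equal(r$category, "cat2_bacteroid_undifferentiated")
  expect_true(r$consistent)
  # TR3/TE7: infection threads but no symbiotic cells
  r <- classifyMutant(obs("TR3", cell = "undifferentiated", bact = FALSE))
  expect_equal(r$category, "cat3_infected_no_symbiotic_cells")
  expect_true(r$consistent)
  # fully differentiated Fix- mutant with both waves
  r <- classifyMutant(obs("TR36", bact = TRUE, w1 = TRUE, w2 = TRUE))
  expect_equal(r$category, "cat1_fix_minus_fully_differentiated")
  expect_true(r$consistent)
  # a nitrogen-fixing nodule with the same markers is wild-type-like
  r <- classifyMutant(obs("wt", bact = TRUE, w1 = TRUE, w2 = TRUE,
                          fix = TRUE))
  expect_equal(r$category, "wild_type_like")
})

test_that("wave mismatches warn and clear the consistency flag only", {
  expect_warning(
    r <- classifyMutant(obs("odd", bact = TRUE, w1 = TRUE, w2 = FALSE)),
    "expected pattern")
  expect_equal(r$category, "cat1_fix_minus_fully_differentiated")
  expect_false(r$consistent)
})

test_that("classification is total over the reachable observation space", {
  grid <- expand.grid(infected = c(TRUE, FALSE), it = c(TRUE, FALSE),
                      cell = c("differentiated", "undifferentiated",
                               "indeterminate"),
                      bact = c(TRUE, FALSE), w1 = c(TRUE, FALSE),
                      w2 = c(TRUE, FALSE), fix = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    b <- if (g$infected) g$bact else NA
    o <- try(mutantObservation("g", g$infected, g$it, g$cell, b, g$w1,
                               g$w2, g$fix), silent = TRUE)
    if (inherits(o, "try-error")) next  # invariant-violating combination
    res <- try(suppressWarnings(classifyMutant(o)), silent = TRUE)
    if (g$cell == "indeterminate") {
      expect_match(attr(res, "condition")$message, "more data")
    } else if (g$cell == "differentiated" && !g$infected) {
      expect_match(attr(res, "condition")$message, "outside the observable")
    } else if (g$infected && g$cell == "undifferentiated" && !g$it) {
      expect_match(attr(res, "condition")$message, "outside the observable")
    } else {
      expect_true(res$category %in% noduleWaves:::mutantCategories)
    }
  }
  # bacteroid evidence must agree with the infection status
  expect_error(mutantObservation("z", FALSE, FALSE, "undifferentiated",
                                 TRUE, FALSE, FALSE),
               "must be NA")
  expect_error(mutantObservation("z", TRUE, TRUE, "differentiated",
                                 NA, FALSE, FALSE),
               "required")
})

test_that("panel classification is order invariant and counts categories", {
  panel <- list(
    obs("TR36", bact = TRUE, w1 = TRUE, w2 = TRUE),
    obs("bacA", bact = FALSE, w1 = TRUE, w2 = FALSE),
    obs("TR3", cell = "undifferentiated", bact = FALSE),
    obs("V1", infected = FALSE, it = FALSE, cell = "undifferentiated",
        bact = NA))
  r1 <- classifyPanel(panel)
  expect_equal(r1$n_categories, 4L)
  r2 <- classifyPanel(rev(panel))
  expect_equal(sort(r1$table$genotype), sort(r2$table$genotype))
  m1 <- setNames(r1$table$category, r1$table$genotype)
  m2 <- setNames(r2$table$category, r2$table$genotype)
  expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
  # a lone wild type yields only the wild-type-like class
  wt <- classifyPanel(list(obs("wt", bact = TRUE, w1 = TRUE, w2 = TRUE,
                               fix = TRUE)))
  expect_equal(wt$n_categories, 0L)
  expect_equal(wt$table$category, "wild_type_like")
  expect_error(classifyPanel(list()), "empty")
})

test_that("common induced genes require induction in every queried mutant", {
  # toy matrix: g1 induced in both mutants, g2 in only one, g3 in none
  m <- rbind(
    g1 = c(0, 0.1, -0.1, 3, 3.1, 2.9, 2, 2.2, 1.9),
    g2 = c(0, 0.1, -0.1, 3, 3.1, 2.9, 0, 0.2, -0.1),
    g3 = c(0, 0.1, -0.1, 0.1, 0, -0.2, 0, 0.1, 0.1))
  colnames(m) <- c(paste0("r", 1:3), paste0("m1_", 1:3), paste0("m2_", 1:3))
  expr <- exprFromMatrix(m)
  got <- commonInducedGenes(expr,
                            list(m1 = paste0("m1_", 1:3),
                                 m2 = paste0("m2_", 1:3)),
                            paste0("r", 1:3))
  expect_identical(got, "g1")
  expect_error(commonInducedGenes(expr, list(), paste0("r", 1:3)), "empty")
  expect_error(commonInducedGenes(expr, list(m1 = "m1_1"), paste0("r", 1:3)),
               "fewer than 2")
})

test_that("zero-noise synthetic panels recover archetypes and common genes", {
  cfg <- zeroNoiseConfig()
  panel <- simulateMutantPanel(cfg, seed = 1)
  raw <- buildRatioMatrix(panel$tables, panel$metadata)
  mnorm <- normalizeArrays(raw, selectInvariantGenes(raw, cfg$anchor_id,
                                                     cfg$n_invariant))
  md <- panel$metadata
  roots <- md$array_id[md$genotype == "root"]
  rootlike <- panel$truth$genotypes$genotype[
    panel$truth$genotypes$expression == "root_like"]
  ids <- lapply(setNames(rootlike, rootlike),
                function(g) md$array_id[md$genotype == g])
  common <- commonInducedGenes(mnorm, ids, roots)
  expect_setequal(common,
                  panel$truth$genes$gene_id[panel$truth$genes$common])
})
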