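# The generators are pure functions of (config, seed), emit complete truth
# labels, and plant the structure the downstream analysis assumes.

test_that("time-course generator is deterministic in the seed", {
  cfg <- smallConfig()
  a <- simulateTimecourse(cfg, seed = 1)
  b <- simulateTimecourse(cfg, seed = 1)
  c <- simulateTimecourse(cfg, seed = 2)
  expect_identical(a$tables, b$tables)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$tables, c$tables))
})

test_that("zero-noise differential genes sit exactly on their templates", {
  cfg <- zeroNoiseConfig()
  tc <- simulateTimecourse(cfg, seed = 1)
  tmpl <- profileTemplates(cfg$de_effect)
  de <- tc$truth$genes[!is.na(tc$truth$genes$profile), ]
  for (stage in c("roots", "incipient", "nodules")) {
    arr <- tc$metadata$array_id[tc$truth$samples$stage == stage][1]
    tab <- tc$tables[[arr]]
    r <- collapseReplicates(tab)
    expect_equal(unname(log2(r[de$gene_id])),
                 unname(tmpl[de$profile, stage]), tolerance = 1e-12)
  }
})

test_that("truth labels are complete and the anchor is replicated", {
  cfg <- smallConfig()
  tc <- simulateTimecourse(cfg, seed = 3)
  expect_setequal(tc$truth$genes$gene_id,
                  setdiff(unique(tc$tables[[1]]$gene_id), cfg$anchor_id))
  expect_false(any(is.na(tc$truth$genes$label)))
  expect_false(any(is.na(tc$truth$samples$stage)))
  expect_equal(sum(tc$tables[[1]]$gene_id == cfg$anchor_id),
               cfg$replicate_spots)
  # every array of the design is emitted
  expect_equal(length(tc$tables),
               length(cfg$timepoints) * cfg$arrays_per_timepoint)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generatorConfig(n_genes = 100, n_de = 80, n_invariant = 50),
               "exceeds n_genes")
  expect_error(generatorConfig(profile_sizes = rep(10L, 8L)),
               "sum to n_de")
  expect_error(generatorConfig(ploidy_mixtures = list(root = c("2" = 0.5))),
               "sum to 1")
  expect_error(generatorConfig(
    qpcr_params = list(efficiency = c(target = 2.5, reference = 2),
                       base_cp = c(target = 24, reference = 18),
                       folds = c(a = 1), replicates = 3L,
                       cp_noise_sd = 0.1, load_sd = 0.2)),
    "\\(1, 2\\]")
  cfg <- smallConfig()
  cfg$mutant_archetypes <- c(x1 = "no_such_archetype")
  expect_error(simulateMutantPanel(cfg, seed = 1), "unknown archetype")
})

test_that("mutant archetypes express the planted wave structure at zero noise", {
  cfg <- zeroNoiseConfig()
  panel <- simulateMutantPanel(cfg, seed = 1)
  tmpl <- profileTemplates(cfg$de_effect)
  g7 <- tc_g <- panel$truth$genes$gene_id[
    which(panel$truth$genes$profile == 7L)[1]]
  ratioOf <- function(genotype, gene) {
    arr <- panel$metadata$array_id[panel$metadata$genotype == genotype][1]
    log2(collapseReplicates(panel$tables[[arr]])[[gene]])
  }
  # wild-type-like genotype: profile-7 gene at its nodule template level
  expect_equal(ratioOf("TR36", g7), tmpl["7", "nodules"], tolerance = 1e-12)
  # bacA-like genotype: second-wave gene stays at its root level
  expect_equal(ratioOf("bacA", g7), tmpl["7", "roots"], tolerance = 1e-12)
  # but first-wave genes are activated in bacA
  g6 <- panel$truth$genes$gene_id[which(panel$truth$genes$profile == 6L)[1]]
  expect_equal(ratioOf("bacA", g6), tmpl["6", "nodules"], tolerance = 1e-12)
  # root-like genotype: everything at root levels except common genes
  expect_equal(ratioOf("V1", g7), tmpl["7", "roots"], tolerance = 1e-12)
  cg <- panel$truth$genes$gene_id[panel$truth$genes$common][1]
  expect_equal(ratioOf("V1", cg) - ratioOf("root", cg),
               cfg$common_induction, tolerance = 1e-12)
})

test_that("ploidy histograms recover the planted mixture", {
  cfg <- smallConfig()
  # degenerate single-class mixture with vanishing peak width
  cfg1 <- smallConfig(ploidy_mixtures = list(only2c = c("2" = 1)),
                      ploidy_cv = 1e-9)
  h <- simulatePloidy("only2c", 1000, seed = 1, config = cfg1)
  p <- callPloidyFractions(h, cfg1$anchor_2c)
  expect_equal(unname(ploidyFractions(p)), c(100, 0, 0, 0, 0, 0))
  # default root mixture at n = 10000: within 2 percentage points
  h2 <- simulatePloidy("root", 10000, seed = 2, config = cfg)
  p2 <- callPloidyFractions(h2, cfg$anchor_2c)
  planted <- 100 * c(cfg$ploidy_mixtures$root, "16" = 0, "32" = 0, "64" = 0)
  expect_true(all(abs(ploidyFractions(p2) - planted[names(ploidyFractions(p2))]) < 2))
  expect_length(h2, cfg$ploidy_replicates)
  expect_error(simulatePloidy("no_such_mixture", 1000, seed = 1, config = cfg),
               "configuration error")
  expect_error(simulatePloidy("root", 10, seed = 1, config = cfg), ">= 100")
})

test_that("bacteroid length models have the stated support and fold", {
  cfg <- smallConfig()
  lc <- simulateBacteroidLengths("cultured", 1000, seed = 1, config = cfg)
  expect_true(all(lc >= 1 & lc <= 2))
  ld <- simulateBacteroidLengths("differentiated", 1000, seed = 2, config = cfg)
  fold <- mean(ld) / mean(lc)
  expect_gt(fold, 4 * 0.93)
  expect_lt(fold, 5 * 1.07)
  expect_identical(simulateBacteroidLengths("cultured", 50, seed = 7),
                   simulateBacteroidLengths("cultured", 50, seed = 7))
  expect_error(simulateBacteroidLengths("no_such_model", 100, seed = 1),
               "configuration error")
})

test_that("qPCR generator encodes folds as efficiency-corrected CPs", {
  # planted fold 8 with E = 2 and no noise: target CPs differ by exactly 3
  cfg <- smallConfig(qpcr_params = list(
    efficiency = c(target = 2, reference = 2),
    base_cp = c(target = 24, reference = 18),
    folds = c(a = 1, b = 8), replicates = 3L,
    cp_noise_sd = 0, load_sd = 0))
  ds <- simulateQpcr(cfg, seed = 1)
  cp <- ds$cp
  cpt <- function(s) mean(cp$cp[cp$transcript == "target" & cp$sample == s])
  expect_equal(cpt("a") - cpt("b"), 3, tolerance = 1e-12)
  # planted fold 1 everywhere: relative expression is 1 for all samples
  cfg1 <- smallConfig(qpcr_params = list(
    efficiency = c(target = 2, reference = 2),
    base_cp = c(target = 24, reference = 18),
    folds = c(a = 1, b = 1, c = 1), replicates = 3L,
    cp_noise_sd = 0, load_sd = 0))
  re <- pfafflRelativeExpression(simulateQpcr(cfg1, seed = 1))
  expect_equal(re$fold, rep(1, 3), tolerance = 1e-12)
  # noisy recovery of planted folds within 15 percent
  cfg2 <- smallConfig(qpcr_params = list(
    efficiency = c(target = 2, reference = 2),
    base_cp = c(target = 24, reference = 18),
    folds = c(a = 1, b = 4, c = 16), replicates = 3L,
    cp_noise_sd = 0.1, load_sd = 0.2))
  re2 <- pfafflRelativeExpression(simulateQpcr(cfg2, seed = 4))
  expect_true(all(abs(re2$fold / c(1, 4, 16) - 1) < 0.15))
})

test_that("generator configuration survives a YAML round trip", {
  cfg <- smallConfig()
  path <- tempfile(fileext = ".yaml")
  writeGeneratorConfig(cfg, path)
  back <- readGeneratorConfig(path)
  expect_equal(back$n_genes, cfg$n_genes)
  expect_equal(back$profile_sizes, cfg$profile_sizes)
  expect_equal(back$ploidy_mixtures, cfg$ploidy_mixtures)
  expect_equal(back$mutant_archetypes, cfg$mutant_archetypes)
})
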