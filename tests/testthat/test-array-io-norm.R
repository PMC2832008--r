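# Spot-table input, replicate collapse, invariant-gene selection and
# invariant-median normalization.

writeToySpots <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("spot tables round-trip exactly and malformed input is named", {
  rows <- data.frame(
    spot_id = c("s1", "s2", "s3"), gene_id = c("g1", "g2", "g2"),
    replicate_index = c(1L, 1L, 2L),
    sample_intensity = c(100.25, 7, 0),
    reference_intensity = c(50, 14.5, 3))
  tab <- readSpotTable(writeToySpots(rows), array_id = "toy")
  expect_equal(tab$sample_intensity, rows$sample_intensity)
  expect_equal(tab$reference_intensity, rows$reference_intensity)
  expect_equal(attr(tab, "array_id"), "toy")
  expect_equal(as.integer(attr(tab, "replicate_counts")["g2"]), 2L)

  bad <- rows; bad$sample_intensity[2] <- "oops"
  expect_error(readSpotTable(writeToySpots(bad)), "line 3.*oops")
  neg <- rows; neg$reference_intensity[3] <- -1
  expect_error(readSpotTable(writeToySpots(neg)), "negative intensity")
})

test_that("the generated anchor is spotted 12 times and collapses cleanly", {
  cfg <- smallConfig()
  tc <- simulateTimecourse(cfg, seed = 1)
  path <- writeSpotTables(tc$tables[1], tempfile("spots_"))
  tab <- readSpotTable(path[1])
  expect_equal(as.integer(attr(tab, "replicate_counts")[cfg$anchor_id]), 12L)
  r <- collapseReplicates(tab)
  # anchor planted at unit ratio; 12-spot median stays close under noise
  scale <- median(r[tc$truth$genes$gene_id[tc$truth$genes$label == "invariant"]])
  expect_equal(unname(r[cfg$anchor_id] / scale), 1, tolerance = 0.3)
})

test_that("replicate collapse is the median over usable spots", {
  tab <- data.frame(
    spot_id = paste0("s", 1:5),
    gene_id = c("a", "b", "b", "b", "c"),
    replicate_index = c(1L, 1L, 2L, 3L, 1L),
    sample_intensity = c(100, 10, 40, 90, 5),
    reference_intensity = c(50, 10, 20, 10, 0))
  expect_warning(r <- collapseReplicates(tab), "c")
  expect_equal(unname(r["a"]), 2.0)
  expect_equal(unname(r["b"]), 2.0)  # median of {1, 2, 9}
  expect_false("c" %in% names(r))
  expect_equal(attr(r, "excluded"), "c")
})

test_that("invariant selection scores against the anchor with brute force", {
  set.seed(42)
  n_arr <- 6
  ids <- sprintf("g%03d", 1:100)
  m <- matrix(NA_real_, 101, n_arr,
              dimnames = list(c(ids, "anch"), paste0("a", 1:n_arr)))
  m["anch", ] <- 2^rnorm(n_arr, 0, 0.3)
  planted <- ids[31:60]  # proportional to the anchor up to tiny noise
  for (g in ids) {
    m[g, ] <- if (g %in% planted) m["anch", ] * 2^rnorm(n_arr, 0, 0.01)
              else 2^rnorm(n_arr, 0, 0.8)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = m),
    colData = S4Vectors::DataFrame(array_id = colnames(m),
                                   row.names = colnames(m)))
  raw <- new("NoduleArraySet", se, normalized = FALSE)
  sel <- selectInvariantGenes(raw, "anch", 30)
  expect_setequal(sel, planted)
  # brute-force score oracle
  oracle <- sapply(ids, function(g) sd(log2(m[g, ] / m["anch", ])))
  expect_setequal(sel, names(sort(oracle))[1:30])
  expect_error(selectInvariantGenes(raw, "missing_anchor", 10),
               "missing")
})

test_that("perfectly anchor-proportional genes tie and break lexicographically", {
  m <- matrix(rep(c(1, 2, 4), each = 5), 5, 3, byrow = FALSE)
  rownames(m) <- c("z", "y", "anch", "b", "a")
  colnames(m) <- paste0("arr", 1:3)
  m <- sweep(m, 1, c(3, 1, 1, 2, 5), "*")   # gene-specific constants
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = m),
    colData = S4Vectors::DataFrame(array_id = colnames(m),
                                   row.names = colnames(m)))
  raw <- new("NoduleArraySet", se, normalized = FALSE)
  sel <- selectInvariantGenes(raw, "anch", 2)
  expect_identical(sort(sel), c("a", "b"))
})

test_that("normalization divides by the invariant median and is idempotent", {
  m <- matrix(2, 5, 2, dimnames = list(c("i1", "i2", "i3", "g", "h"),
                                       c("a1", "a2")))
  m["g", ] <- 6
  m["h", ] <- 1
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = m),
    colData = S4Vectors::DataFrame(array_id = colnames(m),
                                   row.names = colnames(m)))
  raw <- new("NoduleArraySet", se, normalized = FALSE)
  norm <- normalizeArrays(raw, c("i1", "i2", "i3"))
  a <- SummarizedExperiment::assay(norm, "log2ratio")
  expect_equal(unname(a["g", ]), rep(log2(3), 2))
  expect_equal(unname(scaleFactors(norm)), rep(2, 2))
  # invariant-median identity on every array
  lin <- 2^a[invariantGenes(norm), ]
  expect_equal(unname(apply(lin, 2, median)), c(1, 1), tolerance = 1e-12)
  # idempotence: renormalizing changes nothing
  norm2 <- normalizeArrays(norm, c("i1", "i2", "i3"))
  expect_equal(SummarizedExperiment::assay(norm2, "log2ratio"), a)
  expect_equal(unname(scaleFactors(norm2)), c(1, 1))
})

test_that("normalization is equivariant to per-array intensity scale", {
  cfg <- smallConfig()
  tc <- simulateTimecourse(cfg, seed = 5)
  tabs <- tc$tables
  tabs2 <- tabs
  tabs2[[3]]$sample_intensity <- tabs2[[3]]$sample_intensity * 7.3
  inv <- function(tabs) {
    raw <- buildRatioMatrix(tabs, tc$metadata)
    sel <- selectInvariantGenes(raw, cfg$anchor_id, cfg$n_invariant)
    SummarizedExperiment::assay(normalizeArrays(raw, sel), "log2ratio")
  }
  expect_equal(inv(tabs), inv(tabs2), tolerance = 1e-10)
})

test_that("zero-noise normalization reproduces templates and planted invariants", {
  cfg <- zeroNoiseConfig()
  tc <- simulateTimecourse(cfg, seed = 1)
  raw <- buildRatioMatrix(tc$tables, tc$metadata)
  sel <- selectInvariantGenes(raw, cfg$anchor_id, cfg$n_invariant)
  planted <- tc$truth$genes$gene_id[tc$truth$genes$label == "invariant"]
  expect_setequal(sel, planted)
  norm <- normalizeArrays(raw, sel)
  a <- SummarizedExperiment::assay(norm, "log2ratio")
  tmpl <- profileTemplates(cfg$de_effect)
  de <- tc$truth$genes[!is.na(tc$truth$genes$profile), ]
  for (stage in c("roots", "incipient", "nodules")) {
    arr <- tc$metadata$array_id[tc$metadata$stage == stage]
    got <- rowMeans(a[de$gene_id, arr, drop = FALSE])
    expect_equal(unname(got), unname(tmpl[de$profile, stage]),
                 tolerance = 1e-9)
  }
})

test_that("expression matrices round-trip through text plus sidecar", {
  cfg <- smallConfig()
  tc <- simulateTimecourse(cfg, seed = 2)
  raw <- buildRatioMatrix(tc$tables, tc$metadata)
  sel <- selectInvariantGenes(raw, cfg$anchor_id, cfg$n_invariant)
  norm <- normalizeArrays(raw, sel)
  path <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(norm, path)
  back <- readExpressionMatrix(path)
  expect_equal(SummarizedExperiment::assay(back, "log2ratio"),
               SummarizedExperiment::assay(norm, "log2ratio"),
               tolerance = 1e-12)
  expect_setequal(invariantGenes(back), invariantGenes(norm))
  expect_equal(arrayStages(back), arrayStages(norm))
})
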