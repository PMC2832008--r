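# Shared fixtures: a scaled-down generator configuration for fast unit
# tests, and a direct constructor for normalized expression objects.

smallConfig <- function(...) {
  generatorConfig(
    n_genes = 120L, n_de = 40L, n_invariant = 60L, n_common = 4L,
    profile_sizes = rep(5L, 8L), arrays_per_timepoint = 3L,
    ...
  )
}

zeroNoiseConfig <- function(...) {
  smallConfig(noise_sd = 0, scale_sd = 0, ...)
}

# Build a normalized NoduleArraySet straight from a log2 matrix.
exprFromMatrix <- function(m, stage = NULL, genotype = NA_character_,
                           dpi = NA_real_) {
  cd <- S4Vectors::DataFrame(
    array_id = colnames(m),
    genotype = genotype,
    dpi = dpi,
    row.names = colnames(m)
  )
  if (!is.null(stage)) cd$stage <- stage
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = m), colData = cd)
  new("NoduleArraySet", se, normalized = TRUE,
      invariantGenes = character(0), scaleFactors = rep(1, ncol(m)))
}

# Truth-derived helpers
plantedDeGenes <- function(truth) truth$genes$gene_id[!is.na(truth$genes$profile)]
plantedProfiles <- function(truth, genes) {
  truth$genes$profile[match(genes, truth$genes$gene_id)]
}
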