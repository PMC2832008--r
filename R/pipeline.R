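# End-to-end orchestration: simulate -> normalize -> DE -> profiles ->
# enrichment -> differentiation -> mutant classification -> report.

#' Pipeline configuration
#'
#' @param out_dir directory for intermediate artifacts and the report.
#' @param alpha significance threshold for DE selection and induction tests.
#' @param k_profiles number of temporal profiles.
#' @param k_sample_clusters number of sample clusters.
#' @param wave_threshold wave activation threshold (log2 units).
#' @param ei_bounds endoreduplication-index decision bounds.
#' @param bacteroid_fold_threshold bacteroid differentiation fold threshold.
#' @param n_invariant invariant genes used for normalization.
#' @param seed master seed for all generated inputs.
#' @param generator a \code{\link{generatorConfig}} for the synthetic
#'   inputs.
#' @return validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(out_dir = tempfile("nodulewaves_run_"),
                           alpha = 0.01, k_profiles = 8L,
                           k_sample_clusters = 3L, wave_threshold = 1.0,
                           ei_bounds = c(2, 15),
                           bacteroid_fold_threshold = 2.5,
                           n_invariant = 1500L, seed = 1L,
                           generator = generatorConfig(seed = seed)) {
  stopifnot(alpha > 0, wave_threshold > 0, all(ei_bounds > 0),
            bacteroid_fold_threshold > 0, n_invariant > 0)
  structure(list(
    out_dir = out_dir, alpha = alpha, k_profiles = as.integer(k_profiles),
    k_sample_clusters = as.integer(k_sample_clusters),
    wave_threshold = wave_threshold, ei_bounds = ei_bounds,
    bacteroid_fold_threshold = bacteroid_fold_threshold,
    n_invariant = as.integer(n_invariant), seed = as.integer(seed),
    generator = generator
  ), class = "PipelineConfig")
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Generates the time-course and mutant-panel arrays, flow-cytometry
#' histograms, bacteroid lengths and annotation table from the configured
#' generator, then runs normalization, stage differential expression,
#' profile clustering, secretome enrichment, differentiation scoring and the
#' four-category mutant classification, writing intermediate tables and a
#' machine-readable JSON report.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param write_artifacts write intermediate tables under
#'   \code{config$out_dir}.
#' @return the run report (list), invisibly also written as
#'   \code{report.json}.
#' @export
runPipeline <- function(config = pipelineConfig(), write_artifacts = TRUE) {
  cfg <- config
  gen <- cfg$generator
  if (write_artifacts && !dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    message("[noduleWaves] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  tc <- stage("simulate", simulateTimecourse(gen, seed = cfg$seed))
  panel <- stage("simulate", simulateMutantPanel(gen, seed = cfg$seed + 1L))

  norm <- stage("normalize", {
    raw <- buildRatioMatrix(tc$tables, tc$metadata)
    inv <- selectInvariantGenes(raw, gen$anchor_id, cfg$n_invariant)
    normalizeArrays(raw, inv)
  })

  de <- stage("de", {
    groups <- assignStages(norm)
    res <- pairwiseStageTests(norm, groups)
    list(groups = groups, result = res, genes = selectDeGenes(res, cfg$alpha))
  })
  digital <- stage("de", digitalTransform(de$result, de$genes, cfg$alpha))

  prof <- stage("profiles",
    clusterGeneProfiles(norm, de$genes, cfg$k_profiles, de$groups))
  pca <- stage("profiles", pcaSamples(norm))
  sclust <- stage("profiles", clusterSamples(norm, cfg$k_sample_clusters))

  enrich <- stage("enrichment", {
    ann <- simulateAnnotations(tc$truth, seed = cfg$seed + 2L, config = gen)
    wave_set <- names(prof$assignment)[prof$assignment >= 5L]
    fisherEnrichment(wave_set, ann$gene_id, ann)
  })

  mut <- stage("classification", {
    raw <- buildRatioMatrix(panel$tables, panel$metadata)
    inv <- selectInvariantGenes(raw, gen$anchor_id, cfg$n_invariant)
    mnorm <- normalizeArrays(raw, inv)
    md <- panel$metadata
    root_arrays <- md$array_id[md$genotype == "root"]
    baseline <- rootBaseline(mnorm, root_arrays)
    waves <- waveActivation(mnorm, prof, baseline, cfg$wave_threshold)
    gts <- panel$truth$genotypes
    obs <- list(); ei <- list(); bac <- list()
    cultured <- simulateBacteroidLengths("cultured", 1000L,
                                         seed = cfg$seed + 3L, config = gen)
    for (i in seq_len(nrow(gts))) {
      g <- gts$genotype[i]
      if (g == "root") next
      h <- simulatePloidy(gts$ploidy[i], 10000L, seed = cfg$seed + 10L + i,
                          config = gen)
      prof_p <- callPloidyFractions(h, gen$anchor_2c, g)
      ei[[g]] <- endoreduplicationIndex(prof_p)
      cell <- classifyCellDifferentiation(ei[[g]], cfg$ei_bounds)
      bdiff <- NA
      if (gts$infected[i]) {
        lens <- simulateBacteroidLengths(gts$bacteroid[i], 1000L,
                                         seed = cfg$seed + 40L + i,
                                         config = gen)
        call <- classifyBacteroidDifferentiation(lens, cultured,
                                                 cfg$bacteroid_fold_threshold)
        bac[[g]] <- call$fold
        bdiff <- call$differentiated
      }
      warr <- md$array_id[md$genotype == g]
      w1 <- mean(waves$wave1_score[waves$sample %in% warr]) >= cfg$wave_threshold
      w2 <- mean(waves$wave2_score[waves$sample %in% warr]) >= cfg$wave_threshold
      obs[[g]] <- mutantObservation(
        genotype = g, infected = gts$infected[i],
        infection_thread_network = gts$infection_thread_network[i],
        cell_diff = cell, bacteroid_diff = bdiff,
        wave1_active = w1, wave2_active = w2,
        nitrogen_fixing = gts$nitrogen_fixing[i])
    }
    panelRes <- classifyPanel(obs)
    # genes induced in every root-like mutant (categories 3 and 4), the
    # genotypes whose nodules otherwise display a root transcriptome
    rootlike <- panelRes$table$genotype[panelRes$table$category %in%
      c("cat3_infected_no_symbiotic_cells", "cat4_empty_uninfected")]
    mut_ids <- lapply(setNames(rootlike, rootlike),
                      function(g) md$array_id[md$genotype == g])
    common <- commonInducedGenes(mnorm, mut_ids, root_arrays, cfg$alpha)
    list(waves = waves, ei = unlist(ei), bacteroid_folds = unlist(bac),
         panel = panelRes, common_induced = common)
  })

  report <- stage("report", {
    rep <- list(
      software = list(package = "noduleWaves",
                      version = as.character(packageVersion("noduleWaves"))),
      seed = cfg$seed,
      config = list(alpha = cfg$alpha, k_profiles = cfg$k_profiles,
                    k_sample_clusters = cfg$k_sample_clusters,
                    wave_threshold = cfg$wave_threshold,
                    ei_bounds = cfg$ei_bounds,
                    bacteroid_fold_threshold = cfg$bacteroid_fold_threshold,
                    n_invariant = cfg$n_invariant),
      normalization = list(
        n_invariant = length(invariantGenes(norm)),
        scale_factors = as.list(scaleFactors(norm))),
      de = list(n_selected = length(de$genes)),
      profiles = list(sizes = as.list(table(prof$assignment))),
      sample_clusters = list(labels = as.list(sclust$labels),
                             pc_variance = pca$variance_fraction[1:2]),
      enrichment = enrich,
      differentiation = list(ei = as.list(mut$ei),
                             bacteroid_folds = as.list(mut$bacteroid_folds)),
      classification = list(
        categories = mut$panel$table,
        counts = as.list(mut$panel$counts),
        n_categories = mut$panel$n_categories,
        common_induced = mut$common_induced)
    )
    validateRunReport(rep)
    rep
  })

  if (write_artifacts) {
    writeExpressionMatrix(norm, file.path(cfg$out_dir, "expression.tsv"))
    writeDeTable(de$result, file.path(cfg$out_dir, "de_result.tsv"))
    writeDeTable(digital, file.path(cfg$out_dir, "digital_matrix.tsv"))
    write.table(data.frame(gene_id = names(prof$assignment),
                           profile_id = prof$assignment),
                file.path(cfg$out_dir, "profiles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    dendrogramNewick(sclust$tree, file.path(cfg$out_dir, "samples.nwk"))
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
  }
  invisible(report)
}

# Minimal structural validation of the run report against the schema
# shipped at inst/extdata/run-report-schema.json.
validateRunReport <- function(report) {
  schema_path <- system.file("extdata", "run-report-schema.json",
                             package = "noduleWaves")
  required <- if (nzchar(schema_path)) {
    sch <- jsonlite::read_json(schema_path)
    unlist(sch$required)
  } else {
    c("software", "seed", "config", "normalization", "de", "profiles",
      "sample_clusters", "enrichment", "differentiation", "classification")
  }
  missing <- setdiff(required, names(report))
  if (length(missing))
    stop("run report lacks required sections: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
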