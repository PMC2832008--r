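# Synthetic two-channel array generator.
#
# Layout of the synthetic probe set: gene ids are zero-padded ("MTU0001" ...)
# and assigned in truth blocks — the invariant core takes the
# lexicographically smallest ids among non-differential genes, then the
# differential genes in profile order, then the background genes (the first
# n_common of which form the planted common-induction set). GeneratorTruth is
# the authoritative label source; the id layout only guarantees that the
# documented lexicographic tie-break of invariant selection is well defined
# in fully degenerate (zero-variance) inputs.

geneLayout <- function(cfg) {
  ids <- sprintf("MTU%04d", seq_len(cfg$n_genes))
  n_bg <- cfg$n_genes - cfg$n_de - cfg$n_invariant
  label <- c(
    rep("invariant", cfg$n_invariant),
    rep(paste0("profile", 1:8), times = cfg$profile_sizes),
    rep("background", n_bg)
  )
  profile <- c(
    rep(NA_integer_, cfg$n_invariant),
    rep(1:8, times = cfg$profile_sizes),
    rep(NA_integer_, n_bg)
  )
  common <- rep(FALSE, cfg$n_genes)
  if (cfg$n_common > 0L)
    common[cfg$n_invariant + cfg$n_de + seq_len(cfg$n_common)] <- TRUE
  data.frame(gene_id = ids, label = label, profile = profile,
             common = common, stringsAsFactors = FALSE)
}

# Per-gene log2 true sample/reference ratios for one condition.
# `stage_col` is "roots"/"incipient"/"nodules" for time-course stages;
# `expression` is one of wild_type_like / bacA_like / root_like /
# root_control for mutant-panel arrays (stage_col then ignored).
trueLog2Ratio <- function(layout, cfg, baseLog2, stage_col = NULL,
                          expression = NULL) {
  tmpl <- profileTemplates(cfg$de_effect)
  out <- baseLog2  # invariant/background constitutive levels, 0 for DE genes
  de <- !is.na(layout$profile)
  if (!is.null(expression)) {
    col <- switch(expression,
      wild_type_like = rep("nodules", sum(de)),
      bacA_like = ifelse(layout$profile[de] %in% c(5L, 6L), "nodules", "roots"),
      root_like = rep("roots", sum(de)),
      root_control = rep("roots", sum(de)),
      stop("configuration error: unknown expression archetype '", expression, "'")
    )
    out[de] <- tmpl[cbind(layout$profile[de], match(col, colnames(tmpl)))]
    if (expression != "root_control" && cfg$n_common > 0L)
      out[layout$common] <- out[layout$common] + cfg$common_induction
  } else {
    out[de] <- tmpl[layout$profile[de], stage_col]
  }
  out
}

# Emit one spot table: every gene once plus the anchor replicate_spots times.
makeSpotTable <- function(array_id, layout, cfg, log2ratio, refBase,
                          arrayScaleLog2, jitterLog2) {
  gene_id <- c(layout$gene_id, rep(cfg$anchor_id, cfg$replicate_spots))
  replicate_index <- c(rep(1L, nrow(layout)), seq_len(cfg$replicate_spots))
  l2r <- c(log2ratio + jitterLog2, rep(0, cfg$replicate_spots))
  base <- c(refBase, rep(stats::median(refBase), cfg$replicate_spots))
  n <- length(gene_id)
  refNoise <- if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else numeric(n)
  samNoise <- if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else numeric(n)
  data.frame(
    spot_id = sprintf("%s_S%05d", array_id, seq_len(n)),
    gene_id = gene_id,
    replicate_index = replicate_index,
    sample_intensity = base * 2^(l2r + arrayScaleLog2 + samNoise),
    reference_intensity = base * 2^refNoise,
    stringsAsFactors = FALSE
  )
}

simulateArraySet <- function(cfg, seed, conditions) {
  withSeed(seed, {
    layout <- geneLayout(cfg)
    refBase <- 2^rnorm(cfg$n_genes, mean = 10, sd = 1.2)
    baseLog2 <- numeric(cfg$n_genes)
    nonde <- is.na(layout$profile)
    baseLog2[nonde] <- rnorm(sum(nonde), 0, 0.5)
    inv <- layout$label == "invariant"
    # anchor the invariant core so its median linear level is exactly 1
    baseLog2[inv] <- baseLog2[inv] - log2(stats::median(2^baseLog2[inv]))
    bg <- layout$label == "background"
    # planted common genes are signal, not noise, in the mutant panel
    if ("expression" %in% names(conditions)) bg <- bg & !layout$common
    jsd <- cfg$bg_jitter_factor * cfg$noise_sd
    tables <- vector("list", nrow(conditions))
    names(tables) <- conditions$array_id
    for (i in seq_len(nrow(conditions))) {
      l2r <- trueLog2Ratio(layout, cfg, baseLog2,
                           stage_col = conditions$stage_col[i] %||% NULL,
                           expression = if ("expression" %in% names(conditions))
                             conditions$expression[i] else NULL)
      jitter <- numeric(cfg$n_genes)
      if (jsd > 0) jitter[bg] <- rnorm(sum(bg), 0, jsd)
      scl <- if (cfg$scale_sd > 0) rnorm(1, 0, cfg$scale_sd) else 0
      tables[[i]] <- makeSpotTable(conditions$array_id[i], layout, cfg,
                                   l2r, refBase, scl, jitter)
    }
    list(layout = layout, tables = tables)
  })
}

#' Simulate the wild-type nodulation time course
#'
#' Generates one spot table per array over the sampled time points (default
#' 0--29 dpi, three arrays per time point), with 520 differential genes
#' following the eight planted temporal profiles, a constant invariant core,
#' background genes with unstructured jitter and the constitutive anchor gene
#' spotted \code{replicate_spots} times per array.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param seed integer seed; the generator is a pure function of
#'   \code{(config, seed)}.
#' @return list with \code{tables} (named list of spot-table data.frames),
#'   \code{metadata} (array_id, genotype, dpi, stage) and \code{truth}
#'   (a \code{GeneratorTruth} list with per-gene and per-sample labels).
#' @export
simulateTimecourse <- function(config = generatorConfig(), seed = config$seed) {
  validateGeneratorConfig(config)
  meta <- expand.grid(rep = seq_len(config$arrays_per_timepoint),
                      dpi = config$timepoints)
  meta <- data.frame(
    array_id = sprintf("wt_dpi%02d_r%d", meta$dpi, meta$rep),
    genotype = "wild_type", dpi = meta$dpi, stringsAsFactors = FALSE
  )
  meta$stage <- stageForDpi(meta$dpi)
  conditions <- data.frame(array_id = meta$array_id, stage_col = meta$stage,
                           stringsAsFactors = FALSE)
  sim <- simulateArraySet(config, seed, conditions)
  truth <- structure(list(
    genes = sim$layout,
    samples = meta,
    kind = "timecourse",
    seed = as.integer(seed)
  ), class = "GeneratorTruth")
  list(tables = sim$tables, metadata = meta, truth = truth)
}

#' Simulate the mutant nodule array panel
#'
#' One set of replicate arrays per genotype of the mutant panel plus
#' root-control reference arrays. Wild-type-like genotypes express all
#' profile genes at mature-nodule levels; the bacA-like archetype activates
#' profiles 5--6 only; root-like archetypes stay at root levels except for a
#' small planted set of common genes mildly induced in every mutant nodule.
#'
#' @inheritParams simulateTimecourse
#' @param include_root_control emit root reference arrays (genotype
#'   \code{"root"}) needed as the baseline for wave scoring and induction
#'   tests.
#' @return as \code{\link{simulateTimecourse}}; \code{truth$genotypes} holds
#'   the planted archetype, phenotype flags and expected category per
#'   genotype.
#' @export
simulateMutantPanel <- function(config = generatorConfig(), seed = config$seed,
                                include_root_control = TRUE) {
  validateGeneratorConfig(config)
  arch <- config$mutant_archetypes
  tab <- archetypeTable()
  bad <- setdiff(unname(arch), tab$archetype)
  if (length(bad))
    stop("configuration error: unknown archetype name(s): ",
         paste(unique(bad), collapse = ", "))
  genotypes <- names(arch)
  if (include_root_control) {
    genotypes <- c("root", genotypes)
    arch <- c(root = "root_control", arch)
  }
  meta <- expand.grid(rep = seq_len(config$arrays_per_timepoint),
                      genotype = genotypes, stringsAsFactors = FALSE)
  meta <- data.frame(
    array_id = sprintf("%s_r%d", meta$genotype, meta$rep),
    genotype = meta$genotype,
    dpi = ifelse(meta$genotype == "root", 0, 21),
    stringsAsFactors = FALSE
  )
  meta$stage <- NA_character_
  expr <- tab$expression[match(arch[meta$genotype], tab$archetype)]
  conditions <- data.frame(array_id = meta$array_id, expression = expr,
                           stringsAsFactors = FALSE)
  sim <- simulateArraySet(config, seed, conditions)
  gt <- tab[match(arch[genotypes], tab$archetype), ]
  gt$genotype <- genotypes
  rownames(gt) <- NULL
  truth <- structure(list(
    genes = sim$layout,
    samples = meta,
    genotypes = gt[, c("genotype", "archetype", "expression", "infected",
                       "infection_thread_network", "ploidy", "bacteroid",
                       "nitrogen_fixing")],
    kind = "mutant_panel",
    seed = as.integer(seed)
  ), class = "GeneratorTruth")
  list(tables = sim$tables, metadata = meta, truth = truth)
}

#' Write spot tables and generator truth to disk
#'
#' Spot tables are tab-delimited with columns \code{spot_id, gene_id,
#' replicate_index, sample_intensity, reference_intensity}; one file per
#' array named after the array id. Truth is a structured JSON document.
#'
#' @param tables named list of spot tables.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeSpotTables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(names(tables), ".tsv"))
  for (i in seq_along(tables))
    write.table(tables[[i]], paths[i], sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(paths)
}

#' @rdname writeSpotTables
#' @param truth a \code{GeneratorTruth}.
#' @param path output JSON path.
#' @export
writeGeneratorTruth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
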