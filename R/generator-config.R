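#' Canonical temporal profile templates
#'
#' The eight temporal expression profiles are encoded as stage-tier triples
#' (roots, incipient nodules, mature nodules) on the log2 sample/reference
#' scale, with tiers low = 0, medium = \code{deEffect}, high = 2 *
#' \code{deEffect}. Profiles 1--3 are repressed variants (expressed in roots,
#' switched off at or after nodule initiation), profile 4 is the transient
#' incipient-nodule induction, profiles 5--6 form the first activation wave
#' and profiles 7--8 the second, mature-nodule wave.
#'
#' @param deEffect log2 step between adjacent expression tiers.
#' @return 8 x 3 numeric matrix, rownames "1".."8", colnames
#'   \code{c("roots","incipient","nodules")}.
#' @export
profileTemplates <- function(deEffect = 1.5) {
  tiers <- c(low = 0, medium = 1, high = 2) * deEffect
  m <- rbind(
    "1" = tiers[c("high", "low", "low")],
    "2" = tiers[c("high", "medium", "low")],
    "3" = tiers[c("high", "high", "low")],
    "4" = tiers[c("low", "high", "low")],
    "5" = tiers[c("low", "high", "medium")],
    "6" = tiers[c("low", "high", "high")],
    "7" = tiers[c("low", "medium", "high")],
    "8" = tiers[c("low", "low", "high")]
  )
  colnames(m) <- c("roots", "incipient", "nodules")
  m
}

# Default genotype -> archetype map: the fifteen symbiotic mutants of the
# study panel. Archetypes: fix_minus_differentiated (category 1),
# bacteroid_blocked (category 2, bacA), infected_no_symbiotic_cells
# (category 3), empty_uninfected (category 4).
defaultMutantArchetypes <- function() {
  c(
    TR36 = "fix_minus_differentiated", TR183 = "fix_minus_differentiated",
    TRV36 = "fix_minus_differentiated", TRV43 = "fix_minus_differentiated",
    nifH = "fix_minus_differentiated", nifA = "fix_minus_differentiated",
    fixG = "fix_minus_differentiated", fixJ = "fix_minus_differentiated",
    fixK = "fix_minus_differentiated", lpsB = "fix_minus_differentiated",
    bacA = "bacteroid_blocked",
    TR3 = "infected_no_symbiotic_cells", TE7 = "infected_no_symbiotic_cells",
    V1 = "empty_uninfected", exoY = "empty_uninfected"
  )
}

# Expression pattern, infection phenotype, ploidy mixture and bacteroid model
# implied by each archetype.
archetypeTable <- function() {
  data.frame(
    archetype = c("wild_type", "fix_minus_differentiated", "bacteroid_blocked",
                  "infected_no_symbiotic_cells", "empty_uninfected",
                  "root_control"),
    expression = c("wild_type_like", "wild_type_like", "bacA_like",
                   "root_like", "root_like", "root_control"),
    infected = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    infection_thread_network = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    ploidy = c("wild_type_nodule", "wild_type_nodule", "wild_type_nodule",
               "root", "root", "root"),
    bacteroid = c("differentiated", "differentiated", "undifferentiated",
                  "undifferentiated", NA, NA),
    nitrogen_fixing = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic-data generator
#'
#' Bundles and validates every tunable of the generator. Defaults encode the
#' study design: a 2366-gene probe set, 520 differential genes planted on the
#' eight temporal profiles, a 1500-gene invariant core anchored on a
#' constitutive control spotted 12 times per array, the ten sampled time
#' points, the fifteen-mutant panel, root and nodule ploidy mixtures and
#' cultured versus elongated bacteroid length models.
#'
#' @param n_genes probe-set size.
#' @param n_de number of differential genes planted on the profile templates.
#' @param n_invariant size of the planted invariant core.
#' @param anchor_id id of the constitutive anchor gene.
#' @param replicate_spots spots per array for the anchor gene.
#' @param timepoints sampled days post inoculation.
#' @param arrays_per_timepoint replicate arrays per time point (and per
#'   genotype in the mutant panel).
#' @param de_effect log2 step between expression tiers of the templates.
#' @param noise_sd log2-scale standard deviation of the multiplicative
#'   per-spot channel noise.
#' @param scale_sd log2-scale sd of the per-array global intensity scale
#'   (removed by normalization).
#' @param bg_jitter_factor background (non-differential, non-invariant) genes
#'   receive array-to-array log2 jitter of sd \code{bg_jitter_factor *
#'   noise_sd}.
#' @param n_common number of planted "common" genes mildly induced in every
#'   mutant nodule.
#' @param common_induction log2 induction of the common genes in mutants.
#' @param profile_sizes integer vector (length 8) of genes per planted
#'   profile; must sum to \code{n_de}. Default puts 321 genes on profiles
#'   5--8.
#' @param mutant_archetypes named character map genotype -> archetype.
#' @param ploidy_mixtures named list of mixtures over the classes
#'   2,4,8,16,32,64 (fractions summing to 1).
#' @param ploidy_cv coefficient of variation of each fluorescence peak.
#' @param anchor_2c fluorescence position (a.u.) of the 2C peak.
#' @param ploidy_replicates replicate histograms emitted per sample.
#' @param bacteroid_length_models named list of length-distribution
#'   parameters (micrometres) per bacteroid archetype.
#' @param qpcr_params efficiencies, baseline crossing points, planted folds
#'   and CP noise for the qPCR generator.
#' @param seed default seed used when an operation is not given one.
#' @return a validated list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(n_genes = 2366L,
                            n_de = 520L,
                            n_invariant = 1500L,
                            anchor_id = "mtc27",
                            replicate_spots = 12L,
                            timepoints = c(0, 2, 4, 6, 7, 8, 10, 13, 20, 29),
                            arrays_per_timepoint = 3L,
                            de_effect = 1.5,
                            noise_sd = 0.25,
                            scale_sd = 0.25,
                            bg_jitter_factor = 2,
                            n_common = 10L,
                            common_induction = 2.5,
                            profile_sizes = c(50L, 50L, 50L, 49L, 80L, 80L, 80L, 81L),
                            mutant_archetypes = defaultMutantArchetypes(),
                            ploidy_mixtures = list(
                              root = c("2" = 0.60, "4" = 0.30, "8" = 0.10),
                              wild_type_nodule = c("2" = 0.40, "4" = 0.28,
                                                   "8" = 0.17, "16" = 0.08,
                                                   "32" = 0.05, "64" = 0.02)
                            ),
                            ploidy_cv = 0.04,
                            anchor_2c = 100,
                            ploidy_replicates = 3L,
                            bacteroid_length_models = list(
                              cultured = list(type = "uniform", min = 1, max = 2),
                              undifferentiated = list(type = "uniform", min = 1, max = 2),
                              differentiated = list(type = "gamma", mean = 6.75, cv = 0.18)
                            ),
                            qpcr_params = list(
                              efficiency = c(target = 2.0, reference = 2.0),
                              base_cp = c(target = 24, reference = 18),
                              folds = c(roots = 1, incipient = 4, nodules = 16),
                              replicates = 3L,
                              cp_noise_sd = 0.1,
                              load_sd = 0.2
                            ),
                            seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_de = as.integer(n_de),
    n_invariant = as.integer(n_invariant), anchor_id = anchor_id,
    replicate_spots = as.integer(replicate_spots), timepoints = timepoints,
    arrays_per_timepoint = as.integer(arrays_per_timepoint),
    de_effect = de_effect, noise_sd = noise_sd, scale_sd = scale_sd,
    bg_jitter_factor = bg_jitter_factor, n_common = as.integer(n_common),
    common_induction = common_induction,
    profile_sizes = as.integer(profile_sizes),
    mutant_archetypes = mutant_archetypes,
    ploidy_mixtures = ploidy_mixtures, ploidy_cv = ploidy_cv,
    anchor_2c = anchor_2c, ploidy_replicates = as.integer(ploidy_replicates),
    bacteroid_length_models = bacteroid_length_models,
    qpcr_params = qpcr_params, seed = as.integer(seed)
  )
  validateGeneratorConfig(cfg)
  class(cfg) <- "GeneratorConfig"
  cfg
}

validateGeneratorConfig <- function(cfg) {
  if (cfg$n_de + cfg$n_invariant > cfg$n_genes)
    stop("configuration error: n_de + n_invariant exceeds n_genes")
  if (cfg$n_common > cfg$n_genes - cfg$n_de - cfg$n_invariant)
    stop("configuration error: not enough background genes for the common set")
  if (cfg$noise_sd < 0 || cfg$scale_sd < 0)
    stop("configuration error: noise sds must be >= 0")
  if (length(cfg$profile_sizes) != 8L)
    stop("configuration error: profile_sizes must have length 8")
  if (sum(cfg$profile_sizes) != cfg$n_de)
    stop("configuration error: profile_sizes must sum to n_de")
  tmpl <- profileTemplates(cfg$de_effect)
  if (anyDuplicated(apply(tmpl, 1L, paste, collapse = "/")))
    stop("configuration error: profile templates must be pairwise distinct")
  for (nm in names(cfg$ploidy_mixtures)) {
    mix <- cfg$ploidy_mixtures[[nm]]
    if (!length(mix)) stop("configuration error: empty ploidy mixture '", nm, "'")
    if (!all(names(mix) %in% c("2", "4", "8", "16", "32", "64")))
      stop("configuration error: ploidy classes must be 2,4,8,16,32,64")
    if (abs(sum(mix) - 1) > 1e-8)
      stop("configuration error: ploidy mixture '", nm, "' must sum to 1")
  }
  eff <- cfg$qpcr_params$efficiency
  if (any(eff <= 1 | eff > 2))
    stop("configuration error: qPCR efficiencies must lie in (1, 2]")
  if (cfg$arrays_per_timepoint < 1L)
    stop("configuration error: arrays_per_timepoint must be >= 1")
  invisible(TRUE)
}

#' Write or read a generator configuration as YAML
#'
#' Every default is overridable from the file; unknown keys are rejected.
#'
#' @param config a \code{GeneratorConfig}.
#' @param path file path.
#' @return \code{readGeneratorConfig} returns a \code{GeneratorConfig}.
#' @export
writeGeneratorConfig <- function(config, path) {
  x <- unclass(config)
  # yaml drops names of atomic vectors; store named vectors as maps
  x$mutant_archetypes <- as.list(x$mutant_archetypes)
  x$ploidy_mixtures <- lapply(x$ploidy_mixtures, as.list)
  x$qpcr_params <- lapply(x$qpcr_params,
                          function(v) if (!is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeGeneratorConfig
#' @export
readGeneratorConfig <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(generatorConfig))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("configuration error: unknown keys: ", paste(bad, collapse = ", "))
  # yaml flattens named numeric vectors to lists; restore where needed
  for (nm in intersect(names(x), c("mutant_archetypes")))
    x[[nm]] <- unlist(x[[nm]])
  if (!is.null(x$ploidy_mixtures))
    x$ploidy_mixtures <- lapply(x$ploidy_mixtures, unlist)
  if (!is.null(x$qpcr_params))
    x$qpcr_params <- lapply(x$qpcr_params, function(v) if (is.list(v)) unlist(v) else v)
  do.call(generatorConfig, x)
}
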