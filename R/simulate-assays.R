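# Synthetic flow-cytometry, bacteroid-length, qPCR and annotation inputs.

ploidyClasses <- c(2, 4, 8, 16, 32, 64)

#' Simulate DAPI flow-cytometry histograms
#'
#' Fluorescence values are drawn from a mixture of log-normal peaks at
#' \code{anchor_2c * 2^j} (j = 0..5) with the configured per-peak coefficient
#' of variation, then binned on a fixed geometric grid. Three replicate
#' histograms per sample are emitted, mirroring pooled-nodule measurements
#' repeated three times.
#'
#' @param archetype name of a mixture in \code{config$ploidy_mixtures}
#'   (default mixtures: \code{"root"}, \code{"wild_type_nodule"}).
#' @param n_nuclei nuclei per replicate (>= 100).
#' @param seed integer seed.
#' @param config a \code{\link{generatorConfig}}.
#' @param n_bins number of geometric histogram bins.
#' @return list of \code{config$ploidy_replicates} histogram data.frames with
#'   columns \code{bin_center}, \code{count}; attributes \code{sample_id},
#'   \code{anchor_2c} and \code{truth} (the planted mixture).
#' @export
simulatePloidy <- function(archetype, n_nuclei = 10000L,
                           seed = config$seed, config = generatorConfig(),
                           n_bins = 256L) {
  mix <- config$ploidy_mixtures[[archetype]]
  if (is.null(mix) || !length(mix))
    stop("configuration error: no ploidy mixture for archetype '", archetype, "'")
  if (n_nuclei < 100L) stop("n_nuclei must be >= 100")
  anchor <- config$anchor_2c
  centers <- anchor * 2^(0:5)
  names(centers) <- as.character(ploidyClasses)
  edges <- anchor * 2^seq(-1.5, 7.5, length.out = n_bins + 1L)
  mids <- sqrt(edges[-1] * edges[-(n_bins + 1L)])
  sdlog <- sqrt(log(1 + config$ploidy_cv^2))
  withSeed(seed, {
    reps <- lapply(seq_len(config$ploidy_replicates), function(r) {
      cls <- sample(names(mix), n_nuclei, replace = TRUE, prob = mix)
      fl <- centers[cls] * exp(rnorm(n_nuclei, 0, sdlog))
      fl <- pmin(pmax(fl, edges[1] * 1.000001), edges[n_bins + 1L] * 0.999999)
      cnt <- tabulate(findInterval(fl, edges, rightmost.closed = TRUE), n_bins)
      h <- data.frame(bin_center = mids, count = cnt)
      attr(h, "replicate") <- r
      h
    })
    attr(reps, "sample_id") <- archetype
    attr(reps, "anchor_2c") <- anchor
    attr(reps, "truth") <- mix
    reps
  })
}

#' Simulate bacteroid length measurements
#'
#' Cultured and undifferentiated archetypes draw lengths uniformly on
#' 1--2 um (small rods); the differentiated archetype draws from a gamma
#' model whose mean is 4.5x the cultured mean, matching elongated bacteroids.
#'
#' @param archetype name of a model in
#'   \code{config$bacteroid_length_models}.
#' @param n number of cells measured (>= 10).
#' @inheritParams simulatePloidy
#' @return numeric vector of lengths (micrometres) with attribute
#'   \code{truth} (the model parameters).
#' @export
simulateBacteroidLengths <- function(archetype, n = 1000L,
                                     seed = config$seed,
                                     config = generatorConfig()) {
  model <- config$bacteroid_length_models[[archetype]]
  if (is.null(model))
    stop("configuration error: unknown bacteroid archetype '", archetype, "'")
  if (n < 10L) stop("n must be >= 10")
  withSeed(seed, {
    x <- switch(model$type,
      uniform = runif(n, model$min, model$max),
      gamma = {
        shape <- 1 / model$cv^2
        rgamma(n, shape = shape, rate = shape / model$mean)
      },
      stop("configuration error: unknown length model type '", model$type, "'")
    )
    attr(x, "truth") <- model
    x
  })
}

#' Simulate an efficiency-corrected qPCR dataset
#'
#' Crossing points are generated to be consistent with the planted fold
#' changes under the Pfaffl model: per-replicate cDNA load shifts both the
#' target and the reference CP, the planted fold shifts only the target.
#'
#' @inheritParams simulatePloidy
#' @return list of class \code{"QpcrDataset"} with \code{cp} (data.frame
#'   transcript, sample, replicate, cp), \code{efficiency} (named per
#'   transcript), \code{reference} (reference transcript id) and
#'   \code{truth} (planted folds).
#' @export
simulateQpcr <- function(config = generatorConfig(), seed = config$seed) {
  p <- config$qpcr_params
  if (any(p$efficiency <= 1 | p$efficiency > 2))
    stop("configuration error: qPCR efficiencies must lie in (1, 2]")
  folds <- p$folds
  ref_id <- "TC106487"
  tgt_id <- "target"
  withSeed(seed, {
    rows <- list()
    for (s in names(folds)) {
      for (r in seq_len(p$replicates)) {
        load <- rnorm(1, 0, p$load_sd)  # log2 cDNA input variation
        noise <- function() if (p$cp_noise_sd > 0) rnorm(1, 0, p$cp_noise_sd) else 0
        cp_ref <- p$base_cp[["reference"]] -
          (load * log(2)) / log(p$efficiency[["reference"]]) + noise()
        cp_tgt <- p$base_cp[["target"]] -
          ((log2(folds[[s]]) + load) * log(2)) / log(p$efficiency[["target"]]) +
          noise()
        rows[[length(rows) + 1L]] <- data.frame(
          transcript = c(tgt_id, ref_id), sample = s, replicate = r,
          cp = c(cp_tgt, cp_ref), stringsAsFactors = FALSE)
      }
    }
    structure(list(
      cp = do.call(rbind, rows),
      efficiency = c(setNames(p$efficiency[["target"]], tgt_id),
                     setNames(p$efficiency[["reference"]], ref_id)),
      reference = ref_id,
      truth = folds
    ), class = "QpcrDataset")
  })
}

#' Simulate a per-gene secretome annotation table
#'
#' Emulates the curated SignalP/TMHMM/BLAST evidence: genes on the planted
#' wave profiles (5--8) are enriched for signal-peptide-bearing secretory
#' proteins (about half, many of them short peptides under 220 aa) relative
#' to the probe-set background.
#'
#' @param truth a \code{GeneratorTruth} from \code{\link{simulateTimecourse}}.
#' @inheritParams simulatePloidy
#' @return data.frame with columns \code{gene_id, signal_peptide,
#'   tm_domain_count, secretory_system, length_aa}.
#' @export
simulateAnnotations <- function(truth, seed = 1L, config = generatorConfig()) {
  genes <- truth$genes
  wave <- !is.na(genes$profile) & genes$profile >= 5L
  n <- nrow(genes)
  withSeed(seed, {
    # category draw: secretory_system / membrane / secretory / none
    p_wave <- c(sys = 0.04, mem = 0.08, sec = 0.50)
    p_bg <- c(sys = 0.03, mem = 0.08, sec = 0.17)
    u <- runif(n)
    p <- matrix(rep(p_bg, each = n), nrow = n)
    p[wave, ] <- matrix(rep(p_wave, each = sum(wave)), nrow = sum(wave))
    cat3 <- ifelse(u < p[, 1], "sys",
            ifelse(u < p[, 1] + p[, 2], "mem",
            ifelse(u < rowSums(p), "sec", "none")))
    len <- integer(n)
    len[cat3 == "sec"] <- ifelse(runif(sum(cat3 == "sec")) < 0.7,
                                 sample(60:219, sum(cat3 == "sec"), TRUE),
                                 sample(220:800, sum(cat3 == "sec"), TRUE))
    len[cat3 != "sec"] <- sample(150:900, sum(cat3 != "sec"), TRUE)
    data.frame(
      gene_id = genes$gene_id,
      signal_peptide = cat3 == "sec" | (cat3 == "mem" & runif(n) < 0.3),
      tm_domain_count = ifelse(cat3 == "mem", pmax(1L, stats::rpois(n, 4)), 0L),
      secretory_system = cat3 == "sys",
      length_aa = len,
      stringsAsFactors = FALSE
    )
  })
}

#' Read and write flow-cytometry histograms
#'
#' Two-column comma-separated text: \code{bin_center,count}.
#'
#' @param h histogram data.frame.
#' @param path file path.
#' @export
writePloidyHistogram <- function(h, path) {
  write.table(h[, c("bin_center", "count")], path, sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePloidyHistogram
#' @export
readPloidyHistogram <- function(path) {
  h <- utils::read.csv(path)
  if (!all(c("bin_center", "count") %in% names(h)))
    stop("histogram file must have columns bin_center,count: ", path)
  if (any(h$count < 0)) stop("negative counts in ", path)
  if (any(diff(h$bin_center) <= 0)) stop("bin centers must be strictly increasing")
  h
}
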