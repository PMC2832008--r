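# Temporal-profile clustering of differential genes, PCA and hierarchical
# clustering of samples, and wave-activation scoring.

# Standardize a matrix of stage triples row-wise (zero mean, unit sd).
standardizeRows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  s[s == 0] <- 1
  (m - mu) / s
}

pearsonDist <- function(m) stats::as.dist(1 - stats::cor(t(m)))

# Cut `tree` into exactly k clusters of at least min_size members: deepen
# the cut until k cores of that size exist (cores are the k largest), then
# attach every remaining gene to the core whose mean standardized triple it
# correlates with best. Reduces to a plain cutree(k) when that cut already
# yields k sufficiently large clusters.
cutToCores <- function(tree, std, k, min_size = NULL) {
  n <- nrow(std)
  if (is.null(min_size)) min_size <- max(3L, ceiling(0.02 * n))
  min_size <- min(min_size, floor(n / k))
  for (kk in k:n) {
    cut <- stats::cutree(tree, k = kk)
    sizes <- table(cut)
    big <- as.integer(names(sizes)[sizes >= min_size])
    if (length(big) >= k) {
      cores <- as.integer(names(sort(sizes[as.character(big)],
                                     decreasing = TRUE))[seq_len(k)])
      if (kk == k && length(big) == k) return(cut)
      centers <- t(sapply(cores, function(cl)
        colMeans(std[cut == cl, , drop = FALSE])))
      out <- integer(n)
      incore <- cut %in% cores
      out[incore] <- match(cut[incore], cores)
      if (any(!incore)) {
        cc <- stats::cor(t(std[!incore, , drop = FALSE]), t(centers))
        out[!incore] <- apply(cc, 1L, which.max)
      }
      names(out) <- names(cut)
      return(out)
    }
  }
  stats::cutree(tree, k = k)
}

#' Cluster differential genes into temporal profiles
#'
#' Each gene is represented by its standardized stage-mean triple;
#' hierarchical clustering with distance 1 - Pearson correlation and average
#' linkage is cut to exactly \code{k} clusters. For k = 8 the clusters are
#' renumbered to the canonical semantic order (repressed profiles 1--3,
#' incipient-transient 4, first wave 5--6, second wave 7--8) by optimal
#' correlation matching of the cluster mean triples against
#' \code{\link{profileTemplates}}; for other k, clusters are numbered by
#' increasing stage-weighted template shape.
#'
#' @param expr a normalized \linkS4class{NoduleArraySet} restricted (or
#'   restrictable via \code{genes}) to the differential genes.
#' @param genes genes to cluster (default: all rows).
#' @param k number of profiles (default 8).
#' @param groups stage labels per array.
#' @param min_size minimum size of a profile core (default
#'   \code{max(3, ceiling(0.02 * n))}). The tree is cut at exactly \code{k}
#'   when that yields \code{k} clusters of at least this size; otherwise the
#'   cut is deepened until \code{k} stable cores emerge and the remaining
#'   (noise) genes are assigned to the core their stage triple correlates
#'   with best. This is the usual noise-tolerant reading of a fixed-k cut
#'   (cf. dynamic tree cutting): raw-p gene selection admits a few percent
#'   of false positives whose noise-driven triples would otherwise occupy
#'   cluster slots.
#' @return list of class \code{"ProfileAssignment"}: \code{assignment} (named
#'   integer gene -> profile), \code{templates} (k x 3 matrix of mean
#'   standardized triples), \code{tree} (hclust), \code{k}.
#' @export
clusterGeneProfiles <- function(expr, genes = rownames(expr), k = 8L,
                                groups = arrayStages(expr),
                                min_size = NULL) {
  m <- SummarizedExperiment::assay(expr, 1L)[genes, , drop = FALSE]
  if (nrow(m) < k) stop("fewer genes than profiles requested")
  groups <- groups[colnames(m)]
  triples <- sapply(stageLevels, function(s)
    rowMeans(m[, groups == s, drop = FALSE]))
  std <- standardizeRows(triples)
  d <- pearsonDist(std)
  if (any(!is.finite(d))) stop("non-finite gene distances (constant gene?)")
  tree <- stats::hclust(d, method = "average")
  cut <- cutToCores(tree, std, k, min_size)
  if (length(unique(cut)) < k)
    stop("tree cannot be cut into ", k, " distinct profiles")
  tmplMean <- t(sapply(seq_len(k), function(cl)
    colMeans(std[cut == cl, , drop = FALSE])))
  colnames(tmplMean) <- stageLevels
  if (k == 8L) {
    canon <- standardizeRows(profileTemplates())
    sc <- matrix(0, 8L, 8L)
    for (i in 1:8) for (j in 1:8)
      sc[i, j] <- stats::cor(tmplMean[i, ], canon[j, ])
    perm <- bestAssignment(sc)       # cluster i -> canonical profile perm[i]
  } else {
    # order by centre of expression mass along the stage axis
    key <- tmplMean %*% (1:3)
    perm <- match(seq_len(k), order(key))
  }
  relab <- perm[cut]
  templates <- tmplMean[order(perm), , drop = FALSE]
  rownames(templates) <- seq_len(k)
  structure(list(
    assignment = setNames(as.integer(relab), names(cut)),
    templates = templates,
    tree = tree,
    k = as.integer(k)
  ), class = "ProfileAssignment")
}

#' Principal component analysis of samples
#'
#' Genes are mean-centred across samples; principal components of the
#' sample-by-gene matrix are returned with their variance fractions.
#'
#' @param expr a normalized \linkS4class{NoduleArraySet}.
#' @return list with \code{coordinates} (samples x components) and
#'   \code{variance_fraction}.
#' @export
pcaSamples <- function(expr) {
  m <- SummarizedExperiment::assay(expr, 1L)
  if (ncol(m) < 2L) stop("need at least 2 samples")
  keep <- apply(m, 1L, function(r) all(is.finite(r)))
  m <- m[keep, , drop = FALSE]
  if (all(apply(m, 1L, stats::sd) == 0))
    stop("constant matrix: no variance for PCA")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = pc$x, variance_fraction = vf)
}

#' Hierarchical clustering of samples
#'
#' Distance 1 - Pearson correlation between sample expression vectors,
#' average linkage, tree cut at \code{k}.
#'
#' @inheritParams pcaSamples
#' @param k number of sample clusters (default 3).
#' @return list with \code{labels} (named cluster id per sample) and
#'   \code{tree} (hclust).
#' @export
clusterSamples <- function(expr, k = 3L) {
  m <- SummarizedExperiment::assay(expr, 1L)
  if (ncol(m) < k) stop("k exceeds the number of samples")
  keep <- apply(m, 1L, function(r) all(is.finite(r)))
  d <- pearsonDist(t(m[keep, , drop = FALSE]))
  tree <- stats::hclust(d, method = "average")
  labels <- stats::cutree(tree, k = k)
  list(labels = labels, tree = tree)
}

#' Wave-activation scores for query samples
#'
#' The first transcriptome wave is carried by profile 5--6 genes, the second
#' by profile 7--8 genes. For each query sample the wave score is the median
#' log2 induction of the wave's gene set over the root baseline; a wave is
#' active when its score reaches \code{threshold} (default 1.0 log2 units,
#' i.e. two-fold).
#'
#' @param expr a normalized \linkS4class{NoduleArraySet} containing the query
#'   samples.
#' @param profiles a \code{ProfileAssignment} (profiles 5--8 must be
#'   non-empty).
#' @param baseline named per-gene mean log2 value over root samples.
#' @param threshold activation threshold in log2 units.
#' @return data.frame per sample: wave1_score, wave2_score, wave1_active,
#'   wave2_active.
#' @export
waveActivation <- function(expr, profiles, baseline, threshold = 1.0) {
  m <- SummarizedExperiment::assay(expr, 1L)
  wave1 <- names(profiles$assignment)[profiles$assignment %in% c(5L, 6L)]
  wave2 <- names(profiles$assignment)[profiles$assignment %in% c(7L, 8L)]
  if (!length(wave1) || !length(wave2))
    stop("empty wave gene set (profiles 5-8 undefined)")
  if (!all(c(wave1, wave2) %in% names(baseline)))
    stop("baseline does not cover the wave gene sets")
  score <- function(genes, j)
    stats::median(m[genes, j] - baseline[genes])
  w1 <- vapply(seq_len(ncol(m)), function(j) score(wave1, j), numeric(1))
  w2 <- vapply(seq_len(ncol(m)), function(j) score(wave2, j), numeric(1))
  data.frame(
    sample = colnames(m),
    wave1_score = w1, wave2_score = w2,
    wave1_active = w1 >= threshold, wave2_active = w2 >= threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Root-baseline expression
#'
#' Per-gene mean log2 value over the arrays labelled as roots (by stage or by
#' genotype \code{"root"}).
#'
#' @param expr a normalized \linkS4class{NoduleArraySet}.
#' @param arrays array ids to use as the root baseline; by default arrays
#'   whose stage is \code{"roots"} or genotype is \code{"root"}.
#' @return named numeric vector.
#' @export
rootBaseline <- function(expr, arrays = NULL) {
  cd <- as.data.frame(SummarizedExperiment::colData(expr))
  if (is.null(arrays)) {
    arrays <- cd$array_id[(!is.na(cd$stage) & cd$stage == "roots") |
                          (!is.na(cd$genotype) & cd$genotype == "root")]
  }
  if (!length(arrays)) stop("no root baseline arrays found")
  rowMeans(SummarizedExperiment::assay(expr, 1L)[, arrays, drop = FALSE])
}

#' Export a dendrogram as a Newick string
#'
#' @param tree an \code{hclust} object.
#' @param path optional file to write to.
#' @return the Newick string, invisibly if written to file.
#' @export
dendrogramNewick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
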