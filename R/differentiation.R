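# Flow-cytometry ploidy quantification, the endoreduplication index, ploidy
# clustering and bacteroid differentiation calls.

#' Call ploidy-class fractions from a DAPI histogram
#'
#' Expected class centres sit at \code{anchor_2c * 2^j} (j = 0..5, classes
#' 2C--64C); each histogram bin's mass is assigned to the nearest expected
#' centre in log2 fluorescence. With replicate histograms, percentages are
#' computed per replicate and then averaged.
#'
#' @param h a histogram data.frame (\code{bin_center, count}) or a list of
#'   replicate histograms.
#' @param anchor_2c fluorescence position of the 2C peak (> 0); the
#'   instrument calibration.
#' @param sample_id sample identifier for the profile.
#' @return a \linkS4class{PloidyProfile}.
#' @export
callPloidyFractions <- function(h, anchor_2c, sample_id = "sample") {
  if (missing(anchor_2c) || is.null(anchor_2c) || !is.finite(anchor_2c) ||
      anchor_2c <= 0)
    stop("anchor_2c must be a positive fluorescence position")
  reps <- if (is.data.frame(h)) list(h) else h
  if (!length(reps)) stop("empty histogram input")
  one <- function(hh) {
    stopifnot(all(c("bin_center", "count") %in% names(hh)))
    if (sum(hh$count) <= 0) stop("empty histogram (no counts)")
    cls <- apply(abs(outer(log2(hh$bin_center), log2(anchor_2c * 2^(0:5)), "-")),
                 1L, which.min)
    pct <- vapply(1:6, function(j) sum(hh$count[cls == j]), numeric(1))
    100 * pct / sum(pct)
  }
  mats <- vapply(reps, one, numeric(6))
  frac <- rowMeans(mats)
  n <- sum(vapply(reps, function(hh) sum(hh$count), numeric(1)))
  PloidyProfile(setNames(frac, c("2", "4", "8", "16", "32", "64")),
                nNuclei = n, sampleId = sample_id,
                replicateAveraged = length(reps) > 1L)
}

#' Endoreduplication index
#'
#' EI = (\%16C nuclei) * 3 + (\%32C nuclei) * 4 + (\%64C nuclei) * 5,
#' summarizing the high-ploidy content characteristic of differentiated
#' symbiotic cells.
#'
#' @param p a \linkS4class{PloidyProfile} (or a named percentage vector).
#' @return numeric EI value (0--500).
#' @export
endoreduplicationIndex <- function(p) {
  f <- if (is(p, "PloidyProfile")) ploidyFractions(p) else p
  unname(f[["16"]] * 3 + f[["32"]] * 4 + f[["64"]] * 5)
}

#' Highest occupied ploidy class
#'
#' @param p a \linkS4class{PloidyProfile}.
#' @param floor minimum percentage for a class to count as occupied
#'   (default 0.5).
#' @return integer C-value (2, 4, ..., 64) of the largest occupied class.
#' @export
maxPloidyClass <- function(p, floor = 0.5) {
  f <- ploidyFractions(p)
  occ <- which(f > floor)
  if (!length(occ)) stop("no ploidy class above the occupancy floor")
  ploidyClasses[max(occ)]
}

#' Hierarchical clustering of ploidy profiles
#'
#' Euclidean distance on the 6-dimensional percentage vectors, average
#' linkage. Cutting at k = 2 separates root-like from nodule-like samples on
#' archetypal data.
#'
#' @param profiles list of \linkS4class{PloidyProfile} objects (named by
#'   sample).
#' @param k number of groups for the cut (default 2).
#' @return list with \code{labels}, \code{tree} (hclust) and the percentage
#'   \code{matrix}.
#' @export
clusterPloidyProfiles <- function(profiles, k = 2L) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  m <- t(vapply(profiles, ploidyFractions, numeric(6)))
  rownames(m) <- names(profiles) %||%
    vapply(profiles, function(p) p@sampleId, character(1))
  tree <- stats::hclust(stats::dist(m), method = "average")
  list(labels = stats::cutree(tree, k = k), tree = tree, matrix = m)
}

#' Classify symbiotic cell differentiation from the EI
#'
#' EI below 2 indicates the absence of symbiotic cell differentiation
#' (root-like ploidy); EI above 15 indicates differentiated symbiotic cells;
#' the never-observed gap returns "indeterminate".
#'
#' @param ei numeric endoreduplication index.
#' @param bounds lower/upper decision bounds (default c(2, 15)).
#' @return "undifferentiated", "differentiated" or "indeterminate".
#' @export
classifyCellDifferentiation <- function(ei, bounds = c(2, 15)) {
  stopifnot(length(ei) == 1L, is.finite(ei))
  if (ei < bounds[1]) "undifferentiated"
  else if (ei > bounds[2]) "differentiated"
  else "indeterminate"
}

#' Call bacteroid differentiation from length distributions
#'
#' Fully differentiated bacteroids are several-fold longer than cultured
#' rhizobia; the call compares mean lengths and declares differentiation at
#' a fold ratio of \code{threshold} or more (default 2.5, the midpoint
#' between the about-1x undifferentiated and 4--5x differentiated regimes).
#'
#' @param nodule_lengths lengths (um) of bacteria isolated from nodules.
#' @param cultured_lengths lengths (um) of cultured reference bacteria.
#' @param threshold fold-ratio decision threshold.
#' @return list of class \code{"BacteroidCall"}: mean lengths, \code{fold},
#'   \code{differentiated}, \code{threshold}.
#' @export
classifyBacteroidDifferentiation <- function(nodule_lengths, cultured_lengths,
                                             threshold = 2.5) {
  if (length(nodule_lengths) < 10L || length(cultured_lengths) < 10L)
    stop("need at least 10 length measurements per sample")
  mn <- mean(nodule_lengths); mc <- mean(cultured_lengths)
  if (!is.finite(mn) || !is.finite(mc) || mc <= 0)
    stop("invalid length samples")
  fold <- mn / mc
  structure(list(
    mean_nodule = mn, mean_cultured = mc, fold = fold,
    differentiated = fold >= threshold, threshold = threshold
  ), class = "BacteroidCall")
}
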