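#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Two-channel nodule array set
#'
#' A \linkS4class{SummarizedExperiment} holding per-gene sample/reference
#' ratios of a common-reference two-channel microarray experiment. The single
#' assay is \code{"ratio"} (linear sample/reference ratios) before
#' normalization and \code{"log2ratio"} afterwards. \code{colData} carries
#' \code{array_id}, \code{genotype}, \code{dpi} and (after stage assignment)
#' \code{stage}.
#'
#' @slot normalized logical scalar; whether invariant-gene median
#'   normalization has been applied.
#' @slot invariantGenes character vector of gene ids used for normalization
#'   (empty before normalization).
#' @slot scaleFactors numeric per-array scale factors applied (empty before
#'   normalization).
#'
#' @export
setClass("NoduleArraySet",
  contains = "SummarizedExperiment",
  slots = c(
    normalized = "logical",
    invariantGenes = "character",
    scaleFactors = "numeric"
  ),
  prototype = prototype(
    normalized = FALSE,
    invariantGenes = character(0),
    scaleFactors = numeric(0)
  )
)

setValidity("NoduleArraySet", function(object) {
  msg <- character(0)
  an <- SummarizedExperiment::assayNames(object)
  if (!length(an) || !an[1] %in% c("ratio", "log2ratio"))
    msg <- c(msg, "first assay must be 'ratio' (raw) or 'log2ratio' (normalized)")
  if (length(object@normalized) != 1L)
    msg <- c(msg, "'normalized' must be a logical scalar")
  if (isTRUE(object@normalized)) {
    if (!"log2ratio" %in% an)
      msg <- c(msg, "normalized object must carry a 'log2ratio' assay")
    if (length(object@scaleFactors) != ncol(object))
      msg <- c(msg, "one scale factor per array required")
    inv <- object@invariantGenes
    if (length(inv) && all(inv %in% rownames(object))) {
      {
        lin <- 2^SummarizedExperiment::assay(object, "log2ratio")[inv, , drop = FALSE]
        med <- apply(lin, 2L, stats::median, na.rm = TRUE)
        if (any(abs(med - 1) > 1e-9))
          msg <- c(msg, "median normalized linear ratio over invariant genes must be 1 per array")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ploidy-class profile of a nodule or root sample
#'
#' Percentages of nuclei at the six ploidy classes 2C--64C, as recovered from
#' DAPI flow-cytometry histograms.
#'
#' @slot fractions named numeric of length 6 (names "2","4","8","16","32",
#'   "64"); percentages summing to 100.
#' @slot nNuclei total nuclei counted.
#' @slot sampleId sample identifier.
#' @slot replicateAveraged whether the profile is a mean over replicate
#'   measurements.
#'
#' @export
setClass("PloidyProfile",
  slots = c(
    fractions = "numeric",
    nNuclei = "numeric",
    sampleId = "character",
    replicateAveraged = "logical"
  )
)

setValidity("PloidyProfile", function(object) {
  f <- object@fractions
  if (length(f) != 6L || !identical(names(f), c("2", "4", "8", "16", "32", "64")))
    return("fractions must be named '2','4','8','16','32','64'")
  if (any(f < 0)) return("fractions must be non-negative")
  if (abs(sum(f) - 100) > 1e-6) return("fractions must sum to 100")
  TRUE
})

#' @describeIn PloidyProfile-class Construct a ploidy profile from class
#'   percentages.
#' @param fractions named numeric percentages over the classes 2C--64C.
#' @param nNuclei total nuclei counted.
#' @param sampleId sample identifier.
#' @param replicateAveraged whether fractions are replicate means.
#' @export
PloidyProfile <- function(fractions, nNuclei = NA_real_, sampleId = NA_character_,
                          replicateAveraged = FALSE) {
  cls <- c("2", "4", "8", "16", "32", "64")
  f <- setNames(numeric(6L), cls)
  if (is.null(names(fractions))) {
    stopifnot(length(fractions) == 6L)
    f[] <- fractions
  } else {
    stopifnot(all(names(fractions) %in% cls))
    f[names(fractions)] <- fractions
  }
  new("PloidyProfile", fractions = f, nNuclei = as.numeric(nNuclei),
      sampleId = as.character(sampleId), replicateAveraged = replicateAveraged)
}

#' @describeIn PloidyProfile-class Percentages of nuclei per ploidy class.
#' @param object,x a \code{PloidyProfile}.
#' @export
setGeneric("ploidyFractions", function(x) standardGeneric("ploidyFractions"))

#' @rdname PloidyProfile-class
#' @export
setMethod("ploidyFractions", "PloidyProfile", function(x) x@fractions)

setMethod("show", "PloidyProfile", function(object) {
  cat("PloidyProfile for", object@sampleId,
      if (isTRUE(object@replicateAveraged)) "(replicate mean)" else "", "\n")
  print(round(object@fractions, 2))
  cat("n nuclei:", object@nNuclei,
      "| endoreduplication index:",
      round(endoreduplicationIndex(object), 2), "\n")
  invisible(NULL)
})

#' @describeIn NoduleArraySet-class Invariant gene set used for normalization.
#' @param x a \code{NoduleArraySet}.
#' @export
setGeneric("invariantGenes", function(x) standardGeneric("invariantGenes"))

#' @rdname NoduleArraySet-class
#' @export
setMethod("invariantGenes", "NoduleArraySet", function(x) x@invariantGenes)

#' @describeIn NoduleArraySet-class Per-array normalization scale factors.
#' @export
setGeneric("scaleFactors", function(x) standardGeneric("scaleFactors"))

#' @rdname NoduleArraySet-class
#' @export
setMethod("scaleFactors", "NoduleArraySet", function(x) x@scaleFactors)

#' @describeIn NoduleArraySet-class Whether the object is normalized.
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname NoduleArraySet-class
#' @export
setMethod("isNormalized", "NoduleArraySet", function(x) isTRUE(x@normalized))

#' @describeIn NoduleArraySet-class Stage label per array (from colData).
#' @export
setGeneric("arrayStages", function(x) standardGeneric("arrayStages"))

#' @rdname NoduleArraySet-class
#' @export
setMethod("arrayStages", "NoduleArraySet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"stage" %in% colnames(cd)) return(NULL)
  setNames(as.character(cd$stage), colnames(x))
})

#' @describeIn NoduleArraySet-class Subset genes/arrays; per-array scale
#'   factors follow column subsetting.
#' @param i,j,...,drop as for \code{SummarizedExperiment} subsetting.
#' @export
setMethod("[", "NoduleArraySet", function(x, i, j, ..., drop = FALSE) {
  out <- callNextMethod()
  if (!missing(j) && length(x@scaleFactors)) {
    jj <- if (is.character(j)) match(j, colnames(x)) else seq_len(ncol(x))[j]
    out@scaleFactors <- x@scaleFactors[jj]
  }
  out
})

setMethod("show", "NoduleArraySet", function(object) {
  cat("NoduleArraySet:", nrow(object), "genes x", ncol(object), "arrays",
      if (isTRUE(object@normalized)) "(normalized log2 ratios)" else "(raw ratios)", "\n")
  if (length(object@invariantGenes))
    cat("invariant set:", length(object@invariantGenes), "genes\n")
  cd <- SummarizedExperiment::colData(object)
  if ("stage" %in% colnames(cd))
    print(table(stage = cd$stage))
  invisible(NULL)
})
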