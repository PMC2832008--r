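# Stage assignment, pairwise stage t-tests, differential-gene selection and
# the integer "digital genes" transform.

stageLevels <- c("roots", "incipient", "nodules")
stagePairs <- rbind(c("roots", "incipient"), c("roots", "nodules"),
                    c("incipient", "nodules"))
stagePairNames <- c("roots_vs_incipient", "roots_vs_nodules",
                    "incipient_vs_nodules")

stageForDpi <- function(dpi) {
  out <- ifelse(dpi >= 0 & dpi <= 6, "roots",
         ifelse(dpi >= 7 & dpi <= 10, "incipient",
         ifelse(dpi >= 13, "nodules", NA_character_)))
  out
}

#' Assign arrays to developmental stages by dpi
#'
#' Stage cutpoints follow the sampled design: roots 0--6 dpi, incipient
#' nodules 7--10 dpi, mature nodules >= 13 dpi. A dpi in the never-sampled
#' 11--12 gap (or negative) raises an error naming the array.
#'
#' @param metadata data.frame with columns \code{array_id} and \code{dpi},
#'   or a \linkS4class{NoduleArraySet} whose colData has them.
#' @return named character vector array_id -> stage.
#' @export
assignStages <- function(metadata) {
  if (is(metadata, "NoduleArraySet"))
    metadata <- as.data.frame(SummarizedExperiment::colData(metadata))
  stopifnot(all(c("array_id", "dpi") %in% names(metadata)))
  if (any(is.na(metadata$dpi)))
    stop("array without dpi: ",
         metadata$array_id[which(is.na(metadata$dpi))[1]])
  stage <- stageForDpi(metadata$dpi)
  if (any(is.na(stage)))
    stop("dpi outside defined stage ranges for array ",
         metadata$array_id[which(is.na(stage))[1]],
         " (dpi ", metadata$dpi[which(is.na(stage))[1]], ")")
  setNames(stage, metadata$array_id)
}

# Vectorised Welch two-sided t-test over the rows of x (group a) vs y
# (group b). Degenerate zero-variance rows: p = 1 when the means are equal,
# p = 0 when they differ.
welchRows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1L, stats::var); vb <- apply(xb, 1L, stats::var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degen <- se2 == 0 | !is.finite(se2)
  if (any(degen))
    p[degen] <- ifelse(abs(ma[degen] - mb[degen]) <
                         1e-12 * pmax(1, abs(ma[degen])), 1, 0)
  p
}

#' Pairwise stage t-tests per gene
#'
#' Welch (unequal-variance) two-sided t-tests on log2 values for each of the
#' three stage pairs. Rows where both groups have zero variance get p = 1
#' (equal means) or p = 0 (unequal means).
#'
#' @param expr a normalized \linkS4class{NoduleArraySet}.
#' @param groups named character vector array_id -> stage (see
#'   \code{\link{assignStages}}).
#' @return data.frame (one row per gene) with the three p-values, the three
#'   stage means and \code{min_p}; class \code{"DeResult"}.
#' @export
pairwiseStageTests <- function(expr, groups = arrayStages(expr)) {
  m <- SummarizedExperiment::assay(expr, 1L)
  if (is.null(groups)) stop("no stage grouping available")
  groups <- groups[colnames(m)]
  if (any(is.na(groups))) stop("every array needs a stage label")
  sizes <- table(factor(groups, levels = stageLevels))
  if (any(sizes < 2L))
    stop("stage with fewer than 2 arrays: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  cols <- split(seq_along(groups), factor(groups, levels = stageLevels))
  means <- vapply(stageLevels,
                  function(s) rowMeans(m[, cols[[s]], drop = FALSE]),
                  numeric(nrow(m)))
  p <- vapply(seq_len(nrow(stagePairs)), function(k) {
    welchRows(m[, cols[[stagePairs[k, 1]]], drop = FALSE],
              m[, cols[[stagePairs[k, 2]]], drop = FALSE])
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) {
    means <- matrix(means, 1L); p <- matrix(p, 1L)
  }
  colnames(means) <- paste0("mean_", stageLevels)
  colnames(p) <- paste0("p_", stagePairNames)
  res <- data.frame(gene_id = rownames(m), p, means,
                    min_p = apply(p, 1L, min),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("DeResult", "data.frame")
  res
}

#' Select differential genes
#'
#' A gene is retained when the smallest of its three pairwise stage p-values
#' is below \code{alpha} (raw p, no multiple-testing correction).
#'
#' @param res a \code{DeResult} from \code{\link{pairwiseStageTests}}.
#' @param alpha significance threshold (default 0.01).
#' @return character vector of selected gene ids.
#' @export
selectDeGenes <- function(res, alpha = 0.01) {
  res$gene_id[res$min_p < alpha]
}

#' Digital expression transform
#'
#' Maps each gene's three stage means to integers 1--3 reflecting strength of
#' expression and statistical support: stages are visited in ascending order
#' of their means (ties broken by the fixed stage order roots < incipient <
#' nodules); the lowest stage gets tier 1 and each subsequent stage
#' increments the tier only if its pairwise p-value against the current
#' tier's representative (the first stage assigned that tier) is below
#' \code{alpha}, otherwise it joins the current tier.
#'
#' @inheritParams selectDeGenes
#' @param genes genes to transform (default: all in \code{res}).
#' @return integer matrix genes x stages with values in {1, 2, 3}.
#' @export
digitalTransform <- function(res, genes = res$gene_id, alpha = 0.01) {
  idx <- match(genes, res$gene_id)
  if (anyNA(idx)) stop("genes without test results: ", genes[is.na(idx)][1])
  pmat <- as.matrix(res[idx, paste0("p_", stagePairNames), drop = FALSE])
  mmat <- as.matrix(res[idx, paste0("mean_", stageLevels), drop = FALSE])
  pLookup <- function(s1, s2) {
    k <- which((stagePairs[, 1] == s1 & stagePairs[, 2] == s2) |
               (stagePairs[, 1] == s2 & stagePairs[, 2] == s1))
    k
  }
  out <- matrix(NA_integer_, length(genes), 3L,
                dimnames = list(genes, stageLevels))
  for (i in seq_along(genes)) {
    ord <- order(mmat[i, ], seq_len(3L))  # ascending means, fixed-order ties
    tier <- integer(3L)
    tier[ord[1]] <- 1L
    rep_stage <- ord[1]
    for (j in 2:3) {
      s <- ord[j]
      p <- pmat[i, pLookup(stageLevels[rep_stage], stageLevels[s])]
      if (p < alpha) {
        tier[s] <- tier[rep_stage] + 1L
        rep_stage <- s
      } else {
        tier[s] <- tier[rep_stage]
      }
    }
    out[i, ] <- tier
  }
  out
}

#' Write a DE result or digital matrix as tab-delimited text
#'
#' @param x a \code{DeResult} data.frame or an integer digital matrix.
#' @param path file path.
#' @export
writeDeTable <- function(x, path) {
  if (is.matrix(x)) x <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
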