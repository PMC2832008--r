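# Secretory-pathway categorization from annotation evidence and Fisher's
# exact enrichment against the probe-set background.

secretomeCategories <- c("secretory_system", "membrane_protein",
                         "secretory_protein", "non_secretory")

#' Categorize genes into secretory-pathway classes
#'
#' Precedence: curated secretory-system membership beats everything; then a
#' gene with one or more transmembrane domains is a membrane protein (a
#' signal peptide together with a TM domain is read as a signal anchor);
#' then a signal peptide without TM domains makes a secretory protein; all
#' else is non-secretory. Secretory proteins shorter than 220 amino acids
#' (signal peptide included) carry the peptide subclass.
#'
#' @param annotations data.frame with columns \code{gene_id,
#'   signal_peptide, tm_domain_count, secretory_system, length_aa}.
#' @return data.frame \code{gene_id, category, peptide}.
#' @export
categorizeGenes <- function(annotations) {
  a <- annotations
  need <- c("gene_id", "signal_peptide", "tm_domain_count",
            "secretory_system", "length_aa")
  stopifnot(all(need %in% names(a)))
  if (any(a$length_aa <= 0)) stop("protein lengths must be positive")
  if (any(a$tm_domain_count < 0)) stop("tm_domain_count must be >= 0")
  category <- ifelse(a$secretory_system, "secretory_system",
              ifelse(a$tm_domain_count >= 1L, "membrane_protein",
              ifelse(a$signal_peptide, "secretory_protein", "non_secretory")))
  data.frame(
    gene_id = a$gene_id,
    category = factor(category, levels = secretomeCategories),
    peptide = category == "secretory_protein" & a$length_aa < 220L,
    stringsAsFactors = FALSE
  )
}

#' @rdname categorizeGenes
#' @param signal_peptide,tm_domain_count,secretory_system,length_aa scalar
#'   annotation evidence for a single gene.
#' @export
categorizeGene <- function(signal_peptide, tm_domain_count, secretory_system,
                           length_aa) {
  row <- categorizeGenes(data.frame(
    gene_id = "g", signal_peptide = signal_peptide,
    tm_domain_count = tm_domain_count, secretory_system = secretory_system,
    length_aa = length_aa))
  list(category = as.character(row$category), peptide = row$peptide)
}

# Two-sided Fisher exact p for a 2x2 table (a b / c d), computed by exact
# hypergeometric summation in log space (valid far below double underflow of
# the individual terms). Two-sided rule as in the classical test: sum all
# tables with point probability <= that of the observed table (with a small
# relative tolerance against round-off).
fisherLogP <- function(a, b, c, d) {
  m <- a + b          # margin: row 1
  n <- c + d          # row 2
  k <- a + c          # column 1
  lo <- max(0L, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  logd <- stats::dhyper(xs, m, n, k, log = TRUE)
  obs <- logd[match(a, xs)]
  keep <- logd <= obs + 1e-7
  logSumExp(logd[keep])
}

#' Fisher's exact enrichment of secretome categories
#'
#' For each category, tests the 2x2 table (gene in set vs not) x (gene in
#' category vs not) with a two-sided Fisher exact test computed by log-space
#' hypergeometric summation, so that p-values far below 1e-60 are exact in
#' log space. The odds ratio uses a Haldane 0.5 correction when a cell is
#' zero.
#'
#' @param set_genes character vector, the query set (must be a subset of the
#'   background).
#' @param background_genes character vector, the probe-set background.
#' @param annotations annotation data.frame (see
#'   \code{\link{categorizeGenes}}).
#' @param combined also test the combined "protein_secretion" super-category
#'   (secretory system + membrane + secretory proteins).
#' @return data.frame per category: counts, odds ratio, log10 p, p, and
#'   direction ("enriched"/"depleted").
#' @export
fisherEnrichment <- function(set_genes, background_genes, annotations,
                             combined = TRUE) {
  if (!length(set_genes)) stop("query set is empty")
  if (!all(set_genes %in% background_genes))
    stop("query set must be a subset of the background")
  cats <- categorizeGenes(annotations)
  cat_of <- setNames(as.character(cats$category), cats$gene_id)
  if (!all(background_genes %in% names(cat_of)))
    stop("annotation missing for some background genes")
  bg <- cat_of[background_genes]
  if (length(unique(bg)) < 2L)
    stop("background must represent at least 2 categories")
  inset <- background_genes %in% set_genes
  testCat <- function(name, members) {
    n11 <- sum(inset & members); n12 <- sum(inset & !members)
    n21 <- sum(!inset & members); n22 <- sum(!inset & !members)
    lp <- fisherLogP(n11, n12, n21, n22)
    orr <- if (any(c(n11, n12, n21, n22) == 0))
      ((n11 + .5) * (n22 + .5)) / ((n12 + .5) * (n21 + .5))
    else (n11 * n22) / (n12 * n21)
    data.frame(
      category = name, set_in = n11, set_out = n12, bg_in = n21, bg_out = n22,
      odds_ratio = orr, log10_p = lp / log(10), p = exp(lp),
      direction = ifelse(orr >= 1, "enriched", "depleted"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(secretomeCategories, function(cc)
    testCat(cc, bg == cc)))
  if (combined)
    out <- rbind(out, testCat("protein_secretion", bg != "non_secretory"))
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Read a tab-delimited annotation table
#'
#' Columns: \code{gene_id, signal_peptide, tm_domain_count,
#' secretory_system, length_aa}; booleans as TRUE/FALSE or 0/1.
#'
#' @param path file path.
#' @return typed annotation data.frame.
#' @export
readAnnotationTable <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  a <- read.delim(path)
  need <- c("gene_id", "signal_peptide", "tm_domain_count",
            "secretory_system", "length_aa")
  if (!all(need %in% names(a)))
    stop("annotation table lacks columns: ",
         paste(setdiff(need, names(a)), collapse = ", "))
  a$signal_peptide <- as.logical(a$signal_peptide)
  a$secretory_system <- as.logical(a$secretory_system)
  a$tm_domain_count <- as.integer(a$tm_domain_count)
  a$length_aa <- as.integer(a$length_aa)
  a
}

#' @rdname readAnnotationTable
#' @param annotations annotation data.frame.
#' @export
writeAnnotationTable <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
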