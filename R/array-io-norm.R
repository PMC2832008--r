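# Two-channel spot-table input, replicate collapse and invariant-gene median
# normalization anchored on the replicated constitutive control.

#' Read a two-channel spot table
#'
#' Tab-delimited with header \code{spot_id, gene_id, replicate_index,
#' sample_intensity, reference_intensity}. Intensities must be numeric and
#' non-negative; malformed rows are reported with their line number.
#'
#' @param path file path.
#' @param array_id array identifier; defaults to the file name without
#'   extension.
#' @return data.frame of typed rows with attributes \code{array_id} and
#'   \code{replicate_counts} (spots tallied per gene).
#' @export
readSpotTable <- function(path, array_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("spot_id", "gene_id", "replicate_index",
            "sample_intensity", "reference_intensity")
  if (!all(need %in% names(raw)))
    stop("spot table ", path, " lacks required columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  numify <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad))
      stop("parse error in ", path, ", line ", bad[1] + 1L,
           ": non-numeric value '", raw[[col]][bad[1]], "' in column ", col)
    v
  }
  tab <- data.frame(
    spot_id = raw$spot_id,
    gene_id = raw$gene_id,
    replicate_index = as.integer(numify("replicate_index")),
    sample_intensity = numify("sample_intensity"),
    reference_intensity = numify("reference_intensity"),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(tab$gene_id)))
    stop("validation error in ", path, ": empty gene_id")
  neg <- which(tab$sample_intensity < 0 | tab$reference_intensity < 0)
  if (length(neg))
    stop("validation error in ", path, ", line ", neg[1] + 1L,
         ": negative intensity")
  attr(tab, "array_id") <- array_id
  attr(tab, "replicate_counts") <- table(tab$gene_id)
  tab
}

#' Collapse replicate spots to per-gene ratios
#'
#' The per-gene ratio is the median over its replicate spots of
#' sample/reference intensity; spots with a non-positive intensity in either
#' channel are unusable, and genes with no usable spot are excluded with a
#' warning.
#'
#' @param table a spot table (see \code{\link{readSpotTable}}).
#' @return named numeric vector of per-gene ratios; excluded genes recorded
#'   in attribute \code{"excluded"}.
#' @export
collapseReplicates <- function(table) {
  ok <- table$sample_intensity > 0 & table$reference_intensity > 0
  ratios <- table$sample_intensity[ok] / table$reference_intensity[ok]
  out <- vapply(split(ratios, table$gene_id[ok]), stats::median, numeric(1))
  excluded <- setdiff(unique(table$gene_id), names(out))
  if (length(excluded))
    warning("genes with no usable spot excluded: ",
            paste(excluded, collapse = ", "))
  attr(out, "excluded") <- excluded
  out
}

#' Assemble a raw ratio matrix from spot tables
#'
#' @param tables named list of spot tables (names = array ids).
#' @param metadata data.frame with one row per array (\code{array_id},
#'   \code{genotype}, \code{dpi}, optionally \code{stage}).
#' @return an unnormalized \linkS4class{NoduleArraySet} (assay
#'   \code{"ratio"}). Genes excluded on some array carry \code{NA} there.
#' @export
buildRatioMatrix <- function(tables, metadata = NULL) {
  ratios <- lapply(tables, collapseReplicates)
  genes <- sort(unique(unlist(lapply(ratios, names))))
  m <- matrix(NA_real_, length(genes), length(ratios),
              dimnames = list(genes, names(tables)))
  for (j in seq_along(ratios)) m[names(ratios[[j]]), j] <- ratios[[j]]
  if (is.null(metadata))
    metadata <- data.frame(array_id = colnames(m), genotype = NA_character_,
                           dpi = NA_real_, stringsAsFactors = FALSE)
  stopifnot(all(colnames(m) %in% metadata$array_id))
  metadata <- metadata[match(colnames(m), metadata$array_id), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ratio = m),
    colData = S4Vectors::DataFrame(metadata, row.names = colnames(m))
  )
  new("NoduleArraySet", se, normalized = FALSE)
}

#' Select invariant genes relative to the constitutive anchor
#'
#' Scores each gene by the standard deviation, across arrays, of the log2
#' ratio of its value to the anchor's value on the same array, and returns
#' the \code{n} lowest-scoring genes. Ties are broken deterministically by
#' lexicographic gene id. Genes with a missing or non-positive ratio on any
#' array are excluded from scoring.
#'
#' @param raw an unnormalized \linkS4class{NoduleArraySet}.
#' @param anchor_id id of the anchor gene (must be present on every array).
#' @param n number of invariant genes to select.
#' @return character vector of \code{n} gene ids; per-gene scores in
#'   attribute \code{"score"}.
#' @export
selectInvariantGenes <- function(raw, anchor_id = "mtc27", n = 1500L) {
  m <- SummarizedExperiment::assay(raw, 1L)
  if (!anchor_id %in% rownames(m))
    stop("anchor gene '", anchor_id, "' missing from the matrix")
  anchor <- m[anchor_id, ]
  if (any(is.na(anchor) | anchor <= 0))
    stop("anchor gene '", anchor_id, "' missing or non-positive on some array")
  cand <- setdiff(rownames(m), anchor_id)
  mm <- m[cand, , drop = FALSE]
  usable <- rowSums(is.na(mm) | mm <= 0) == 0L
  if (sum(usable) < n)
    stop("only ", sum(usable), " scoreable genes for n = ", n)
  rel <- log2(sweep(mm[usable, , drop = FALSE], 2L, anchor, "/"))
  score <- apply(rel, 1L, stats::sd)
  ord <- order(score, names(score), method = "radix")
  sel <- names(score)[ord[seq_len(n)]]
  sel <- sort(sel)
  attr(sel, "score") <- score
  sel
}

#' Normalize arrays by the invariant-gene median
#'
#' Each array's scale is the median, over the invariant set, of the raw
#' linear ratio; every ratio on the array is divided by it and stored as
#' log2. After normalization the median normalized linear ratio over the
#' invariant genes is exactly 1 on every array.
#'
#' @param raw an unnormalized \linkS4class{NoduleArraySet}.
#' @param invariant character vector of invariant gene ids.
#' @return a normalized \linkS4class{NoduleArraySet} (assay
#'   \code{"log2ratio"}) carrying the scale factors and invariant set.
#' @export
normalizeArrays <- function(raw, invariant) {
  if (!length(invariant)) stop("invariant set is empty")
  m <- SummarizedExperiment::assay(raw, 1L)
  if (SummarizedExperiment::assayNames(raw)[1] == "log2ratio") m <- 2^m
  missing <- setdiff(invariant, rownames(m))
  if (length(missing))
    stop("invariant genes absent from the matrix: ", missing[1], " ...")
  scales <- apply(m[invariant, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
  if (any(!is.finite(scales) | scales == 0))
    stop("non-finite or zero normalization scale")
  norm <- log2(sweep(m, 2L, scales, "/"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = norm),
    colData = SummarizedExperiment::colData(raw)
  )
  out <- new("NoduleArraySet", se, normalized = TRUE,
             invariantGenes = as.character(invariant),
             scaleFactors = scales)
  validObject(out)
  out
}

#' Write and read a normalized expression matrix
#'
#' Tab-delimited text, first column \code{gene_id}, header of array ids; a
#' JSON sidecar (\code{<path>.json}) stores scale factors, the invariant set
#' and stage metadata.
#'
#' @param x a normalized \linkS4class{NoduleArraySet}.
#' @param path file path for the matrix.
#' @export
writeExpressionMatrix <- function(x, path) {
  stopifnot(isNormalized(x))
  m <- SummarizedExperiment::assay(x, "log2ratio")
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(
    scale_factors = as.list(scaleFactors(x)),
    invariant_genes = invariantGenes(x),
    metadata = as.data.frame(SummarizedExperiment::colData(x))
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  md <- as.data.frame(side$metadata)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2ratio = m),
    colData = S4Vectors::DataFrame(md, row.names = colnames(m))
  )
  new("NoduleArraySet", se, normalized = TRUE,
      invariantGenes = as.character(side$invariant_genes),
      scaleFactors = unlist(side$scale_factors)[colnames(m)])
}
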