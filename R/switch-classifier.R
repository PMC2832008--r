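# Four-category classification of symbiotic mutants from fused infection,
# differentiation and transcriptome-wave evidence.

mutantCategories <- c("cat1_fix_minus_fully_differentiated",
                      "cat2_bacteroid_undifferentiated",
                      "cat3_infected_no_symbiotic_cells",
                      "cat4_empty_uninfected",
                      "wild_type_like")

#' Assemble a mutant observation record
#'
#' @param genotype genotype id.
#' @param infected bacteria present in the nodule.
#' @param infection_thread_network infection-thread network present.
#' @param cell_diff symbiotic-cell differentiation call
#'   ("differentiated"/"undifferentiated"/"indeterminate").
#' @param bacteroid_diff bacteroid differentiation (logical, or NA when no
#'   bacteria are present).
#' @param wave1_active,wave2_active transcriptome wave calls.
#' @param nitrogen_fixing whether the nodule fixes nitrogen (separates the
#'   wild type from category-1 Fix- mutants with otherwise identical
#'   differentiation markers).
#' @return validated list of class \code{"MutantObservation"}.
#' @export
mutantObservation <- function(genotype, infected, infection_thread_network,
                              cell_diff, bacteroid_diff,
                              wave1_active, wave2_active,
                              nitrogen_fixing = FALSE) {
  obs <- list(genotype = genotype, infected = infected,
              infection_thread_network = infection_thread_network,
              cell_diff = cell_diff, bacteroid_diff = bacteroid_diff,
              wave1_active = wave1_active, wave2_active = wave2_active,
              nitrogen_fixing = nitrogen_fixing)
  stopifnot(is.logical(infected), is.logical(infection_thread_network),
            cell_diff %in% c("differentiated", "undifferentiated",
                             "indeterminate"),
            is.logical(wave1_active), is.logical(wave2_active))
  if (!infected && !is.na(bacteroid_diff))
    stop("validation error: bacteroid_diff must be NA when no bacteria are present")
  if (infected && is.na(bacteroid_diff))
    stop("validation error: bacteroid_diff required when bacteria are present")
  class(obs) <- "MutantObservation"
  obs
}

#' Classify one mutant into the four nodulation categories
#'
#' Decision rules over the differentiation markers: uninfected nodules with
#' undifferentiated cells are category 4 (empty); infected nodules with an
#' infection-thread network but undifferentiated cells are category 3;
#' differentiated symbiotic cells with undifferentiated bacteroids are
#' category 2; differentiated cells with differentiated bacteroids are
#' category 1 (or wild-type-like when the nodule fixes nitrogen). The wave
#' calls corroborate: category 1 expects both waves, category 2 only the
#' first, categories 3--4 neither; a mismatch clears the consistency flag
#' with a warning but does not change the category.
#'
#' @param obs a \code{\link{mutantObservation}}.
#' @return list: \code{genotype}, \code{category}, \code{consistent}.
#' @export
classifyMutant <- function(obs) {
  stopifnot(inherits(obs, "MutantObservation"))
  if (obs$cell_diff == "indeterminate")
    stop("classification error: indeterminate cell differentiation for ",
         obs$genotype, "; more data required")
  if (obs$cell_diff == "differentiated" && !obs$infected)
    stop("validation error: differentiated symbiotic cells without infection (",
         obs$genotype, ") is outside the observable space")
  category <-
    if (!obs$infected) "cat4_empty_uninfected"
    else if (obs$cell_diff == "undifferentiated") {
      if (!obs$infection_thread_network)
        stop("validation error: infected nodule without infection-thread ",
             "network and without symbiotic cells (", obs$genotype,
             ") is outside the observable space")
      "cat3_infected_no_symbiotic_cells"
    }
    else if (!isTRUE(obs$bacteroid_diff)) "cat2_bacteroid_undifferentiated"
    else if (isTRUE(obs$nitrogen_fixing)) "wild_type_like"
    else "cat1_fix_minus_fully_differentiated"
  expected <- switch(category,
    cat1_fix_minus_fully_differentiated = c(TRUE, TRUE),
    wild_type_like = c(TRUE, TRUE),
    cat2_bacteroid_undifferentiated = c(TRUE, FALSE),
    c(FALSE, FALSE))
  consistent <- identical(c(obs$wave1_active, obs$wave2_active), expected)
  if (!consistent)
    warning("wave calls of ", obs$genotype,
            " do not match the expected pattern for ", category)
  list(genotype = obs$genotype, category = category, consistent = consistent)
}

#' Classify a panel of mutants
#'
#' @param observations list of \code{\link{mutantObservation}} records.
#' @return list with \code{table} (genotype, category, consistent),
#'   \code{counts} per category and \code{n_categories} (distinct mutant
#'   categories, the wild-type-like class excluded).
#' @export
classifyPanel <- function(observations) {
  if (!length(observations)) stop("empty panel")
  rows <- lapply(observations, classifyMutant)
  tab <- data.frame(
    genotype = vapply(rows, `[[`, character(1), "genotype"),
    category = vapply(rows, `[[`, character(1), "category"),
    consistent = vapply(rows, `[[`, logical(1), "consistent"),
    stringsAsFactors = FALSE
  )
  counts <- table(factor(tab$category, levels = mutantCategories))
  list(table = tab, counts = counts,
       n_categories = sum(counts[setdiff(mutantCategories,
                                         "wild_type_like")] > 0))
}

#' Genes induced in every queried mutant
#'
#' One-sided (greater) Welch t-tests of each mutant's arrays against the
#' root baseline arrays; a gene is returned when p < alpha in every queried
#' mutant (intersection rule).
#'
#' @param expr a normalized \linkS4class{NoduleArraySet} containing mutant
#'   and root arrays.
#' @param mutants named list genotype -> array ids (>= 2 arrays each).
#' @param root_arrays root baseline array ids (>= 2).
#' @param alpha significance threshold.
#' @return character vector of gene ids.
#' @export
commonInducedGenes <- function(expr, mutants, root_arrays, alpha = 0.01) {
  if (!length(mutants)) stop("empty mutant list")
  if (length(root_arrays) < 2L) stop("need >= 2 root baseline arrays")
  m <- SummarizedExperiment::assay(expr, 1L)
  roots <- m[, root_arrays, drop = FALSE]
  nr <- ncol(roots)
  mr <- rowMeans(roots); vr <- apply(roots, 1L, stats::var)
  induced <- rep(TRUE, nrow(m))
  for (g in names(mutants)) {
    cols <- mutants[[g]]
    if (length(cols) < 2L) stop("mutant ", g, " has fewer than 2 arrays")
    x <- m[, cols, drop = FALSE]
    nx <- ncol(x)
    mx <- rowMeans(x); vx <- apply(x, 1L, stats::var)
    se2 <- vx / nx + vr / nr
    t <- (mx - mr) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vr / nr)^2 / (nr - 1))
    p <- stats::pt(t, df, lower.tail = FALSE)  # one-sided: induction
    degen <- se2 == 0 | !is.finite(se2)
    if (any(degen)) p[degen] <- ifelse(mx[degen] > mr[degen] + 1e-12, 0, 1)
    induced <- induced & (p < alpha)
  }
  rownames(m)[induced]
}
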