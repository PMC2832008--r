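# Efficiency-corrected relative qPCR quantification (Pfaffl method) with
# reference-gene normalization and min-sample scaling.

#' Assemble a qPCR dataset
#'
#' @param cp data.frame with columns \code{transcript, sample, replicate,
#'   cp}.
#' @param efficiency named numeric, amplification efficiency (base, in
#'   (1, 2]) per transcript; values given as percent efficiency (0--100) are
#'   converted via E = 1 + pct/100.
#' @param reference id of the reference (constitutive control) transcript.
#' @return list of class \code{"QpcrDataset"}.
#' @export
qpcrDataset <- function(cp, efficiency, reference) {
  stopifnot(all(c("transcript", "sample", "replicate", "cp") %in% names(cp)))
  if (any(!is.finite(cp$cp))) stop("non-finite CP value")
  # percent efficiencies (e.g. 90 for 90%) convert to base form; bases
  # outside (1, 2] are invalid
  eff <- ifelse(efficiency >= 10, 1 + efficiency / 100, efficiency)
  names(eff) <- names(efficiency)
  if (any(eff <= 1 | eff > 2))
    stop("efficiencies must lie in (1, 2] after conversion")
  if (!reference %in% cp$transcript)
    stop("reference transcript absent from the CP table")
  structure(list(cp = cp, efficiency = eff, reference = reference),
            class = "QpcrDataset")
}

#' Pfaffl efficiency-corrected relative expression
#'
#' Per biological replicate, the expression ratio of the target in a sample
#' relative to the calibrator is
#' \deqn{E_t^{(CP_{t,cal} - CP_{t,s})} / E_r^{(CP_{r,cal} - CP_{r,s})}}
#' with the reference transcript correcting for cDNA input. Technical
#' replicates (duplicate CP rows per biological replicate) are averaged at
#' the CP level first. The calibrator is the sample with the lowest mean
#' ratio, and the output is rescaled so the minimum sample mean is exactly 1.
#'
#' @param ds a \code{\link{qpcrDataset}} (or the output of
#'   \code{\link{simulateQpcr}}).
#' @param target target transcript id (must differ from the reference).
#' @param samples samples to quantify (default: all with target CPs).
#' @return data.frame per sample: \code{fold} (mean over replicates, min
#'   sample = 1), \code{sd}, \code{n_replicates}.
#' @export
pfafflRelativeExpression <- function(ds, target = setdiff(unique(ds$cp$transcript),
                                                          ds$reference)[1],
                                     samples = NULL) {
  stopifnot(inherits(ds, "QpcrDataset") || is.list(ds))
  cp <- ds$cp
  if (any(!is.finite(cp$cp))) stop("non-finite CP value")
  if (identical(target, ds$reference))
    stop("target must differ from the reference transcript")
  if (!all(c(target, ds$reference) %in% names(ds$efficiency)))
    stop("missing efficiency for target or reference")
  Et <- ds$efficiency[[target]]; Er <- ds$efficiency[[ds$reference]]
  if (is.null(samples))
    samples <- unique(cp$sample[cp$transcript == target])
  # average technical replicates at CP level
  agg <- stats::aggregate(cp ~ transcript + sample + replicate, data = cp,
                          FUN = mean)
  cpOf <- function(tr, s) {
    rows <- agg[agg$transcript == tr & agg$sample == s, ]
    setNames(rows$cp, rows$replicate)
  }
  # ratios vs a provisional calibrator (first sample), per replicate
  ratioVs <- function(s, cal_t, cal_r) {
    t_s <- cpOf(target, s); r_s <- cpOf(ds$reference, s)
    reps <- intersect(names(t_s), names(r_s))
    if (!length(reps)) stop("no paired replicates for sample ", s)
    Et^(cal_t - t_s[reps]) / Er^(cal_r - r_s[reps])
  }
  cal_t0 <- mean(cpOf(target, samples[1]))
  cal_r0 <- mean(cpOf(ds$reference, samples[1]))
  ratios <- lapply(samples, ratioVs, cal_t = cal_t0, cal_r = cal_r0)
  means <- vapply(ratios, mean, numeric(1))
  # calibrator = sample with the lowest mean ratio; rescale so min mean = 1
  scale <- min(means)
  out <- data.frame(
    sample = samples,
    fold = means / scale,
    sd = vapply(ratios, stats::sd, numeric(1)) / scale,
    n_replicates = vapply(ratios, length, integer(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "calibrator") <- samples[which.min(means)]
  out
}

#' Read a tab-delimited CP table and efficiency table
#'
#' CP table columns: \code{transcript, sample, replicate, cp}; efficiency
#' table columns: \code{transcript, efficiency}.
#'
#' @param cp_path,eff_path file paths.
#' @param reference reference transcript id.
#' @return a \code{\link{qpcrDataset}}.
#' @export
readQpcrTables <- function(cp_path, eff_path, reference) {
  cp <- read.delim(cp_path)
  eff <- read.delim(eff_path)
  qpcrDataset(cp, setNames(eff$efficiency, eff$transcript), reference)
}
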