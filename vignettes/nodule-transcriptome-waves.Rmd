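---
title: "Transcriptome waves and symbiotic differentiation in Medicago nodules: methods"
author: "noduleWaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome waves and symbiotic differentiation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleWaves)
```

## The biological question

Indeterminate root nodules of *Medicago truncatula* host nitrogen-fixing
*Sinorhizobium meliloti*. Nodule formation couples three differentiation
processes: organogenesis of the nodule itself, endoreduplication-driven
differentiation of the host symbiotic cells (polyploid cells up to 64C), and
terminal differentiation of the intracellular bacteria into elongated
bacteroids. Transcriptionally, the organ passes through two switch points:
a first wave of gene activation in incipient nodules and a second wave at
nodule maturity. Non-fixing (Fix^-^) mutants of either partner stall at
reproducible points along this trajectory, and the combination of
histological markers (infection, ploidy, bacteroid morphology) with the
position of the transcriptome along the two waves sorts mutants into four
categories.

`noduleWaves` implements that inference chain as a reusable, tested
pipeline: two-channel microarray normalization anchored on an invariant gene
core, stage-wise differential expression, temporal-profile clustering with
wave-activation scoring, secretome enrichment, flow-cytometry ploidy
quantification, efficiency-corrected qPCR, and the rule-based four-category
mutant classifier. Because the original hybridizations are not shipped with
the package, a synthetic-data generator produces all inputs with full ground
truth, which also turns every analysis step into a recovery benchmark.

## Normalization by an invariant gene core

Spot tables carry one row per spot: sample (Cy5) and common-reference (Cy3)
intensities. Replicate spots collapse to a per-gene ratio by the median
(robust to a single bad spot). The constitutive anchor gene (`mtc27`-like)
is spotted 12 times per array; each gene is scored by the standard deviation
across arrays of `log2(gene ratio / anchor ratio)`, and the
`n_invariant = 1500` lowest-scoring genes form the invariant set. Each
array is then rescaled by the median linear ratio over that set, so that
after normalization the invariant-median of every array is exactly 1.

Two open choices were fixed here: the invariance score is anchor-relative
(the only reading that uses the replicated anchor), and the per-array scale
is the median of *linear* ratios, not log ratios. Ties in the invariance
score break by lexicographic gene id, which makes selection well defined
even on degenerate zero-variance input. Genes with any non-positive
intensity are excluded from scoring but kept (as missing) in the matrix.

## Stages, differential expression, digital tiers

Arrays map to three developmental stages by days post inoculation: roots
(0–6 dpi), incipient nodules (7–10 dpi), mature nodules (13 dpi and later);
the never-sampled 11–12 dpi gap raises an error rather than guessing. Each
gene is tested with two-sided Welch *t*-tests (no balance guarantee across
stages, hence unequal variances) on log2 values for the three stage pairs,
and selected when any raw p-value is below `alpha = 0.01` — deliberately
uncorrected, matching the selection rule the analysis was built around.
Degenerate zero-variance comparisons return p = 1 for equal means and p = 0
otherwise, so that noise-free benchmark data behave sensibly.

The "digital" transform maps each gene's three stage means to integers 1–3:
stages are visited in ascending mean order (ties broken by the fixed stage
order), the lowest stage takes tier 1, and a stage opens a new tier only if
its test against the current tier's first member is significant. The exact
algorithm behind the integer heat-map tool it emulates is not documented;
this tier-merge rule is this package's defined reading and is frozen by
tests against an independent re-implementation.

## Temporal profiles and the two waves

Differential genes are represented by standardized stage-mean triples and
clustered hierarchically (distance 1 − Pearson, average linkage — the
Eisen-style defaults), with the tree cut to `k = 8` profiles. Raw-p
selection admits a few percent of false positives whose noise-driven
triples would otherwise occupy cluster slots, so the cut is noise-tolerant:
if cutting at *k* does not yield *k* clusters of at least `min_size`
members (2% of the input by default), the cut is deepened until *k* stable
cores emerge and the remaining genes are attached to the core their triple
correlates with best. This is the same idea as dynamic tree cutting; on
noise-free input it reduces to a plain `cutree(k)`.

Because `hclust` numbers clusters arbitrarily, clusters are renumbered to
the canonical semantic order — repressed profiles 1–3, transient
incipient-nodule profile 4, first-wave profiles 5–6, second-wave profiles
7–8 — by exact optimal assignment (bitmask dynamic programming) of cluster
mean triples to the canonical template shapes.

Wave scores summarize a sample's position along the trajectory: the median
log2 induction over the profile-5∪6 gene set (wave 1) and the profile-7∪8
set (wave 2), relative to a root baseline. A wave is active at a score of
1.0 log2 units (two-fold) or more. The threshold is a package default: the
original activation calls were read off heat maps and RT-qPCR bar charts,
so no numeric rule existed to inherit; two-fold on a median is conservative
given planted inductions of 1.5–3 log2 units.

## Secretome categories and enrichment

Annotation evidence (signal peptide, transmembrane-domain count, curated
secretory-system membership, protein length) is consumed as input — the
predictors themselves are out of scope. Categories are assigned with the
precedence secretory_system > membrane_protein > secretory_protein >
non_secretory; a signal peptide together with a transmembrane domain reads
as a signal anchor (membrane protein). Secretory proteins shorter than 220
amino acids (strict, signal peptide included) form the peptide subclass.
The reference category counts are disjoint but come without a stated
precedence; this order is the package's decision, frozen by an exhaustive
truth-table test.

Enrichment of a gene set against the probe-set background uses a two-sided
Fisher exact test computed by log-space hypergeometric tail summation
(log-scale `dhyper` terms combined with log-sum-exp), so p-values at the
10^-52^ scale of the real secretome enrichment remain exact in log space.
Tests cross-check the implementation against `stats::fisher.test` and
against a rational-arithmetic oracle (exact fractions) on tables up to
N = 200.

## Ploidy, the endoreduplication index, bacteroids

DAPI flow-cytometry peaks sit at geometric positions `anchor_2c * 2^j`
(2C–64C). Lacking a documented gating protocol, each histogram bin is
assigned to the nearest expected peak in log2 fluorescence — the natural
rule for geometrically spaced peaks — giving class percentages that always
sum to 100; replicate histograms are averaged after per-replicate
percentages, mirroring pooled, thrice-repeated measurements. The
endoreduplication index is EI = %16C·3 + %32C·4 + %64C·5. EI below 2 calls
the sample undifferentiated, above 15 differentiated; the gap returns
"indeterminate" rather than guessing, since observed samples never fall
there. Ploidy profiles cluster with Euclidean distance and average linkage;
cutting at k = 2 separates root-like from nodule-like samples.

Bacteroid differentiation compares mean lengths of nodule-extracted
bacteria against cultured rods (1–2 µm): the call threshold of 2.5× is the
midpoint between the ≈1× undifferentiated and 4–5× differentiated regimes,
with the boundary fold counting as differentiated.

## The four-category classifier

A mutant observation fuses infection status, infection-thread evidence, the
EI-based cell call, the bacteroid call, and the two wave calls. The marker
rules are: uninfected and undifferentiated → category 4 (empty nodules);
infected with thread network but undifferentiated cells → category 3;
differentiated cells with undifferentiated bacteroids → category 2;
differentiated cells and bacteroids → category 1 (or wild-type-like when
the nodule fixes nitrogen — the observation therefore carries a
`nitrogen_fixing` flag, since no other marker separates fully
differentiated Fix^-^ mutants from the wild type). Wave calls corroborate
but never override the markers: a mismatch clears a consistency flag with a
warning. Two corners are outside the observable space and raise validation
errors instead of guessing: differentiated symbiotic cells without
infection, and an infected, undifferentiated nodule without an
infection-thread network.

Genes induced in all root-like mutants are detected by one-sided (greater)
Welch tests against the root baseline, intersected across the queried
genotypes — one-sided because the question is induction, and restricted to
the root-like categories because that is where a residual nodulation
program is informative.

## qPCR

Relative expression uses the efficiency-corrected ratio
E_target^(CP_cal − CP_sample) / E_ref^(CP_cal − CP_sample) with a
constitutive reference transcript. Ratios are computed per biological
replicate (technical replicates average at the CP level first), the
calibrator is the sample with the lowest mean ratio, and output is rescaled
so the minimum sample mean is exactly 1. With both efficiencies at 2 the
method reduces to the classical 2^(−ΔΔCP), which the tests assert.

## What the generator emulates — and what it does not

The generator is a pure function of (config, seed). Its defaults encode the
study design: 2366 probes, 520 differential genes on the eight profiles
(321 of them on wave profiles 5–8), a 1500-gene invariant core whose median
linear level is exactly 1, the anchor spotted 12×, ten time points at
0–29 dpi with three arrays each, the fifteen-mutant panel, root
(60/30/10 over 2C/4C/8C) and nodule (spanning 2C–64C, planted EI ≈ 54)
ploidy mixtures, uniform 1–2 µm cultured rods versus a gamma model with
mean 6.75 µm (4.5× elongation) for differentiated bacteroids.

Expression tiers are stage-mean triples with tier step `de_effect = 1.5`
log2; channel noise is multiplicative log-normal per spot
(`noise_sd = 0.25` log2 per channel), plus a per-array global scale
(`scale_sd = 0.25`) that normalization must remove. Non-differential,
non-invariant "background" genes carry array-to-array jitter of
2 × `noise_sd` so that invariant selection has something to reject; the
jitter scales with the channel noise so that noise-free runs recover the
planted structure exactly. Ten "common" genes are planted with 2.5 log2
induction in every mutant nodule — below the 3.0 nodule-high tier but
detectable at p < 0.01 under the generator's own three-replicate design.
Synthetic gene ids are laid out in truth blocks (invariant core first),
which keeps the documented lexicographic tie-break meaningful on
zero-variance input; `GeneratorTruth` is the authoritative label source.

The generator does not emulate: within-stage temporal fine structure (tiers
are stage-constant, so time points inside a stage are exchangeable),
spatial print-tip or intensity-dependent dye bias (normalization is a
single median scale, as in the analysis it implements), probe
cross-hybridization, S-phase nuclei or debris in the histograms, or
cell-to-cell length variation structure beyond the stated distributions.
Passing recovery tests therefore shows the chain is correct under its own
assumptions, not that those assumptions hold for any particular real
dataset.

## Problem sizes and runtime choices

Unit tests run on a 120-gene scaled-down configuration; recovery and
acceptance checks use the full default design (2366 genes × 30 time-course
arrays, 48 panel arrays, 10^4 nuclei per histogram, 10^3 bacteroid
lengths), which a laptop-class CPU completes in well under a minute per
check. The acceptance script reruns the whole chain from scratch at those
sizes.

## Known limitations

- The digital-tier algorithm and the flow-cytometry gating are this
  package's defined readings of underdocumented steps; both are frozen by
  tests but are not guaranteed to reproduce the original tools bit for bit.
- Raw-p selection at 0.01 admits false positives by design; the
  noise-tolerant cut absorbs them into the nearest profile rather than
  reporting them separately.
- The classifier requires a decisive EI call; samples in the 2–15 gap
  deliberately fail with a request for more data.
- Fold-change-based bacteroid calls assume a representative cultured
  reference; length distributions with heavy contamination would need
  upstream filtering.
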