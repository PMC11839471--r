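---
title: "Methods and design notes for oncopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for oncopath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncopath)
```

`oncopath` identifies cancer-type-specific transcripts and proteins from
cell-line expression panels, calls the biological pathways characteristic of
each cancer type, links drugs to cancer types through those pathways, and
validates the predictions quantitatively. This vignette explains the model
behind each stage, the tunable parameters, the numerical choices, what the
synthetic-data generator does and does not emulate, and the package's known
limitations.

## Preprocessing: capping and log2

RNA-Seq input arrives as an RPKM matrix (features × cell lines). Two
operations prepare it for testing:

* **Outlier capping** (`capOutliers`). The per-cell-line maxima are
  collected and their mode is taken as the calibration value; every matrix
  entry above it is replaced by it. Two numerical choices make this
  well-defined on continuous data: maxima are rounded to 4 significant
  digits before mode counting (exact-real modes are degenerate), and ties
  among equally frequent modes are broken toward the smallest value, the
  most conservative cap. The reported calibration value is the smallest
  *original* maximum inside the modal bin, so it is always a value that
  actually occurs. Reading the rule as "cap **all** values above the
  calibration value" (rather than "replace only each sample's single
  maximum") was a deliberate choice: it yields an idempotent, monotone
  operator whose behaviour is easy to state and test — applying it twice
  changes nothing, and no value ever increases.
* **Log2 transform** (`log2Transform`), `x → log2(x + 1)`. The pseudocount
  of 1 preserves zeros exactly and is the community default for RPKM.

Proteomics input is already log2-quantified (TMT workflow) and must *not*
be re-processed. The `scaleTag` slot of `ExpressionMatrix` enforces this
mechanically: capping and log2 only accept `rpkm` matrices, and the protein
reader tags its output `log2`, so the bypass is structural rather than a
convention.

## Marker selection

Selection is one-vs-rest per cancer type, in three steps.

1. **ANOVA screen** (`anovaScreen`, default `alpha = 0.05`): a one-way
   ANOVA across all cancer types drops features with no differential signal
   anywhere. Features with zero total variance are assigned `p = 1`.
   Missing protein values are excluded pairwise; a feature falling below
   one usable group or one residual degree of freedom is likewise assigned
   `p = 1` rather than propagating `NaN`s.
2. **One-vs-rest t-test** (`oneVsRestTTest`): the unpaired two-tailed
   Student's *t* with pooled variance and `n1 + n2 − 2` degrees of freedom.
   Pooled rather than Welch is intentional — the procedure being
   implemented specifies the classical Student form. A feature with fewer
   than 2 usable values on either side is marked missing, not dropped, so
   row accounting stays intact. When both group variances vanish, `t = 0,
   p = 1` for equal means and `p = 0` otherwise.
3. **Cutoff choice.** For transcripts the raw p-values are BH-adjusted and
   a nine-point cutoff grid `1e-10 … 1e-2` (tenfold steps) is evaluated:
   the features passing each cutoff are used to cluster the *samples*
   (complete linkage on Euclidean distances, tree cut at `k = 2`) and the
   cut is scored with Gini purity against binary target-vs-rest labels.
   The cutoff maximizing purity wins; ties break toward the more stringent
   cutoff, which keeps the rule deterministic and biases toward smaller,
   cleaner marker sets. Cutting at `k = 2` with binary labels is the
   natural match for a one-vs-rest selection; a multi-class purity scheme
   (cut at the number of cancer types, score against all labels) would
   also be defensible, but the binary scheme is what the selection
   criterion acts on, so it is the implemented default. Empty subsets
   score as undefined and can never be chosen; if *all* nine subsets are
   empty the selection returns an empty set with a warning rather than an
   error, since downstream stages handle empty inputs.

Proteins use a fixed raw `p < 0.05` (strict) after the same ANOVA screen —
protein panels are an order of magnitude smaller than transcript panels,
and a grid search on a few hundred features is not meaningful. The
threshold applies to the *raw* p-value by design.

A note on calibration testing: the package's null-calibration test measures
the t-test selection step with the ANOVA screen disabled (`anovaAlpha = 1`).
With the screen active the selected fraction is the joint probability of
passing both tests, which is not 5% by construction; 5% is the size of the
selection threshold itself, and that is what the test checks.

## Pathway enrichment

`fisherEnrich` computes, per pathway, the one-sided Fisher exact p-value as
the hypergeometric upper tail `P(X ≥ k)` with `N` universe genes, `n`
significant genes, `K` pathway genes in the universe and `k` overlapping.
Choices that matter:

* **One-sided.** Depletion has no meaning for calling *enriched* pathways.
* **Universe = platform.** The universe is the set of gene symbols
  measurable on the layer at hand (all mapped transcript symbols, or all
  quantified proteins), not the whole genome — the standard guard against
  platform-coverage bias.
* **Symbol-less features are excluded.** Most non-coding biotypes carry no
  gene symbol and cannot join a symbol-keyed pathway database; they are
  excluded from both the significant set and the universe. All symbols are
  upper-cased at parse time, because case mismatches are the dominant
  silent-join failure.

Pathways reaching FDR `p < 0.05` are confirmed by a **permutation
bootstrap** (`bootstrapPathway`, 1000 replicates): each replicate draws a
uniform random gene set of the significant set's size from the universe and
recomputes the pathway's Fisher p; the bootstrap p is the *count* of
replicate p-values strictly below the observed one divided by the number of
replicates. The estimator is the plain counting ratio — 5 of 1000 gives
0.005, and 0 of 1000 is reported as 0, not smoothed — and is bit-for-bit
reproducible given a seed. Random gene-set draws of matched size are the
simplest permutation scheme preserving both `n` and the pathway, and are
equivalent to permuting significance labels over the universe.

The transcript and protein evidence for a pathway are combined as the
average of the **base-10** logarithms of the two FDR-adjusted p-values
(`combineScores`); base 10 makes scores read directly as mean exponents
(e.g. FDR p-values of 1e-2 and 1e-6 give −4). A p of exactly 0 is floored
at the smallest representable positive double with a warning. A pathway is
**characteristic** of a cancer type when significant in *both* layers
(FDR < 0.05 and bootstrap < 0.05 each); characteristic pathways are ranked
by ascending score with alphabetical tie-breaks.

## Drug linking

`collectMultiPathwayTargets` keeps genes present in at least
`minPathways = 2` characteristic pathways — the smallest honest reading of
"multiple", and configurable. `linkDrugs` then admits every drug with at
least one annotated target among those genes, links it to *all*
characteristic pathways containing *any* of its targets (the union over the
full target set, which is what produces large per-drug pathway counts), and
ranks by descending pathway count with alphabetical tie-breaks. Raising
`minPathways` is anti-monotone: it can only remove candidates.
`flagApproved` annotates candidates against an approved-therapy table and
warns about cancer-type strings that match nothing, so vocabulary drift
between sources is always surfaced.

## Validation

* `compareMnAUC`: two-sided Wilcoxon rank-sum on candidate vs reference
  mnAUC values. The exact null distribution is used when both samples have
  ≤ 25 values and no ties; otherwise the normal approximation with tie
  correction. Means are reported to 2 decimals.
* `randomizationHitTest`: each of `nReps = 100` replicates samples
  `nPairs = 1000` drug–cancer-type pairs uniformly *without replacement*
  from the pair universe and counts approved pairs. The predicted set's
  hit count is compared against the pooled replicate counts in a single
  2×2 Fisher exact table. Pooling was chosen because one aggregate
  comparison yields one p-value; the per-replicate hit counts are returned
  alongside for diagnostics.

## The synthetic-study generator

`generateStudy(simConfig())` builds the seven pipeline inputs with planted
ground truth. Defaults define the study conditions used throughout the
tests: 4 cancer types × 15 cell lines, 2000 transcripts (70% protein
coding), 50 planted markers per type shifted by +2 log2 units over a
within-class sd of 0.5, a protein layer covering 50% of coding genes with
2% missing values, 30 pathways of 40 genes (3 planted per type drawing 60%
of members from that type's markers, so markers recur across a type's
planted pathways and become multi-pathway genes), 40 drugs (one planted per
type, targeting genes shared by ≥ 2 of its planted pathways; null drugs
target genes outside every planted pathway), and mnAUC drawn from
N(0.87, 0.08) for planted drugs vs N(0.96, 0.08) otherwise — centring the
two groups on the means the validation stage is meant to resolve.
Per-feature baselines are Uniform(2, 8) in log2 units, a realistic dynamic
range for expressed genes; the transcript matrix is exported on the RPKM
scale via `2^x − 1` (floored at 0) so that preprocessing is genuinely
exercised.

The generator is deliberately Gaussian in log2 space: the pipeline consumes
log2 RPKM, so count-level realism (overdispersion, library-size effects)
would add nothing the statistics downstream could detect. It also does not
emulate TMT channel/batch structure, correlated gene modules, or
dose–response curves — mnAUC is consumed as an input, never re-estimated.
Passing recovery tests on this generator therefore demonstrates that the
pipeline's selection, enrichment, linking and validation logic is correct
and calibrated, not that real CCLE-scale data would yield any particular
biological result.

Test problem sizes are the package's own choice of desk scale: recovery
runs use the full default configuration above, while loops repeated over
many seeds (null calibration over 20 seeds, determinism reruns) use a
reduced 600-feature × 40-sample configuration with 200 bootstrap
replicates, which preserves every code path at a fraction of the cost.

## Pipeline orchestration and reproducibility

`runPipeline` validates its config strictly (unknown keys are rejected by
name; all seven inputs must exist before any computation starts), writes
every stage table as TSV, and records a manifest (package version, seed,
parameters, input MD5 checksums, per-stage row counts). A single global
seed is expanded into fixed per-stage substreams so the bootstrap and the
randomization test are individually replayable; reruns with the same
config produce byte-identical outputs. Cancer types with fewer than 2
samples on either omics layer are skipped with a message — the t statistics
are undefined below that.

## Known limitations

* Significance thresholds (0.05 everywhere, FDR grid bounds) are fixed
  conventions of the implemented procedure, configurable but not tuned.
* The clustering purity criterion assumes the target type can separate in
  a 2-cluster cut; cancer types that fragment into several expression
  subtypes may be under-selected.
* Gene-symbol joins are exact (after upper-casing); no alias resolution is
  attempted, and an explicit id-mapping step upstream is the intended way
  to harmonize cell-line identifiers across omics sources.
* The bootstrap's resolution is `1/nReps`; with 1000 replicates p-values
  below 0.001 are indistinguishable from 0.
* `compareMnAUC` tests location only; it does not model drug-class
  composition differences between candidate and reference sets.
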