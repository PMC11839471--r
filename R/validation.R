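#' Compare mnAUC of candidate drugs against a reference set
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of the candidate drugs'
#' mnAUC values against a reference distribution; an effective candidate set
#' should sit lower (fewer cells surviving).  The exact null distribution is
#' used when both samples have at most 25 values and no ties are present;
#' otherwise the normal approximation with tie correction is used.  Means
#' are reported rounded to 2 decimals.
#'
#' @param candidates,reference numeric vectors of mnAUC values (non-empty).
#' @return an object of class `MnAUCComparison`: a list with
#'   `meanCandidates`, `meanReference`, `wilcoxonP`, `nCandidates`,
#'   `nReference`.
#' @export
compareMnAUC <- function(candidates, reference) {
    if (!length(candidates) || !length(reference))
        stop("both mnAUC samples must be non-empty")
    ties <- anyDuplicated(c(candidates, reference)) > 0L
    exact <- !ties && max(length(candidates), length(reference)) <= 25L
    p <- suppressWarnings(stats::wilcox.test(
        candidates, reference, alternative = "two.sided",
        exact = exact, correct = TRUE)$p.value)
    structure(list(meanCandidates = round(mean(candidates), 2L),
                   meanReference = round(mean(reference), 2L),
                   wilcoxonP = p,
                   nCandidates = length(candidates),
                   nReference = length(reference)),
              class = "MnAUCComparison")
}

#' @export
print.MnAUCComparison <- function(x, ...) {
    cat(sprintf("mnAUC comparison: candidates %.2f (n=%d) vs reference %.2f (n=%d), Wilcoxon p = %g\n",
                x$meanCandidates, x$nCandidates, x$meanReference,
                x$nReference, x$wilcoxonP))
    invisible(x)
}

.pairKey <- function(pairs)
    paste(pairs$drug_id, pairs$cancer_type, sep = "\r")

#' Randomized hit-rate test for predicted drug--cancer-type pairs
#'
#' A pair is a hit when the drug is an approved targeted therapy for that
#' cancer type.  Each replicate samples `nPairs` pairs uniformly without
#' replacement from the full pair universe and counts hits; the mean random
#' hit rate over `nReps` replicates is compared with the predicted set's hit
#' rate by a two-sided Fisher exact test on the 2x2 table
#' `[[predicted hits, predicted misses], [pooled random hits, pooled random
#' misses]]` (replicates pooled into a single table; the per-replicate hit
#' counts are also returned for diagnostics).
#'
#' @param predicted data.frame of predicted pairs (`drug_id`, `cancer_type`);
#'   must be non-empty and a subset of `allPairs`.
#' @param allPairs data.frame of the full pair universe.
#' @param approved data.frame of approved pairs.
#' @param nPairs pairs sampled per replicate (1000 in the reference
#'   procedure).
#' @param nReps number of replicates (100 in the reference procedure).
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `HitRateResult`: a list with `predictedPairs`,
#'   `predictedHits`, `predictedHitRate`, `nPairsPerRep`, `nReps`,
#'   `meanRandomHitRate`, `fisherP`, `replicateHits`.
#' @export
randomizationHitTest <- function(predicted, allPairs, approved,
                                 nPairs = 1000L, nReps = 100L, seed = NULL) {
    predKeys <- unique(.pairKey(predicted))
    allKeys <- unique(.pairKey(allPairs))
    apprKeys <- unique(.pairKey(approved))
    if (!length(predKeys)) stop("the predicted pair set is empty")
    outside <- setdiff(predKeys, allKeys)
    if (length(outside))
        stop("predicted pairs outside the pair universe: ",
             length(outside), " pair(s)")
    if (nPairs > length(allKeys))
        stop("nPairs exceeds the size of the pair universe")
    if (nReps < 1L) stop("nReps must be at least 1")
    if (!is.null(seed)) set.seed(seed)
    isHit <- allKeys %in% apprKeys
    repHits <- vapply(seq_len(nReps), function(i)
        sum(isHit[sample.int(length(allKeys), nPairs)]), integer(1))
    predHits <- sum(predKeys %in% apprKeys)
    pooledHits <- sum(repHits)
    tab <- matrix(c(predHits, length(predKeys) - predHits,
                    pooledHits, nReps * nPairs - pooledHits),
                  nrow = 2L, byrow = TRUE)
    structure(list(predictedPairs = length(predKeys),
                   predictedHits = predHits,
                   predictedHitRate = predHits / length(predKeys),
                   nPairsPerRep = nPairs, nReps = nReps,
                   meanRandomHitRate = mean(repHits / nPairs),
                   fisherP = stats::fisher.test(tab)$p.value,
                   replicateHits = repHits),
              class = "HitRateResult")
}

#' @export
print.HitRateResult <- function(x, ...) {
    cat(sprintf("Hit-rate test: predicted %.4f (%d/%d) vs random %.4f (%d reps x %d pairs), Fisher p = %g\n",
                x$predictedHitRate, x$predictedHits, x$predictedPairs,
                x$meanRandomHitRate, x$nReps, x$nPairsPerRep, x$fisherP))
    invisible(x)
}
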