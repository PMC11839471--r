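#' Fisher exact pathway enrichment
#'
#' One-sided (enrichment) Fisher exact test per pathway: with `N` universe
#' genes, `n` significant genes, `K` pathway genes in the universe and `k`
#' significant pathway genes, the p-value is the hypergeometric upper tail
#' `P(X >= k)`.  Pathways are intersected with the universe before counting;
#' pathways with no universe gene are skipped.  p-values are BH-adjusted
#' across all tested pathways.
#'
#' The universe should be the genes measurable on the platform at hand (all
#' mapped symbols in the expression matrix), not the whole genome, to guard
#' against platform-coverage bias.
#'
#' @param sigGenes character vector of significant gene symbols (must be a
#'   subset of `universe`).
#' @param universe character vector of all measurable gene symbols.
#' @param db a [PathwayDB-class].
#' @return data.frame with one row per tested pathway: `pathway_id`, `k`,
#'   `K`, `n`, `N`, `p_fisher`, `p_fdr`, `p_bootstrap` (initialised to `NA`;
#'   see [enrichWithBootstrap()]).
#' @export
fisherEnrich <- function(sigGenes, universe, db) {
    stopifnot(methods::is(db, "PathwayDB"))
    universe <- unique(universe)
    sigGenes <- unique(sigGenes)
    outside <- setdiff(sigGenes, universe)
    if (length(outside))
        stop("significant genes outside the universe: ",
             paste(utils::head(outside, 10L), collapse = ", "))
    N <- length(universe)
    n <- length(sigGenes)
    K <- vapply(geneSets(db), function(g) sum(g %in% universe), integer(1))
    keep <- K > 0L
    k <- vapply(geneSets(db)[keep], function(g)
        sum(sigGenes %in% g), integer(1))
    K <- K[keep]
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    out <- data.frame(pathway_id = pathwayIds(db)[keep], k = unname(k),
                      K = unname(K), n = n, N = N, p_fisher = unname(p),
                      p_fdr = bhAdjust(unname(p)), p_bootstrap = NA_real_,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Bootstrap p-value from replicate Fisher p-values
#'
#' The counting estimator behind the permutation bootstrap: the fraction of
#' replicate p-values strictly smaller than the observed one.  Five of 1000
#' replicates below the observed value gives a bootstrap p of 0.005; a
#' bootstrap p of 0 is reported as 0 (not smoothed).
#'
#' @param observedP the observed Fisher p-value.
#' @param replicateP numeric vector of replicate Fisher p-values.
#' @return the bootstrap p-value.
#' @export
bootstrapPFromReplicates <- function(observedP, replicateP) {
    if (length(replicateP) < 1L) stop("at least one replicate is required")
    sum(replicateP < observedP) / length(replicateP)
}

#' Permutation bootstrap for one enriched pathway
#'
#' Confirms a significant Fisher result by permutation: each replicate draws
#' a uniform random gene set of the same size as the significant set from
#' the universe, recomputes the pathway's Fisher p-value, and the bootstrap
#' p-value is the fraction of replicates beating the observed p-value
#' ([bootstrapPFromReplicates()]).  Intended for pathways that already have
#' an FDR-adjusted p < 0.05; bootstrap p < 0.05 confirms significance.
#'
#' @param observedP the observed Fisher p-value for the pathway.
#' @param universe character vector of universe gene symbols.
#' @param pathwayGenes the pathway's gene set.
#' @param nSig size of the significant gene set (replicate draw size).
#' @param nReps number of replicates (1000 in the reference procedure).
#' @param seed optional integer seed; when supplied the result is
#'   bit-for-bit reproducible.
#' @return the bootstrap p-value.
#' @export
bootstrapPathway <- function(observedP, universe, pathwayGenes, nSig,
                             nReps = 1000L, seed = NULL) {
    if (nReps < 1L) stop("nReps must be at least 1")
    if (!is.null(seed)) set.seed(seed)
    universe <- unique(universe)
    N <- length(universe)
    if (nSig > N) stop("significant set larger than the universe")
    memb <- universe %in% pathwayGenes
    K <- sum(memb)
    reps <- vapply(seq_len(nReps), function(i) {
        kRep <- sum(memb[sample.int(N, nSig)])
        stats::phyper(kRep - 1L, K, N - K, nSig, lower.tail = FALSE)
    }, numeric(1))
    bootstrapPFromReplicates(observedP, reps)
}

#' Fisher enrichment with bootstrap confirmation
#'
#' Runs [fisherEnrich()] and then [bootstrapPathway()] for every pathway with
#' `p_fdr < fdrThreshold`, filling the `p_bootstrap` column.
#'
#' @inheritParams fisherEnrich
#' @param fdrThreshold FDR threshold gating the bootstrap stage.
#' @param nReps bootstrap replicates per pathway.
#' @param seed integer seed for the bootstrap stream.
#' @return the [fisherEnrich()] data.frame with `p_bootstrap` filled for
#'   bootstrapped pathways (`NA` elsewhere).
#' @export
enrichWithBootstrap <- function(sigGenes, universe, db, fdrThreshold = 0.05,
                                nReps = 1000L, seed = NULL) {
    rec <- fisherEnrich(sigGenes, universe, db)
    todo <- which(rec$p_fdr < fdrThreshold)
    if (length(todo)) {
        if (!is.null(seed)) set.seed(seed)
        for (i in todo)
            rec$p_bootstrap[i] <- bootstrapPathway(
                rec$p_fisher[i], universe, db[[rec$pathway_id[i]]],
                nSig = rec$n[i], nReps = nReps, seed = NULL)
    }
    rec
}

#' Combined cross-omics significance score
#'
#' The average of the base-10 logarithms of the transcript- and protein-layer
#' FDR-adjusted p-values; smaller (more negative) means more significant.
#' A p of 0 is floored at the smallest representable positive double with a
#' warning.
#'
#' @param pFdrTranscript,pFdrProtein FDR-adjusted p-values from the two
#'   layers (vectorized).
#' @return numeric score(s), `<= 0`.
#' @examples
#' combineScores(1e-2, 1e-6)  # -4
#' @export
combineScores <- function(pFdrTranscript, pFdrProtein) {
    floorP <- function(p) {
        if (any(p <= 0, na.rm = TRUE)) {
            warning("p-value of 0 floored at the smallest representable double")
            p[!is.na(p) & p <= 0] <- .Machine$double.xmin
        }
        if (any(p > 1, na.rm = TRUE)) stop("p-values must lie in (0, 1]")
        p
    }
    (log10(floorP(pFdrTranscript)) + log10(floorP(pFdrProtein))) / 2
}

#' Characteristic pathways of a cancer type
#'
#' A pathway is characteristic when it is significant in both the
#' transcript-derived and the protein-derived enrichment (FDR-adjusted
#' p < 0.05 and bootstrap p < 0.05 in each layer).  The shared pathways are
#' scored with [combineScores()] and returned most-significant first, ties
#' broken alphabetically by pathway id.
#'
#' @param transcriptRecords,proteinRecords enrichment tables from
#'   [enrichWithBootstrap()] for the two layers.
#' @param cancerType label copied into the output.
#' @param fdrThreshold,bootstrapThreshold per-layer significance thresholds.
#' @return data.frame with columns `pathway_id`, `cancer_type`, `score`,
#'   `p_fdr_transcript`, `p_fdr_protein`, `p_bootstrap_transcript`,
#'   `p_bootstrap_protein`; empty when the significant sets are disjoint.
#' @export
characteristicPathways <- function(transcriptRecords, proteinRecords,
                                   cancerType = NA_character_,
                                   fdrThreshold = 0.05,
                                   bootstrapThreshold = 0.05) {
    sig <- function(rec) rec[!is.na(rec$p_fdr) & rec$p_fdr < fdrThreshold &
                             !is.na(rec$p_bootstrap) &
                             rec$p_bootstrap < bootstrapThreshold, ,
                             drop = FALSE]
    t <- sig(transcriptRecords)
    p <- sig(proteinRecords)
    shared <- intersect(t$pathway_id, p$pathway_id)
    if (!length(shared))
        return(data.frame(pathway_id = character(0),
                          cancer_type = character(0), score = numeric(0),
                          p_fdr_transcript = numeric(0),
                          p_fdr_protein = numeric(0),
                          p_bootstrap_transcript = numeric(0),
                          p_bootstrap_protein = numeric(0),
                          stringsAsFactors = FALSE))
    t <- t[match(shared, t$pathway_id), , drop = FALSE]
    p <- p[match(shared, p$pathway_id), , drop = FALSE]
    out <- data.frame(pathway_id = shared, cancer_type = cancerType,
                      score = combineScores(t$p_fdr, p$p_fdr),
                      p_fdr_transcript = t$p_fdr, p_fdr_protein = p$p_fdr,
                      p_bootstrap_transcript = t$p_bootstrap,
                      p_bootstrap_protein = p$p_bootstrap,
                      stringsAsFactors = FALSE)
    out <- out[order(out$score, out$pathway_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}
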