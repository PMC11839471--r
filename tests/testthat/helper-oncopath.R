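# Shared fixture builders; everything is generated in code at test time.

tinyExpr <- function(values, scale = "rpkm", geneSymbols = NULL,
                     biotypes = NULL) {
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
    ExpressionMatrix(values, scaleTag = scale, geneSymbols = geneSymbols,
                     biotypes = biotypes)
}

# Two-class gaussian matrix (no planted effect unless shift != 0).
nullStudyMatrix <- function(nFeatures, nPerClass, shift = 0, sd = 1,
                            nClasses = 2L, seed = 1L) {
    set.seed(seed)
    n <- nClasses * nPerClass
    lab <- stats::setNames(rep(paste0("cls", seq_len(nClasses)),
                               each = nPerClass),
                           sprintf("s%03d", seq_len(n)))
    v <- matrix(rnorm(nFeatures * n, sd = sd), nFeatures, n,
                dimnames = list(sprintf("f%04d", seq_len(nFeatures)),
                                names(lab)))
    v[, lab == "cls1"] <- v[, lab == "cls1"] + shift
    list(m = tinyExpr(v, scale = "log2"), labels = lab)
}

# Reduced-size synthetic study for loops that repeat over many seeds.
smallConfig <- function(...) {
    defaults <- list(nClasses = 4L, nSamplesPerClass = 10L,
                     nFeatures = 600L, nMarkersPerClass = 25L,
                     nPathways = 20L, pathwaySize = 25L, nDrugs = 20L)
    do.call(simConfig, utils::modifyList(defaults, list(...)))
}

# Exhaustive hypergeometric upper-tail oracle, written from the counting
# definition (independent of phyper).
hyperTailOracle <- function(k, K, n, N) {
    lo <- max(k, n - (N - K))
    hi <- min(K, n)
    if (lo > hi) return(0)
    sum(vapply(lo:hi, function(j)
        choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
}

# Step-up BH oracle from the definition: adj(i) = min_{j >= i} min(1, p(j)*n/j).
bhOracle <- function(p) {
    n <- length(p)
    ord <- order(p)
    adj <- pmin(1, p[ord] * n / seq_len(n))
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[ord] <- adj
    out
}

# In-memory selection + enrichment + characteristic pathways for one bundle,
# mirroring the pipeline stages without file IO.
characteristicForBundle <- function(bundle, target, bootReps = 200L,
                                    seed = 1L) {
    exprLog <- log2Transform(capOutliers(transcriptMatrix(bundle))$matrix)
    lab <- studyLabels(bundle)
    st <- suppressWarnings(selectTranscripts(exprLog, lab, target))
    sp <- selectProteins(proteinMatrix(bundle), lab, target)
    sym <- geneSymbols(exprLog)
    tUniverse <- unique(sym[!is.na(sym)])
    tGenes <- unique(sym[featureIds(st)])
    tGenes <- tGenes[!is.na(tGenes)]
    db <- pathwayDB(bundle)
    et <- enrichWithBootstrap(tGenes, tUniverse, db, nReps = bootReps,
                              seed = seed)
    ep <- enrichWithBootstrap(featureIds(sp),
                              unique(rownames(proteinMatrix(bundle))), db,
                              nReps = bootReps, seed = seed + 1L)
    characteristicPathways(et, ep, cancerType = target)
}
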