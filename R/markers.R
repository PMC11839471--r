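# Row-wise one-way ANOVA F-test p-values with pairwise NA handling.
# Features with zero total variance get p = 1; zero within-group variance
# with non-zero between-group variance gets p = 0; features with too few
# usable observations (within df < 1 or fewer than 2 usable groups) get
# p = 1 so they are never retained.
.rowOneWayF <- function(v, groupIdx) {
    G <- length(groupIdx)
    n <- s <- ss <- matrix(0, nrow(v), G)
    for (g in seq_len(G)) {
        xg <- v[, groupIdx[[g]], drop = FALSE]
        ok <- !is.na(xg)
        xg[!ok] <- 0
        n[, g] <- rowSums(ok)
        s[, g] <- rowSums(xg)
        ss[, g] <- rowSums(xg * xg)
    }
    N <- rowSums(n)
    S <- rowSums(s)
    gEff <- rowSums(n >= 1L)
    sst <- rowSums(ss) - S^2 / N
    ssb <- rowSums(ifelse(n > 0, s^2 / n, 0)) - S^2 / N
    ssw <- sst - ssb
    df1 <- gEff - 1
    df2 <- N - gEff
    tol <- 1e-12 * pmax(1, abs(sst))
    p <- rep(NA_real_, nrow(v))
    degenerate <- df1 < 1 | df2 < 1 | sst <= tol
    p[degenerate] <- 1
    pureSig <- !degenerate & ssw <= tol
    p[pureSig] <- 0
    idx <- which(!degenerate & !pureSig)
    if (length(idx)) {
        f <- (ssb[idx] / df1[idx]) / (ssw[idx] / df2[idx])
        p[idx] <- stats::pf(f, df1[idx], df2[idx], lower.tail = FALSE)
    }
    stats::setNames(p, rownames(v))
}

#' ANOVA screen across cancer types
#'
#' First-stage filter: a one-way ANOVA of expression across all cancer types;
#' only features with `p < alpha` proceed to the one-vs-rest tests.  Features
#' with zero total variance are assigned `p = 1` and dropped.
#'
#' @param m a log2-scale [ExpressionMatrix-class].
#' @param labels named character vector mapping sample id to cancer type;
#'   every class must have at least 2 samples.
#' @param alpha retention threshold on the ANOVA p-value.
#' @return data.frame with columns `feature_id`, `anova_p`, `retained`.
#' @export
anovaScreen <- function(m, labels, alpha = 0.05) {
    stopifnot(methods::is(m, "ExpressionMatrix"))
    if (!identical(scaleTag(m), "log2"))
        stop("anovaScreen expects a log2-scale matrix")
    labels <- alignLabels(m, labels)
    classes <- sort(unique(labels))
    if (length(classes) < 2L)
        stop("at least 2 cancer types are required")
    sizes <- table(labels)
    if (any(sizes < 2L))
        stop("cancer types with fewer than 2 samples: ",
             paste(names(sizes)[sizes < 2L], collapse = ", "))
    v <- exprValues(m)[, names(labels), drop = FALSE]
    groupIdx <- lapply(classes, function(cl) which(labels == cl))
    p <- .rowOneWayF(v, groupIdx)
    data.frame(feature_id = rownames(v), anova_p = unname(p),
               retained = unname(p) < alpha, stringsAsFactors = FALSE)
}

#' One-vs-rest pooled-variance t-test
#'
#' Compares expression in the target cancer type against the pooled remaining
#' types with the unpaired two-tailed Student's t-test (pooled variance,
#' `n1 + n2 - 2` degrees of freedom).  Missing values are excluded pairwise;
#' a feature with fewer than 2 usable values on either side is marked missing
#' (`NA` statistics) rather than dropped.
#'
#' @param m a log2-scale [ExpressionMatrix-class].
#' @param labels named character vector mapping sample id to cancer type.
#' @param target the cancer type to contrast against the rest.
#' @return data.frame with columns `feature_id`, `t_stat`, `p_raw`,
#'   `direction` (`"up"` iff the target mean exceeds the rest mean),
#'   `n_target`, `n_rest`.
#' @export
oneVsRestTTest <- function(m, labels, target) {
    stopifnot(methods::is(m, "ExpressionMatrix"))
    labels <- alignLabels(m, labels)
    if (!target %in% labels)
        stop("target cancer type ", sQuote(target), " not present in labels")
    v <- exprValues(m)[, names(labels), drop = FALSE]
    grpStats <- function(x) {
        ok <- !is.na(x)
        x[!ok] <- 0
        n <- rowSums(ok)
        s <- rowSums(x)
        ss <- rowSums(x * x)
        mean <- ifelse(n > 0, s / n, NA_real_)
        var <- ifelse(n > 1, (ss - n * mean^2) / (n - 1), NA_real_)
        list(n = n, mean = mean, var = pmax(var, 0))
    }
    a <- grpStats(v[, labels == target, drop = FALSE])
    b <- grpStats(v[, labels != target, drop = FALSE])
    usable <- a$n >= 2L & b$n >= 2L
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    diff <- a$mean - b$mean
    t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
    p <- 2 * stats::pt(-abs(t), df)
    p[!is.na(t) & t == 0] <- 1
    t[!usable] <- p[!usable] <- NA_real_
    data.frame(feature_id = rownames(v), t_stat = unname(t),
               p_raw = unname(p),
               direction = ifelse(diff > 0, "up", "down"),
               n_target = unname(a$n), n_rest = unname(b$n),
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (clipped to 1, monotone in rank), as implemented
#' by [stats::p.adjust()]; inputs are validated to lie in \[0, 1\].  `NA`
#' entries (features marked missing upstream) stay `NA`.
#'
#' @param p numeric vector of raw p-values.
#' @return numeric vector of FDR-adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p)) stop("p must be numeric")
    ok <- p[!is.na(p)]
    if (any(ok < 0 | ok > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Gini purity of a clustering against class labels
#'
#' One minus the sample-weighted Gini impurity: `sum_c (n_c / N) *
#' sum_j p_cj^2`, where `p_cj` is the fraction of cluster `c` carrying label
#' `j`.  Ranges over \[0, 1\]; 1 means every cluster is label-pure.  Invariant
#' to cluster relabelling and to sample order.
#'
#' @param clusters vector of cluster assignments, one per sample (no `NA`).
#' @param labels vector of class labels, aligned with `clusters`.
#' @return the Gini purity, a number in \[0, 1\].
#' @examples
#' giniPurity(c(1, 1, 1, 1), c("t", "t", "t", "r"))  # (9 + 1) / 16 = 0.625
#' @export
giniPurity <- function(clusters, labels) {
    if (length(clusters) == 0L) stop("empty clustering")
    if (length(clusters) != length(labels))
        stop("clusters and labels must have the same length")
    if (anyNA(clusters) || anyNA(labels))
        stop("every sample must carry a cluster and a label")
    N <- length(clusters)
    purity <- 0
    for (cl in unique(clusters)) {
        inCl <- clusters == cl
        pj <- table(labels[inCl]) / sum(inCl)
        purity <- purity + (sum(inCl) / N) * sum(pj^2)
    }
    unname(purity)
}

# Cluster samples on a feature subset (complete linkage, Euclidean), cut at
# k = 2, and score the cut against target-vs-rest labels.
.clusterPurity <- function(v, ids, binLabels) {
    sub <- v[ids, , drop = FALSE]
    if (anyNA(sub)) {   # pairwise-complete distances for proteomics use
        d <- stats::dist(t(sub))
        d[is.na(d)] <- max(d, na.rm = TRUE)
    } else d <- stats::dist(t(sub))
    cl <- stats::cutree(stats::hclust(d, method = "complete"), k = 2L)
    giniPurity(cl, binLabels)
}

#' Select significant transcripts for one cancer type
#'
#' The transcript-selection procedure: after the [anovaScreen()] filter and
#' the [oneVsRestTTest()] against the target type, raw p-values are
#' BH-adjusted and a grid of FDR cutoffs (by default `1e-10` to `1e-2` in
#' tenfold steps, 9 values) is evaluated.  At each cutoff the features with
#' `p_fdr < cutoff` are used to cluster the samples (agglomerative complete
#' linkage, Euclidean distance, tree cut at 2 clusters) and the cut is scored
#' with [giniPurity()] against target-vs-rest labels.  The chosen cutoff
#' maximizes the purity, with ties broken toward the smaller (more stringent)
#' cutoff.
#'
#' @param m a log2-scale [ExpressionMatrix-class].
#' @param labels named character vector mapping sample id to cancer type.
#' @param target the cancer type to select markers for.
#' @param grid numeric vector of FDR cutoffs to evaluate.
#' @param anovaAlpha retention threshold for the first-stage ANOVA screen.
#' @return a [SignificantFeatureSet-class]; when no feature passes any
#'   cutoff the set is empty with `chosenCutoff = NA` (a warning, not an
#'   error).
#' @export
selectTranscripts <- function(m, labels, target, grid = 10^seq(-10, -2),
                              anovaAlpha = 0.05) {
    labels <- alignLabels(m, labels)
    screen <- anovaScreen(m, labels, alpha = anovaAlpha)
    kept <- screen$feature_id[screen$retained]
    stats <- merge(screen[c("feature_id", "anova_p")],
                   oneVsRestTTest(m, labels, target),
                   by = "feature_id", sort = FALSE)
    stats$p_fdr <- NA_real_
    inKeep <- stats$feature_id %in% kept
    stats$p_fdr[inKeep] <- bhAdjust(stats$p_raw[inKeep])
    grid <- sort(grid)
    v <- exprValues(m)[, names(labels), drop = FALSE]
    binLabels <- ifelse(labels == target, "target", "rest")
    evals <- data.frame(fdr_cutoff = grid, subset_size = 0L,
                        gini_purity = NA_real_)
    subsets <- vector("list", length(grid))
    for (i in seq_along(grid)) {
        ids <- stats$feature_id[inKeep & !is.na(stats$p_fdr) &
                                stats$p_fdr < grid[i]]
        subsets[[i]] <- ids
        evals$subset_size[i] <- length(ids)
        if (length(ids))
            evals$gini_purity[i] <- .clusterPurity(v, ids, binLabels)
    }
    valid <- which(!is.na(evals$gini_purity))
    if (!length(valid)) {
        warning("no transcript passes any FDR cutoff for ", sQuote(target))
        chosen <- NA_real_
        ids <- character(0)
    } else {
        best <- valid[which.max(evals$gini_purity[valid])]  # first max = most stringent
        chosen <- grid[best]
        ids <- subsets[[best]]
    }
    methods::new("SignificantFeatureSet", cancerType = target,
                 omicsLayer = "transcript", featureIds = ids,
                 chosenCutoff = chosen, evaluations = evals, stats = stats)
}

#' Select significant proteins for one cancer type
#'
#' Protein selection uses a fixed raw-p threshold: after the ANOVA screen,
#' proteins with a one-vs-rest t-test `p_raw < alpha` (default 0.05, strict)
#' are selected.  FDR-adjusted p-values are still reported for reference.
#'
#' @inheritParams selectTranscripts
#' @param alpha raw p-value threshold for selection.
#' @return a [SignificantFeatureSet-class] with `chosenCutoff = alpha`.
#' @export
selectProteins <- function(m, labels, target, alpha = 0.05,
                           anovaAlpha = 0.05) {
    labels <- alignLabels(m, labels)
    screen <- anovaScreen(m, labels, alpha = anovaAlpha)
    kept <- screen$feature_id[screen$retained]
    stats <- merge(screen[c("feature_id", "anova_p")],
                   oneVsRestTTest(m, labels, target),
                   by = "feature_id", sort = FALSE)
    stats$p_fdr <- NA_real_
    inKeep <- stats$feature_id %in% kept
    stats$p_fdr[inKeep] <- bhAdjust(stats$p_raw[inKeep])
    ids <- stats$feature_id[inKeep & !is.na(stats$p_raw) &
                            stats$p_raw < alpha]
    methods::new("SignificantFeatureSet", cancerType = target,
                 omicsLayer = "protein", featureIds = ids,
                 chosenCutoff = alpha,
                 evaluations = data.frame(fdr_cutoff = numeric(0),
                                          subset_size = integer(0),
                                          gini_purity = numeric(0)),
                 stats = stats)
}
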