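#' Cap expression outliers at the modal per-sample maximum
#'
#' The RPKM matrix is cleaned of extreme outliers by calibrating against the
#' per-cell-line maxima: the calibration value is the value occurring most
#' frequently among the maximum RPKM values of all cell lines, and every
#' matrix entry above it is replaced by it.  Because maxima are continuous,
#' they are rounded to 4 significant digits before mode counting; ties among
#' equally frequent modes are broken toward the smallest value (the most
#' conservative cap), and the calibration value reported is the smallest
#' original maximum falling in the modal bin.  The operation is idempotent
#' and never increases a value.
#'
#' @param m an RPKM-scale [ExpressionMatrix-class] with at least one sample.
#' @return a list with `matrix` (the capped [ExpressionMatrix-class]) and
#'   `report`, a `CappingReport` list: `perSampleMax` (named numeric of the
#'   original per-sample maxima), `calibrationValue`, `nValuesCapped`.
#' @examples
#' m <- ExpressionMatrix(matrix(c(1, 10, 2, 10, 3, 50), 2,
#'     dimnames = list(c("f1", "f2"), c("s1", "s2", "s3"))), "rpkm")
#' capOutliers(m)$report$calibrationValue  # 10: the modal per-sample maximum
#' @export
capOutliers <- function(m) {
    stopifnot(methods::is(m, "ExpressionMatrix"))
    if (!identical(scaleTag(m), "rpkm"))
        stop("capOutliers expects an rpkm-scale matrix (proteomics and log2 ",
             "matrices bypass preprocessing)")
    v <- exprValues(m)
    if (nrow(v) == 0L || ncol(v) == 0L) stop("empty expression matrix")
    colMax <- apply(v, 2L, max, na.rm = TRUE)
    binned <- signif(colMax, 4L)
    counts <- table(binned)
    modal <- as.numeric(names(counts)[counts == max(counts)])
    modalBin <- min(modal)
    calibration <- min(colMax[binned == modalBin])
    over <- !is.na(v) & v > calibration
    nCapped <- sum(over)
    if (nCapped) v[over] <- calibration
    out <- ExpressionMatrix(v, scaleTag = "rpkm",
                            geneSymbols = geneSymbols(m),
                            biotypes = biotypes(m))
    report <- structure(list(perSampleMax = colMax,
                             calibrationValue = calibration,
                             nValuesCapped = nCapped),
                        class = "CappingReport")
    list(matrix = out, report = report)
}

#' @export
print.CappingReport <- function(x, ...) {
    cat(sprintf("CappingReport: calibration value %g, %d values capped over %d samples\n",
                x$calibrationValue, x$nValuesCapped, length(x$perSampleMax)))
    invisible(x)
}

#' Log2-transform an RPKM matrix
#'
#' Applies `x -> log2(x + pseudocount)` and flips the scale tag to `log2`.
#' The default pseudocount of 1 maps zeros to zero and is the community
#' default for RPKM data.
#'
#' @param m an RPKM-scale [ExpressionMatrix-class] with non-negative values.
#' @param pseudocount positive offset added before taking logs.
#' @return a log2-scale [ExpressionMatrix-class].
#' @export
log2Transform <- function(m, pseudocount = 1) {
    stopifnot(methods::is(m, "ExpressionMatrix"))
    if (!identical(scaleTag(m), "rpkm"))
        stop("log2Transform expects an rpkm-scale matrix")
    if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
        pseudocount <= 0)
        stop("pseudocount must be a single positive number")
    v <- exprValues(m)
    if (any(v < 0, na.rm = TRUE))
        stop("negative values cannot be log2-transformed")
    ExpressionMatrix(log2(v + pseudocount), scaleTag = "log2",
                     geneSymbols = geneSymbols(m), biotypes = biotypes(m))
}
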