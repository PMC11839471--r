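#' ExpressionMatrix: a labelled feature-by-sample expression container
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `exprs` assay plus a scale tag that records whether values are raw
#' RPKM or log2-transformed.  The tag is what enforces the analysis contract:
#' outlier capping only accepts `rpkm` matrices, the statistical layer only
#' accepts `log2` matrices, and proteomics input (already log2) therefore
#' bypasses preprocessing by construction.
#'
#' Feature metadata (`gene_symbol`, `biotype`) lives in `rowData`.  Missing
#' values are permitted (TMT proteomics routinely has missing channels) and are
#' excluded pairwise by the statistical functions; non-missing values must be
#' finite, and RPKM-scale values must be non-negative.
#'
#' @slot scaleTag either `"rpkm"` or `"log2"`.
#' @aliases ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    contains = "SummarizedExperiment",
    representation(scaleTag = "character"))

setValidity("ExpressionMatrix", function(object) {
    msg <- character(0)
    if (length(object@scaleTag) != 1L ||
        !object@scaleTag %in% c("rpkm", "log2"))
        msg <- c(msg, "scaleTag must be one of \"rpkm\", \"log2\"")
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay \"exprs\" is required")
    else {
        v <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(v))
            msg <- c(msg, "exprs values must be numeric")
        else {
            ok <- v[!is.na(v)]
            if (any(!is.finite(ok)))
                msg <- c(msg, "exprs values must be finite (NA allowed)")
            if (identical(object@scaleTag, "rpkm") && any(ok < 0))
                msg <- c(msg, "rpkm-scale values must be non-negative")
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric feature x sample matrix with unique row and column
#'   names.
#' @param scaleTag `"rpkm"` for raw abundance or `"log2"` for log2 values.
#' @param geneSymbols optional character vector of gene symbols per feature
#'   (`NA` for features without one, e.g. most non-coding biotypes).  Symbols
#'   are upper-cased so that joins against pathway and drug-target tables
#'   cannot fail on case.
#' @param biotypes optional character vector of feature biotypes.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("f", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m, "rpkm")
#' @export
ExpressionMatrix <- function(values, scaleTag, geneSymbols = NULL,
                             biotypes = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    n <- nrow(values)
    rd <- S4Vectors::DataFrame(
        gene_symbol = if (is.null(geneSymbols)) rep(NA_character_, n)
                      else toupper(as.character(geneSymbols)),
        biotype = if (is.null(biotypes)) rep(NA_character_, n)
                  else as.character(biotypes),
        row.names = rownames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values), rowData = rd)
    methods::new("ExpressionMatrix", se, scaleTag = scaleTag)
}

#' @describeIn ExpressionMatrix compact display.
#' @param object an `ExpressionMatrix`.
#' @export
setMethod("show", "ExpressionMatrix", function(object) {
    nsym <- sum(!is.na(geneSymbols(object)))
    cat(sprintf("ExpressionMatrix: %d features x %d samples [%s scale, %d with gene symbol]\n",
                nrow(object), ncol(object), object@scaleTag, nsym))
})

#' PathwayDB: named gene sets
#'
#' A pathway database as read from a GMT file: a named list of non-empty,
#' upper-cased gene-symbol vectors, with an optional description per pathway.
#'
#' @slot sets named list of character vectors (gene symbols).
#' @slot descriptions named character vector, same names as `sets`.
#' @aliases PathwayDB-class
#' @exportClass PathwayDB
setClass("PathwayDB",
    representation(sets = "list", descriptions = "character"))

setValidity("PathwayDB", function(object) {
    msg <- character(0)
    nm <- names(object@sets)
    if (length(object@sets) && (is.null(nm) || anyDuplicated(nm) ||
        any(!nzchar(nm))))
        msg <- c(msg, "pathway ids must be present, non-empty and unique")
    if (any(!vapply(object@sets, function(g)
            is.character(g) && length(g) >= 1L && all(nzchar(g)), logical(1))))
        msg <- c(msg, "every gene set must be a non-empty character vector")
    if (length(object@descriptions) != length(object@sets))
        msg <- c(msg, "one description per pathway required")
    if (length(msg)) msg else TRUE
})

#' Construct a PathwayDB
#'
#' @param sets named list of character gene-symbol vectors.
#' @param descriptions optional character vector of pathway descriptions.
#' @return a [PathwayDB-class] object.
#' @export
PathwayDB <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
    if (is.null(descriptions))
        descriptions <- stats::setNames(rep("", length(sets)), names(sets))
    methods::new("PathwayDB", sets = sets,
                 descriptions = stats::setNames(as.character(descriptions),
                                                names(sets)))
}

#' @describeIn PathwayDB number of pathways.
#' @param x a `PathwayDB`.
#' @export
setMethod("length", "PathwayDB", function(x) length(x@sets))

#' @describeIn PathwayDB extract one gene set by id or position.
#' @param i pathway id or index.
#' @export
setMethod("[[", "PathwayDB", function(x, i) x@sets[[i]])

#' @describeIn PathwayDB compact display.
#' @param object a `PathwayDB`.
#' @export
setMethod("show", "PathwayDB", function(object) {
    sz <- lengths(object@sets)
    cat(sprintf("PathwayDB: %d pathways (set sizes %s)\n", length(object@sets),
                if (length(sz)) paste0(min(sz), "-", max(sz)) else "none"))
})

#' DrugTargetMap: drug to target-gene annotations
#'
#' @slot targets named list mapping drug id to a non-empty set of upper-cased
#'   target gene symbols.
#' @aliases DrugTargetMap-class
#' @exportClass DrugTargetMap
setClass("DrugTargetMap", representation(targets = "list"))

setValidity("DrugTargetMap", function(object) {
    msg <- character(0)
    nm <- names(object@targets)
    if (length(object@targets) && (is.null(nm) || anyDuplicated(nm)))
        msg <- c(msg, "drug ids must be present and unique")
    if (any(!vapply(object@targets, function(g)
            is.character(g) && length(g) >= 1L, logical(1))))
        msg <- c(msg, "every drug must have at least one target gene")
    if (length(msg)) msg else TRUE
})

#' Construct a DrugTargetMap
#'
#' @param targets named list of character target-gene vectors, one per drug.
#'   Several sources (e.g. DrugBank- and KEGG-derived tables) can simply be
#'   concatenated before construction; duplicate (drug, gene) entries are
#'   removed here.
#' @return a [DrugTargetMap-class] object.
#' @export
DrugTargetMap <- function(targets) {
    targets <- lapply(targets, function(g) unique(toupper(as.character(g))))
    methods::new("DrugTargetMap", targets = targets)
}

#' @describeIn DrugTargetMap number of drugs.
#' @param x a `DrugTargetMap`.
#' @export
setMethod("length", "DrugTargetMap", function(x) length(x@targets))

#' @describeIn DrugTargetMap extract one target set by drug id or position.
#' @param i drug id or index.
#' @export
setMethod("[[", "DrugTargetMap", function(x, i) x@targets[[i]])

#' @describeIn DrugTargetMap compact display.
#' @param object a `DrugTargetMap`.
#' @export
setMethod("show", "DrugTargetMap", function(object) {
    cat(sprintf("DrugTargetMap: %d drugs, %d (drug, gene) annotations\n",
                length(object@targets), sum(lengths(object@targets))))
})

#' SignificantFeatureSet: the outcome of per-cancer-type feature selection
#'
#' Holds the selected feature ids for one cancer type and omics layer, the
#' chosen significance cutoff, the per-cutoff grid evaluations (transcript
#' layer only) and the full per-feature test table.
#'
#' @slot cancerType the target cancer type.
#' @slot omicsLayer `"transcript"` or `"protein"`.
#' @slot featureIds selected feature ids.
#' @slot chosenCutoff the cutoff in force (`NA` when nothing passed any
#'   cutoff).
#' @slot evaluations data.frame with columns `fdr_cutoff`, `subset_size`,
#'   `gini_purity` (empty for the protein layer).
#' @slot stats per-feature data.frame: `feature_id`, `anova_p`, `t_stat`,
#'   `p_raw`, `p_fdr`, `direction`.
#' @aliases SignificantFeatureSet-class
#' @exportClass SignificantFeatureSet
setClass("SignificantFeatureSet",
    representation(cancerType = "character", omicsLayer = "character",
                   featureIds = "character", chosenCutoff = "numeric",
                   evaluations = "data.frame", stats = "data.frame"))

setValidity("SignificantFeatureSet", function(object) {
    msg <- character(0)
    if (!object@omicsLayer %in% c("transcript", "protein"))
        msg <- c(msg, "omicsLayer must be \"transcript\" or \"protein\"")
    if (anyDuplicated(object@featureIds))
        msg <- c(msg, "featureIds must be unique")
    if (length(msg)) msg else TRUE
})

#' @describeIn SignificantFeatureSet compact display.
#' @param object a `SignificantFeatureSet`.
#' @export
setMethod("show", "SignificantFeatureSet", function(object) {
    cat(sprintf("SignificantFeatureSet: %s / %s layer: %d features (cutoff %s)\n",
                object@cancerType, object@omicsLayer,
                length(object@featureIds),
                ifelse(is.na(object@chosenCutoff), "none",
                       format(object@chosenCutoff))))
})

#' SyntheticStudyBundle: a complete generated input set with planted truth
#'
#' Everything a pipeline run needs (transcript and protein matrices, labels,
#' pathways, drug targets, approved pairs, mnAUC values) plus the planted
#' ground truth used by recovery tests.
#'
#' @slot transcripts RPKM-scale [ExpressionMatrix-class].
#' @slot proteins log2-scale [ExpressionMatrix-class].
#' @slot labels named character vector: sample id -> cancer type.
#' @slot pathways [PathwayDB-class].
#' @slot drugTargets [DrugTargetMap-class].
#' @slot approved data.frame with `drug_id`, `cancer_type`.
#' @slot mnauc named numeric vector of mnAUC values per drug.
#' @slot truth list: planted `markers`, `pathways` and `drugs` per class.
#' @slot config the [simConfig] list that produced the bundle.
#' @aliases SyntheticStudyBundle-class
#' @exportClass SyntheticStudyBundle
setClass("SyntheticStudyBundle",
    representation(transcripts = "ExpressionMatrix",
                   proteins = "ExpressionMatrix",
                   labels = "character", pathways = "PathwayDB",
                   drugTargets = "DrugTargetMap", approved = "data.frame",
                   mnauc = "numeric", truth = "list", config = "list"))

setValidity("SyntheticStudyBundle", function(object) {
    msg <- character(0)
    if (!identical(sort(names(object@labels)),
                   sort(colnames(object@transcripts))))
        msg <- c(msg, "labels must cover exactly the transcript samples")
    sym <- geneSymbols(object@transcripts)
    if (!all(rownames(object@proteins) %in% sym[!is.na(sym)]))
        msg <- c(msg, "protein features must be a subset of transcript gene symbols")
    if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticStudyBundle compact display.
#' @param object a `SyntheticStudyBundle`.
#' @export
setMethod("show", "SyntheticStudyBundle", function(object) {
    cat(sprintf(paste0("SyntheticStudyBundle: %d transcripts x %d samples, ",
                       "%d proteins, %d classes, %d pathways, %d drugs\n"),
                nrow(object@transcripts), ncol(object@transcripts),
                nrow(object@proteins), length(unique(object@labels)),
                length(object@pathways), length(object@drugTargets)))
})
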