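#' Accessors for oncopath S4 containers
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an oncopath S4 object.
#' @return `exprValues` the numeric assay matrix; `scaleTag` `"rpkm"` or
#'   `"log2"`; `geneSymbols`/`biotypes` per-feature character vectors (`NA`
#'   where absent); `featureIds` feature identifiers; `geneSets`/`pathwayIds`
#'   the sets and ids of a [PathwayDB-class]; `targetSets`/`drugIds` those of
#'   a [DrugTargetMap-class]; `chosenCutoff`/`cutoffEvaluations`/
#'   `featureStats` components of a [SignificantFeatureSet-class];
#'   `plantedTruth` the ground-truth list of a [SyntheticStudyBundle-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix",
    function(x) SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))
#' @rdname accessors
#' @export
setMethod("scaleTag", "ExpressionMatrix", function(x) x@scaleTag)

#' @rdname accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))
#' @rdname accessors
#' @export
setMethod("geneSymbols", "ExpressionMatrix", function(x)
    stats::setNames(SummarizedExperiment::rowData(x)$gene_symbol, rownames(x)))

#' @rdname accessors
#' @export
setGeneric("biotypes", function(x) standardGeneric("biotypes"))
#' @rdname accessors
#' @export
setMethod("biotypes", "ExpressionMatrix", function(x)
    stats::setNames(SummarizedExperiment::rowData(x)$biotype, rownames(x)))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname accessors
#' @export
setMethod("featureIds", "ExpressionMatrix", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("featureIds", "SignificantFeatureSet", function(x) x@featureIds)

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "PathwayDB", function(x) x@sets)

#' @rdname accessors
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))
#' @rdname accessors
#' @export
setMethod("pathwayIds", "PathwayDB", function(x) names(x@sets))

#' @rdname accessors
#' @export
setGeneric("targetSets", function(x) standardGeneric("targetSets"))
#' @rdname accessors
#' @export
setMethod("targetSets", "DrugTargetMap", function(x) x@targets)

#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' @rdname accessors
#' @export
setMethod("drugIds", "DrugTargetMap", function(x) names(x@targets))

#' @rdname accessors
#' @export
setGeneric("chosenCutoff", function(x) standardGeneric("chosenCutoff"))
#' @rdname accessors
#' @export
setMethod("chosenCutoff", "SignificantFeatureSet", function(x) x@chosenCutoff)

#' @rdname accessors
#' @export
setGeneric("cutoffEvaluations", function(x)
    standardGeneric("cutoffEvaluations"))
#' @rdname accessors
#' @export
setMethod("cutoffEvaluations", "SignificantFeatureSet",
    function(x) x@evaluations)

#' @rdname accessors
#' @export
setGeneric("featureStats", function(x) standardGeneric("featureStats"))
#' @rdname accessors
#' @export
setMethod("featureStats", "SignificantFeatureSet", function(x) x@stats)

#' @rdname accessors
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))
#' @rdname accessors
#' @export
setMethod("plantedTruth", "SyntheticStudyBundle", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("studyLabels", function(x) standardGeneric("studyLabels"))
#' @rdname accessors
#' @export
setMethod("studyLabels", "SyntheticStudyBundle", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("transcriptMatrix", function(x) standardGeneric("transcriptMatrix"))
#' @rdname accessors
#' @export
setMethod("transcriptMatrix", "SyntheticStudyBundle",
    function(x) x@transcripts)

#' @rdname accessors
#' @export
setGeneric("proteinMatrix", function(x) standardGeneric("proteinMatrix"))
#' @rdname accessors
#' @export
setMethod("proteinMatrix", "SyntheticStudyBundle", function(x) x@proteins)

#' @rdname accessors
#' @export
setGeneric("pathwayDB", function(x) standardGeneric("pathwayDB"))
#' @rdname accessors
#' @export
setMethod("pathwayDB", "SyntheticStudyBundle", function(x) x@pathways)

#' @rdname accessors
#' @export
setGeneric("drugTargetMap", function(x) standardGeneric("drugTargetMap"))
#' @rdname accessors
#' @export
setMethod("drugTargetMap", "SyntheticStudyBundle", function(x) x@drugTargets)

#' @rdname accessors
#' @export
setGeneric("approvedPairs", function(x) standardGeneric("approvedPairs"))
#' @rdname accessors
#' @export
setMethod("approvedPairs", "SyntheticStudyBundle", function(x) x@approved)

#' @rdname accessors
#' @export
setGeneric("mnaucValues", function(x) standardGeneric("mnaucValues"))
#' @rdname accessors
#' @export
setMethod("mnaucValues", "SyntheticStudyBundle", function(x) x@mnauc)
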