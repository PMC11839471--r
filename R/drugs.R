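#' Collect genes involved in multiple characteristic pathways
#'
#' Molecular targets involved in at least `minPathways` of a cancer type's
#' characteristic pathways; these multi-pathway genes seed drug candidate
#' identification.
#'
#' @param charPathwayIds character vector of characteristic pathway ids.
#' @param db a [PathwayDB-class].
#' @param minPathways minimum number of characteristic pathways a gene must
#'   appear in (default 2, the smallest reading of "multiple").
#' @return character vector of gene symbols.
#' @export
collectMultiPathwayTargets <- function(charPathwayIds, db, minPathways = 2L) {
    stopifnot(methods::is(db, "PathwayDB"))
    if (minPathways < 1L) stop("minPathways must be at least 1")
    if (!length(charPathwayIds)) return(character(0))
    missing <- setdiff(charPathwayIds, pathwayIds(db))
    if (length(missing))
        stop("unknown pathway ids: ", paste(missing, collapse = ", "))
    counts <- table(unlist(lapply(geneSets(db)[charPathwayIds], unique),
                           use.names = FALSE))
    sort(names(counts)[counts >= minPathways])
}

#' Link drugs to a cancer type through its characteristic pathways
#'
#' A drug qualifies when at least one of its annotated targets lies in the
#' multi-pathway gene set; its linked pathways are then all characteristic
#' pathways containing any of its targets, and drugs touching at least
#' `minPathways` of them are reported, ranked by descending pathway count
#' (ties alphabetical by drug id).
#'
#' @param genes multi-pathway gene set from [collectMultiPathwayTargets()].
#' @param drugs a [DrugTargetMap-class].
#' @param charPathwayIds characteristic pathway ids for the cancer type.
#' @param db a [PathwayDB-class].
#' @param cancerType label copied into the output.
#' @param minPathways minimum pathway count for a candidate.
#' @return data.frame with columns `drug_id`, `cancer_type`, `pathway_count`,
#'   `target_genes_hit`, `linked_pathways` (the last two semicolon-joined).
#' @export
linkDrugs <- function(genes, drugs, charPathwayIds, db,
                      cancerType = NA_character_, minPathways = 2L) {
    stopifnot(methods::is(drugs, "DrugTargetMap"), methods::is(db, "PathwayDB"))
    if (minPathways < 1L) stop("minPathways must be at least 1")
    sets <- geneSets(db)[charPathwayIds]
    rows <- lapply(drugIds(drugs), function(d) {
        tg <- drugs[[d]]
        hit <- intersect(tg, genes)
        if (!length(hit)) return(NULL)
        linked <- charPathwayIds[vapply(sets, function(g)
            any(tg %in% g), logical(1))]
        if (length(linked) < minPathways) return(NULL)
        data.frame(drug_id = d, cancer_type = cancerType,
                   pathway_count = length(linked),
                   target_genes_hit = paste(sort(hit), collapse = ";"),
                   linked_pathways = paste(sort(linked), collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(
        data.frame(drug_id = character(0), cancer_type = character(0),
                   pathway_count = integer(0),
                   target_genes_hit = character(0),
                   linked_pathways = character(0),
                   stringsAsFactors = FALSE))))
    out <- out[order(-out$pathway_count, out$drug_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Flag approved drug--cancer-type pairs among candidates
#'
#' Annotates each candidate with whether the (drug, cancer type) pair is an
#' approved targeted therapy.  Cancer-type strings appearing in the approved
#' table but absent from the known vocabulary are reported with a warning so
#' that vocabulary mismatches never pass silently.
#'
#' @param candidates data.frame from [linkDrugs()].
#' @param approved data.frame with columns `drug_id`, `cancer_type`.
#' @param knownTypes vocabulary of cancer-type labels to check the approved
#'   table against (defaults to those present among the candidates).
#' @return `candidates` with a logical `approved` column appended.
#' @export
flagApproved <- function(candidates, approved,
                         knownTypes = unique(candidates$cancer_type)) {
    stopifnot(all(c("drug_id", "cancer_type") %in% colnames(approved)))
    unmatched <- setdiff(unique(approved$cancer_type), knownTypes)
    if (length(unmatched) && length(knownTypes))
        warning("approved-table cancer types not in the vocabulary: ",
                paste(unmatched, collapse = ", "))
    key <- function(d, t) paste(d, t, sep = "\r")
    candidates$approved <- key(candidates$drug_id, candidates$cancer_type) %in%
        key(approved$drug_id, approved$cancer_type)
    candidates
}
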