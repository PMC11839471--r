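.defaultParams <- function() list(
    anova_alpha = 0.05, protein_alpha = 0.05,
    fdr_grid = 10^seq(-10, -2), min_pathways = 2L,
    bootstrap_reps = 1000L, pseudocount = 1,
    hitrate_pairs = 1000L, hitrate_reps = 100L, seed = 1L,
    label_id_column = "cell_line", label_type_column = "cancer_type")

# Deterministic per-stage substream seeds derived from the global seed, so
# the bootstrap and randomization stages are individually replayable.
.stageSeed <- function(seed, stage)
    (as.integer(seed) + stage * 10007L) %% .Machine$integer.max

.readConfig <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config)) stop("config file not found: ", config)
        config <- yaml::read_yaml(config)
    }
    unknownTop <- setdiff(names(config), c("inputs", "params"))
    if (length(unknownTop))
        stop("unknown config keys: ", paste(unknownTop, collapse = ", "))
    inputKeys <- c("gct", "protein", "labels", "gmt", "drug_targets",
                   "approved", "mnauc")
    unknownIn <- setdiff(names(config$inputs), inputKeys)
    if (length(unknownIn))
        stop("unknown input keys: ", paste(unknownIn, collapse = ", "))
    missingIn <- setdiff(inputKeys, names(config$inputs))
    if (length(missingIn))
        stop("config must name all inputs; missing: ",
             paste(missingIn, collapse = ", "))
    params <- .defaultParams()
    unknownPar <- setdiff(names(config$params), names(params))
    if (length(unknownPar))
        stop("unknown parameter keys: ", paste(unknownPar, collapse = ", "))
    params[names(config$params)] <- config$params
    list(inputs = config$inputs, params = params)
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages in order: read and validate the seven inputs,
#' preprocess the transcript matrix (outlier capping then log2), select
#' significant transcripts and proteins per cancer type, run Fisher + FDR +
#' bootstrap pathway enrichment on both omics layers, intersect into
#' characteristic pathways with combined scores, link drugs through
#' multi-pathway target genes, flag approved pairs, and run the two
#' quantitative validations (mnAUC Wilcoxon comparison of candidate drugs
#' against the remaining drugs, and the randomized hit-rate test).  All
#' randomness derives from a single seed expanded into per-stage substreams,
#' so a rerun with the same config is byte-identical.
#'
#' Cancer types with fewer than 2 labelled samples on either omics layer are
#' skipped with a message.
#'
#' @param config a YAML file path or a list with elements `inputs` (file
#'   paths: `gct`, `protein`, `labels`, `gmt`, `drug_targets`, `approved`,
#'   `mnauc`) and optional `params` (`anova_alpha`, `protein_alpha`,
#'   `fdr_grid`, `min_pathways`, `bootstrap_reps`, `pseudocount`,
#'   `hitrate_pairs`, `hitrate_reps`, `seed`, `label_id_column`,
#'   `label_type_column`).  Unknown keys are rejected.
#' @param outDir output directory; receives `capping_report.tsv`,
#'   `markers.tsv`, `cutoff_evaluations.tsv`, `enrichment.tsv`,
#'   `pathways.tsv`, `candidates.tsv`, `validation.tsv` and
#'   `manifest.json`.
#' @return invisibly, a list with the in-memory stage results (`markers`,
#'   `enrichment`, `pathways`, `candidates`, `validation`, `manifest`).
#' @export
runPipeline <- function(config, outDir) {
    cfg <- .readConfig(config)
    inputs <- cfg$inputs
    params <- cfg$params
    missing <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing))
        stop("missing input file(s): ", paste(missing, collapse = ", "))
    if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
        stop("cannot create output directory: ", outDir)
    tsv <- function(df, name) utils::write.table(
        df, file.path(outDir, name), sep = "\t", quote = FALSE,
        row.names = FALSE)
    logMsg <- function(...) message(sprintf("[oncopath] %s", sprintf(...)))

    logMsg("reading inputs")
    expr <- readGCT(inputs$gct)
    prot <- readProteinMatrix(inputs$protein)
    labels <- readLabels(inputs$labels, idColumn = params$label_id_column,
                         typeColumn = params$label_type_column)
    db <- readGMT(inputs$gmt)
    drugs <- readDrugTargets(inputs$drug_targets)
    approved <- readApprovedPairs(inputs$approved)
    mnauc <- readMnAUC(inputs$mnauc)

    logMsg("preprocessing transcripts (capping + log2)")
    capped <- capOutliers(expr)
    tsv(data.frame(sample_id = names(capped$report$perSampleMax),
                   original_max = unname(capped$report$perSampleMax),
                   calibration_value = capped$report$calibrationValue,
                   n_values_capped = capped$report$nValuesCapped),
        "capping_report.tsv")
    exprLog <- log2Transform(capped$matrix, pseudocount = params$pseudocount)

    tLabels <- alignLabels(exprLog, labels)
    pLabels <- alignLabels(prot, labels)
    okType <- function(lab) names(table(lab))[table(lab) >= 2L]
    types <- sort(intersect(okType(tLabels), okType(pLabels)))
    skipped <- setdiff(sort(unique(c(tLabels, pLabels))), types)
    if (length(skipped))
        logMsg("skipping cancer types with < 2 samples on a layer: %s",
               paste(skipped, collapse = ", "))
    if (length(types) < 2L)
        stop("fewer than 2 usable cancer types")

    tSym <- geneSymbols(exprLog)
    tUniverse <- unique(tSym[!is.na(tSym)])
    pUniverse <- unique(rownames(prot))

    markers <- list(); evals <- list(); enrich <- list(); charPw <- list()
    cands <- list()
    for (i in seq_along(types)) {
        ct <- types[i]
        logMsg("cancer type %s: selecting markers", ct)
        st <- selectTranscripts(exprLog, tLabels, ct, grid = params$fdr_grid,
                                anovaAlpha = params$anova_alpha)
        sp <- selectProteins(prot, pLabels, ct, alpha = params$protein_alpha,
                             anovaAlpha = params$anova_alpha)
        markers[[ct]] <- list(transcript = st, protein = sp)
        ev <- cutoffEvaluations(st)
        if (nrow(ev)) evals[[ct]] <- cbind(cancer_type = ct, ev)

        logMsg("cancer type %s: pathway enrichment (%d transcripts, %d proteins)",
               ct, length(featureIds(st)), length(featureIds(sp)))
        tGenes <- unique(tSym[featureIds(st)])
        tGenes <- tGenes[!is.na(tGenes)]     # symbol-less biotypes excluded
        pGenes <- featureIds(sp)
        et <- enrichWithBootstrap(tGenes, tUniverse, db,
                                  nReps = params$bootstrap_reps,
                                  seed = .stageSeed(params$seed, 2L * i))
        ep <- enrichWithBootstrap(pGenes, pUniverse, db,
                                  nReps = params$bootstrap_reps,
                                  seed = .stageSeed(params$seed, 2L * i + 1L))
        enrich[[ct]] <- rbind(cbind(cancer_type = ct, layer = "transcript", et),
                              cbind(cancer_type = ct, layer = "protein", ep))
        cp <- characteristicPathways(et, ep, cancerType = ct)
        charPw[[ct]] <- cp

        genes <- collectMultiPathwayTargets(cp$pathway_id, db,
                                            minPathways = params$min_pathways)
        cands[[ct]] <- linkDrugs(genes, drugs, cp$pathway_id, db,
                                 cancerType = ct,
                                 minPathways = params$min_pathways)
        logMsg("cancer type %s: %d characteristic pathways, %d drug candidates",
               ct, nrow(cp), nrow(cands[[ct]]))
    }

    markerTab <- do.call(rbind, lapply(types, function(ct)
        do.call(rbind, lapply(c("transcript", "protein"), function(layer) {
            s <- markers[[ct]][[layer]]
            st <- featureStats(s)
            sel <- st[st$feature_id %in% featureIds(s), , drop = FALSE]
            if (!nrow(sel)) return(NULL)
            cbind(cancer_type = ct, layer = layer, sel,
                  chosen_cutoff = chosenCutoff(s))
        }))))
    tsv(markerTab, "markers.tsv")
    tsv(do.call(rbind, evals), "cutoff_evaluations.tsv")
    tsv(do.call(rbind, enrich), "enrichment.tsv")
    pathwayTab <- do.call(rbind, charPw)
    tsv(pathwayTab, "pathways.tsv")
    candTab <- do.call(rbind, cands)
    candTab <- flagApproved(candTab, approved, knownTypes = types)
    tsv(candTab, "candidates.tsv")

    logMsg("validation")
    candDrugs <- unique(candTab$drug_id)
    val <- data.frame()
    if (length(candDrugs) && length(setdiff(names(mnauc), candDrugs))) {
        mn <- compareMnAUC(mnauc[intersect(candDrugs, names(mnauc))],
                           mnauc[setdiff(names(mnauc), candDrugs)])
        val <- rbind(val, data.frame(
            check = "mnauc_wilcoxon",
            statistic = sprintf("mean_cand=%.2f;mean_ref=%.2f",
                                mn$meanCandidates, mn$meanReference),
            p_value = mn$wilcoxonP, n = mn$nCandidates + mn$nReference))
    }
    allPairs <- expand.grid(drug_id = names(mnauc), cancer_type = types,
                            stringsAsFactors = FALSE)
    predicted <- unique(candTab[, c("drug_id", "cancer_type")])
    if (nrow(predicted)) {
        hr <- randomizationHitTest(
            predicted, allPairs, approved,
            nPairs = min(params$hitrate_pairs, nrow(allPairs)),
            nReps = params$hitrate_reps,
            seed = .stageSeed(params$seed, 999L))
        val <- rbind(val, data.frame(
            check = "randomized_hit_rate",
            statistic = sprintf("predicted_rate=%.4f;random_rate=%.4f",
                                hr$predictedHitRate, hr$meanRandomHitRate),
            p_value = hr$fisherP, n = hr$predictedPairs))
    } else hr <- NULL
    tsv(val, "validation.tsv")

    manifest <- list(
        version = as.character(utils::packageVersion("oncopath")),
        seed = params$seed,
        params = params[setdiff(names(params), "fdr_grid")],
        fdr_grid = params$fdr_grid,
        input_md5 = as.list(tools::md5sum(unlist(inputs))),
        row_counts = list(markers = nrow(markerTab),
                          enrichment = sum(vapply(enrich, nrow, integer(1))),
                          pathways = nrow(pathwayTab),
                          candidates = nrow(candTab),
                          validation = nrow(val)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    logMsg("done: outputs in %s", outDir)
    invisible(list(markers = markers, enrichment = enrich,
                   pathways = pathwayTab, candidates = candTab,
                   validation = val, manifest = manifest))
}
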