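#' Configuration for a synthetic multi-omics study
#'
#' Defaults describe the study conditions the package is exercised under:
#' 4 cancer types with 15 cell lines each, 2000 transcripts of which 50 per
#' type are planted markers shifted by 2 log2 units over a within-class
#' noise sd of 0.5, a protein layer covering half of the coding genes, a
#' pathway database where each class has 3 planted pathways drawing 60% of
#' their members from the class's markers, one planted effective drug per
#' class targeting genes shared by several planted pathways, and mnAUC
#' values centred at 0.87 for effective drugs versus 0.96 for the rest.
#'
#' @param nClasses number of cancer types.
#' @param nSamplesPerClass cell lines per cancer type.
#' @param nFeatures total transcript features.
#' @param nMarkersPerClass planted marker transcripts per cancer type.
#' @param effectSizeLog2 log2 shift applied to a marker in its own class.
#' @param noiseSd within-class standard deviation in log2 units.
#' @param codingFraction fraction of features that are protein coding (and
#'   so carry a gene symbol); the rest are symbol-less non-coding biotypes,
#'   exercising the symbol-mapping exclusion path.
#' @param proteinCoverageFraction fraction of coding genes measured on the
#'   protein layer.
#' @param proteinMissingFraction fraction of protein measurements set to
#'   missing (TMT-style missing channels).
#' @param nPathways number of pathways in the database.
#' @param pathwaySize genes per pathway.
#' @param plantedPathwaysPerClass planted pathways per cancer type.
#' @param plantedPathwayMarkerFraction fraction of a planted pathway's genes
#'   drawn from its class's markers.
#' @param nDrugs number of drugs.
#' @param drugTargetsPerDrug target genes per drug.
#' @param mnaucEffectiveMean,mnaucEffectiveSd mnAUC distribution of planted
#'   effective drugs.
#' @param mnaucNullMean,mnaucNullSd mnAUC distribution of the remaining
#'   drugs.
#' @param seed integer seed recorded in the bundle.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(nClasses = 4L, nSamplesPerClass = 15L,
                      nFeatures = 2000L, nMarkersPerClass = 50L,
                      effectSizeLog2 = 2, noiseSd = 0.5,
                      codingFraction = 0.7, proteinCoverageFraction = 0.5,
                      proteinMissingFraction = 0.02,
                      nPathways = 30L, pathwaySize = 40L,
                      plantedPathwaysPerClass = 3L,
                      plantedPathwayMarkerFraction = 0.6,
                      nDrugs = 40L, drugTargetsPerDrug = 5L,
                      mnaucEffectiveMean = 0.87, mnaucEffectiveSd = 0.08,
                      mnaucNullMean = 0.96, mnaucNullSd = 0.08,
                      seed = 1L) {
    cfg <- list(nClasses = as.integer(nClasses),
                nSamplesPerClass = as.integer(nSamplesPerClass),
                nFeatures = as.integer(nFeatures),
                nMarkersPerClass = as.integer(nMarkersPerClass),
                effectSizeLog2 = effectSizeLog2, noiseSd = noiseSd,
                codingFraction = codingFraction,
                proteinCoverageFraction = proteinCoverageFraction,
                proteinMissingFraction = proteinMissingFraction,
                nPathways = as.integer(nPathways),
                pathwaySize = as.integer(pathwaySize),
                plantedPathwaysPerClass = as.integer(plantedPathwaysPerClass),
                plantedPathwayMarkerFraction = plantedPathwayMarkerFraction,
                nDrugs = as.integer(nDrugs),
                drugTargetsPerDrug = as.integer(drugTargetsPerDrug),
                mnaucEffectiveMean = mnaucEffectiveMean,
                mnaucEffectiveSd = mnaucEffectiveSd,
                mnaucNullMean = mnaucNullMean, mnaucNullSd = mnaucNullSd,
                seed = as.integer(seed))
    counts <- c("nClasses", "nSamplesPerClass", "nFeatures",
                "nMarkersPerClass", "nPathways", "pathwaySize",
                "plantedPathwaysPerClass", "nDrugs", "drugTargetsPerDrug")
    if (any(vapply(cfg[counts], function(x) is.na(x) || x < 1L, logical(1))))
        stop("all counts must be at least 1")
    fracs <- c("codingFraction", "proteinCoverageFraction",
               "plantedPathwayMarkerFraction")
    if (any(vapply(cfg[fracs], function(x) x <= 0 || x > 1, logical(1))))
        stop("fractions must lie in (0, 1]")
    if (cfg$proteinMissingFraction < 0 || cfg$proteinMissingFraction >= 1)
        stop("proteinMissingFraction must lie in [0, 1)")
    if (cfg$effectSizeLog2 < 0) stop("effectSizeLog2 must be non-negative")
    if (cfg$noiseSd <= 0) stop("noiseSd must be positive")
    structure(cfg, class = c("SimConfig", "list"))
}

#' Generate a synthetic multi-omics study with planted ground truth
#'
#' Builds every input the pipeline consumes.  Baseline log2 expression per
#' feature is `Normal(mu0, noiseSd)` with feature baselines `mu0 ~
#' Uniform(2, 8)`; planted markers are shifted by `+effectSizeLog2` in their
#' class only.  The transcript matrix is exported on the RPKM scale via
#' `2^x - 1` (floored at 0) so preprocessing is exercised; the protein
#' matrix stays on the log2 scale and covers a random subset of coding
#' genes, with the same planted shifts and a sprinkle of missing values.
#' Planted pathways draw a fixed fraction of their members from the class's
#' markers (so the same markers recur across a class's planted pathways,
#' creating multi-pathway genes); planted effective drugs target genes
#' shared by at least two of their class's planted pathways; mnAUC is drawn
#' lower for planted drugs; the approved table lists the planted
#' drug--class pairs.
#'
#' @param cfg a [simConfig()] list.
#' @return a [SyntheticStudyBundle-class] whose `truth` records planted
#'   `markers` (feature ids), `markerSymbols`, `pathways` and `drugs` per
#'   class.
#' @export
generateStudy <- function(cfg = simConfig()) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    classes <- paste0("cancer_", LETTERS[seq_len(cfg$nClasses)])
    nS <- cfg$nClasses * cfg$nSamplesPerClass
    sampleIds <- paste0("CL_", rep(classes, each = cfg$nSamplesPerClass),
                        "_", sprintf("%02d", seq_len(cfg$nSamplesPerClass)))
    labels <- stats::setNames(rep(classes, each = cfg$nSamplesPerClass),
                              sampleIds)

    nF <- cfg$nFeatures
    featureIds <- sprintf("TR%05d", seq_len(nF))
    nCoding <- max(1L, round(cfg$codingFraction * nF))
    codingIdx <- sort(sample.int(nF, nCoding))
    symbols <- rep(NA_character_, nF)
    symbols[codingIdx] <- sprintf("G%05d", seq_len(nCoding))
    biotype <- rep(NA_character_, nF)
    biotype[codingIdx] <- "protein_coding"
    biotype[-codingIdx] <- sample(c("lincRNA", "pseudogene", "antisense",
                                    "miRNA", "misc_RNA"),
                                  nF - nCoding, replace = TRUE)

    nMark <- cfg$nMarkersPerClass
    if (nMark * cfg$nClasses > nCoding)
        stop("nMarkersPerClass x nClasses exceeds the number of coding features")
    markerPool <- sample(codingIdx, nMark * cfg$nClasses)
    markerIdx <- split(markerPool, rep(classes, each = nMark))

    mu0 <- stats::runif(nF, 2, 8)
    log2mat <- matrix(stats::rnorm(nF * nS, mean = mu0, sd = cfg$noiseSd),
                      nrow = nF, ncol = nS,
                      dimnames = list(featureIds, sampleIds))
    for (cl in classes)
        log2mat[markerIdx[[cl]], labels == cl] <-
            log2mat[markerIdx[[cl]], labels == cl] + cfg$effectSizeLog2
    rpkm <- pmax(2^log2mat - 1, 0)
    transcripts <- ExpressionMatrix(rpkm, scaleTag = "rpkm",
                                    geneSymbols = symbols, biotypes = biotype)

    # protein layer: a coding-gene subset, log2 scale, same planted shifts
    nProt <- max(1L, round(cfg$proteinCoverageFraction * nCoding))
    protFeatIdx <- sort(sample(codingIdx, nProt))
    protSym <- symbols[protFeatIdx]
    protMat <- matrix(stats::rnorm(nProt * nS, mean = mu0[protFeatIdx],
                                   sd = cfg$noiseSd),
                      nrow = nProt, ncol = nS,
                      dimnames = list(protSym, sampleIds))
    for (cl in classes) {
        covered <- protFeatIdx %in% markerIdx[[cl]]
        protMat[covered, labels == cl] <-
            protMat[covered, labels == cl] + cfg$effectSizeLog2
    }
    if (cfg$proteinMissingFraction > 0) {
        nMiss <- round(cfg$proteinMissingFraction * length(protMat))
        protMat[sample.int(length(protMat), nMiss)] <- NA_real_
    }
    proteins <- ExpressionMatrix(protMat, scaleTag = "log2",
                                 geneSymbols = protSym)

    # pathways: planted per class, the remainder random coding gene draws
    codingSym <- symbols[codingIdx]
    markerSym <- lapply(markerIdx, function(i) symbols[i])
    nPlanted <- cfg$plantedPathwaysPerClass * cfg$nClasses
    if (nPlanted > cfg$nPathways)
        stop("plantedPathwaysPerClass x nClasses exceeds nPathways")
    pwIds <- sprintf("PW%03d", seq_len(cfg$nPathways))
    sets <- vector("list", cfg$nPathways)
    names(sets) <- pwIds
    plantedPw <- stats::setNames(vector("list", cfg$nClasses), classes)
    slot <- 1L
    nFromMark <- round(cfg$plantedPathwayMarkerFraction * cfg$pathwaySize)
    nonMarkerSym <- setdiff(codingSym, unlist(markerSym))
    for (cl in classes) {
        for (j in seq_len(cfg$plantedPathwaysPerClass)) {
            mPart <- sample(markerSym[[cl]], min(nFromMark, nMark))
            rPart <- sample(nonMarkerSym, cfg$pathwaySize - length(mPart))
            sets[[slot]] <- unique(c(mPart, rPart))
            plantedPw[[cl]] <- c(plantedPw[[cl]], pwIds[slot])
            slot <- slot + 1L
        }
    }
    for (i in seq(slot, length.out = cfg$nPathways - slot + 1L))
        sets[[i]] <- sample(codingSym, min(cfg$pathwaySize, nCoding))
    pathways <- PathwayDB(sets)

    # drugs: one planted effective drug per class targeting genes shared by
    # at least two of the class's planted pathways
    drugIds <- sprintf("DRUG%03d", seq_len(cfg$nDrugs))
    if (cfg$nClasses > cfg$nDrugs)
        stop("need at least one drug per class")
    plantedDrugIds <- stats::setNames(sample(drugIds, cfg$nClasses), classes)
    targets <- stats::setNames(vector("list", cfg$nDrugs), drugIds)
    for (cl in classes) {
        pw <- lapply(plantedPw[[cl]], function(id) sets[[id]])
        shared <- names(which(table(unlist(lapply(pw, unique))) >= 2L))
        if (!length(shared)) shared <- markerSym[[cl]]
        targets[[plantedDrugIds[[cl]]]] <-
            sample(shared, min(cfg$drugTargetsPerDrug, length(shared)))
    }
    # null drugs target genes outside every planted pathway, so only planted
    # drugs can reach the planted signal
    nullPool <- setdiff(codingSym,
                        unlist(sets[unlist(plantedPw, use.names = FALSE)]))
    if (length(nullPool) < cfg$drugTargetsPerDrug)
        nullPool <- setdiff(codingSym, unlist(markerSym))
    for (d in setdiff(drugIds, plantedDrugIds))
        targets[[d]] <- sample(nullPool, cfg$drugTargetsPerDrug)
    drugTargets <- DrugTargetMap(targets)

    approved <- data.frame(drug_id = unname(plantedDrugIds),
                           cancer_type = classes, stringsAsFactors = FALSE)

    mnauc <- stats::setNames(
        stats::rnorm(cfg$nDrugs, cfg$mnaucNullMean, cfg$mnaucNullSd), drugIds)
    mnauc[plantedDrugIds] <- stats::rnorm(cfg$nClasses,
                                          cfg$mnaucEffectiveMean,
                                          cfg$mnaucEffectiveSd)
    mnauc <- pmin(pmax(mnauc, 0.01), 2)

    truth <- list(
        markers = lapply(markerIdx, function(i) featureIds[i]),
        markerSymbols = markerSym,
        pathways = plantedPw,
        drugs = as.list(plantedDrugIds))

    methods::new("SyntheticStudyBundle", transcripts = transcripts,
                 proteins = proteins, labels = labels, pathways = pathways,
                 drugTargets = drugTargets, approved = approved,
                 mnauc = mnauc, truth = truth, config = unclass(cfg))
}

#' Write a synthetic study bundle to disk
#'
#' Emits `expr.gct` (GCT 1.2, RPKM), `prot.tsv`, `labels.tsv`,
#' `pathways.gmt`, `drug_targets.tsv`, `approved.tsv`, `mnauc.tsv` and
#' `truth.json`, all readable by the package's readers.
#'
#' @param bundle a [SyntheticStudyBundle-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
    stopifnot(methods::is(bundle, "SyntheticStudyBundle"))
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create output directory: ", dir)
    tsv <- function(df, path) utils::write.table(
        df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(expr = file.path(dir, "expr.gct"),
               prot = file.path(dir, "prot.tsv"),
               labels = file.path(dir, "labels.tsv"),
               pathways = file.path(dir, "pathways.gmt"),
               drug_targets = file.path(dir, "drug_targets.tsv"),
               approved = file.path(dir, "approved.tsv"),
               mnauc = file.path(dir, "mnauc.tsv"),
               truth = file.path(dir, "truth.json"))
    writeGCT(bundle@transcripts, paths[["expr"]])
    pv <- exprValues(bundle@proteins)
    tsv(data.frame(protein_id = rownames(pv), pv, check.names = FALSE,
                   stringsAsFactors = FALSE), paths[["prot"]])
    tsv(data.frame(cell_line = names(bundle@labels),
                   cancer_type = unname(bundle@labels),
                   stringsAsFactors = FALSE), paths[["labels"]])
    writeGMT(bundle@pathways, paths[["pathways"]])
    tg <- targetSets(bundle@drugTargets)
    tsv(data.frame(drug_id = rep(names(tg), lengths(tg)),
                   gene_symbol = unlist(tg, use.names = FALSE),
                   stringsAsFactors = FALSE), paths[["drug_targets"]])
    tsv(bundle@approved, paths[["approved"]])
    tsv(data.frame(drug_id = names(bundle@mnauc),
                   mnauc = unname(bundle@mnauc), stringsAsFactors = FALSE),
        paths[["mnauc"]])
    jsonlite::write_json(bundle@truth, paths[["truth"]], auto_unbox = FALSE,
                         pretty = TRUE)
    invisible(paths)
}
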