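test_that("generated study honours the configured shapes and truth counts", {
    cfg <- smallConfig(seed = 4)
    b <- generateStudy(cfg)
    expect_equal(dim(transcriptMatrix(b)), c(600L, 40L))
    expect_length(studyLabels(b), 40)
    expect_length(unique(studyLabels(b)), 4)
    expect_identical(scaleTag(transcriptMatrix(b)), "rpkm")
    expect_identical(scaleTag(proteinMatrix(b)), "log2")
    tr <- plantedTruth(b)
    expect_equal(length(unlist(tr$markers)), 4 * 25)
    expect_equal(length(unlist(tr$pathways)), 4 * cfg$plantedPathwaysPerClass)
    expect_length(pathwayDB(b), cfg$nPathways)
    # protein features are a subset of transcript gene symbols
    sym <- geneSymbols(transcriptMatrix(b))
    expect_true(all(rownames(proteinMatrix(b)) %in% sym[!is.na(sym)]))
    # non-coding features carry a biotype but no symbol
    bt <- biotypes(transcriptMatrix(b))
    expect_true(any(is.na(sym)))
    expect_true(all(bt[is.na(sym)] != "protein_coding"))
    expect_error(generateStudy(smallConfig(nMarkersPerClass = 500)),
                 "exceeds")
})

test_that("planted marker shifts are realized at the configured effect size", {
    cfg <- smallConfig(seed = 12)
    b <- generateStudy(cfg)
    lab <- studyLabels(b)
    lg <- log2(exprValues(transcriptMatrix(b)) + 1)
    tr <- plantedTruth(b)
    tol <- 3 * cfg$noiseSd / sqrt(cfg$nSamplesPerClass)
    for (cl in unique(lab)) {
        mk <- tr$markers[[cl]]
        diff <- rowMeans(lg[mk, lab == cl]) - rowMeans(lg[mk, lab != cl])
        expect_lt(abs(mean(diff) - cfg$effectSizeLog2), tol)
    }
})

test_that("identical seeds give identical bundles and byte-identical files", {
    b1 <- generateStudy(smallConfig(seed = 33))
    b2 <- generateStudy(smallConfig(seed = 33))
    expect_equal(exprValues(transcriptMatrix(b1)),
                 exprValues(transcriptMatrix(b2)))
    expect_identical(geneSets(pathwayDB(b1)), geneSets(pathwayDB(b2)))
    expect_identical(plantedTruth(b1), plantedTruth(b2))
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    f1 <- writeBundle(b1, d1); f2 <- writeBundle(b2, d2)
    for (nm in names(f1))
        expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                         label = nm)
})

test_that("a written bundle reads back through the package's own readers", {
    b <- generateStudy(smallConfig(seed = 8))
    dir <- withr::local_tempdir()
    paths <- writeBundle(b, dir)
    back <- readGCT(paths[["expr"]])
    expect_equal(exprValues(back), exprValues(transcriptMatrix(b)))
    expect_identical(unname(geneSymbols(back)),
                     unname(geneSymbols(transcriptMatrix(b))))
    lab <- readLabels(paths[["labels"]])
    expect_identical(lab, studyLabels(b))
    db <- readGMT(paths[["pathways"]])
    expect_equal(length(readLines(paths[["pathways"]])), 20L)
    expect_identical(geneSets(db), geneSets(pathwayDB(b)))
    dt <- readDrugTargets(paths[["drug_targets"]])
    expect_identical(targetSets(dt)[sort(drugIds(dt))],
                     targetSets(drugTargetMap(b))[sort(drugIds(dt))])
    expect_equal(readMnAUC(paths[["mnauc"]]), mnaucValues(b),
                 tolerance = 1e-10)
    prot <- readProteinMatrix(paths[["prot"]])
    expect_equal(exprValues(prot), exprValues(proteinMatrix(b)),
                 tolerance = 1e-10)
    truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
    expect_equal(sort(unlist(truth$markers)),
                 sort(unlist(plantedTruth(b)$markers)), ignore_attr = TRUE)
})

test_that("config validation rejects out-of-range parameters", {
    expect_error(simConfig(nClasses = 0), "at least 1")
    expect_error(simConfig(codingFraction = 0), "\\(0, 1\\]")
    expect_error(simConfig(effectSizeLog2 = -1), "non-negative")
    expect_error(simConfig(noiseSd = 0), "positive")
})
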