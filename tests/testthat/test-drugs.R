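toyDB <- PathwayDB(list(P1 = c("A", "B", "C"), P2 = c("B", "C", "D"),
                        P3 = c("C", "E")))

test_that("multi-pathway gene collection applies the membership threshold", {
    expect_setequal(collectMultiPathwayTargets(c("P1", "P2", "P3"), toyDB),
                    c("B", "C"))                      # >= 2 pathways
    expect_equal(collectMultiPathwayTargets(c("P1", "P2", "P3"), toyDB,
                                            minPathways = 3L), "C")
    expect_setequal(collectMultiPathwayTargets(c("P1", "P2"), toyDB,
                                               minPathways = 1L),
                    c("A", "B", "C", "D"))            # union at min = 1
    expect_length(collectMultiPathwayTargets(character(0), toyDB), 0)
    expect_error(collectMultiPathwayTargets("P1", toyDB, minPathways = 0),
                 "at least 1")
})

test_that("drug linking counts characteristic pathways hit by any target", {
    drugs <- DrugTargetMap(list(d_c = "C", d_a = "A", d_out = "ZZZ",
                                d_e = c("E", "C")))
    genes <- collectMultiPathwayTargets(c("P1", "P2", "P3"), toyDB)
    out <- linkDrugs(genes, drugs, c("P1", "P2", "P3"), toyDB, "ct")
    # gene C sits in all 3 characteristic pathways
    expect_equal(out$pathway_count[out$drug_id == "d_c"], 3)
    # d_a's only target A is not multi-pathway -> absent; d_out unmapped
    expect_false(any(c("d_a", "d_out") %in% out$drug_id))
    # equal counts are adjacent and alphabetical
    expect_equal(out$drug_id, c("d_c", "d_e"))
    expect_true(all(diff(out$pathway_count) <= 0))
})

test_that("every linked pathway re-derives as characteristic and target-hit", {
    set.seed(101)
    sets <- stats::setNames(lapply(1:12, function(i)
        sample(LETTERS, 6)), sprintf("P%02d", 1:12))
    db <- PathwayDB(sets)
    drugs <- DrugTargetMap(stats::setNames(
        lapply(1:8, function(i) sample(LETTERS, 3)), paste0("d", 1:8)))
    char <- sprintf("P%02d", 1:6)
    genes <- collectMultiPathwayTargets(char, db)
    out <- linkDrugs(genes, drugs, char, db, "ct")
    for (i in seq_len(nrow(out))) {
        linked <- strsplit(out$linked_pathways[i], ";")[[1]]
        expect_true(all(linked %in% char))
        tg <- targetSets(drugs)[[out$drug_id[i]]]
        expect_true(all(vapply(linked, function(pw)
            any(tg %in% db[[pw]]), logical(1))))
    }
    # raising minPathways never adds candidates
    out3 <- linkDrugs(genes, drugs, char, db, "ct", minPathways = 3L)
    expect_true(all(out3$drug_id %in% out$drug_id))
    expect_lte(nrow(out3), nrow(out))
})

test_that("approved flag joins on exact (drug, type) pairs and warns on vocabulary drift", {
    cands <- data.frame(drug_id = c("d1", "d2"), cancer_type = "AML",
                        pathway_count = c(3L, 2L), stringsAsFactors = FALSE)
    approved <- data.frame(drug_id = "d1", cancer_type = "AML")
    out <- flagApproved(cands, approved)
    expect_identical(out$approved, c(TRUE, FALSE))
    none <- flagApproved(cands, approved[0, , drop = FALSE])
    expect_identical(none$approved, c(FALSE, FALSE))
    expect_warning(
        flagApproved(cands, data.frame(drug_id = "d1",
                                       cancer_type = "Leukemia (AML)")),
        "Leukemia")
})
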