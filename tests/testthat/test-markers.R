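test_that("ANOVA screen matches aov on random data and handles degeneracy", {
    set.seed(21)
    n <- c(4, 5, 3)
    lab <- stats::setNames(rep(c("a", "b", "c"), n),
                           sprintf("s%02d", 1:sum(n)))
    v <- matrix(rnorm(20 * sum(n)), 20, sum(n),
                dimnames = list(sprintf("f%02d", 1:20), names(lab)))
    v[3, ] <- 5                               # constant feature
    v[4, lab == "a"] <- v[4, lab == "a"] + 5  # strong planted effect
    v[5, c(1, 6)] <- NA                       # missing values
    m <- tinyExpr(v, scale = "log2")
    scr <- anovaScreen(m, lab)
    for (i in c(1, 2, 4, 5)) {
        keep <- !is.na(v[i, ])
        ref <- summary(aov(v[i, keep] ~ factor(lab[keep])))[[1]][1, "Pr(>F)"]
        expect_equal(scr$anova_p[i], ref, tolerance = 1e-10)
    }
    expect_equal(scr$anova_p[3], 1)      # zero variance -> dropped
    expect_false(scr$retained[3])
    expect_true(scr$retained[4])
    # label-only dependence: permuting sample order leaves p unchanged
    perm <- sample(colnames(v))
    scr2 <- anovaScreen(tinyExpr(v[, perm], scale = "log2"), lab[perm])
    expect_equal(scr2$anova_p, scr$anova_p)
    # a class with < 2 samples is an error naming the class
    expect_error(anovaScreen(m, c(lab[1:11], s12 = "tiny")), "tiny")
})

test_that("one-vs-rest t equals the pooled-variance closed form and t.test", {
    v <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
                dimnames = list("f1", paste0("s", 1:6)))
    lab <- stats::setNames(rep(c("t", "r"), each = 3), paste0("s", 1:6))
    res <- oneVsRestTTest(tinyExpr(v, scale = "log2"), lab, "t")
    expect_equal(abs(res$t_stat), 3.674, tolerance = 1e-3)
    expect_equal(res$p_raw, 0.0213, tolerance = 1e-3)
    expect_identical(res$direction, "down")
    # random matrices with missing values against stats::t.test
    set.seed(31)
    lab2 <- stats::setNames(rep(c("x", "y", "z"), each = 6),
                            sprintf("s%02d", 1:18))
    v2 <- matrix(rnorm(10 * 18), 10, 18,
                 dimnames = list(sprintf("f%02d", 1:10), names(lab2)))
    v2[sample(length(v2), 15)] <- NA
    res2 <- oneVsRestTTest(tinyExpr(v2, scale = "log2"), lab2, "x")
    for (i in 1:10) {
        a <- v2[i, lab2 == "x"]; b <- v2[i, lab2 != "x"]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2 || length(b) < 2) {
            expect_true(is.na(res2$p_raw[i]))
        } else {
            ref <- t.test(a, b, var.equal = TRUE)
            expect_equal(res2$t_stat[i], unname(ref$statistic),
                         tolerance = 1e-10)
            expect_equal(res2$p_raw[i], ref$p.value, tolerance = 1e-10)
        }
    }
    # equal group means and variances -> t = 0, p = 1
    ve <- matrix(c(1, 2, 1, 2), 1, 4,
                 dimnames = list("f1", paste0("s", 1:4)))
    rese <- oneVsRestTTest(tinyExpr(ve, scale = "log2"),
                           stats::setNames(c("t", "t", "r", "r"),
                                           paste0("s", 1:4)), "t")
    expect_equal(rese$t_stat, 0)
    expect_equal(rese$p_raw, 1)
})

test_that("scaling only one group changes the t test, scaling both does not", {
    set.seed(8)
    lab <- stats::setNames(rep(c("t", "r"), each = 5), paste0("s", 1:10))
    v <- matrix(rnorm(10, 5), 1, 10, dimnames = list("f1", names(lab)))
    base <- oneVsRestTTest(tinyExpr(v, scale = "log2"), lab, "t")
    both <- oneVsRestTTest(tinyExpr(2 * v, scale = "log2"), lab, "t")
    expect_equal(both$p_raw, base$p_raw, tolerance = 1e-12)
    one <- v; one[, lab == "t"] <- 2 * one[, lab == "t"]
    oneRes <- oneVsRestTTest(tinyExpr(one, scale = "log2"), lab, "t")
    expect_false(isTRUE(all.equal(oneRes$p_raw, base$p_raw)))
})

test_that("BH adjustment matches the step-up definition", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhAdjust(0.2), 0.2)
    expect_equal(bhAdjust(rep(0.4, 5)), rep(0.4, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    set.seed(13)
    for (i in 1:50) {
        p <- runif(sample(1:20, 1))
        expect_equal(bhAdjust(p), bhOracle(p))
    }
})

test_that("Gini purity: worked values and invariance to relabelling/order", {
    expect_equal(giniPurity(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
    expect_equal(giniPurity(rep(1, 4), c("t", "t", "r", "r")), 0.5)
    expect_equal(giniPurity(rep(1, 4), c("t", "t", "t", "r")), 0.625)
    set.seed(17)
    cl <- sample(1:3, 30, replace = TRUE)
    lb <- sample(c("t", "r"), 30, replace = TRUE)
    g <- giniPurity(cl, lb)
    expect_equal(giniPurity(c("x", "y", "z")[cl], lb), g)  # relabelling
    o <- sample(30)
    expect_equal(giniPurity(cl[o], lb[o]), g)              # sample order
    expect_error(giniPurity(integer(0), character(0)), "empty")
})

test_that("transcript selection evaluates the 9-cutoff grid with monotone subsets", {
    sim <- nullStudyMatrix(300, 8, nClasses = 3, seed = 3)
    v <- exprValues(sim$m)
    v[1:20, sim$labels == "cls1"] <- v[1:20, sim$labels == "cls1"] + 3
    s <- selectTranscripts(tinyExpr(v, scale = "log2"), sim$labels, "cls1")
    ev <- cutoffEvaluations(s)
    expect_equal(nrow(ev), 9L)
    expect_equal(ev$fdr_cutoff, 10^seq(-10, -2))
    expect_true(all(diff(ev$subset_size) >= 0))   # monotone in the cutoff
    expect_true(all(featureIds(s) %in%
        featureStats(s)$feature_id[!is.na(featureStats(s)$p_fdr) &
                                   featureStats(s)$p_fdr < chosenCutoff(s)]))
})

test_that("selection is empty with a warning when nothing passes any cutoff", {
    # constant features carry no signal: the ANOVA screen drops everything
    lab <- stats::setNames(rep(c("cls1", "cls2"), each = 5),
                           sprintf("s%02d", 1:10))
    v <- matrix(rep(1:20, 10), 20, 10,
                dimnames = list(sprintf("f%02d", 1:20), names(lab)))
    m <- tinyExpr(v, scale = "log2")
    expect_warning(s <- selectTranscripts(m, lab, "cls1"),
                   "no transcript passes")
    expect_length(featureIds(s), 0)
    expect_true(is.na(chosenCutoff(s)))
})

test_that("label permutation destroys the purity of selected subsets", {
    sim <- nullStudyMatrix(300, 10, nClasses = 2, seed = 5)
    v <- exprValues(sim$m)
    v[1:25, sim$labels == "cls1"] <- v[1:25, sim$labels == "cls1"] + 2.5
    m <- tinyExpr(v, scale = "log2")
    intact <- selectTranscripts(m, sim$labels, "cls1")
    set.seed(6)
    permLab <- stats::setNames(sample(unname(sim$labels)), names(sim$labels))
    perm <- suppressWarnings(selectTranscripts(m, permLab, "cls1"))
    purity <- function(s) {
        ev <- cutoffEvaluations(s)
        if (all(is.na(ev$gini_purity))) 0 else max(ev$gini_purity, na.rm = TRUE)
    }
    expect_gt(purity(intact), purity(perm))
})

test_that("protein selection applies a strict raw-p threshold", {
    sim <- nullStudyMatrix(400, 15, nClasses = 2, seed = 23)
    v <- exprValues(sim$m)
    v[1:10, sim$labels == "cls1"] <- v[1:10, sim$labels == "cls1"] + 3
    m <- tinyExpr(v, scale = "log2")
    s <- selectProteins(m, sim$labels, "cls1")
    st <- featureStats(s)
    kept <- st$feature_id[st$anova_p < 0.05 & !is.na(st$p_raw) &
                          st$p_raw < 0.05]
    expect_setequal(featureIds(s), kept)     # strict "< 0.05", post-screen
    expect_equal(chosenCutoff(s), 0.05)
    expect_true(all(sprintf("f%04d", 1:10) %in% featureIds(s)))
})
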