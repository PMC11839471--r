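makeUniverse <- function(N) sprintf("G%03d", seq_len(N))

# Build a 1-pathway enrichment problem with exact counts (k of n significant
# genes inside a K-gene pathway, universe size N).
enrichCase <- function(k, K, n, N) {
    u <- makeUniverse(N)
    db <- PathwayDB(list(P = u[seq_len(K)]))
    sig <- c(u[seq_len(k)], u[K + seq_len(n - k)])
    fisherEnrich(sig, u, db)
}

test_that("Fisher enrichment p matches worked values and fisher.test", {
    rec <- enrichCase(5, 5, 5, 10)
    expect_equal(rec$p_fisher, 1 / choose(10, 5), tolerance = 1e-12)
    expect_equal(rec$p_fisher, 0.003968, tolerance = 1e-4)
    expect_equal(enrichCase(0, 5, 5, 10)$p_fisher, 1)   # upper tail at zero
    # independent cross-check against stats::fisher.test (greater)
    for (case in list(c(3, 6, 5, 20), c(2, 4, 8, 15), c(1, 10, 3, 30))) {
        rec <- enrichCase(case[1], case[2], case[3], case[4])
        ft <- fisher.test(matrix(c(case[1], case[2] - case[1],
                                   case[3] - case[1],
                                   case[4] - case[2] - case[3] + case[1]),
                                 2, 2), alternative = "greater")
        expect_equal(rec$p_fisher, ft$p.value, tolerance = 1e-10)
    }
})

test_that("enrichment p is monotone decreasing in the overlap k", {
    for (spec in list(c(8, 10, 25), c(5, 5, 12))) {
        K <- spec[1]; n <- spec[2]; N <- spec[3]
        p <- vapply(0:min(K, n), function(k)
            enrichCase(k, K, n, N)$p_fisher, numeric(1))
        expect_true(all(diff(p) <= 1e-14))
    }
})

test_that("pathways outside the universe are intersected; stray genes error", {
    u <- makeUniverse(20)
    db <- PathwayDB(list(P1 = c(u[1:5], "NOT_MEASURED"), P2 = "ABSENT"))
    rec <- fisherEnrich(u[1:3], u, db)
    expect_equal(rec$pathway_id, "P1")   # P2 has no universe gene -> skipped
    expect_equal(rec$K, 5)
    expect_error(fisherEnrich(c(u[1], "ALIEN"), u, db), "ALIEN")
})

test_that("bootstrap counting estimator: worked value and extremes", {
    reps <- c(rep(1e-6, 5), rep(0.5, 995))
    expect_identical(bootstrapPFromReplicates(1e-4, reps), 0.005)
    expect_identical(bootstrapPFromReplicates(1e-9, reps), 0)
    expect_identical(bootstrapPFromReplicates(0.9, reps), 1)
    expect_error(bootstrapPFromReplicates(0.5, numeric(0)), "replicate")
})

test_that("bootstrap p is seed-reproducible and binomially calibrated", {
    u <- makeUniverse(200)
    pw <- u[1:30]
    obs <- stats::phyper(7, 30, 170, 40, lower.tail = FALSE)  # k_obs = 8
    b1 <- bootstrapPathway(obs, u, pw, nSig = 40, nReps = 500, seed = 99)
    b2 <- bootstrapPathway(obs, u, pw, nSig = 40, nReps = 500, seed = 99)
    expect_identical(b1, b2)
    expect_error(bootstrapPathway(obs, u, pw, 40, nReps = 0), "nReps")
    # exceedance probability is exactly P(k_rep > k_obs) under uniform draws
    q <- stats::phyper(8, 30, 170, 40, lower.tail = FALSE)
    est <- vapply(1:20, function(s)
        bootstrapPathway(obs, u, pw, 40, nReps = 1000, seed = s), numeric(1))
    tol <- 4 * sqrt(q * (1 - q) / 1000)
    expect_true(all(abs(est - q) <= tol))
    expect_lt(abs(mean(est) - q), 4 * sqrt(q * (1 - q) / (1000 * 20)))
})

test_that("combined score averages log10 FDR p-values with a floor at 0", {
    expect_equal(combineScores(1e-4, 1e-4), -4)
    expect_equal(combineScores(1e-2, 1e-6), -4)
    expect_equal(combineScores(1, 1), 0)
    expect_warning(s <- combineScores(0, 1e-2), "floored")
    expect_true(is.finite(s) && s < -150)
    expect_error(suppressWarnings(combineScores(1.5, 0.5)), "\\(0, 1\\]")
})

test_that("characteristic pathways need joint significance; ranked by score", {
    rec <- function(ids, fdr, boot) data.frame(
        pathway_id = ids, k = 1, K = 2, n = 3, N = 10, p_fisher = fdr,
        p_fdr = fdr, p_bootstrap = boot, stringsAsFactors = FALSE)
    t <- rec(c("A", "B", "C"), c(1e-3, 1e-4, 0.2), c(0.001, 0.001, NA))
    p <- rec(c("B", "C", "D"), c(1e-5, 1e-2, 1e-6), c(0.01, 0.01, 0))
    out <- characteristicPathways(t, p, cancerType = "ct")
    expect_equal(out$pathway_id, "B")   # only B is significant in both
    expect_equal(out$score, (log10(1e-4) + log10(1e-5)) / 2)
    # disjoint significant sets -> empty result
    empty <- characteristicPathways(rec("A", 1e-3, 0.001),
                                    rec("B", 1e-3, 0.001))
    expect_equal(nrow(empty), 0)
    # equal scores break ties alphabetically
    t2 <- rec(c("Z", "M"), c(1e-3, 1e-3), c(0, 0))
    p2 <- rec(c("Z", "M"), c(1e-5, 1e-5), c(0, 0))
    expect_equal(characteristicPathways(t2, p2)$pathway_id, c("M", "Z"))
    # a failed bootstrap (p >= 0.05) vetoes an otherwise significant pathway
    t3 <- rec("A", 1e-4, 0.2)
    expect_equal(nrow(characteristicPathways(t3, rec("A", 1e-4, 0))), 0)
})

test_that("null significant sets do not inflate the pathway FDR", {
    set.seed(77)
    u <- makeUniverse(400)
    db <- PathwayDB(stats::setNames(
        lapply(1:40, function(i) sample(u, 25)), sprintf("P%02d", 1:40)))
    frac <- vapply(1:30, function(i) {
        sig <- sample(u, 30)
        mean(fisherEnrich(sig, u, db)$p_fdr < 0.05)
    }, numeric(1))
    expect_lte(mean(frac), 0.05 + 2.58 * sqrt(0.05 * 0.95 / (30 * 40)))
})
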