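test_that("LOOCV evaluates exactly the pairs whose endpoints keep a link", {
    net <- toyNetwork()
    cv <- loocv(net, "lpbni")
    # of the 6 edges only (l1,p1) and (l2,p1) leave both endpoints with a
    # remaining link when withheld
    rec <- cvRecords(cv)
    expect_equal(nrow(rec), 2)
    expect_setequal(rec$query, c("l1", "l2"))
    expect_true(all(rec$heldOut == "p1"))
    expect_equal(nrow(cvSkipped(cv)), 4)
    # withheld pair absent from its training fold, and net is untouched
    expect_equal(nEdges(net), 6)
    expect_identical(adjacencyMatrix(net), adjacencyMatrix(toyNetwork()))
})

test_that("duplicate interaction profiles are recovered at rank 1", {
    # la and lb share an identical protein set; p4 is reachable only
    # through lc, so it never outscores the twin-supported protein
    edges <- data.frame(
        l = c("la", "la", "la", "lb", "lb", "lb", "lc", "lc"),
        p = c("p1", "p2", "p3", "p1", "p2", "p3", "p1", "p4"))
    net <- buildNetwork(edges)
    cv <- loocv(net, "lpbni")
    twins <- cvRecords(cv)[cvRecords(cv)$query %in% c("la", "lb"), ]
    expect_gt(nrow(twins), 0)
    expect_true(all(twins$rank == 1))
})

test_that("rank tie rules: pessimistic worst case vs mean mid-range", {
    cand <- c(a = 1, b = 1, c = 1, d = 1, e = 1)
    expect_equal(lpbni:::.rankAmong(cand, 1, "pessimistic"), 5)
    expect_equal(lpbni:::.rankAmong(cand, 1, "mean"), 3)   # (N+1)/2
    expect_equal(lpbni:::.rankAmong(c(2, 2, 1, 0), 1, "pessimistic"), 3)
    expect_equal(lpbni:::.rankAmong(c(2, 2, 1, 0), 1, "mean"), 3)
})

test_that("k-fold CV is seeded, deterministic, and validates k", {
    A <- randomAdjacency(8, 14, 0.3, 99)
    net <- asNetwork(A)
    cv1 <- kfoldCV(net, "lpbni", k = 5, seed = 7)
    cv2 <- kfoldCV(net, "lpbni", k = 5, seed = 7)
    expect_identical(cvRecords(cv1), cvRecords(cv2))
    cv3 <- kfoldCV(net, "lpbni", k = 5, seed = 8)
    expect_false(identical(cvRecords(cv1), cvRecords(cv3)))
    expect_error(kfoldCV(net, "lpbni", k = 1), "k must be >= 2")
    expect_error(kfoldCV(net, "lpbni", k = nEdges(net) + 1),
        "exceeds edge count")
})

test_that("k = nEdges jackknife reduces to LOOCV up to skip rules", {
    A <- randomAdjacency(6, 9, 0.4, 5)
    net <- asNetwork(A)
    jk <- cvRecords(kfoldCV(net, "lpbni", k = nEdges(net), seed = 1))
    lo <- cvRecords(loocv(net, "lpbni"))
    key <- function(d) {
        d <- d[order(d$query, d$heldOut), c("query", "heldOut", "score",
            "rank", "nCandidates")]
        rownames(d) <- NULL
        d
    }
    expect_equal(key(jk), key(lo), tolerance = 1e-12)
})

test_that("ROC/AUC: worked examples and tie conventions", {
    expect_equal(rocAuc(c(0.9, 0.8), c(0.7, 0.85))$auc, 0.75)
    expect_equal(rocAuc(c(5, 6, 7), c(1, 2, 3))$auc, 1.0)
    expect_warning(res <- rocAuc(rep(1, 4), rep(1, 6)),
        "identical")
    expect_equal(res$auc, 0.5)
    roc <- rocAuc(c(0.9, 0.8), c(0.7, 0.85))$roc
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("AUC equals the brute-force Mann-Whitney count, pROC agreeing", {
    skip_if_not_installed("pROC")
    for (seed in 1:6) {
        set.seed(seed + 400)
        # coarse grid forces plenty of ties
        pos <- sample(seq(0, 1, 0.1), 40, replace = TRUE)
        neg <- sample(seq(0, 1, 0.1), 100, replace = TRUE)
        auc <- rocAuc(pos, neg)$auc
        expect_equal(auc, oracleAUC(pos, neg), tolerance = 1e-12)
        pr <- pROC::roc(response = c(rep(1, 40), rep(0, 100)),
            predictor = c(pos, neg), quiet = TRUE, direction = "<")
        expect_equal(auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    }
})

test_that("random scores give a null AUC of one half", {
    set.seed(2026)
    pos <- runif(2000)
    neg <- runif(8000)
    expect_equal(rocAuc(pos, neg)$auc, 0.5, tolerance = 0.02)
})

test_that("fixed-specificity metrics reproduce hand confusion tables", {
    # perfectly separating scorer
    m <- metricsAtSpecificity(c(5, 6), c(1, 2, 3), specificity = 0.99)
    expect_equal(m$sensitivity, 1)
    expect_equal(m$precision, 1)
    expect_equal(m$mcc, 1)
    # TP=2 FP=1 TN=9 FN=0: MCC = 18/sqrt(3*2*10*9)
    m2 <- metricsAtSpecificity(c(5, 4), c(4.5, rep(1, 9)),
        specificity = 0.9)
    expect_equal(m2$sensitivity, 1)
    expect_equal(m2$accuracy, 11 / 12)
    expect_equal(m2$precision, 2 / 3)
    expect_equal(m2$mcc, 18 / sqrt(3 * 2 * 10 * 9), tolerance = 1e-12)
    expect_equal(m2$mcc, 0.7746, tolerance = 1e-4)
    expect_error(metricsAtSpecificity(c(1, 2), specificity = 0.95,
        negatives = numeric(0)), "negatives")
})

test_that("null sensitivity at 95% specificity is about 5%", {
    set.seed(31)
    pos <- runif(4000)
    neg <- runif(4000)
    m <- metricsAtSpecificity(pos, specificity = 0.95, negatives = neg)
    expect_lt(abs(m$sensitivity - 0.05), 0.015)
})

test_that("fold enrichment reproduces (N/2)/n arithmetic", {
    expect_equal(foldEnrichment(manualCV(ranks = 13, nCandidates = 26)), 1)
    expect_equal(foldEnrichment(manualCV(ranks = 2, nCandidates = 20)), 5)
    expect_equal(foldEnrichment(manualCV(ranks = c(13, 2),
        nCandidates = c(26, 20))), 3)
    # always-rank-1 scorer: mean over records of N/2
    cv <- manualCV(ranks = c(1, 1, 1), nCandidates = c(10, 20, 30))
    expect_equal(foldEnrichment(cv), mean(c(10, 20, 30) / 2))
})

test_that("percentile recovery counts and monotonicity", {
    cv <- manualCV(ranks = c(1, 3, 10, 18), nCandidates = rep(20, 4))
    rec <- percentileRecovery(cv, c(5, 10, 15, 20, 50, 100))
    # ceil(x% of 20): 1, 2, 3, 4, 10, 20
    expect_equal(rec$count, c(1, 1, 2, 2, 3, 4))
    expect_true(all(diff(rec$count) >= 0))
    expect_equal(rec$count[rec$percentile == 100],
        nrow(cvRecords(cv)))
    expect_error(percentileRecovery(cv, c(0, 50)), "percentiles")
    expect_error(percentileRecovery(cv, 101), "percentiles")
    # always-rank-1 scorer recovers everything at every percentile
    cv1 <- manualCV(ranks = rep(1, 5), nCandidates = rep(8, 5))
    expect_true(all(percentileRecovery(cv1)$count == 5))
})

test_that("uniform-random ranks recover about x percent of records", {
    set.seed(77)
    N <- 40
    ranks <- sample.int(N, 4000, replace = TRUE)
    cv <- manualCV(ranks = ranks, nCandidates = rep(N, 4000))
    rec <- percentileRecovery(cv, c(10, 50))
    expect_equal(rec$count / 4000, c(0.1, 0.5), tolerance = 0.03)
})

test_that("evaluateCV bundles a coherent metric report", {
    A <- randomAdjacency(8, 16, 0.35, 12)
    net <- asNetwork(A)
    cv <- loocv(net, "lpbni")
    rep <- evaluateCV(cv, specificities = 0.9, percentiles = c(10, 50))
    expect_s4_class(rep, "MetricReport")
    expect_gte(rep@auc, 0)
    expect_lte(rep@auc, 1)
    expect_equal(rep@auc, rocAuc(cv)$auc)
    expect_equal(rep@foldEnrichment, foldEnrichment(cv))
    expect_true(all(rep@thresholdMetrics$mcc >= -1 &
        rep@thresholdMetrics$mcc <= 1))
    # AUC recomputed from the stored ROC by trapezoid agrees with the slot
    roc <- rep@roc
    expect_equal(sum(diff(roc$fpr) * (head(roc$tpr, -1) +
        tail(roc$tpr, -1)) / 2), rep@auc, tolerance = 1e-12)
})
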