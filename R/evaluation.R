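# Cross-validation harness and ranking metrics.

# competition ranking of the held-out score among candidate scores
# (candidates include the held-out protein itself).
# pessimistic: every tie counts against the held-out pair (worst case);
# mean: ties share their average rank.
.rankAmong <- function(candScores, heldScore, ties) {
    greater <- sum(candScores > heldScore)
    equal <- sum(candScores == heldScore)   # >= 1: includes itself
    if (ties == "pessimistic") greater + equal
    else greater + (equal + 1) / 2
}

# evaluate one held-out pair on a training adjacency; returns NULL when the
# scorer fails (caller logs it)
.scoreFold <- function(trainA, query, heldOut, kernel, params, ties, fold) {
    s <- kernel(trainA, query, params)
    names(s) <- rownames(trainA)
    cand <- which(trainA[, query] == 0)
    candScores <- s[cand]
    heldScore <- unname(candScores[heldOut])
    list(
        record = data.frame(query = query, heldOut = heldOut,
            score = heldScore,
            rank = .rankAmong(candScores, heldScore, ties),
            nCandidates = length(cand), fold = fold,
            stringsAsFactors = FALSE),
        negatives = unname(candScores[names(candScores) != heldOut])
    )
}

.emptySkip <- function() data.frame(query = character(),
    heldOut = character(), reason = character(), stringsAsFactors = FALSE)

.assembleCV <- function(recs, negs, skipped, method, mode) {
    records <- if (length(recs)) do.call(rbind, recs) else
        data.frame(query = character(), heldOut = character(),
            score = numeric(), rank = numeric(), nCandidates = integer(),
            fold = integer(), stringsAsFactors = FALSE)
    rownames(records) <- NULL
    new("CVResult", records = records, negatives = negs,
        skipped = skipped, method = method, mode = mode)
}

#' Leave-one-out cross-validation of a network scorer
#'
#' Withholds each known interaction in turn, zeroes it in the adjacency,
#' reruns the scorer from scratch on the training network (the propagation
#' matrix is recomputed for every fold), and records the rank of the
#' withheld protein among the candidate proteins — those not linked to the
#' query lncRNA in the training fold, the withheld one included. Pairs whose
#' removal would leave either endpoint with no training link are skipped and
#' logged: no information can propagate through a node with fewer than two
#' links, so such pairs are not evaluated. Run [filterMinDegree()] with
#' `minLinks = 2` first to restrict the gold standard to evaluable pairs.
#'
#' @param net a [BipartiteNetwork-class]
#' @param method scorer name: "lpbni", "procf" or "rwr"
#' @param params named list of scorer options (`restart`, `tol`, `maxIter`
#'   for rwr; `sqrtSimilarity` for procf)
#' @param ties rank tie rule: "pessimistic" (competition ranking, ties count
#'   against the withheld pair; default) or "mean" (ties share their average
#'   rank)
#' @param maxFailFrac abort when more than this fraction of folds error
#'   (default 0.1); individual failures are logged and skipped.
#' @return a [CVResult-class]
#' @seealso [kfoldCV()], [evaluateCV()]
#' @export
loocv <- function(net, method = c("lpbni", "procf", "rwr"),
                  params = list(), ties = c("pessimistic", "mean"),
                  maxFailFrac = 0.1) {
    method <- match.arg(method)
    ties <- match.arg(ties)
    stopifnot(is(net, "BipartiteNetwork"))
    kernel <- .scorerKernel(method)
    A <- adjacencyMatrix(net)
    dp <- rowSums(A)
    dl <- colSums(A)
    idx <- which(A == 1, arr.ind = TRUE)
    recs <- list()
    negs <- list()
    skipped <- .emptySkip()
    nFail <- 0L
    for (f in seq_len(nrow(idx))) {
        i <- idx[f, "row"]
        j <- idx[f, "col"]
        prot <- rownames(A)[i]
        lnc <- colnames(A)[j]
        if (dp[i] < 2 || dl[j] < 2) {
            skipped <- rbind(skipped, data.frame(query = lnc,
                heldOut = prot, reason = "endpoint would lose last link",
                stringsAsFactors = FALSE))
            next
        }
        trainA <- A
        trainA[i, j] <- 0
        res <- tryCatch(
            .scoreFold(trainA, lnc, prot, kernel, params, ties, f),
            error = function(e) conditionMessage(e))
        if (is.character(res)) {
            nFail <- nFail + 1L
            skipped <- rbind(skipped, data.frame(query = lnc,
                heldOut = prot, reason = paste("scorer failed:", res),
                stringsAsFactors = FALSE))
            next
        }
        recs[[length(recs) + 1L]] <- res$record
        negs[[length(negs) + 1L]] <- res$negatives
    }
    if (nrow(idx) > 0 && nFail / nrow(idx) > maxFailFrac)
        stop("scorer failed on ", nFail, " of ", nrow(idx), " folds")
    .assembleCV(recs, negs, skipped, method, "loocv")
}

# run `code` under a seeded RNG without disturbing the caller's stream
.withSeed <- function(seed, code) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env))
    set.seed(seed)
    code
}

#' k-fold cross-validation of a network scorer
#'
#' Partitions the known interactions uniformly at random into `k` folds
#' (seeded, reproducible), zeroes each fold's edges together, and evaluates
#' each withheld pair as in [loocv()]. Nodes that lose all training links
#' when a fold is removed cannot receive or propagate information, so
#' withheld pairs touching them are skipped and logged rather than scored.
#'
#' @inheritParams loocv
#' @param k number of folds (>= 2, at most the edge count); `k = nEdges(net)`
#'   reduces to leave-one-out.
#' @param seed RNG seed for the partition (default 0)
#' @return a [CVResult-class]
#' @export
kfoldCV <- function(net, method = c("lpbni", "procf", "rwr"), k = 10,
                    seed = 0, params = list(),
                    ties = c("pessimistic", "mean"), maxFailFrac = 0.1) {
    method <- match.arg(method)
    ties <- match.arg(ties)
    stopifnot(is(net, "BipartiteNetwork"))
    A <- adjacencyMatrix(net)
    idx <- which(A == 1, arr.ind = TRUE)
    nE <- nrow(idx)
    if (k < 2) stop("k must be >= 2")
    if (k > nE) stop("k (", k, ") exceeds edge count (", nE, ")")
    kernel <- .scorerKernel(method)
    folds <- .withSeed(seed, sample(rep_len(seq_len(k), nE)))
    recs <- list()
    negs <- list()
    skipped <- .emptySkip()
    nFail <- 0L
    for (fold in seq_len(k)) {
        inFold <- which(folds == fold)
        trainA <- A
        trainA[idx[inFold, , drop = FALSE]] <- 0
        keepP <- rowSums(trainA) > 0
        keepL <- colSums(trainA) > 0
        subA <- trainA[keepP, keepL, drop = FALSE]
        for (f in inFold) {
            prot <- rownames(A)[idx[f, "row"]]
            lnc <- colnames(A)[idx[f, "col"]]
            if (!keepP[idx[f, "row"]] || !keepL[idx[f, "col"]]) {
                skipped <- rbind(skipped, data.frame(query = lnc,
                    heldOut = prot,
                    reason = "endpoint has no training links",
                    stringsAsFactors = FALSE))
                next
            }
            res <- tryCatch(
                .scoreFold(subA, lnc, prot, kernel, params, ties, fold),
                error = function(e) conditionMessage(e))
            if (is.character(res)) {
                nFail <- nFail + 1L
                skipped <- rbind(skipped, data.frame(query = lnc,
                    heldOut = prot,
                    reason = paste("scorer failed:", res),
                    stringsAsFactors = FALSE))
                next
            }
            recs[[length(recs) + 1L]] <- res$record
            negs[[length(negs) + 1L]] <- res$negatives
        }
    }
    if (nE > 0 && nFail / nE > maxFailFrac)
        stop("scorer failed on ", nFail, " of ", nE, " folds")
    .assembleCV(recs, negs, skipped, method, "kfold")
}

.pooledScores <- function(x, negatives) {
    if (is(x, "CVResult")) {
        list(pos = x@records$score, neg = unlist(x@negatives))
    } else {
        if (is.null(negatives))
            stop("negatives required when positives are given as a vector")
        list(pos = as.numeric(x), neg = as.numeric(negatives))
    }
}

#' Pooled ROC curve and AUC
#'
#' Pools withheld-pair scores as positives and all candidate-protein scores
#' (per fold) as negatives, sweeps a threshold over the pooled score set,
#' and reports (FPR, TPR) points plus the trapezoidal area under the curve.
#' Because each distinct score contributes one ROC vertex, the trapezoid
#' rule handles ties by the midpoint convention, making the AUC identical to
#' the normalized Mann-Whitney statistic (ties counted 1/2).
#'
#' @param x a [CVResult-class], or a numeric vector of positive scores
#' @param negatives numeric vector of negative scores (only when `x` is a
#'   vector)
#' @return list with elements `auc` (scalar) and `roc` (data.frame with
#'   columns `threshold`, `fpr`, `tpr`)
#' @export
rocAuc <- function(x, negatives = NULL) {
    p <- .pooledScores(x, negatives)
    if (length(p$pos) == 0L || length(p$neg) == 0L)
        stop("need at least one positive and one negative score")
    thr <- sort(unique(c(p$pos, p$neg)), decreasing = TRUE)
    tpr <- vapply(thr, function(t) mean(p$pos >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(p$neg >= t), numeric(1))
    roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
        tpr = c(0, tpr))
    if (length(thr) == 1L)
        warning("all pooled scores identical; AUC is 0.5 by convention")
    auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
        utils::tail(roc$tpr, -1)) / 2)
    list(auc = auc, roc = roc)
}

#' Confusion-table metrics at a fixed specificity
#'
#' Sweeps the pooled scores for the most sensitive threshold whose pooled
#' false-positive rate stays within `1 - specificity`, then reports the
#' confusion-table summaries at that threshold: sensitivity
#' `Sn = TP/(TP+FN)`, accuracy `Acc = (TP+TN)/total`, precision
#' `Pre = TP/(TP+FP)`, and the Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as
#' 0 when any factor of the denominator vanishes. A score >= threshold
#' counts as a predicted interaction.
#'
#' @inheritParams rocAuc
#' @param specificity target specificity (e.g. 0.99 or 0.95); may be a
#'   vector.
#' @return data.frame with one row per requested specificity: `specificity`,
#'   `threshold`, `sensitivity`, `accuracy`, `precision`, `mcc`
#' @export
metricsAtSpecificity <- function(x, specificity, negatives = NULL) {
    p <- .pooledScores(x, negatives)
    if (length(p$neg) == 0L)
        stop("pooled negatives are empty; no specificity is measurable")
    stopifnot(all(specificity > 0 & specificity <= 1))
    thr <- sort(unique(c(p$pos, p$neg)))
    fp <- vapply(thr, function(t) sum(p$neg >= t), numeric(1))
    tp <- vapply(thr, function(t) sum(p$pos >= t), numeric(1))
    out <- lapply(specificity, function(sp) {
        # small epsilon so binary representation of 1 - sp cannot exclude
        # a threshold that meets the target exactly (e.g. FPR 0.1 at 0.9)
        ok <- fp / length(p$neg) <= 1 - sp + 1e-12
        if (!any(ok)) {   # every finite threshold admits too many FP
            t0 <- Inf
            TP <- 0; FP <- 0
        } else {
            # most sensitive feasible threshold; among TP ties, take the
            # largest threshold (fewest false positives)
            cand <- which(ok)
            best <- cand[max(which(tp[cand] == max(tp[cand])))]
            t0 <- thr[best]
            TP <- tp[best]; FP <- fp[best]
        }
        FN <- length(p$pos) - TP
        TN <- length(p$neg) - FP
        den2 <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
        data.frame(specificity = sp, threshold = t0,
            sensitivity = TP / (TP + FN),
            accuracy = (TP + TN) / (TP + TN + FP + FN),
            precision = if (TP + FP > 0) TP / (TP + FP) else 0,
            mcc = if (den2 > 0) (TP * TN - FP * FN) / sqrt(den2) else 0)
    })
    do.call(rbind, out)
}

#' Mean fold enrichment of withheld-pair ranks
#'
#' Per evaluated pair the enrichment is `(N/2)/n`: how much better than the
#' median the withheld protein's rank `n` is among its `N` candidate
#' proteins. A scorer ranking every withheld pair exactly mid-list scores
#' 1; random ranking averages slightly above 1 because `E[1/n] > 1/E[n]`.
#'
#' @param cv a [CVResult-class]
#' @return mean enrichment over all records
#' @export
foldEnrichment <- function(cv) {
    stopifnot(is(cv, "CVResult"))
    r <- cv@records
    if (nrow(r) == 0L) stop("no cross-validation records")
    mean((r$nCandidates / 2) / r$rank)
}

#' Recovery counts at rank percentiles
#'
#' For each percentile `x`, counts the withheld interactions recovered
#' within the top `x`% of their per-query candidate list, i.e. records with
#' rank `n <= ceiling(x/100 * N)`. Counts are nondecreasing in `x`.
#'
#' @param cv a [CVResult-class]
#' @param percentiles numeric vector in (0, 100]
#' @return data.frame with columns `percentile`, `count`
#' @export
percentileRecovery <- function(cv, percentiles = c(5, 10, 15, 20, 50)) {
    stopifnot(is(cv, "CVResult"))
    if (any(percentiles <= 0 | percentiles > 100))
        stop("percentiles must lie in (0, 100]")
    r <- cv@records
    if (nrow(r) == 0L) stop("no cross-validation records")
    counts <- vapply(percentiles, function(x)
        sum(r$rank <= ceiling(x / 100 * r$nCandidates)), numeric(1))
    data.frame(percentile = percentiles, count = counts)
}

#' Full metric report for a cross-validation run
#'
#' Combines [rocAuc()], [metricsAtSpecificity()], [foldEnrichment()] and
#' [percentileRecovery()] into a single [MetricReport-class].
#'
#' @param cv a [CVResult-class]
#' @param specificities specificity targets for the confusion metrics
#' @param percentiles recovery percentiles in (0, 100]
#' @return a [MetricReport-class]
#' @export
evaluateCV <- function(cv, specificities = c(0.99, 0.95),
                       percentiles = c(5, 10, 15, 20, 50)) {
    stopifnot(is(cv, "CVResult"))
    ra <- rocAuc(cv)
    new("MetricReport",
        auc = ra$auc,
        roc = ra$roc,
        thresholdMetrics = metricsAtSpecificity(cv, specificities),
        foldEnrichment = foldEnrichment(cv),
        recovery = percentileRecovery(cv, percentiles))
}

#' AUC for recovering a held-out edge set
#'
#' Scores every (protein, lncRNA) pair of a training network with the
#' chosen scorer, takes the scores of the supplied held-out pairs as
#' positives and the scores of all remaining non-edges as negatives, and
#' returns the pooled AUC. This is the natural figure of merit for the
#' planted test edges produced by [simulateNetwork()].
#'
#' @inheritParams loocv
#' @param heldOut data.frame with columns `lncRNA` and `protein`; every
#'   identifier must exist in `net` and no pair may be a training edge.
#' @return list with `auc`, plus the pooled `positives` and `negatives`
#'   score vectors for downstream use (e.g. permutation nulls)
#' @export
heldOutAUC <- function(net, heldOut, method = c("lpbni", "procf", "rwr"),
                       params = list()) {
    method <- match.arg(method)
    stopifnot(is(net, "BipartiteNetwork"),
        all(c("lncRNA", "protein") %in% names(heldOut)))
    A <- adjacencyMatrix(net)
    i <- match(heldOut$protein, rownames(A))
    j <- match(heldOut$lncRNA, colnames(A))
    if (anyNA(i) || anyNA(j))
        stop("held-out pair references a node absent from the network")
    S <- scoreMatrix(net, method, params)
    posIdx <- cbind(i, j)
    if (any(A[posIdx] == 1))
        stop("held-out pair is present as a training edge")
    negMask <- A == 0
    negMask[posIdx] <- FALSE
    pos <- S[posIdx]
    neg <- S[negMask]
    c(rocAuc(pos, neg)["auc"], list(positives = pos, negatives = neg))
}
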