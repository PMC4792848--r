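# Independent oracles and fixture generators for the test suite. These
# deliberately use naive nested loops / direct linear algebra so they share
# no code path with the package implementations they check.

# w_ik = (1/d(p_k)) * sum_j a_ij a_kj / d(l_j), by triple loop
oracleW <- function(A) {
    m <- nrow(A)
    n <- ncol(A)
    dp <- rowSums(A)
    dl <- colSums(A)
    W <- matrix(0, m, m, dimnames = list(rownames(A), rownames(A)))
    for (i in seq_len(m)) for (k in seq_len(m)) {
        acc <- 0
        for (j in seq_len(n)) acc <- acc + A[i, j] * A[k, j] / dl[j]
        W[i, k] <- acc / dp[k]
    }
    W
}

# two-step propagation by explicit double summation
oracleLpbni <- function(A, s0) {
    m <- nrow(A)
    n <- ncol(A)
    dp <- rowSums(A)
    dl <- colSums(A)
    sL <- numeric(n)
    for (j in seq_len(n)) for (i in seq_len(m))
        sL[j] <- sL[j] + A[i, j] * s0[i] / dp[i]
    sF <- numeric(m)
    for (i in seq_len(m)) for (j in seq_len(n))
        sF[i] <- sF[i] + A[i, j] * sL[j] / dl[j]
    sF
}

# ProCF by pairwise loops over the printed formula
oracleProcf <- function(A, j, useSqrt = TRUE) {
    m <- nrow(A)
    sim <- function(i, k) {
        shared <- sum(A[i, ] * A[k, ])
        d <- if (useSqrt) sqrt(sum(A[i, ]) * sum(A[k, ]))
             else sum(A[i, ]) * sum(A[k, ])
        if (d == 0) 0 else shared / d
    }
    s <- numeric(m)
    for (i in seq_len(m)) {
        num <- 0
        den <- 0
        for (k in seq_len(m)[-i]) {
            num <- num + sim(i, k) * A[k, j]
            den <- den + sim(i, k)
        }
        s[i] <- if (den > 0) num / den else 0
    }
    s
}

# RWR stationary vector by direct linear solve of p = (1-r) M p + r e
oracleRwr <- function(A, queryIdx, r) {
    m <- nrow(A)
    n <- ncol(A)
    B <- rbind(cbind(matrix(0, m, m), A), cbind(t(A), matrix(0, n, n)))
    M <- sweep(B, 2L, colSums(B), "/")
    e <- numeric(m + n)
    e[m + queryIdx] <- 1
    p <- solve(diag(m + n) - (1 - r) * M, r * e)
    unname(p[seq_len(m)])
}

# AUC as the normalized Mann-Whitney pair count, ties counted 1/2
oracleAUC <- function(pos, neg) {
    wins <- 0
    for (p in pos) for (q in neg)
        wins <- wins + (p > q) + 0.5 * (p == q)
    wins / (length(pos) * length(neg))
}

# random bipartite adjacency with guaranteed min degree 1, independent of
# the package's simulator
randomAdjacency <- function(m, n, p = 0.3, seed = 1) {
    set.seed(seed)
    A <- matrix(rbinom(m * n, 1, p), m, n)
    for (i in which(rowSums(A) == 0)) A[i, sample.int(n, 1)] <- 1
    for (j in which(colSums(A) == 0)) A[sample.int(m, 1), j] <- 1
    rownames(A) <- sprintf("P%03d", seq_len(m))
    colnames(A) <- sprintf("L%03d", seq_len(n))
    A
}

# wrap a raw adjacency as a BipartiteNetwork through the public constructor
asNetwork <- function(A) {
    idx <- which(A == 1, arr.ind = TRUE)
    buildNetwork(data.frame(lncRNA = colnames(A)[idx[, "col"]],
        protein = rownames(A)[idx[, "row"]], stringsAsFactors = FALSE))
}

# minimal CVResult built by hand for metric-arithmetic tests
manualCV <- function(ranks, nCandidates, scores = NULL,
                     negatives = NULL) {
    n <- length(ranks)
    if (is.null(scores)) scores <- rep(1, n)
    if (is.null(negatives)) negatives <- replicate(n, numeric(0),
        simplify = FALSE)
    new("CVResult",
        records = data.frame(query = paste0("l", seq_len(n)),
            heldOut = paste0("p", seq_len(n)), score = scores,
            rank = ranks, nCandidates = nCandidates, fold = seq_len(n),
            stringsAsFactors = FALSE),
        negatives = negatives,
        skipped = data.frame(query = character(), heldOut = character(),
            reason = character(), stringsAsFactors = FALSE),
        method = "lpbni", mode = "loocv")
}
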