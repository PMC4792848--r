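# ProCF and RWR comparator kernels (raw-adjacency internals + S4-facing
# wrappers, matching propagation.R).

.cosineSimMatrix <- function(A, sqrtSimilarity = TRUE) {
    shared <- A %*% t(A)            # |N(i) /\ N(k)|
    d <- rowSums(A)
    denom <- if (sqrtSimilarity) sqrt(outer(d, d)) else outer(d, d)
    S <- shared / denom
    S[denom == 0] <- 0
    S
}

.procf <- function(A, j, sqrtSimilarity = TRUE) {
    S <- .cosineSimMatrix(A, sqrtSimilarity)
    diag(S) <- 0                    # k != i in both sums
    num <- as.vector(S %*% A[, j])
    den <- rowSums(S)
    s <- ifelse(den > 0, num / den, 0)
    s
}

.rwr <- function(A, queryIdx, restart, tol, maxIter) {
    m <- nrow(A)
    n <- ncol(A)
    # full bipartite graph, proteins first then lncRNAs; column-normalized
    B <- rbind(cbind(matrix(0, m, m), A),
               cbind(t(A), matrix(0, n, n)))
    M <- sweep(B, 2L, colSums(B), "/")
    e <- numeric(m + n)
    e[m + queryIdx] <- 1            # restart at the query lncRNA
    p <- e
    for (it in seq_len(maxIter)) {
        pNew <- (1 - restart) * as.vector(M %*% p) + restart * e
        if (sum(abs(pNew - p)) < tol) return(pNew[seq_len(m)])
        p <- pNew
    }
    stop("random walk did not converge after ", maxIter, " iterations")
}

#' Cosine similarity between two proteins' lncRNA neighbourhoods
#'
#' For binary interaction profiles the cosine similarity is the shared
#' neighbour count over the geometric mean of the degrees,
#' `|N(i) /\ N(k)| / sqrt(d(p_i) d(p_k))`. Setting
#' `sqrtSimilarity = FALSE` divides by the plain degree product instead
#' (a harsher penalty on hub proteins), kept for sensitivity analysis.
#'
#' @param net a [BipartiteNetwork-class]
#' @param i,k protein identifiers or row indices
#' @param sqrtSimilarity logical; use the geometric-mean denominator
#'   (default TRUE).
#' @return a similarity in [0, 1]
#' @examples
#' cosineSimilarity(toyNetwork(), "p1", "p2")  # 1/sqrt(4) = 0.5
#' @export
cosineSimilarity <- function(net, i, k, sqrtSimilarity = TRUE) {
    stopifnot(is(net, "BipartiteNetwork"))
    A <- adjacencyMatrix(net)
    S <- .cosineSimMatrix(A, sqrtSimilarity)
    unname(S[i, k])
}

#' Protein-based collaborative filtering scores
#'
#' Scores candidate proteins for a query lncRNA by similarity-weighted
#' votes: proteins already linked to the query recommend proteins with
#' similar interaction profiles. For protein `p_i` and query `l_j`,
#' \deqn{score_{ij} = \frac{\sum_{k \ne i} S_P(p_i,p_k)\,a_{kj}}
#'                         {\sum_{k \ne i} S_P(p_i,p_k)}}
#' with `S_P` the cosine similarity of [cosineSimilarity()]. A protein
#' sharing no lncRNA with any other protein has an empty similarity row and
#' scores 0 for every query.
#'
#' @inheritParams lpbniScores
#' @inheritParams cosineSimilarity
#' @return named numeric vector of scores in [0, 1], one per protein
#' @export
procfScores <- function(net, query, sqrtSimilarity = TRUE) {
    A <- .queryCheck(net, query)
    s <- .procf(A, query, sqrtSimilarity)
    names(s) <- rownames(A)
    s
}

#' Random walk with restart on the bipartite graph
#'
#' Stationary visiting probabilities of a walker on the full (m + n)-node
#' bipartite graph that at each step either moves along a uniformly chosen
#' edge (column-normalized transition matrix) or, with probability
#' `restart`, teleports back to the query lncRNA. Iterates
#' `p <- (1 - r) M p + r e_query` until the L1 change drops below `tol`;
#' the fixed point is unique, so the result does not depend on the starting
#' vector. The protein block of the stationary vector is returned; it sums
#' to at most 1.
#'
#' @inheritParams lpbniScores
#' @param restart restart (teleport) probability in (0, 1); default 0.7,
#'   the common choice in network-prioritization random walks.
#' @param tol L1 convergence threshold (default 1e-10)
#' @param maxIter iteration cap; exceeding it is an error.
#' @return named numeric vector of protein visiting probabilities
#' @export
rwrScores <- function(net, query, restart = 0.7, tol = 1e-10,
                      maxIter = 1e5) {
    A <- .queryCheck(net, query)
    if (!is.numeric(restart) || restart <= 0 || restart >= 1)
        stop("restart probability must lie strictly in (0, 1)")
    s <- .rwr(A, match(query, colnames(A)), restart, tol, maxIter)
    names(s) <- rownames(A)
    s
}

# scorer registry used by the CV harness and the CLI
.scorerKernel <- function(method) {
    switch(method,
        lpbni = function(A, j, params) .lpbni(A, A[, j]),
        procf = function(A, j, params) {
            sq <- if (is.null(params$sqrtSimilarity)) TRUE
                  else params$sqrtSimilarity
            .procf(A, j, sq)
        },
        rwr = function(A, j, params) {
            r <- if (is.null(params$restart)) 0.7 else params$restart
            tol <- if (is.null(params$tol)) 1e-10 else params$tol
            mi <- if (is.null(params$maxIter)) 1e5 else params$maxIter
            .rwr(A, match(j, colnames(A)), r, tol, mi)
        },
        stop("unknown scorer: ", method)
    )
}
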