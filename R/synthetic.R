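#' The canonical worked-example network
#'
#' The minimal three-protein, four-lncRNA network on which the two-step
#' propagation can be followed by hand: protein `p1` interacts with
#' `l1..l4`, `p2` with `l1` only, and `p3` with `l2` only. Its propagation
#' matrix and the final scores for initial resource (1, 1, 0) have simple
#' rational entries, making this the bit-exact anchor of the test suite.
#'
#' @return a [BipartiteNetwork-class] with protein degrees (4, 1, 1) and
#'   lncRNA degrees (2, 2, 1, 1)
#' @examples
#' propagationMatrix(toyNetwork())
#' @export
toyNetwork <- function() {
    buildNetwork(data.frame(
        lncRNA  = c("l1", "l2", "l3", "l4", "l1", "l2"),
        protein = c("p1", "p1", "p1", "p1", "p2", "p3")))
}

#' Simulate a block-structured bipartite network with planted test edges
#'
#' Generates a seeded random lncRNA-protein network whose statistical
#' structure is what neighbourhood-propagation scorers exploit: lncRNAs and
#' proteins are partitioned into co-interaction blocks, pairs inside a block
#' interact with probability `withinProb` and pairs across blocks with the
#' much smaller `backgroundProb`. Optionally a fraction of the within-block
#' edges is withheld as a labelled test set; withheld edges are removed from
#' the returned training network (never both copies), and only edges whose
#' removal leaves both endpoints with at least one training link are
#' eligible. Hub-protein degree heterogeneity can be emulated by a
#' power-law weight on protein participation.
#'
#' Any node left with no edges after sampling is repaired by attaching one
#' uniformly random partner (within its block when blocks exist), so the
#' returned network always satisfies the degree >= 1 invariant; repairs are
#' reported via a message.
#'
#' @param nLnc,nProt node counts (>= 1)
#' @param nBlocks number of co-interaction blocks (1 = homogeneous random
#'   network); nodes are split into blocks as evenly as possible.
#' @param withinProb edge probability inside a block
#' @param backgroundProb edge probability across blocks
#' @param heldOutFrac fraction of within-block edges withheld as planted
#'   test edges (default 0)
#' @param protExponent optional power-law exponent; when set, protein `i`'s
#'   edge probabilities are scaled by a weight proportional to
#'   `i^(-protExponent)` (normalized to mean 1, capped at probability 1),
#'   mimicking hub proteins that bind many lncRNAs.
#' @param seed RNG seed; the same spec and seed reproduce the network
#'   exactly.
#' @return list with elements `network` (the training
#'   [BipartiteNetwork-class]), `heldOut` (data.frame of withheld
#'   lncRNA/protein pairs), and `spec` (echo of all parameters)
#' @examples
#' sim <- simulateNetwork(nLnc = 50, nProt = 10, seed = 0)
#' sim$network
#' @export
simulateNetwork <- function(nLnc = 50, nProt = 10, nBlocks = 5,
                            withinProb = 0.8, backgroundProb = 0.05,
                            heldOutFrac = 0.1, protExponent = NULL,
                            seed = 0) {
    stopifnot(nLnc >= 1, nProt >= 1, nBlocks >= 1,
        withinProb >= 0, withinProb <= 1,
        backgroundProb >= 0, backgroundProb <= 1,
        heldOutFrac >= 0, heldOutFrac < 1)
    if (nBlocks > min(nLnc, nProt))
        stop("more blocks than nodes on one side")
    spec <- list(nLnc = nLnc, nProt = nProt, nBlocks = nBlocks,
        withinProb = withinProb, backgroundProb = backgroundProb,
        heldOutFrac = heldOutFrac, protExponent = protExponent,
        seed = seed)
    .withSeed(seed, {
        lncBlock <- rep_len(seq_len(nBlocks), nLnc)
        protBlock <- rep_len(seq_len(nBlocks), nProt)
        P <- matrix(backgroundProb, nProt, nLnc)
        same <- outer(protBlock, lncBlock, "==")
        P[same] <- withinProb
        if (!is.null(protExponent)) {
            w <- seq_len(nProt)^(-protExponent)
            w <- w / mean(w)
            P <- pmin(P * w, 1)
        }
        A <- matrix(as.numeric(stats::runif(nProt * nLnc) < P),
            nProt, nLnc)
        # zero-width digit padding keeps lexicographic == numeric order
        rownames(A) <- sprintf("prot%0*d", nchar(nProt), seq_len(nProt))
        colnames(A) <- sprintf("lnc%0*d", nchar(nLnc), seq_len(nLnc))
        if (all(P == 0))
            stop("infeasible spec: all edge probabilities are zero")
        repairs <- 0L
        for (i in which(rowSums(A) == 0)) {
            pool <- which(lncBlock == protBlock[i])
            A[i, pool[sample.int(length(pool), 1L)]] <- 1
            repairs <- repairs + 1L
        }
        for (j in which(colSums(A) == 0)) {
            pool <- which(protBlock == lncBlock[j])
            A[pool[sample.int(length(pool), 1L)], j] <- 1
            repairs <- repairs + 1L
        }
        if (repairs > 0)
            message(repairs, " isolated node(s) repaired with one random edge")
        heldOut <- data.frame(lncRNA = character(), protein = character(),
            stringsAsFactors = FALSE)
        if (heldOutFrac > 0) {
            within <- which(A == 1 & same, arr.ind = TRUE)
            nHold <- floor(heldOutFrac * nrow(within))
            cand <- within[sample.int(nrow(within)), , drop = FALSE]
            taken <- 0L
            for (r in seq_len(nrow(cand))) {
                if (taken >= nHold) break
                i <- cand[r, "row"]
                j <- cand[r, "col"]
                if (sum(A[i, ]) > 1 && sum(A[, j]) > 1) {
                    A[i, j] <- 0
                    heldOut <- rbind(heldOut, data.frame(
                        lncRNA = colnames(A)[j], protein = rownames(A)[i],
                        stringsAsFactors = FALSE))
                    taken <- taken + 1L
                }
            }
        }
        list(network = .newNetwork(A), heldOut = heldOut, spec = spec)
    })
}
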