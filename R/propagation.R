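# Internal scorer kernels operate on a raw 0/1 adjacency (proteins x
# lncRNAs) so the cross-validation loops can rescore modified folds without
# re-running object validity on every iteration.

.propMatrix <- function(A) {
    dp <- rowSums(A)
    dl <- colSums(A)
    if (any(dp == 0) || any(dl == 0))
        stop("zero-degree node: every node must have degree >= 1")
    # w_ik = (1/d(p_k)) * sum_j a_ij * a_kj / d(l_j)
    M <- (A %*% (t(A) / dl))        # column j of t(A) scaled by 1/d(l_j)
    sweep(M, 2L, dp, "/")
}

.lpbni <- function(A, s0) {
    dp <- rowSums(A)
    dl <- colSums(A)
    sL <- as.vector(crossprod(A, s0 / dp))  # resource on each lncRNA
    as.vector(A %*% (sL / dl))              # returned to the protein layer
}

#' Protein-to-protein propagation matrix
#'
#' One round trip of resource through the lncRNA layer: each protein splits
#' its resource equally over its lncRNA neighbours, and each lncRNA splits
#' what it received equally over its protein neighbours. The resulting
#' matrix `W` has entries
#' \deqn{w_{ik} = \frac{1}{d(p_k)} \sum_j \frac{a_{ij} a_{kj}}{d(l_j)}}
#' where `d(p_k)` and `d(l_j)` are protein and lncRNA degrees. `W` is
#' column-stochastic (each protein's unit resource is conserved), satisfies
#' the degree-weighted symmetry `d(p_k) w_ik = d(p_i) w_ki`, and `w_ik > 0`
#' exactly when proteins `i` and `k` share a lncRNA neighbour. It is not
#' symmetric: high-degree proteins retain and attract more resource.
#'
#' @param net a [BipartiteNetwork-class]; every node must have degree >= 1
#'   (guaranteed by construction).
#' @return an m x m numeric matrix with protein identifiers as dimnames
#' @examples
#' propagationMatrix(toyNetwork())   # columns sum to 1
#' @export
propagationMatrix <- function(net) {
    stopifnot(is(net, "BipartiteNetwork"))
    .propMatrix(adjacencyMatrix(net))
}

#' LPBNI two-step propagation scores for a query lncRNA
#'
#' The initial resource vector `S0` places one unit on every protein known
#' to interact with the query lncRNA. The first step propagates `S0` to the
#' lncRNA layer (each protein shares equally among its lncRNA neighbours);
#' the second returns the resource to the proteins (each lncRNA shares
#' equally among its protein neighbours). The final vector `S_F` ranks
#' candidate interactors; it equals `W %*% S0` for the matrix `W` of
#' [propagationMatrix()], and its total equals `sum(S0)` (resource
#' conservation). The default evaluates the explicit two-step sums; the
#' matrix route is retained as a cross-check.
#'
#' @param net a [BipartiteNetwork-class]
#' @param query a lncRNA identifier present in `net`
#' @param form "twostep" (default) or "matrix"; both agree to machine
#'   precision.
#' @return named numeric vector of non-negative scores, one per protein
#' @examples
#' lpbniScores(toyNetwork(), "l1")   # (5/4, 5/8, 1/8)
#' @export
lpbniScores <- function(net, query, form = c("twostep", "matrix")) {
    form <- match.arg(form)
    A <- .queryCheck(net, query)
    s0 <- A[, query]
    s <- if (form == "twostep") .lpbni(A, s0)
         else as.vector(.propMatrix(A) %*% s0)
    names(s) <- rownames(A)
    s
}

.queryCheck <- function(net, query) {
    stopifnot(is(net, "BipartiteNetwork"))
    if (!is.character(query) || length(query) != 1L)
        stop("query must be a single lncRNA identifier")
    if (!query %in% lncIDs(net))
        stop("unknown query lncRNA: ", query)
    adjacencyMatrix(net)
}
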