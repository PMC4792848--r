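#' Build a bipartite lncRNA-protein network from an edge list
#'
#' Constructs a [BipartiteNetwork-class] from known interaction pairs. Each
#' distinct (lncRNA, protein) pair becomes a single edge; duplicate pairs
#' collapse to one edge with a warning (database exports routinely repeat
#' pairs). Node order is lexicographic, so the adjacency matrix is a pure
#' function of the edge *set*: shuffling the input rows yields an identical
#' network.
#'
#' @param edges two-column data.frame or matrix; first column lncRNA
#'   identifiers, second column protein identifiers.
#' @return a [BipartiteNetwork-class]
#' @examples
#' net <- buildNetwork(data.frame(
#'     lncRNA  = c("l1", "l2", "l3", "l4", "l1", "l2"),
#'     protein = c("p1", "p1", "p1", "p1", "p2", "p3")))
#' proteinDegrees(net)
#' @export
buildNetwork <- function(edges) {
    if (is.matrix(edges)) edges <- as.data.frame(edges)
    if (!is.data.frame(edges) || ncol(edges) < 2L)
        stop("edges must be a two-column data.frame (lncRNA, protein)")
    if (nrow(edges) == 0L)
        stop("no edges")
    lnc <- as.character(edges[[1L]])
    prot <- as.character(edges[[2L]])
    bad <- which(is.na(lnc) | is.na(prot) | lnc == "" | prot == "")
    if (length(bad))
        stop("malformed edge at line ", bad[1L],
             ": both identifiers are required")
    key <- paste(lnc, prot, sep = "\r")
    if (anyDuplicated(key)) {
        warning(sum(duplicated(key)), " duplicate edge(s) collapsed")
        keep <- !duplicated(key)
        lnc <- lnc[keep]
        prot <- prot[keep]
    }
    lncU <- sort(unique(lnc))
    protU <- sort(unique(prot))
    A <- matrix(0, nrow = length(protU), ncol = length(lncU),
        dimnames = list(protU, lncU))
    A[cbind(match(prot, protU), match(lnc, lncU))] <- 1
    .newNetwork(A)
}

#' Filter nodes by minimum degree
#'
#' Removes nodes with fewer than `minLinks` interactions. The single-pass
#' default removes every node below the threshold once and then discards any
#' node this leaves with no edges at all; this is the pre-filter applied
#' before leave-one-out cross-validation, where a node needs at least two
#' links for one to be withheld while information still propagates through
#' the other. With `iterate = TRUE` the removal is repeated to a fixed point
#' (removal can push other nodes below the threshold), after which every
#' retained node is guaranteed degree `>= minLinks`.
#'
#' @param net a [BipartiteNetwork-class]
#' @param minLinks minimum degree to retain a node (>= 1); `1` is a no-op.
#' @param iterate logical; repeat removal until no node falls below
#'   `minLinks` (default `FALSE`, a single pass).
#' @return the reduced [BipartiteNetwork-class]
#' @export
filterMinDegree <- function(net, minLinks, iterate = FALSE) {
    stopifnot(is(net, "BipartiteNetwork"))
    if (!is.numeric(minLinks) || length(minLinks) != 1L || minLinks < 1)
        stop("minLinks must be a single count >= 1")
    A <- adjacencyMatrix(net)
    repeat {
        dp <- rowSums(A)
        dl <- colSums(A)
        dropP <- dp < minLinks
        dropL <- dl < minLinks
        if (!any(dropP) && !any(dropL)) break
        A <- A[!dropP, !dropL, drop = FALSE]
        if (nrow(A) == 0L || ncol(A) == 0L || sum(A) == 0)
            stop("no nodes survive filter")
        if (!iterate) {
            # single pass: only clean up nodes left with no edges at all
            A <- A[rowSums(A) > 0, colSums(A) > 0, drop = FALSE]
            if (nrow(A) == 0L || ncol(A) == 0L)
                stop("no nodes survive filter")
            break
        }
    }
    .newNetwork(A)
}

#' Read and write edge-list files
#'
#' The interchange format is tab-separated text with two required columns
#' (lncRNA identifier, protein identifier), as in NPInter-style exports.
#' Lines starting with `#` are skipped; a header row is consumed when
#' `header = TRUE`. `writeEdgeList()` emits the same format in deterministic
#' order (lncRNA, then protein), so write/read round-trips reproduce the
#' network exactly.
#'
#' @param path file path
#' @param header logical; does the file carry a header row?
#' @return `readEdgeList()` returns a [BipartiteNetwork-class];
#'   `writeEdgeList()` returns `path` invisibly.
#' @export
readEdgeList <- function(path, header = FALSE) {
    edges <- utils::read.table(path, header = header, sep = "\t",
        comment.char = "#", colClasses = "character",
        stringsAsFactors = FALSE, quote = "")
    buildNetwork(edges)
}

#' @rdname readEdgeList
#' @param net a [BipartiteNetwork-class] to serialize
#' @export
writeEdgeList <- function(net, path, header = FALSE) {
    stopifnot(is(net, "BipartiteNetwork"))
    A <- adjacencyMatrix(net)
    idx <- which(A == 1, arr.ind = TRUE)
    df <- data.frame(lncRNA = colnames(A)[idx[, "col"]],
        protein = rownames(A)[idx[, "row"]], stringsAsFactors = FALSE)
    df <- df[order(df$lncRNA, df$protein), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = header)
    invisible(path)
}
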