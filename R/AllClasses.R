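#' @import methods
NULL

#' BipartiteNetwork: a lncRNA-protein interaction network
#'
#' Container for a binary bipartite interaction network between long
#' non-coding RNAs (lncRNAs) and RNA-binding proteins. The adjacency matrix
#' has one row per protein and one column per lncRNA; entry `(i, j)` is 1 if
#' protein `i` is known to interact with lncRNA `j` and 0 otherwise. Node
#' identifiers are kept in lexicographic order so every derived matrix and
#' output file is reproducible byte for byte.
#'
#' Objects satisfy these invariants, checked by the validity method:
#' the adjacency is strictly binary with no duplicate edges (a cell is 0 or
#' 1); every retained node has degree at least 1; identifier vectors contain
#' no duplicates and the lncRNA and protein namespaces are disjoint.
#'
#' @slot lncIDs character vector of lncRNA identifiers (columns), sorted.
#' @slot protIDs character vector of protein identifiers (rows), sorted.
#' @slot adjacency numeric matrix of 0/1, `length(protIDs)` rows by
#'   `length(lncIDs)` columns, with dimnames set to the identifier vectors.
#'
#' @seealso [buildNetwork()], [filterMinDegree()], [propagationMatrix()]
#' @export
setClass("BipartiteNetwork",
    representation(
        lncIDs = "character",
        protIDs = "character",
        adjacency = "matrix"
    )
)

setValidity("BipartiteNetwork", function(object) {
    A <- object@adjacency
    msgs <- character()
    if (nrow(A) != length(object@protIDs) || ncol(A) != length(object@lncIDs))
        msgs <- c(msgs, "adjacency dimensions do not match identifier lists")
    if (!all(A %in% c(0, 1)))
        msgs <- c(msgs, "adjacency must be strictly binary")
    if (anyDuplicated(object@lncIDs))
        msgs <- c(msgs, "duplicate lncRNA identifiers")
    if (anyDuplicated(object@protIDs))
        msgs <- c(msgs, "duplicate protein identifiers")
    if (length(intersect(object@lncIDs, object@protIDs)) > 0L)
        msgs <- c(msgs, "lncRNA and protein namespaces must be disjoint")
    if (length(A) && (any(rowSums(A) < 1) || any(colSums(A) < 1)))
        msgs <- c(msgs, "isolated nodes are not allowed (degree >= 1 required)")
    if (length(msgs)) msgs else TRUE
})

# internal constructor; callers guarantee sorted ids and dimnames
.newNetwork <- function(A) {
    new("BipartiteNetwork",
        lncIDs = colnames(A), protIDs = rownames(A), adjacency = A)
}

#' @describeIn BipartiteNetwork-accessors number of proteins (rows)
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))
#' @describeIn BipartiteNetwork-accessors number of lncRNAs (columns)
#' @export
setGeneric("nLncRNAs", function(x) standardGeneric("nLncRNAs"))
#' @describeIn BipartiteNetwork-accessors protein identifiers
#' @export
setGeneric("protIDs", function(x) standardGeneric("protIDs"))
#' @describeIn BipartiteNetwork-accessors lncRNA identifiers
#' @export
setGeneric("lncIDs", function(x) standardGeneric("lncIDs"))
#' @describeIn BipartiteNetwork-accessors binary adjacency matrix
#'   (proteins x lncRNAs)
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @describeIn BipartiteNetwork-accessors per-protein degrees d(p_i),
#'   the number of lncRNAs each protein interacts with
#' @export
setGeneric("proteinDegrees", function(x) standardGeneric("proteinDegrees"))
#' @describeIn BipartiteNetwork-accessors per-lncRNA degrees d(l_j),
#'   the number of proteins each lncRNA interacts with
#' @export
setGeneric("lncDegrees", function(x) standardGeneric("lncDegrees"))
#' @describeIn BipartiteNetwork-accessors number of edges |E|
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' Accessors for BipartiteNetwork objects
#'
#' Degree accessors return named vectors; `sum(proteinDegrees(x))` and
#' `sum(lncDegrees(x))` both equal `nEdges(x)`.
#'
#' @param x a [BipartiteNetwork-class] object
#' @name BipartiteNetwork-accessors
#' @aliases nProteins nLncRNAs protIDs lncIDs adjacencyMatrix
#'   proteinDegrees lncDegrees nEdges
NULL

#' @rdname BipartiteNetwork-accessors
#' @export
setMethod("nProteins", "BipartiteNetwork", function(x) length(x@protIDs))
#' @rdname BipartiteNetwork-accessors
#' @export
setMethod("nLncRNAs", "BipartiteNetwork", function(x) length(x@lncIDs))
#' @rdname BipartiteNetwork-accessors
#' @export
setMethod("protIDs", "BipartiteNetwork", function(x) x@protIDs)
#' @rdname BipartiteNetwork-accessors
#' @export
setMethod("lncIDs", "BipartiteNetwork", function(x) x@lncIDs)
#' @rdname BipartiteNetwork-accessors
#' @export
setMethod("adjacencyMatrix", "BipartiteNetwork", function(x) x@adjacency)
#' @rdname BipartiteNetwork-accessors
#' @export
setMethod("proteinDegrees", "BipartiteNetwork",
    function(x) rowSums(x@adjacency))
#' @rdname BipartiteNetwork-accessors
#' @export
setMethod("lncDegrees", "BipartiteNetwork", function(x) colSums(x@adjacency))
#' @rdname BipartiteNetwork-accessors
#' @export
setMethod("nEdges", "BipartiteNetwork", function(x) sum(x@adjacency))

setMethod("show", "BipartiteNetwork", function(object) {
    cat("BipartiteNetwork:", nLncRNAs(object), "lncRNAs x",
        nProteins(object), "proteins,", nEdges(object), "interactions\n")
    dp <- proteinDegrees(object)
    cat("  protein degree range:", min(dp), "-", max(dp), "\n")
})

#' CVResult: pooled cross-validation records
#'
#' One record per evaluated held-out interaction: the query lncRNA, the
#' withheld protein, its score under the scorer retrained without the pair,
#' its competition rank `n` among the `N` candidate proteins (proteins not
#' linked to the query in the training fold, the withheld one included), and
#' the scores of the remaining candidates, pooled later as ROC negatives.
#'
#' @slot records data.frame with columns `query`, `heldOut`, `score`,
#'   `rank`, `nCandidates`, `fold`.
#' @slot negatives list parallel to `records`; each element holds the
#'   candidate-protein scores for that fold, withheld protein excluded.
#' @slot skipped data.frame of pairs not evaluated, with a `reason` column
#'   (e.g. an endpoint would lose its last training link).
#' @slot method scorer name ("lpbni", "procf" or "rwr").
#' @slot mode "loocv" or "kfold".
#' @seealso [loocv()], [kfoldCV()], [evaluateCV()]
#' @export
setClass("CVResult",
    representation(
        records = "data.frame",
        negatives = "list",
        skipped = "data.frame",
        method = "character",
        mode = "character"
    )
)

setValidity("CVResult", function(object) {
    r <- object@records
    need <- c("query", "heldOut", "score", "rank", "nCandidates", "fold")
    if (!all(need %in% names(r)))
        return("records must have columns query/heldOut/score/rank/nCandidates/fold")
    if (length(object@negatives) != nrow(r))
        return("negatives list must parallel records")
    if (nrow(r) && any(r$rank < 1 | r$rank > r$nCandidates))
        return("ranks must lie in [1, nCandidates]")
    TRUE
})

#' @describeIn CVResult-accessors per-fold record table
#' @export
setGeneric("cvRecords", function(x) standardGeneric("cvRecords"))
#' @describeIn CVResult-accessors list of candidate (negative) score vectors
#' @export
setGeneric("cvNegatives", function(x) standardGeneric("cvNegatives"))
#' @describeIn CVResult-accessors table of skipped pairs with reasons
#' @export
setGeneric("cvSkipped", function(x) standardGeneric("cvSkipped"))

#' Accessors for CVResult objects
#' @param x a [CVResult-class] object
#' @name CVResult-accessors
#' @aliases cvRecords cvNegatives cvSkipped
NULL

#' @rdname CVResult-accessors
#' @export
setMethod("cvRecords", "CVResult", function(x) x@records)
#' @rdname CVResult-accessors
#' @export
setMethod("cvNegatives", "CVResult", function(x) x@negatives)
#' @rdname CVResult-accessors
#' @export
setMethod("cvSkipped", "CVResult", function(x) x@skipped)

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult (%s, %s): %d evaluated pairs, %d skipped\n",
        object@method, object@mode, nrow(object@records),
        nrow(object@skipped)))
    if (nrow(object@records))
        cat(sprintf("  median rank %g of median %g candidates\n",
            stats::median(object@records$rank),
            stats::median(object@records$nCandidates)))
})

#' MetricReport: evaluation summary for one scorer
#'
#' Bundles the pooled ROC curve and AUC, confusion-table metrics at the
#' requested specificities (sensitivity, accuracy, precision, Matthews
#' correlation coefficient), the mean fold enrichment (N/2)/n, and the
#' percentile-recovery counts.
#'
#' @slot auc numeric scalar in [0, 1].
#' @slot roc data.frame with columns `threshold`, `fpr`, `tpr`.
#' @slot thresholdMetrics data.frame, one row per requested specificity:
#'   `specificity`, `threshold`, `sensitivity`, `accuracy`, `precision`,
#'   `mcc`.
#' @slot foldEnrichment numeric scalar, mean over records of (N/2)/n.
#' @slot recovery data.frame with columns `percentile`, `count`.
#' @seealso [evaluateCV()]
#' @export
setClass("MetricReport",
    representation(
        auc = "numeric",
        roc = "data.frame",
        thresholdMetrics = "data.frame",
        foldEnrichment = "numeric",
        recovery = "data.frame"
    )
)

setMethod("show", "MetricReport", function(object) {
    cat(sprintf("MetricReport: AUC %.4f, mean fold enrichment %.3f\n",
        object@auc, object@foldEnrichment))
    if (nrow(object@thresholdMetrics)) {
        cat("  at fixed specificity:\n")
        print(object@thresholdMetrics, row.names = FALSE, digits = 4)
    }
})
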