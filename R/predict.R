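# Ranked-prediction front end and evaluation orchestration.

.scoreQuery <- function(A, query, method, params) {
    s <- .scorerKernel(method)(A, query, params)
    names(s) <- rownames(A)
    s
}

#' Score every (protein, lncRNA) pair of a network
#'
#' Runs the chosen scorer once per lncRNA and assembles the results into a
#' proteins x lncRNAs score matrix (column `j` is the score vector for
#' query lncRNA `j`). Convenient for genome-scale ranking and for computing
#' AUCs over held-out edge sets.
#'
#' @inheritParams loocv
#' @return numeric matrix with the same dimnames as the adjacency
#' @export
scoreMatrix <- function(net, method = c("lpbni", "procf", "rwr"),
                        params = list()) {
    method <- match.arg(method)
    stopifnot(is(net, "BipartiteNetwork"))
    A <- adjacencyMatrix(net)
    S <- vapply(colnames(A), function(j) .scoreQuery(A, j, method, params),
        numeric(nrow(A)))
    dimnames(S) <- dimnames(A)
    S
}

#' Ranked candidate proteins for query lncRNAs
#'
#' Scores all proteins for each query lncRNA, separates known interactors
#' (flagged `known = TRUE`, excluded from the candidate ranking) from
#' candidates, and returns the top `topK` candidates per query in
#' descending score. Candidate ranks are competition ranks with ties broken
#' pessimistically and then by protein identifier, so output order is fully
#' deterministic.
#'
#' @inheritParams loocv
#' @param queries character vector of query lncRNA identifiers; default all
#'   lncRNAs in the network.
#' @param topK candidates reported per query (clamped to the number of
#'   candidates)
#' @param includeKnown also emit rows for known interactors (score given,
#'   `rank` NA, `known = TRUE`); default TRUE.
#' @return data.frame with columns `query`, `protein`, `score`, `rank`,
#'   `known`
#' @examples
#' predictInteractions(toyNetwork(), queries = "l1", topK = 1)
#' @export
predictInteractions <- function(net, method = c("lpbni", "procf", "rwr"),
                                queries = NULL, topK = 5, params = list(),
                                includeKnown = TRUE) {
    method <- match.arg(method)
    stopifnot(is(net, "BipartiteNetwork"))
    A <- adjacencyMatrix(net)
    if (is.null(queries)) queries <- colnames(A)
    missing <- setdiff(queries, colnames(A))
    if (length(missing))
        stop("unknown query lncRNA: ", paste(missing, collapse = ", "))
    if (!is.numeric(topK) || topK < 1)
        stop("topK must be a positive count")
    out <- lapply(queries, function(q) {
        s <- .scoreQuery(A, q, method, params)
        known <- A[, q] == 1
        cand <- s[!known]
        ord <- order(-cand, names(cand))
        cand <- cand[ord]
        rank <- vapply(cand, function(x) sum(cand >= x), numeric(1))
        kTop <- min(topK, length(cand))
        res <- data.frame(query = q,
            protein = names(cand)[seq_len(kTop)],
            score = unname(cand[seq_len(kTop)]),
            rank = rank[seq_len(kTop)], known = FALSE,
            stringsAsFactors = FALSE)
        if (includeKnown && any(known)) {
            kn <- sort(names(s)[known])
            res <- rbind(res, data.frame(query = q, protein = kn,
                score = unname(s[kn]), rank = NA_real_, known = TRUE,
                stringsAsFactors = FALSE))
        }
        res
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Run a full cross-validation evaluation and write its artifacts
#'
#' Orchestrates one evaluation run: read (or accept) a network, optionally
#' apply the minimum-degree pre-filter, run the chosen cross-validation,
#' and write the per-fold records, ROC points, metric report (TSV and
#' JSON) and a JSON run manifest (full configuration, seed, package
#' version, input checksum) into `outDir`. The manifest suffices to
#' reproduce the run exactly; the input edge file is never modified.
#'
#' @param input a [BipartiteNetwork-class] or the path of an edge-list file
#'   (see [readEdgeList()])
#' @inheritParams loocv
#' @inheritParams kfoldCV
#' @param mode "loocv" or "kfold"
#' @param outDir output directory, created if needed
#' @param minLinks minimum-degree pre-filter applied before evaluation
#'   (default 2, the evaluability threshold); set 1 to skip.
#' @param header logical, passed to [readEdgeList()] when `input` is a path
#' @param specificities,percentiles passed to [evaluateCV()]
#' @return invisibly, a list with the [CVResult-class] and
#'   [MetricReport-class]
#' @export
runEvaluation <- function(input, method = c("lpbni", "procf", "rwr"),
                          mode = c("loocv", "kfold"), outDir, k = 10,
                          seed = 0, params = list(), minLinks = 2,
                          ties = c("pessimistic", "mean"), header = FALSE,
                          specificities = c(0.99, 0.95),
                          percentiles = c(5, 10, 15, 20, 50)) {
    method <- match.arg(method)
    mode <- match.arg(mode)
    ties <- match.arg(ties)
    checksum <- NA_character_
    if (is.character(input)) {
        checksum <- unname(tools::md5sum(input))
        net <- readEdgeList(input, header = header)
        inputName <- input
    } else {
        stopifnot(is(input, "BipartiteNetwork"))
        net <- input
        inputName <- "<in-memory network>"
    }
    if (minLinks > 1) net <- filterMinDegree(net, minLinks)
    cv <- if (mode == "loocv") loocv(net, method, params, ties)
          else kfoldCV(net, method, k, seed, params, ties)
    report <- evaluateCV(cv, specificities, percentiles)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    tsv <- function(df, name) utils::write.table(df,
        file.path(outDir, name), sep = "\t", quote = FALSE,
        row.names = FALSE)
    tsv(cvRecords(cv), "cv_records.tsv")
    if (nrow(cvSkipped(cv))) tsv(cvSkipped(cv), "cv_skipped.tsv")
    tsv(report@roc, "roc_points.tsv")
    tsv(report@thresholdMetrics, "metrics_at_specificity.tsv")
    tsv(report@recovery, "percentile_recovery.tsv")
    metrics <- list(method = method, mode = mode, auc = report@auc,
        foldEnrichment = report@foldEnrichment,
        nRecords = nrow(cvRecords(cv)), nSkipped = nrow(cvSkipped(cv)),
        atSpecificity = report@thresholdMetrics,
        recovery = report@recovery)
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest <- list(
        package = "lpbni",
        version = as.character(utils::packageVersion("lpbni")),
        input = inputName, inputMD5 = checksum, method = method,
        mode = mode, k = if (mode == "kfold") k else NA,
        seed = seed, minLinks = minLinks, ties = ties,
        scorerParams = params, specificities = specificities,
        percentiles = percentiles,
        nLncRNAs = nLncRNAs(net), nProteins = nProteins(net),
        nEdges = nEdges(net))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, null = "null")
    invisible(list(cv = cv, report = report))
}
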