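test_that("worked example: propagation matrix and two-step scores are exact", {
    net <- toyNetwork()
    W <- propagationMatrix(net)
    expected <- matrix(c(
        3 / 4, 1 / 2, 1 / 2,
        1 / 8, 1 / 2, 0,
        1 / 8, 0, 1 / 2), nrow = 3, byrow = TRUE,
        dimnames = list(c("p1", "p2", "p3"), c("p1", "p2", "p3")))
    expect_equal(W, expected, tolerance = 1e-15)
    # query l1 has interactors p1 and p2, i.e. initial resource (1, 1, 0)
    s <- lpbniScores(net, "l1")
    expect_equal(unname(s), c(5 / 4, 5 / 8, 1 / 8), tolerance = 1e-15)
    expect_equal(unname(lpbniScores(net, "l1", form = "matrix")),
        c(5 / 4, 5 / 8, 1 / 8), tolerance = 1e-15)
    # single-edge network propagates the unit resource back to its protein
    expect_equal(propagationMatrix(buildNetwork(data.frame(l = "l1", p = "p1"))),
        matrix(1, 1, 1, dimnames = list("p1", "p1")))
})

test_that("propagation matrix matches the nested-loop oracle and its invariants", {
    for (seed in 1:20) {
        A <- randomAdjacency(8, 12, 0.3, seed)
        net <- asNetwork(A)
        W <- propagationMatrix(net)
        expect_equal(W, oracleW(adjacencyMatrix(net)), tolerance = 1e-12)
        dp <- proteinDegrees(net)
        # column-stochastic
        expect_equal(unname(colSums(W)), rep(1, nrow(W)), tolerance = 1e-12)
        expect_true(all(W >= 0 & W <= 1))
        # degree-weighted symmetry: d(p_k) w_ik is symmetric in (i, k)
        expect_equal(sweep(W, 2, dp, "*"), t(sweep(W, 2, dp, "*")),
            tolerance = 1e-12)
        # support: w_ik > 0 iff proteins share a lncRNA neighbour
        Anet <- adjacencyMatrix(net)
        shared <- (Anet %*% t(Anet)) > 0
        expect_identical(unname(W > 1e-14), unname(shared))
    }
})

test_that("two-step and matrix forms agree and conserve resource", {
    for (seed in 1:15) {
        A <- randomAdjacency(8, 12, 0.35, seed + 50)
        net <- asNetwork(A)
        for (q in sample(lncIDs(net), 3)) {
            s2 <- lpbniScores(net, q)
            sm <- lpbniScores(net, q, form = "matrix")
            expect_equal(s2, sm, tolerance = 1e-12)
            expect_equal(unname(oracleLpbni(adjacencyMatrix(net),
                adjacencyMatrix(net)[, q])), unname(s2),
                tolerance = 1e-12)
            # conservation: total returned resource equals total initial
            expect_equal(sum(s2), sum(adjacencyMatrix(net)[, q]),
                tolerance = 1e-12)
            expect_true(all(s2 >= 0) && all(is.finite(s2)))
        }
    }
})

test_that("complete bipartite symmetry forces uniform scores", {
    edges <- expand.grid(l = paste0("l", 1:6), p = paste0("p", 1:4),
        stringsAsFactors = FALSE)
    net <- buildNetwork(edges)
    s <- lpbniScores(net, "l3")
    expect_equal(unname(s), rep(sum(adjacencyMatrix(net)[, "l3"]) / 4, 4))
})

test_that("unknown query lncRNA is reported by name", {
    expect_error(lpbniScores(toyNetwork(), "nope"), "nope")
    expect_error(procfScores(toyNetwork(), "nope"), "nope")
    expect_error(rwrScores(toyNetwork(), "nope"), "nope")
})

test_that("all three scorers are label-permutation equivariant", {
    A <- randomAdjacency(7, 10, 0.35, 7)
    net <- asNetwork(A)
    # relabel nodes with new names whose sort order differs
    set.seed(11)
    protMap <- setNames(sprintf("Q%03d", sample(100, nProteins(net))),
        protIDs(net))
    lncMap <- setNames(sprintf("M%03d", sample(100, nLncRNAs(net))),
        lncIDs(net))
    idx <- which(A == 1, arr.ind = TRUE)
    net2 <- buildNetwork(data.frame(
        l = unname(lncMap[colnames(A)[idx[, "col"]]]),
        p = unname(protMap[rownames(A)[idx[, "row"]]])))
    q <- lncIDs(net)[4]
    for (fn in list(lpbniScores, procfScores, rwrScores)) {
        s1 <- fn(net, q)
        s2 <- fn(net2, unname(lncMap[q]))
        expect_equal(unname(s2[protMap[names(s1)]]), unname(s1),
            tolerance = 1e-9)
    }
})
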