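test_that("a single planted clonal cluster is recovered at CCF 1", {
    set.seed(5)
    n <- 300
    d <- rpois(n, 40) + 1L
    a <- rbinom(n, d, 0.5)
    sol <- pruneClusters(clusterCcf(a, d, purity = 1, seed = 5))
    expect_equal(nrow(clusterLocations(sol)), 1L)
    expect_lt(abs(clusterLocations(sol)[1, 1] - 1), 0.05)
})

test_that("two planted 1D clusters are recovered in location and weight", {
    set.seed(8)
    n <- 400
    ccf <- c(rep(1, 280), rep(0.4, 120))     # 70% / 30%
    d <- rpois(n, 40) + 1L
    a <- rbinom(n, d, ccf * 0.5)
    sol <- pruneClusters(clusterCcf(a, d, purity = 1, seed = 8))
    expect_equal(nrow(clusterLocations(sol)), 2L)
    loc <- sort(clusterLocations(sol)[, 1])
    expect_lt(abs(loc[1] - 0.4), 0.05)
    expect_lt(abs(loc[2] - 1.0), 0.05)
    w <- sort(clusterWeights(sol))
    expect_lt(abs(w[1] - 0.3), 0.05)
    expect_lt(abs(w[2] - 0.7), 0.05)
})

test_that("the twin-shared plus twin-private 2D architecture is recovered", {
    sc <- plantedTwinScenario(seed = 17)
    sol <- pruneClusters(clusterCcf(sc$alt, sc$depth, purity = c(1, 1),
                                    seed = 17))
    expect_equal(nrow(clusterLocations(sol)), 3L)
    loc <- clusterLocations(sol)
    truth <- rbind(c(1, 1), c(1, 0), c(0, 1))
    for (k in seq_len(3)) {
        dmat <- abs(sweep(loc, 2, truth[k, ]))
        expect_true(any(rowSums(dmat > 0.05) == 0))
    }
})

test_that("clustering is reproducible under a fixed seed", {
    sc <- plantedTwinScenario(seed = 3)
    s1 <- clusterCcf(sc$alt, sc$depth, purity = c(1, 1), seed = 99,
                     iters = 300, burnIn = 100)
    s2 <- clusterCcf(sc$alt, sc$depth, purity = c(1, 1), seed = 99,
                     iters = 300, burnIn = 100)
    expect_identical(clusterLocations(s1), clusterLocations(s2))
    expect_identical(clusterAssignments(s1), clusterAssignments(s2))
})

test_that("degenerate inputs are rejected", {
    expect_error(clusterCcf(c(1, 2), c(4, 4), purity = 1), "fewer than 5")
    expect_error(clusterCcf(rep(2, 6), rep(0, 6), purity = 1), "depth")
    expect_error(clusterCcf(rep(5, 6), rep(4, 6), purity = 1), "alt")
})

test_that("pruning removes sub-threshold clusters and conserves members", {
    loc <- matrix(c(1.0, 0.3), 2, 1)
    z <- c(rep(1L, 398), 2L, 2L)            # minor cluster at 0.5%
    sol <- manualSolution(loc, z, alt = matrix(20L, 400, 1),
                          depth = matrix(40L, 400, 1))
    pruned <- pruneClusters(sol, minFraction = 0.01)
    expect_equal(nrow(clusterLocations(pruned)), 1L)
    expect_equal(length(clusterAssignments(pruned)), 400L)
    expect_equal(sum(clusterWeights(pruned)), 1)
    ## a cluster holding exactly 1% survives (strict less-than)
    z2 <- c(rep(1L, 396), rep(2L, 4L))      # 4/400 = 1%
    sol2 <- manualSolution(loc, z2, alt = matrix(20L, 400, 1),
                           depth = matrix(40L, 400, 1))
    expect_equal(nrow(clusterLocations(pruneClusters(sol2, 0.01))), 2L)
    ## single full-weight cluster unchanged; all-below is an error
    solo <- manualSolution(matrix(1, 1, 1), rep(1L, 10),
                           alt = matrix(20L, 10, 1),
                           depth = matrix(40L, 10, 1))
    expect_identical(pruneClusters(solo), solo)
    expect_error(pruneClusters(solo, minFraction = 1.01), "below")
})

test_that("pigeonhole labels follow cluster CCFs and ignore ordering", {
    loc <- rbind(c(0.99, 0.98), c(0.90, 0.02), c(0.03, 0.95),
                 c(0.40, 0.30))
    sol <- manualSolution(loc, rep(1:4, each = 10))
    lab <- assignLineagesPigeonhole(sol)
    expect_equal(lab$label, c("ancestral", "lineage_a", "lineage_b",
                              "indeterminate"))
    ## clusters at 0.9 and 0.6 in one sample share that lineage
    both <- assignLineagesPigeonhole(
        manualSolution(rbind(c(0.9, 0.01), c(0.6, 0.02)),
                       rep(1:2, each = 10)))
    expect_equal(both$label, c("lineage_a", "lineage_a"))
    ## reordering clusters permutes rows but not the location -> label map
    perm <- c(3, 1, 4, 2)
    solPerm <- manualSolution(loc[perm, ], rep(1:4, each = 10))
    labPerm <- assignLineagesPigeonhole(solPerm)
    expect_equal(labPerm$label, lab$label[perm])
})

test_that("mutations missing from one twin form axis clusters", {
    ## absent-in-one coded as 0 alt reads at local depth
    set.seed(41)
    n <- 80
    dA <- rpois(n, 40) + 1L; dB <- rpois(n, 40) + 1L
    aA <- rbinom(n, dA, 0.5); aB <- rep(0L, n)
    sol <- pruneClusters(clusterCcf(cbind(aA, aB), cbind(dA, dB),
                                    purity = c(1, 1), seed = 41))
    expect_equal(nrow(clusterLocations(sol)), 1L)
    expect_lt(abs(clusterLocations(sol)[1, 1] - 1), 0.05)
    expect_lt(clusterLocations(sol)[1, 2], 0.05)
    lab <- assignLineagesPigeonhole(sol)
    expect_equal(lab$label, "lineage_a")
})
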