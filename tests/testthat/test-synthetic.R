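test_that("zero mutation rate yields empty histories", {
    p <- simulationParams(0, 0.8, 40, 40, seed = 1)
    tr <- simulateTwinHistory(p, refFixture())
    expect_equal(unname(tr$counts), c(0L, 0L, 0L))
    expect_equal(nrow(tr$shared), 0L)
    obs <- simulateObservations(tr)
    expect_equal(nrow(obs), 0L)
})

test_that("parameter validation rejects impossible histories", {
    expect_error(simulationParams(-1, 0.5, 40, 40), "non-negative")
    expect_error(simulationParams(2, 0, 40, 40), "tMrcaTrue")
    expect_error(simulationParams(2, 45, 40, 40), "tMrcaTrue")
    expect_error(simulationParams(2, 0.5, 40, 40, purityA = 0), "purity")
    expect_error(simulationParams(2, 0.5, 40, 40, ncptgFraction = 1.2),
                 "ncptgFraction")
})

test_that("realized counts follow the Poisson clock accrual model", {
    ## lambda = 2.5, t_MRCA = 0.8, total sampling time 40.77 per twin:
    ## E[s] = 2, E[n_i] = 99.9
    ref <- refFixture()
    nrep <- 2000
    cnts <- t(vapply(seq_len(nrep), function(s) {
        p <- simulationParams(2.5, 0.8, 40, 40, seed = s)
        simulateTwinHistory(p, ref)$counts
    }, c(s = 0, n_a = 0, n_b = 0)))
    eS <- 2.5 * 0.8
    eN <- 2.5 * (40 + 40 * 7 / 365.25 - 0.8)
    expect_lt(abs(mean(cnts[, "s"]) - eS), 3 * sqrt(eS / nrep))
    expect_lt(abs(mean(cnts[, "n_a"]) - eN), 3 * sqrt(eN / nrep))
    expect_lt(abs(mean(cnts[, "n_b"]) - eN), 3 * sqrt(eN / nrep))
    ## variance equals the mean (Poisson), within sampling error
    expect_lt(abs(var(cnts[, "n_a"]) / eN - 1), 0.15)
    ## a chi-square goodness-of-fit on the discrete shared counts
    obs <- table(factor(pmin(cnts[, "s"], 6), levels = 0:6))
    pr <- c(dpois(0:5, eS), 1 - ppois(5, eS))
    expect_gt(stats::chisq.test(obs, p = pr)$p.value, 0.01)
})

test_that("count triples land on the order of the observed N[C>T]pG regime", {
    ## the clock-mutation study regime: rate ~2.5/genome/year, MRCA in
    ## utero, sampling near age 40 -> triples of order (2, 89, 114)
    ref <- refFixture()
    cnts <- t(vapply(1:50, function(s) {
        p <- simulationParams(2.5, 0.8, 39.99, 38.45, seed = 7000 + s)
        simulateTwinHistory(p, ref)$counts
    }, c(s = 0, n_a = 0, n_b = 0)))
    expect_true(mean(cnts[, "s"]) >= 0.5 && mean(cnts[, "s"]) <= 10)
    expect_true(all(abs(colMeans(cnts)[2:3] - c(100, 96)) < 15))
})

test_that("lineage partition is exact and contexts match the reference", {
    p <- simulationParams(8, 2, 40, 40, seed = 11, ncptgFraction = 0.3)
    tr <- simulateTwinHistory(p, refFixture())
    allPos <- c(tr$shared$pos, tr$uniqueA$pos, tr$uniqueB$pos)
    expect_equal(anyDuplicated(allPos), 0L)
    expect_equal(nrow(tr$shared), unname(tr$counts["s"]))
    allv <- rbind(tr$shared, tr$uniqueA, tr$uniqueB)
    ## stored context agrees with a fresh reference lookup
    cls <- classifyNcptg(allv, tr$reference)
    expect_equal(cls, twinclock:::ncptgFromContext(allv$ref, allv$alt,
                                                   allv$context))
})

test_that("classified clock fraction converges to the requested fraction", {
    f <- 0.3
    p <- simulationParams(25, 0.8, 40, 40, seed = 5, ncptgFraction = f)
    tr <- simulateTwinHistory(p, refFixture())
    allv <- rbind(tr$shared, tr$uniqueA, tr$uniqueB)
    n <- nrow(allv)
    expect_gt(n, 1500)
    phat <- mean(twinclock:::ncptgFromContext(allv$ref, allv$alt,
                                              allv$context))
    expect_lt(abs(phat - f), qnorm(0.995) * sqrt(f * (1 - f) / n))
})

test_that("observed VAFs follow the purity/copy-number expectation", {
    ## expected VAF = m rho ccf / (rho CN + 2 (1 - rho))
    p <- simulationParams(14, 2, 40, 40, seed = 2, depthMean = 40,
                          purityA = 0.8, purityB = 1)
    tr <- simulateTwinHistory(p, refFixture())
    obs <- simulateObservations(tr)
    a <- obs[obs$twin == "A" & obs$ccf_true == 1, ]
    b <- obs[obs$twin == "B" & obs$ccf_true == 1, ]
    eA <- 0.8 / (0.8 * 2 + 2 * 0.2)    # 0.4
    vafA <- sum(a$alt_reads) / sum(a$depth)
    seA <- sqrt(eA * (1 - eA) / sum(a$depth))
    expect_lt(abs(vafA - eA), 3 * seA)
    vafB <- sum(b$alt_reads) / sum(b$depth)
    expect_lt(abs(vafB - 0.5), 3 * sqrt(0.25 / sum(b$depth)))
    ## absent-in-twin variants carry zero alt reads
    expect_true(all(obs$alt_reads[obs$ccf_true == 0] == 0))
    expect_true(all(obs$depth >= 1))
    expect_error(simulateObservations(tr, purity = c(0, 1)), "purity")
})

test_that("reference fixture honors the CpG density request", {
    noCpg <- twinclock:::makeReferenceSequence(5000, 0, seed = 3)
    expect_equal(
        Biostrings::countPattern("CG", noCpg[[1]]), 0)
    f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
    writeReferenceFixture(f1, 100000, 0.02, seed = 9)
    writeReferenceFixture(f2, 100000, 0.02, seed = 9)
    expect_identical(readLines(f1), readLines(f2))
    ref <- Biostrings::readDNAStringSet(f1)
    cg <- Biostrings::countPattern("CG", ref[[1]])
    expect_lt(abs(cg - 2000), 200)
    expect_error(writeReferenceFixture(tempfile(), 500, 0.02), ">= 1000")
    expect_error(writeReferenceFixture(tempfile(), 5000, 0.5), "cpgDensity")
})

test_that("caller emission respects sensitivity and private false calls", {
    ## ~1000 truth variants per twin; consensus of three 0.9-sensitivity
    ## callers has expectation 0.9^3 = 0.729 per variant
    p <- simulationParams(25, 0.8, 40, 40, seed = 21)
    tr <- simulateTwinHistory(p, refFixture())
    obs <- simulateObservations(tr)
    dir <- withr::local_tempdir()
    out <- emitCallerCallsets(obs, tr$reference, dir,
                              callerSensitivity = c(0.9, 0.9, 0.9),
                              callerFalseCalls = c(5L, 0L, 0L), seed = 13)
    hc <- intersectCallers(readCallerVcf(out$A["caller1"]),
                           readCallerVcf(out$A["caller2"]),
                           readCallerVcf(out$A["caller3"]))
    nTruthA <- sum(obs$twin == "A" & obs$alt_reads > 0)
    expct <- 0.729 * nTruthA
    se <- sqrt(nTruthA * 0.729 * 0.271)
    expect_lt(abs(nrow(hc) - expct), 3 * se)
    ## false calls are private to caller 1, so never in the consensus
    truthPos <- obs$pos[obs$twin == "A" & obs$alt_reads > 0]
    expect_true(all(hc$pos %in% truthPos))
})
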