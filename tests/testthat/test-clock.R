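test_that("N[C>T]pG classification follows the CpG deamination definition", {
    ref <- Biostrings::DNAStringSet(c(chr1 = "TACGTACATCGATGCA"))
    ##                                  123456789...
    v <- function(pos, r, a) data.frame(chrom = "chr1", pos = pos,
                                        ref = r, alt = a,
                                        stringsAsFactors = FALSE)
    expect_true(classifyNcptg(v(3, "C", "T"), ref))    # A[C]G, C>T
    expect_false(classifyNcptg(v(7, "C", "A"), ref))   # C>A never clock
    expect_false(classifyNcptg(v(8, "A", "T"), ref))
    ## G>A with 5' C is the minus-strand representation
    expect_true(classifyNcptg(v(4, "G", "A"), ref))    # C[G]T -> rc A[C]G
    expect_false(classifyNcptg(v(6, "A", "G"), ref))
    ## C with non-G neighbor
    expect_false(classifyNcptg(v(7, "C", "T"), ref))   # A[C]A
    ## indels never qualify
    expect_false(classifyNcptg(v(3, "CG", "C"), ref))
    ## contig edge: FALSE with a warning
    expect_warning(edge <- classifyNcptg(v(16, "A", "C"), ref), "edge")
    expect_false(edge)
    ## reference mismatch is an error
    expect_error(classifyNcptg(v(3, "T", "A"), ref), "mismatch")
    expect_error(classifyNcptg(v(3, "C", "T"),
                               Biostrings::DNAStringSet(c(chrX = "AAA"))),
                 "contig")
})

test_that("classification is invariant under strand involution", {
    ref <- refFixture()
    p <- simulationParams(20, 1, 40, 40, seed = 6, ncptgFraction = 0.4)
    tr <- simulateTwinHistory(p, ref)
    v <- head(rbind(tr$shared, tr$uniqueA, tr$uniqueB), 200)
    fwd <- classifyNcptg(v, ref)
    ## reverse-complement the genome and re-express every variant
    L <- Biostrings::width(ref)[1]
    rcRef <- Biostrings::reverseComplement(ref)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    vrc <- data.frame(chrom = v$chrom, pos = L - v$pos + 1L,
                      ref = unname(comp[v$ref]), alt = unname(comp[v$alt]),
                      stringsAsFactors = FALSE)
    rev <- classifyNcptg(vrc, rcRef)
    expect_equal(rev, fwd)
})

test_that("clock counts are nested within C>T and total SNV counts", {
    p <- simulationParams(20, 1, 40, 40, seed = 16, ncptgFraction = 0.35)
    tr <- simulateTwinHistory(p, refFixture())
    v <- rbind(tr$shared, tr$uniqueA, tr$uniqueB)
    isClock <- classifyNcptg(v, tr$reference)
    isCT <- (v$ref == "C" & v$alt == "T") | (v$ref == "G" & v$alt == "A")
    expect_lte(sum(isClock), sum(isCT))
    expect_lte(sum(isCT), nrow(v))
    expect_true(all(isCT[isClock]))
})

test_that("packaged fixtures reproduce the study count triples", {
    fx <- twinFixture("all_clonal")
    lc <- assembleLineageCounts(fx$partition, fx$labels, "all_clonal")
    expect_equal(unname(countTriple(lc)), c(7L, 91L, 90L))
    fx2 <- twinFixture("ncptg")
    lc2 <- assembleLineageCounts(fx2$partition, fx2$labels, "ncptg")
    expect_equal(unname(countTriple(lc2)), c(2L, 89L, 114L))
    ## provenance records the filter trail
    expect_equal(lc2@provenance$input, nrow(fx2$partition))
    expect_true(all(c("after_depth", "after_context") %in%
                    names(lc2@provenance)))
})

test_that("count assembly respects depth, context and lineage filters", {
    fx <- twinFixture("ncptg")
    part <- fx$partition
    ## raising the depth floor above the fixture depths empties the counts
    lcHi <- assembleLineageCounts(part, fx$labels, "ncptg", minDepth = 100)
    expect_equal(unname(countTriple(lcHi)), c(0L, 0L, 0L))
    ## the all-clonal view of the clock fixture counts every mutation
    lcAll <- assembleLineageCounts(part, fx$labels, "all_clonal")
    expect_equal(sum(countTriple(lcAll)), nrow(part))
    ## a non-clock context row is excluded from the ncptg class
    part$context[part$lineage == "unique_a"][1] <- "ACA"
    lc <- assembleLineageCounts(part, fx$labels, "ncptg")
    expect_equal(unname(countTriple(lc)), c(2L, 88L, 114L))
    ## indeterminate clusters never contribute
    part2 <- fx$partition
    part2$cluster[part2$lineage == "unique_b"] <- 4L
    labels2 <- rbind(fx$labels[, c("cluster", "label")],
                     data.frame(cluster = 4L, label = "indeterminate"))
    lc2 <- assembleLineageCounts(part2, labels2, "ncptg")
    expect_equal(unname(countTriple(lc2)), c(2L, 89L, 0L))
    ## empty partition -> zero triple; missing labels -> error
    expect_equal(unname(countTriple(assembleLineageCounts(
        part[0, ], fx$labels, "ncptg"))), c(0L, 0L, 0L))
    expect_error(assembleLineageCounts(part, NULL, "ncptg"), "labels")
})

test_that("mean burden per megabase matches the printed tallies", {
    b <- burdenPerMb(c(514, 705), c(240, 44))
    expect_equal(b$rounded, 0.24)
    expect_equal(b$mean, mean(c(754, 749) / 3100))
    expect_equal(burdenPerMb(c(0, 0), c(0, 0))$mean, 0)
    expect_equal(burdenPerMb(310, 0)$rounded, 0.10)
    expect_error(burdenPerMb(100, genomeMb = 0), "genomeMb")
    expect_error(burdenPerMb(-1), "non-negative")
})
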