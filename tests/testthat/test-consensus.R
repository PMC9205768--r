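test_that("VCF reading honors the caller flag dialects", {
    f <- writeTinyVcf(tempfile(fileext = ".vcf"))
    strict <- readCallerVcf(f, dialect = "strict_pass")
    expect_equal(nrow(strict), 7L)          # 7 of 10 records are PASS
    som <- readCallerVcf(f, dialect = "pass_and_somatic")
    expect_equal(nrow(som), 5L)             # PASS records with SOMATIC flag
    expect_false(any(som$pos %in% c(300, 600, 900)))   # non-PASS dropped
    expect_false(any(som$pos %in% c(500, 800)))        # PASS but not somatic
    ## counts come through the AD/DP genotype fields
    expect_equal(som$tumor_alt[som$pos == 200], 12L)
    expect_equal(som$tumor_depth[som$pos == 200], 42L)
    expect_equal(som$germline_alt[som$pos == 200], 0L)
    expect_error(readCallerVcf(tempfile()), "not found")
    bad <- tempfile(); writeLines("not a vcf", bad)
    expect_error(readCallerVcf(bad), "malformed|header")
})

test_that("three-way intersection is exact, order-invariant and idempotent", {
    a <- variantRows(c(1:6, 101:104) * 10)          # 10 records
    b <- variantRows(c(1:6, 201:202) * 10)          # 8 records
    c3 <- variantRows(c(1:6, 301:303) * 10)         # 9 records
    hc <- intersectCallers(a, b, c3)
    expect_equal(nrow(hc), 6L)                      # 6 common keys
    expect_setequal(hc$pos, (1:6) * 10)
    ## order invariance
    hc2 <- intersectCallers(c3, a, b)
    expect_setequal(variantKeyOf(hc), variantKeyOf(hc2))
    ## idempotence
    expect_equal(nrow(intersectCallers(hc, hc, hc)), nrow(hc))
    ## 2/3 support is dropped
    expect_false(any(hc$pos == 1010))
    ## empty inputs allowed
    expect_equal(nrow(intersectCallers(a[0, ], b, c3)), 0L)
})

test_that("indel representation is normalized before matching", {
    x <- variantRows(100, ref = "CAA", alt = "CA")
    y <- variantRows(100, ref = "CA", alt = "C")     # same event, trimmed
    y$pos <- 100L
    expect_equal(nrow(intersectCallers(x, y, x, matchKey = "normalized")),
                 1L)
    expect_equal(nrow(intersectCallers(x, y, x, matchKey = "literal")), 0L)
})

test_that("shared/unique classification is a conservative partition", {
    a <- variantRows(1:10 * 10)
    b <- variantRows(6:15 * 10)
    part <- classifySharedUnique(a, b)
    expect_s4_class(part, "CallSetPartition")
    expect_equal(nrow(sharedVariants(part)), 5L)
    expect_equal(nrow(uniqueVariants(part)$A), 5L)
    expect_equal(nrow(uniqueVariants(part)$B), 5L)
    ## conservation: |shared| + |unique| = |input|
    expect_equal(nrow(sharedVariants(part)) + nrow(uniqueVariants(part)$A),
                 nrow(a))
    expect_equal(nrow(sharedVariants(part)) + nrow(uniqueVariants(part)$B),
                 nrow(b))
    ## identical sets -> no unique; disjoint sets -> no shared
    pid <- classifySharedUnique(a, a)
    expect_equal(nrow(uniqueVariants(pid)$A), 0L)
    expect_equal(nrow(uniqueVariants(pid)$B), 0L)
    pdisj <- classifySharedUnique(a, variantRows(100:109 * 50))
    expect_equal(nrow(sharedVariants(pdisj)), 0L)
})

test_that("VAF/depth filters fire at the stated strict thresholds", {
    v <- variantRows(1:7 * 10)
    v$multiplicity <- 1L
    v$germline_alt[1] <- 3L; v$germline_depth[1] <- 50L   # gVAF 0.06
    v$germline_alt[2] <- 2L; v$germline_depth[2] <- 40L   # gVAF 0.05 exact
    v$tumor_alt[3] <- 3L; v$tumor_depth[3] <- 34L         # tVAF 0.088
    v$tumor_alt[4] <- 2L; v$tumor_depth[4] <- 20L         # tVAF 0.10 exact
    v$tumor_depth[5] <- 19L; v$tumor_alt[5] <- 10L        # depth 19
    v$multiplicity[6] <- 0L
    v$tumor_depth[7] <- 0L; v$tumor_alt[7] <- 0L          # no coverage
    out <- filterVafDepth(v)
    expect_setequal(out$retained$pos, c(20, 40))          # exact boundaries kept
    logmap <- setNames(out$removed$reason, out$removed$key)
    expect_match(logmap[grepl(":10:", names(logmap))], "germline VAF")
    expect_match(logmap[grepl(":30:", names(logmap))], "tumor VAF")
    expect_match(logmap[grepl(":50:", names(logmap))], "depth")
    expect_match(logmap[grepl(":60:", names(logmap))], "multiplicity")
    expect_match(logmap[grepl(":70:", names(logmap))], "no coverage")
})

test_that("tightening any filter threshold never increases survivors", {
    set.seed(31)
    n <- 300
    v <- variantRows(seq_len(n) * 7,
                     tumor_alt = rbinom(n, 40, runif(n, 0.02, 0.6)),
                     tumor_depth = rpois(n, 30) + 1L,
                     germline_alt = rbinom(n, 40, 0.03),
                     germline_depth = rpois(n, 35) + 1L)
    v$multiplicity <- sample(0:2, n, replace = TRUE, prob = c(.05, .8, .15))
    base <- nrow(filterVafDepth(v)$retained)
    for (args in list(list(germlineVafMax = 0.02),
                      list(tumorVafMin = 0.2),
                      list(minDepth = 30))) {
        tightened <- nrow(do.call(filterVafDepth, c(list(v), args))$retained)
        expect_lte(tightened, base)
    }
})

test_that("SV consensus applies the two-route support rule with slop", {
    sv1 <- data.frame(chrom1 = "chr2", pos1 = 1000L, chrom2 = "chr2",
                      pos2 = 50000L, svtype = "DEL", normal_alt = 0L)
    sv2 <- data.frame(chrom1 = "chr2", pos1 = 1150L, chrom2 = "chr2",
                      pos2 = 50120L, svtype = "DEL", normal_alt = 0L)
    ## both callers, breakpoints 150 bp apart -> one merged event
    out <- mergeSvCalls(sv1, sv2, NULL)
    expect_equal(nrow(out), 1L)
    expect_equal(out$n_callers, 2L)
    ## outside the 200 bp slop -> no event survives
    sv2far <- transform(sv2, pos1 = 1300L)
    expect_equal(nrow(mergeSvCalls(sv1, sv2far, NULL)), 0L)
    ## single caller + changepoint 100 bp away -> retained
    cps <- data.frame(chrom = "chr2", pos = 1100L)
    out2 <- mergeSvCalls(sv1, NULL, cps)
    expect_equal(nrow(out2), 1L)
    expect_true(out2$changepoint_support)
    ## single caller, no changepoint -> dropped
    expect_equal(nrow(mergeSvCalls(sv1, NULL, NULL)), 0L)
    ## any alt evidence in the normal removes the call first
    expect_equal(nrow(mergeSvCalls(transform(sv1, normal_alt = 1L),
                                   transform(sv2, normal_alt = 1L), cps)),
                 0L)
    ## slop boundary: exactly 200 matches, 201 does not
    at200 <- transform(sv1, pos1 = 1200L, pos2 = 50200L)
    expect_equal(nrow(mergeSvCalls(sv1, at200, NULL)), 1L)
    at201 <- transform(sv1, pos1 = 1201L, pos2 = 50000L)
    expect_equal(nrow(mergeSvCalls(sv1, at201, NULL)), 0L)
})

test_that("changepoint BED intervals convert to 1-based positions", {
    f <- tempfile(fileext = ".bed")
    writeLines("chr2\t999\t50000", f)
    cps <- readChangepointsBed(f)
    expect_setequal(cps$pos, c(1000L, 50000L))
})
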