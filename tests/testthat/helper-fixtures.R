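## Shared fixture builders (everything is generated in code).

## minimal hand-written VCF: 10 records, 7 PASS, 5 of the PASS ones SOMATIC
writeTinyVcf <- function(path) {
    rows <- c(
        "chr1\t100\t.\tA\tG\t60\tPASS\tSOMATIC\tDP:AD\t40:20,20\t38:38,0",
        "chr1\t200\t.\tC\tT\t60\tPASS\tSOMATIC\tDP:AD\t42:30,12\t40:40,0",
        "chr1\t300\t.\tG\tA\t10\tLowQual\tSOMATIC\tDP:AD\t35:30,5\t36:36,0",
        "chr1\t400\t.\tT\tC\t60\tPASS\tSOMATIC\tDP:AD\t44:22,22\t41:41,0",
        "chr1\t500\t.\tA\tT\t60\tPASS\t.\tDP:AD\t39:19,20\t37:37,0",
        "chr1\t600\t.\tC\tA\t8\tq10\tSOMATIC\tDP:AD\t33:30,3\t35:35,0",
        "chr1\t700\t.\tG\tC\t60\tPASS\tSOMATIC\tDP:AD\t41:20,21\t39:39,0",
        "chr1\t800\t.\tT\tG\t60\tPASS\t.\tDP:AD\t37:18,19\t42:42,0",
        "chr1\t900\t.\tA\tC\t9\tLowQual\t.\tDP:AD\t36:33,3\t38:38,0",
        "chr1\t950\t.\tC\tG\t60\tPASS\tSOMATIC\tDP:AD\t45:23,22\t40:40,0")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic\">",
        "##FILTER=<ID=LowQual,Description=\"low quality\">",
        "##FILTER=<ID=q10,Description=\"q10\">",
        "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
        "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
        "##contig=<ID=chr1>",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL",
        rows), path)
    path
}

## bare variant table rows keyed by position
variantRows <- function(pos, ref = "A", alt = "G", chrom = "chr1",
                        tumor_alt = 20L, tumor_depth = 40L,
                        germline_alt = 0L, germline_depth = 40L) {
    n <- length(pos)
    data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
               ref = rep_len(ref, n), alt = rep_len(alt, n),
               vtype = "SNV",
               tumor_alt = rep_len(as.integer(tumor_alt), n),
               tumor_depth = rep_len(as.integer(tumor_depth), n),
               germline_alt = rep_len(as.integer(germline_alt), n),
               germline_depth = rep_len(as.integer(germline_depth), n),
               stringsAsFactors = FALSE)
}

variantKeyOf <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)

## planted two-dimensional twin scenario: clusters near (1,1), (1,0), (0,1)
plantedTwinScenario <- function(seed, nPer = 100, depthMean = 40) {
    set.seed(seed)
    n <- 3 * nPer
    ccfA <- c(rep(1, nPer), rep(1, nPer), rep(0, nPer))
    ccfB <- c(rep(1, nPer), rep(0, nPer), rep(1, nPer))
    dA <- rpois(n, depthMean) + 1L
    dB <- rpois(n, depthMean) + 1L
    list(alt = cbind(rbinom(n, dA, ccfA * 0.5), rbinom(n, dB, ccfB * 0.5)),
         depth = cbind(dA, dB),
         truth = cbind(ccfA, ccfB))
}

## a ClusterSolution built by hand (for pruning/pigeonhole edge cases)
manualSolution <- function(locations, assignments, alt = NULL,
                           depth = NULL, grid = seq(0, 1.25, by = 0.01)) {
    k <- nrow(locations)
    n <- length(assignments)
    counts <- tabulate(assignments, k)
    if (is.null(alt)) {
        ## likelihood tables consistent with a pure diploid m = 1 setup
        alt <- matrix(20L, n, ncol(locations))
        depth <- matrix(40L, n, ncol(locations))
    }
    lik <- lapply(seq_len(ncol(locations)), function(d) {
        p <- pmin(outer(rep(0.5, n), grid), 1)
        matrix(dbinom(rep(alt[, d], length(grid)),
                      rep(depth[, d], length(grid)), as.vector(p),
                      log = TRUE), n, length(grid))
    })
    new("ClusterSolution", locations = locations, weights = counts / n,
        assignments = as.integer(assignments),
        nDims = as.integer(ncol(locations)),
        sampleNames = c("A", "B")[seq_len(ncol(locations))],
        locationDraws = list(), logPostTrace = numeric(0),
        likTables = lik, grid = grid, params = list())
}

refFixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- twinclock:::makeReferenceSequence(20000L, 0.02,
                                                        seed = 424242L)
        cache
    }
})
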