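## Synthetic twin-pair somatic data with ground truth.
##
## The generator reproduces the statistical structure the downstream
## analysis assumes: Poisson accrual of mutations on a shared pre-MRCA
## lineage and two independent post-MRCA lineages, a configurable fraction
## of clock-like N[C>T]pG substitutions, binomial read sampling given
## depth / purity / copy number, and per-caller sensitivity and false-call
## noise.

#' Simulation parameters for a synthetic twin pair
#'
#' Time is measured in years from fertilization; sampling ages are years
#' since birth and the gestation offset (default 40 weeks = 280/365.25
#' years) is added internally, so the total mutation exposure of twin i is
#' `samplingAge_i + gestationYears`.
#'
#' @param ratePerYear mutation rate, mutations per genome per year (>= 0).
#' @param tMrcaTrue true MRCA time, years since fertilization; must lie in
#'   (0, min sampling time).
#' @param samplingAgeA,samplingAgeB ages at sampling, years since birth.
#' @param gestationYears gestation length in years.
#' @param ncptgFraction expected fraction of mutations that are clock-like
#'   N[C>T]pG substitutions.
#' @param depthMean mean sequencing depth (Poisson, truncated at >= 1).
#' @param purityA,purityB tumor purity per twin, in (0, 1].
#' @param callerSensitivity length-3 vector of per-caller detection
#'   probabilities in (0, 1].
#' @param callerFalseCalls length-3 vector of per-caller private false-call
#'   counts (non-negative integers).
#' @param seed integer RNG seed.
#' @return A validated `SimulationParams` list.
#' @examples
#' p <- simulationParams(ratePerYear = 2.5, tMrcaTrue = 0.8,
#'                       samplingAgeA = 40, samplingAgeB = 40, seed = 1)
#' @export
simulationParams <- function(ratePerYear, tMrcaTrue,
                             samplingAgeA, samplingAgeB,
                             gestationYears = 40 * 7 / 365.25,
                             ncptgFraction = 0.25,
                             depthMean = 40,
                             purityA = 1, purityB = 1,
                             callerSensitivity = c(1, 1, 1),
                             callerFalseCalls = c(0L, 0L, 0L),
                             seed = 1L) {
    if (ratePerYear < 0) stop("ratePerYear must be non-negative")
    tMax <- min(samplingAgeA, samplingAgeB) + gestationYears
    if (tMrcaTrue <= 0 || tMrcaTrue >= tMax)
        stop("tMrcaTrue must lie in (0, min sampling time = ",
             round(tMax, 3), ")")
    if (ncptgFraction < 0 || ncptgFraction > 1)
        stop("ncptgFraction must be in [0, 1]")
    if (depthMean <= 0) stop("depthMean must be positive")
    for (p in c(purityA, purityB))
        if (p <= 0 || p > 1) stop("purity must be in (0, 1]")
    if (length(callerSensitivity) != 3L ||
        any(callerSensitivity <= 0 | callerSensitivity > 1))
        stop("callerSensitivity must be three values in (0, 1]")
    if (length(callerFalseCalls) != 3L || any(callerFalseCalls < 0))
        stop("callerFalseCalls must be three non-negative integers")
    structure(list(ratePerYear = ratePerYear, tMrcaTrue = tMrcaTrue,
                   samplingAgeA = samplingAgeA, samplingAgeB = samplingAgeB,
                   gestationYears = gestationYears,
                   ncptgFraction = ncptgFraction, depthMean = depthMean,
                   purityA = purityA, purityB = purityB,
                   callerSensitivity = callerSensitivity,
                   callerFalseCalls = as.integer(callerFalseCalls),
                   seed = as.integer(seed)),
              class = "SimulationParams")
}

## Build a random sequence with a requested CpG dinucleotide density.
## Emission walks left to right: with probability q = d/(1-d) a "CG" pair
## is emitted, otherwise a single base; a lone G is never emitted directly
## after a C, so every CG dinucleotide is a deliberate one and density 0
## yields a CG-free sequence.
#' @noRd
makeReferenceSequence <- function(lengthBp, cpgDensity = 0.02, seed = 1L) {
    if (lengthBp < 1000) stop("reference length must be >= 1000 bp")
    if (cpgDensity < 0 || cpgDensity > 0.25)
        stop("cpgDensity must be in [0, 0.25]")
    set.seed(seed)
    q <- cpgDensity / (1 - cpgDensity)
    out <- character(0)
    n <- 0L
    while (n < lengthBp) {
        todo <- lengthBp - n
        steps <- max(1000L, ceiling(todo / (1 + q)))
        pair <- runif(steps) < q
        single <- sample(DNA_BASES, steps, replace = TRUE)
        noG <- sample(c("A", "C", "T"), steps, replace = TRUE)
        chunk <- character(steps)
        prevC <- if (n > 0L && substr(out[length(out)],
                      nchar(out[length(out)]), nchar(out[length(out)])) == "C")
            TRUE else FALSE
        for (i in seq_len(steps)) {
            if (pair[i]) {
                chunk[i] <- "CG"; prevC <- FALSE
            } else {
                b <- if (prevC && single[i] == "G") noG[i] else single[i]
                chunk[i] <- b
                prevC <- b == "C"
            }
        }
        out <- c(out, paste(chunk, collapse = ""))
        n <- n + sum(nchar(chunk))
    }
    seqchar <- substr(paste(out, collapse = ""), 1L, lengthBp)
    ref <- Biostrings::DNAStringSet(seqchar)
    names(ref) <- "synth1"
    ref
}

#' Write a synthetic reference FASTA fixture
#'
#' Generates a single-contig random reference whose CpG dinucleotide density
#' is controlled, and writes it as FASTA. Deterministic under `seed`:
#' repeated calls with the same arguments produce byte-identical files.
#'
#' @param path output FASTA path.
#' @param lengthBp contig length in bp (>= 1000).
#' @param cpgDensity requested CpG dinucleotides per bp, in [0, 0.25];
#'   the realized count is within ~10% of `lengthBp * cpgDensity` for
#'   non-trivial lengths, and exactly zero for density 0.
#' @param seed integer RNG seed.
#' @return Invisibly, the path written.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeReferenceFixture(fa, lengthBp = 5000, cpgDensity = 0.02, seed = 1)
#' @export
writeReferenceFixture <- function(path, lengthBp, cpgDensity = 0.02,
                                  seed = 1L) {
    ref <- makeReferenceSequence(lengthBp, cpgDensity, seed)
    Biostrings::writeXStringSet(ref, path)
    invisible(path)
}

## positions usable for a clock (N[C>T]pG) mutation: the C of each CG
## dinucleotide (plus-strand C>T) and the G (read as G>A, i.e. C>T on the
## minus strand).
#' @noRd
cpgSitePositions <- function(seqchar) {
    hits <- gregexpr("CG", seqchar, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(list(cPos = integer(), gPos = integer()))
    list(cPos = as.integer(hits), gPos = as.integer(hits) + 1L)
}

## Uniform draws without replacement, by rejection against a used-position
## mask (collisions are rare, so this stays O(1) per mutation).
#' @noRd
drawMutations <- function(n, clock, seqchar, pool) {
    out <- data.frame(chrom = character(n), pos = integer(n),
                      ref = character(n), alt = character(n),
                      context = character(n), stringsAsFactors = FALSE)
    L <- nchar(seqchar)
    nClockSites <- length(pool$clockSites)
    for (i in seq_len(n)) {
        if (clock[i]) {
            if (pool$clockRemaining <= 0L)
                stop("reference exhausted: not enough CpG sites for the ",
                     "requested clock mutations")
            repeat {
                j <- pool$clockSites[sample.int(nClockSites, 1L)]
                if (!pool$used[j]) break
            }
            pool$used[j] <- TRUE
            pool$clockRemaining <- pool$clockRemaining - 1L
            b <- substr(seqchar, j, j)
            out$pos[i] <- j
            out$ref[i] <- b
            out$alt[i] <- if (b == "C") "T" else "A"
        } else {
            repeat {
                j <- sample.int(L - 2L, 1L) + 1L
                if (!pool$used[j]) break
            }
            pool$used[j] <- TRUE
            if (pool$isClockSite[j])
                pool$clockRemaining <- pool$clockRemaining - 1L
            b <- substr(seqchar, j, j)
            alts <- setdiff(DNA_BASES, b)
            if (b == "C" && substr(seqchar, j + 1L, j + 1L) == "G")
                alts <- setdiff(alts, "T")
            if (b == "G" && substr(seqchar, j - 1L, j - 1L) == "C")
                alts <- setdiff(alts, "A")
            out$pos[i] <- j
            out$ref[i] <- b
            out$alt[i] <- sample(alts, 1L)
        }
        out$context[i] <- substr(seqchar, out$pos[i] - 1L, out$pos[i] + 1L)
    }
    out$chrom <- rep("synth1", n)
    out
}

#' Simulate the mutational history of a twin pair
#'
#' Runs the timing model generatively: the count of mutations shared by the
#' twins is Poisson with mean `rate * tMrca`, and each twin's private count
#' is Poisson with mean `rate * (samplingAge + gestation - tMrca)`. Each
#' mutation is placed on the reference (uniformly, without replacement, so
#' the lineage partition is exact) and is a clock-like N[C>T]pG substitution
#' with probability `ncptgFraction`.
#'
#' @param params a [simulationParams()] object.
#' @param reference optional `DNAStringSet` (single contig) to place
#'   mutations on; by default a 200 kb synthetic contig with CpG density
#'   0.02 is generated from the same seed.
#' @return A `TwinTruth` list with elements `shared`, `uniqueA`, `uniqueB`
#'   (data.frames with chrom, pos, ref, alt, context, lineage, ccf),
#'   `counts` (realized triple s, n_a, n_b), `reference` and `params`.
#' @examples
#' p <- simulationParams(2.5, 0.8, 40, 40, seed = 7)
#' tr <- simulateTwinHistory(p)
#' tr$counts
#' @export
simulateTwinHistory <- function(params, reference = NULL) {
    stopifnot(inherits(params, "SimulationParams"))
    set.seed(params$seed)
    if (is.null(reference))
        reference <- makeReferenceSequence(200000L, 0.02,
                                           seed = params$seed + 1L)
    seqchar <- as.character(reference[[1]])
    lam <- params$ratePerYear
    tA <- params$samplingAgeA + params$gestationYears
    tB <- params$samplingAgeB + params$gestationYears
    s <- rpois(1L, lam * params$tMrcaTrue)
    nA <- rpois(1L, lam * (tA - params$tMrcaTrue))
    nB <- rpois(1L, lam * (tB - params$tMrcaTrue))

    cpg <- cpgSitePositions(seqchar)
    L <- nchar(seqchar)
    clockSites <- c(cpg$cPos, cpg$gPos)
    clockSites <- clockSites[clockSites > 1L & clockSites < L]
    pool <- new.env(parent = emptyenv())
    pool$clockSites <- clockSites
    pool$clockRemaining <- length(clockSites)
    pool$used <- logical(L)
    pool$isClockSite <- logical(L)
    pool$isClockSite[clockSites] <- TRUE

    draw <- function(n, lineage) {
        clock <- runif(n) < params$ncptgFraction
        d <- drawMutations(n, clock, seqchar, pool)
        d$lineage <- rep(lineage, length.out = max(n, 0L))
        d$ccf <- rep(1.0, length.out = max(n, 0L))
        d[order(d$pos), , drop = FALSE]
    }
    shared <- draw(s, "shared")
    uniqueA <- draw(nA, "unique_a")
    uniqueB <- draw(nB, "unique_b")
    structure(list(shared = shared, uniqueA = uniqueA, uniqueB = uniqueB,
                   counts = c(s = s, n_a = nA, n_b = nB),
                   reference = reference, params = params),
              class = "TwinTruth")
}

#' @export
print.TwinTruth <- function(x, ...) {
    cat("TwinTruth: s =", x$counts["s"], ", n_A =", x$counts["n_a"],
        ", n_B =", x$counts["n_b"], "\n")
    invisible(x)
}

#' Simulate read-level observations for a twin pair
#'
#' Forward model for allele counts: per twin and variant, sequencing depth
#' is Poisson(`depthMean`) truncated at >= 1 and the alt read count is
#' binomial with success probability
#' `m * purity * CCF / (purity * CN_t + 2 * (1 - purity))`, the expected
#' VAF of a mutation at cancer cell fraction CCF with multiplicity `m` on a
#' segment of tumor total copy number `CN_t`. Variants private to the other
#' twin are included at CCF 0 (the coding the two-dimensional clustering
#' expects). Germline depth is drawn the same way with zero alt reads.
#'
#' @param truth a `TwinTruth` from [simulateTwinHistory()].
#' @param depthMean mean depth; default from `truth$params`.
#' @param purity length-2 vector (twin A, twin B) in (0, 1]; default from
#'   `truth$params`.
#' @param cnProfile copy-number segments as a data.frame with columns
#'   chrom, start, end, cn_total, cn_minor (1-based inclusive); default a
#'   diploid segment spanning the reference. Every variant must fall in a
#'   segment.
#' @param seed RNG seed (default `truth$params$seed + 2`).
#' @return A long-format data.frame, one row per variant per twin, with
#'   true CCF, copy number, multiplicity, tumor depth / alt reads and
#'   germline depth / alt reads.
#' @export
simulateObservations <- function(truth, depthMean = NULL, purity = NULL,
                                 cnProfile = NULL, seed = NULL) {
    stopifnot(inherits(truth, "TwinTruth"))
    p <- truth$params
    if (is.null(depthMean)) depthMean <- p$depthMean
    if (is.null(purity)) purity <- c(p$purityA, p$purityB)
    if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
    if (is.null(seed)) seed <- p$seed + 2L
    set.seed(seed)
    if (is.null(cnProfile))
        cnProfile <- data.frame(chrom = names(truth$reference)[1], start = 1L,
                                end = Biostrings::width(truth$reference)[1],
                                cn_total = 2L, cn_minor = 1L)
    allv <- rbind(truth$shared, truth$uniqueA, truth$uniqueB)
    if (!nrow(allv)) {
        return(data.frame(twin = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), context = character(),
                          lineage = character(), ccf_true = numeric(),
                          cn_total = integer(), multiplicity = integer(),
                          depth = integer(), alt_reads = integer(),
                          germline_depth = integer(),
                          germline_alt = integer(), stringsAsFactors = FALSE))
    }
    seg <- findSegment(allv$chrom, allv$pos, cnProfile)
    if (anyNA(seg$cn_total))
        stop("variant(s) outside every copy-number segment")
    rtpois <- function(n, mu) {
        d <- rpois(n, mu)
        while (any(d == 0L)) d[d == 0L] <- rpois(sum(d == 0L), mu)
        d
    }
    res <- lapply(c(A = 1L, B = 2L), function(k) {
        twin <- c("A", "B")[k]
        ccf <- ifelse(allv$lineage == "shared", 1,
                      ifelse(allv$lineage == paste0("unique_", tolower(twin)),
                             1, 0))
        rho <- purity[k]
        m <- pmin(1L, seg$cn_total)
        vaf <- m * rho * ccf / (rho * seg$cn_total + 2 * (1 - rho))
        depth <- rtpois(nrow(allv), depthMean)
        alt <- rbinom(nrow(allv), depth, vaf)
        gdepth <- rtpois(nrow(allv), depthMean)
        data.frame(twin = twin, chrom = allv$chrom, pos = allv$pos,
                   ref = allv$ref, alt = allv$alt, context = allv$context,
                   lineage = allv$lineage, ccf_true = ccf,
                   cn_total = seg$cn_total, multiplicity = m,
                   depth = depth, alt_reads = alt,
                   germline_depth = gdepth,
                   germline_alt = rep(0L, nrow(allv)),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    attr(out, "purity") <- setNames(purity, c("A", "B"))
    out
}

## match positions into 1-based inclusive segments
#' @noRd
findSegment <- function(chrom, pos, cnProfile) {
    cn_total <- rep(NA_integer_, length(pos))
    cn_minor <- rep(NA_integer_, length(pos))
    for (i in seq_len(nrow(cnProfile))) {
        hit <- chrom == cnProfile$chrom[i] & pos >= cnProfile$start[i] &
            pos <= cnProfile$end[i]
        cn_total[hit] <- cnProfile$cn_total[i]
        cn_minor[hit] <- cnProfile$cn_minor[i]
    }
    data.frame(cn_total = cn_total, cn_minor = cn_minor)
}

#' Emit per-caller VCF call sets for a simulated twin pair
#'
#' Writes, for each twin, three somatic VCF 4.2 files (one per emulated
#' caller, samples TUMOR and NORMAL, records flagged `PASS` with the
#' `SOMATIC` INFO key) plus one germline VCF. Each true variant enters
#' caller k's file with probability `callerSensitivity[k]`;
#' `callerFalseCalls[k]` false calls, private to that caller and never
#' colliding with a true variant position, are added. The RNG seed is
#' recorded in every header.
#'
#' @param observed output of [simulateObservations()].
#' @param reference the reference the variants were placed on.
#' @param dir output directory (created if needed).
#' @param callerSensitivity,callerFalseCalls per-caller noise settings;
#'   defaults from the simulation parameters are not carried by `observed`,
#'   so pass them explicitly (defaults: perfect callers).
#' @param seed RNG seed.
#' @return Named list of file paths:
#'   `A = c(caller1, caller2, caller3, germline)`, likewise `B`.
#' @export
emitCallerCallsets <- function(observed, reference, dir,
                               callerSensitivity = c(1, 1, 1),
                               callerFalseCalls = c(0L, 0L, 0L),
                               seed = 1L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)
    seqchar <- as.character(reference[[1]])
    contig <- names(reference)[1]
    truthPos <- unique(observed$pos)
    out <- list()
    for (twin in c("A", "B")) {
        tw <- observed[observed$twin == twin & observed$alt_reads > 0L, ,
                       drop = FALSE]
        paths <- character(4L)
        for (k in 1:3) {
            keep <- runif(nrow(tw)) < callerSensitivity[k]
            calls <- tw[keep, , drop = FALSE]
            nf <- callerFalseCalls[k]
            if (nf > 0L) {
                cand <- setdiff(seq(2L, nchar(seqchar) - 1L), truthPos)
                fpos <- sort(sample(cand, nf))
                truthPos <- c(truthPos, fpos)  # keep false calls caller-private
                refb <- vapply(fpos, function(j) substr(seqchar, j, j), "")
                altb <- vapply(refb, function(b)
                    sample(setdiff(DNA_BASES, b), 1L), "")
                fd <- pmax(1L, rpois(nf, mean(observed$depth)))
                falseCalls <- data.frame(twin = twin, chrom = contig,
                    pos = fpos, ref = refb, alt = altb, context = NA,
                    lineage = "false_call", ccf_true = 0, cn_total = 2L,
                    multiplicity = 1L, depth = fd,
                    alt_reads = pmax(1L, rbinom(nf, fd, 0.25)),
                    germline_depth = pmax(1L, rpois(nf, mean(observed$depth))),
                    germline_alt = 0L, stringsAsFactors = FALSE)
                calls <- rbind(calls, falseCalls)
            }
            calls <- calls[order(calls$pos), , drop = FALSE]
            paths[k] <- file.path(dir,
                sprintf("twin%s_caller%d.vcf", twin, k))
            writeSomaticVcf(calls, paths[k], contig, seed, somatic = TRUE)
        }
        paths[4] <- file.path(dir, sprintf("twin%s_germline.vcf", twin))
        gl <- tw[order(tw$pos), , drop = FALSE]
        writeSomaticVcf(gl, paths[4], contig, seed, somatic = FALSE,
                        germlineOnly = TRUE)
        out[[twin]] <- setNames(paths,
            c("caller1", "caller2", "caller3", "germline"))
    }
    out
}

## Minimal two-sample somatic VCF writer on top of VariantAnnotation.
## writeVcf() emits ##fileDate before ##fileformat, which htslib rejects,
## so the header is reordered after writing.
#' @noRd
writeSomaticVcf <- function(calls, path, contig, seed, somatic = TRUE,
                            germlineOnly = FALSE) {
    n <- nrow(calls)
    samples <- if (germlineOnly) "NORMAL" else c("TUMOR", "NORMAL")
    hdr <- VariantAnnotation::VCFHeader(samples = samples)
    VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
        META = S4Vectors::DataFrame(
            Value = c("VCFv4.2", as.character(seed)),
            row.names = c("fileformat", "twinclock_seed")))
    VariantAnnotation::info(hdr) <- S4Vectors::DataFrame(
        Number = "0", Type = "Flag",
        Description = "Somatic variant", row.names = "SOMATIC")
    VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
        Number = c("1", "R"), Type = c("Integer", "Integer"),
        Description = c("Read depth", "Allelic depths (ref, alt)"),
        row.names = c("DP", "AD"))
    gr <- GenomicRanges::GRanges(rep(contig, n),
                                 IRanges::IRanges(calls$pos, width = 1L))
    mkAD <- function(d) {
        m <- matrix(vector("list", n * length(samples)), nrow = n,
                    dimnames = list(NULL, samples))
        for (i in seq_len(n)) {
            vals <- list(TUMOR = c(d$depth[i] - d$alt_reads[i],
                                   d$alt_reads[i]),
                         NORMAL = c(d$germline_depth[i] - d$germline_alt[i],
                                    d$germline_alt[i]))
            for (s in samples) m[i, s] <- vals[s]
        }
        m
    }
    dp <- matrix(NA_integer_, nrow = n, ncol = length(samples),
                 dimnames = list(NULL, samples))
    if ("TUMOR" %in% samples) dp[, "TUMOR"] <- calls$depth
    dp[, "NORMAL"] <- calls$germline_depth
    vcf <- VariantAnnotation::VCF(
        rowRanges = gr,
        colData = S4Vectors::DataFrame(Samples = seq_along(samples),
                                       row.names = samples),
        exptData = list(header = hdr),
        fixed = S4Vectors::DataFrame(
            REF = Biostrings::DNAStringSet(calls$ref),
            ALT = do.call(Biostrings::DNAStringSetList,
                          as.list(calls$alt)),
            QUAL = rep(100, n), FILTER = rep("PASS", n)),
        info = S4Vectors::DataFrame(SOMATIC = rep(somatic, n)),
        geno = S4Vectors::SimpleList(DP = dp, AD = mkAD(calls)))
    VariantAnnotation::writeVcf(vcf, path)
    l <- readLines(path)
    i <- grep("^##fileformat", l)[1]
    if (!is.na(i) && i != 1L) writeLines(c(l[i], l[-i]), path)
    invisible(path)
}
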