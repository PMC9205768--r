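## Consensus somatic call-set construction across callers and twins.

#' Read one caller's somatic VCF
#'
#' Loads a somatic VCF and keeps only records that satisfy the caller's
#' flag dialect: `"pass_and_somatic"` requires `FILTER == "PASS"` and the
#' `SOMATIC` INFO flag (the convention of callers that mark somatic status
#' explicitly), `"strict_pass"` requires only `FILTER == "PASS"`.
#' Multi-allelic records are split into bi-allelic variants. Tumor and
#' germline allele counts are taken from the `AD`/`DP` genotype fields of
#' the named samples when present.
#'
#' @param path VCF file.
#' @param dialect `"pass_and_somatic"` or `"strict_pass"`.
#' @param tumorSample,normalSample sample column names; counts are NA when
#'   a sample is absent.
#' @return A variant data.frame with columns chrom, pos, ref, alt, vtype,
#'   tumor_alt, tumor_depth, germline_alt, germline_depth.
#' @examples
#' \dontrun{readCallerVcf("caller1.vcf", dialect = "pass_and_somatic")}
#' @export
readCallerVcf <- function(path, dialect = c("pass_and_somatic", "strict_pass"),
                          tumorSample = "TUMOR", normalSample = "NORMAL") {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("VCF not found: ", path)
    vcf <- tryCatch(
        VariantAnnotation::readVcf(path, genome = "unknown"),
        error = function(e) stop("malformed VCF '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    vcf <- VariantAnnotation::expand(vcf)
    filt <- VariantAnnotation::filt(vcf)
    keep <- filt == "PASS"
    if (dialect == "pass_and_somatic") {
        som <- if ("SOMATIC" %in% names(VariantAnnotation::info(vcf)))
            VariantAnnotation::info(vcf)$SOMATIC else
            rep(FALSE, length(keep))
        som[is.na(som)] <- FALSE
        keep <- keep & som
    }
    vcf <- vcf[keep]
    n <- nrow(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    getCounts <- function(sample) {
        if (!sample %in% colnames(vcf) || n == 0L)
            return(list(alt = rep(NA_integer_, n),
                        depth = rep(NA_integer_, n)))
        ad <- VariantAnnotation::geno(vcf)$AD
        if (length(dim(ad)) == 3L) {        # expand() yields (rec, sample, allele)
            alt <- as.integer(ad[, sample, 2L])
            adSum <- as.integer(ad[, sample, 1L]) + alt
        } else {
            adl <- ad[, sample]
            alt <- vapply(adl, function(x)
                if (length(x) >= 2L) as.integer(x[2L]) else NA_integer_,
                integer(1))
            adSum <- vapply(adl, function(x) as.integer(sum(x)), integer(1))
        }
        depth <- if ("DP" %in% names(VariantAnnotation::geno(vcf)))
            as.integer(VariantAnnotation::geno(vcf)$DP[, sample])
        else adSum
        list(alt = alt, depth = depth)
    }
    tum <- getCounts(tumorSample)
    nor <- getCounts(normalSample)
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- as.character(VariantAnnotation::alt(vcf))
    data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
               pos = GenomicRanges::start(rr), ref = ref, alt = alt,
               vtype = variantType(ref, alt),
               tumor_alt = tum$alt, tumor_depth = tum$depth,
               germline_alt = nor$alt, germline_depth = nor$depth,
               stringsAsFactors = FALSE)
}

#' Intersect three callers' somatic call sets
#'
#' The high-confidence call set is the exact intersection of the three
#' per-caller call sets: a variant is retained only when all three callers
#' report it under the match key (chrom, pos, ref, alt), after
#' multi-allelic splitting and, in `"normalized"` mode, trimming of
#' redundant indel allele representation. Allele counts are carried from
#' the first call set.
#'
#' @param calls1,calls2,calls3 variant data.frames from [readCallerVcf()].
#' @param matchKey `"normalized"` (default) or `"literal"` allele matching.
#' @return The subset of `calls1` present in all three call sets, with a
#'   `callers` column recording support (always 3 on output).
#' @export
intersectCallers <- function(calls1, calls2, calls3,
                             matchKey = c("normalized", "literal")) {
    matchKey <- match.arg(matchKey)
    for (d in list(calls1, calls2, calls3))
        assertColumns(d, c("chrom", "pos", "ref", "alt"), "call set")
    k1 <- variantKey(calls1, matchKey)
    keep <- k1 %in% variantKey(calls2, matchKey) &
        k1 %in% variantKey(calls3, matchKey)
    out <- calls1[keep, , drop = FALSE]
    out$callers <- rep(3L, nrow(out))
    rownames(out) <- NULL
    out
}

#' Classify consensus variants as twin-shared or twin-unique
#'
#' Compares the two twins' high-confidence call sets under the match key
#' and partitions them into variants present in both twins and variants
#' private to each twin. The partition is conservative:
#' `|shared| + |uniqueA| = |setA|` and `|shared| + |uniqueB| = |setB|`.
#' Shared rows carry twin A's counts as `*_a` columns and twin B's as
#' `*_b` columns.
#'
#' @param setA,setB variant data.frames for twin A and twin B.
#' @param matchKey `"normalized"` or `"literal"`.
#' @return A [CallSetPartition-class] object.
#' @export
classifySharedUnique <- function(setA, setB,
                                 matchKey = c("normalized", "literal")) {
    matchKey <- match.arg(matchKey)
    kA <- variantKey(setA, matchKey)
    kB <- variantKey(setB, matchKey)
    inB <- kA %in% kB
    shared <- setA[inB, , drop = FALSE]
    if (nrow(shared)) {
        idx <- match(kA[inB], kB)
        for (col in c("tumor_alt", "tumor_depth", "germline_alt",
                      "germline_depth"))
            if (col %in% names(setA) && col %in% names(setB)) {
                names(shared)[names(shared) == col] <- paste0(col, "_a")
                shared[[paste0(col, "_b")]] <- setB[[col]][idx]
            }
    }
    uniqueA <- setA[!inB, , drop = FALSE]
    uniqueB <- setB[!(kB %in% kA), , drop = FALSE]
    rownames(shared) <- rownames(uniqueA) <- rownames(uniqueB) <- NULL
    new("CallSetPartition", shared = shared, uniqueA = uniqueA,
        uniqueB = uniqueB, matchKey = matchKey)
}

#' Flag-and-remove filters on allele frequency, depth and multiplicity
#'
#' Applies the per-variant quality filters used before clustering: a
#' variant is removed when its germline VAF exceeds `germlineVafMax`, its
#' tumor VAF is below `tumorVafMin`, its tumor depth is below `minDepth`,
#' or (when `requireMultiplicity`) its mutation multiplicity estimate is
#' zero. All thresholds are strict (`>` / `<`), so a tumor VAF of exactly
#' 0.1 at depth exactly 20 survives. Tumor VAF is `tumor_alt/tumor_depth`
#' from the record's own counts; a tumor depth of zero removes the record
#' with reason `"no coverage"`. The removal log records the first rule
#' that fired for each removed variant; rule order is germline VAF, tumor
#' VAF, depth, multiplicity.
#'
#' @param variants variant data.frame with count columns (and
#'   `multiplicity` when `requireMultiplicity = TRUE`).
#' @param germlineVafMax remove when germline VAF strictly exceeds this.
#' @param tumorVafMin remove when tumor VAF is strictly below this.
#' @param minDepth remove when tumor depth is strictly below this.
#' @param requireMultiplicity remove multiplicity-zero records.
#' @return list with elements `retained` (surviving variants) and
#'   `removed` (removal log: variant key + reason).
#' @export
filterVafDepth <- function(variants, germlineVafMax = 0.05,
                           tumorVafMin = 0.1, minDepth = 20,
                           requireMultiplicity = TRUE) {
    assertColumns(variants, c("tumor_alt", "tumor_depth"), "variant table")
    if (requireMultiplicity)
        assertColumns(variants, "multiplicity", "variant table")
    n <- nrow(variants)
    reason <- rep(NA_character_, n)
    gvaf <- if (all(c("germline_alt", "germline_depth") %in% names(variants)))
        variants$germline_alt / pmax(variants$germline_depth, 1L)
    else rep(0, n)
    gvaf[is.na(gvaf)] <- 0
    tdepth <- variants$tumor_depth
    tvaf <- ifelse(tdepth > 0, variants$tumor_alt / tdepth, NA_real_)
    mark <- function(cond, why) {
        hit <- is.na(reason) & cond & !is.na(cond)
        reason[hit] <<- why
    }
    mark(tdepth == 0L, "no coverage")
    mark(gvaf > germlineVafMax, "germline VAF")
    mark(tvaf < tumorVafMin, "tumor VAF")
    mark(tdepth < minDepth, "depth")
    if (requireMultiplicity) mark(variants$multiplicity == 0L, "multiplicity")
    removed <- data.frame(key = variantKey(variants)[!is.na(reason)],
                          reason = reason[!is.na(reason)],
                          stringsAsFactors = FALSE)
    retained <- variants[is.na(reason), , drop = FALSE]
    rownames(retained) <- NULL
    list(retained = retained, removed = removed)
}
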