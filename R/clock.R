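## Clock-like N[C>T]pG mutation identification and lineage count assembly.

#' Classify variants as clock-like N[C>T]pG substitutions
#'
#' A mutation is clock-like when, in its pyrimidine-strand representation,
#' it is a C>T substitution whose reference 3' neighbor is G (any 5' base)
#' — the product of spontaneous deamination of 5-methylcytosine at CpG
#' dinucleotides. Plus-strand G>A variants are strand-normalized: they
#' qualify when the reference 5' neighbor is C. Indels and other
#' substitutions are never clock mutations. Variants at a contig edge
#' (no neighbor to inspect) return FALSE with a warning; a reference
#' base that contradicts the stated ref allele is an error.
#'
#' @param variants data.frame with chrom, pos, ref, alt.
#' @param reference named `DNAStringSet` (or FASTA path) supplying the
#'   reference context.
#' @return logical vector, one value per variant.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "AACGT"))
#' v <- data.frame(chrom = "chr1", pos = 3, ref = "C", alt = "T")
#' classifyNcptg(v, ref)   # A[C]G with C>T -> TRUE
#' @export
classifyNcptg <- function(variants, reference) {
    assertColumns(variants, c("chrom", "pos", "ref", "alt"), "variant table")
    if (is.character(reference))
        reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
    n <- nrow(variants)
    out <- logical(n)
    edge <- FALSE
    for (i in seq_len(n)) {
        if (nchar(variants$ref[i]) != 1L || nchar(variants$alt[i]) != 1L)
            next                                   # indels are never clock
        chrom <- variants$chrom[i]
        if (!chrom %in% names(reference))
            stop("contig '", chrom, "' not in reference")
        seq <- reference[[chrom]]
        pos <- variants$pos[i]
        refBase <- as.character(Biostrings::subseq(seq, pos, pos))
        if (refBase != variants$ref[i])
            stop("reference mismatch at ", chrom, ":", pos, " (reference ",
                 refBase, ", variant says ", variants$ref[i], ")")
        if (pos <= 1L || pos >= length(seq)) { edge <- TRUE; next }
        if (variants$ref[i] == "C" && variants$alt[i] == "T") {
            out[i] <- as.character(Biostrings::subseq(seq, pos + 1L,
                                                      pos + 1L)) == "G"
        } else if (variants$ref[i] == "G" && variants$alt[i] == "A") {
            out[i] <- as.character(Biostrings::subseq(seq, pos - 1L,
                                                      pos - 1L)) == "C"
        }
    }
    if (edge)
        warning("variant(s) at a contig edge classified FALSE ",
                "(no neighbor base)")
    out
}

## ncptg status from a stored 3-mer reference context string
#' @noRd
ncptgFromContext <- function(ref, alt, context) {
    ok <- nchar(ref) == 1L & nchar(alt) == 1L & !is.na(context) &
        nchar(context) == 3L
    ct <- ref == "C" & alt == "T" & substr(context, 3L, 3L) == "G"
    ga <- ref == "G" & alt == "A" & substr(context, 1L, 1L) == "C"
    ok & (ct | ga)
}

#' Assemble the lineage-restricted count triple for the timing model
#'
#' Counts the mutations inferred to lie on the MPN cell lineage in each
#' twin: the shared (pre-MRCA) count `s` takes mutations shared by the
#' twins that belong to the ancestral cluster, and each twin's unique
#' (post-MRCA) count takes that twin's private mutations in clusters on
#' its lineage (CCF above the pigeonhole cutoff, i.e. labels
#' `lineage_<twin>` or `ancestral`). A minimum-depth filter and, for
#' `contextFilter = "ncptg"`, the clock-context filter are applied first;
#' the full filter trail is recorded in the provenance.
#'
#' @param partition a [CallSetPartition-class], or a data.frame with a
#'   `lineage` column (`"shared"`, `"unique_a"`, `"unique_b"`).
#'   Rows need a `cluster` column matching `lineageLabels$cluster`.
#' @param lineageLabels data.frame from [assignLineagesPigeonhole()]
#'   (columns `cluster` and `label`).
#' @param contextFilter `"all_clonal"` (no context restriction) or
#'   `"ncptg"` (clock-like substitutions only; classified from a
#'   `context` 3-mer column, an `is_ncptg` column, or `reference`).
#' @param minDepth minimum tumor depth; rows below it are dropped. Shared
#'   rows are checked in both twins when per-twin depth columns
#'   (`depth_a`, `depth_b`) are present; rows without depth columns are
#'   not depth-filtered.
#' @param reference optional reference for context classification.
#' @return A [LineageCounts-class] object.
#' @export
assembleLineageCounts <- function(partition, lineageLabels,
                                  contextFilter = c("all_clonal", "ncptg"),
                                  minDepth = 20, reference = NULL) {
    contextFilter <- match.arg(contextFilter)
    if (is(partition, "CallSetPartition")) {
        tag <- function(d, lin) { if (nrow(d)) d$lineage <- lin; d }
        cols <- function(d) d[, intersect(names(d),
            c("chrom", "pos", "ref", "alt", "lineage", "cluster", "context",
              "is_ncptg", "depth_a", "depth_b", "multiplicity")),
            drop = FALSE]
        partition <- do.call(rbind, lapply(list(
            tag(partition@shared, "shared"),
            tag(partition@uniqueA, "unique_a"),
            tag(partition@uniqueB, "unique_b")), cols))
    }
    if (is.null(lineageLabels) || !nrow(lineageLabels))
        stop("lineage labels are required (run assignLineagesPigeonhole)")
    assertColumns(lineageLabels, c("cluster", "label"), "lineage labels")
    prov <- list(input = nrow(partition))
    if (!nrow(partition))
        return(lineageCounts(0L, 0L, 0L, contextFilter,
                             provenance = prov))
    assertColumns(partition, c("lineage", "cluster"), "partition")

    ## depth filter (strict <)
    if (all(c("depth_a", "depth_b") %in% names(partition))) {
        dA <- partition$depth_a; dB <- partition$depth_b
        ok <- ifelse(partition$lineage == "shared",
                     dA >= minDepth & dB >= minDepth,
              ifelse(partition$lineage == "unique_a", dA >= minDepth,
                     dB >= minDepth))
        ok[is.na(ok)] <- TRUE
        partition <- partition[ok, , drop = FALSE]
    }
    prov$after_depth <- nrow(partition)
    if ("multiplicity" %in% names(partition)) {
        partition <- partition[is.na(partition$multiplicity) |
                               partition$multiplicity > 0L, , drop = FALSE]
    }
    prov$after_multiplicity <- nrow(partition)

    ## context filter
    if (contextFilter == "ncptg") {
        isClock <- if ("is_ncptg" %in% names(partition))
            partition$is_ncptg
        else if ("context" %in% names(partition))
            ncptgFromContext(partition$ref, partition$alt, partition$context)
        else if (!is.null(reference))
            classifyNcptg(partition, reference)
        else stop("ncptg filtering needs a context/is_ncptg column or a ",
                  "reference")
        partition <- partition[isClock, , drop = FALSE]
    }
    prov$after_context <- nrow(partition)

    lab <- lineageLabels$label[match(partition$cluster,
                                     lineageLabels$cluster)]
    if (anyNA(lab))
        stop("partition rows reference cluster(s) without a lineage label")
    s <- sum(partition$lineage == "shared" & lab == "ancestral")
    nA <- sum(partition$lineage == "unique_a" &
              lab %in% c("lineage_a", "ancestral"))
    nB <- sum(partition$lineage == "unique_b" &
              lab %in% c("lineage_b", "ancestral"))
    prov$on_lineage <- c(s = s, n_a = nA, n_b = nB)
    lineageCounts(s, nA, nB, contextFilter, provenance = prov)
}

#' Mean genome-wide small-variant burden per megabase
#'
#' Mean over samples of `(SNV + indel) / genomeMb`. The SNV-only rate is
#' returned alongside, since "substitution rate" can be read either way;
#' with per-twin totals of several hundred SNVs plus indels over a ~3.1 Gb
#' genome, the combined small-variant figure is the one that reproduces a
#' two-decimal burden of ~0.24/Mb.
#'
#' @param snvCounts per-sample SNV counts.
#' @param indelCounts per-sample indel counts (default 0).
#' @param genomeMb genome size in Mb (default 3100).
#' @return list with `mean` (full precision), `rounded` (2 decimals),
#'   `perSample`, and `meanSnvOnly`.
#' @examples
#' burdenPerMb(c(514, 705), c(240, 44))$rounded   # 0.24
#' @export
burdenPerMb <- function(snvCounts, indelCounts = 0, genomeMb = 3100) {
    if (genomeMb <= 0) stop("genomeMb must be positive")
    if (any(snvCounts < 0) || any(indelCounts < 0))
        stop("counts must be non-negative")
    indelCounts <- rep_len(indelCounts, length(snvCounts))
    per <- (snvCounts + indelCounts) / genomeMb
    list(mean = mean(per), rounded = round(mean(per), 2), perSample = per,
         meanSnvOnly = mean(snvCounts / genomeMb))
}
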