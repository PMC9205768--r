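## Structural-variant consensus under the two-route support rule.

#' Merge structural-variant calls from two callers
#'
#' Builds the high-confidence SV set from two callers' breakpoint lists.
#' SVs with any alt read evidence in the matched normal are removed first.
#' Two calls match when they have the same SV type, the same chromosome
#' pair, and both breakpoints within a bidirectional slop (default 200 bp);
#' chains of pairwise matches are merged transitively into one event. An
#' event is retained when it is supported by both callers, or by a single
#' caller plus a copy-number changepoint within the same slop of either
#' breakpoint.
#'
#' @param caller1Svs,caller2Svs data.frames with columns chrom1, pos1,
#'   chrom2, pos2, svtype and optionally normal_alt (alt evidence in the
#'   normal, default 0).
#' @param cnvChangepoints data.frame with columns chrom, pos (1-based), or
#'   NULL for none.
#' @param slopBp breakpoint matching tolerance in bp.
#' @return data.frame of consensus events: representative breakpoints
#'   (first member), svtype, n_callers, changepoint support flag and
#'   member count.
#' @export
mergeSvCalls <- function(caller1Svs, caller2Svs, cnvChangepoints = NULL,
                         slopBp = 200) {
    cols <- c("chrom1", "pos1", "chrom2", "pos2", "svtype")
    fill <- function(d, id) {
        if (is.null(d) || !nrow(d)) {
            d <- data.frame(chrom1 = character(), pos1 = integer(),
                            chrom2 = character(), pos2 = integer(),
                            svtype = character(), normal_alt = integer(),
                            caller = integer(), stringsAsFactors = FALSE)
            return(d)
        }
        assertColumns(d, cols, "SV call set")
        if (!"normal_alt" %in% names(d)) d$normal_alt <- 0L
        d$caller <- id
        d[, c(cols, "normal_alt", "caller")]
    }
    svs <- rbind(fill(caller1Svs, 1L), fill(caller2Svs, 2L))
    svs <- svs[svs$normal_alt == 0L, , drop = FALSE]   # normal-evidence filter
    n <- nrow(svs)
    if (!n) return(cbind(svs[, cols], n_callers = integer(),
                         changepoint_support = logical(),
                         n_members = integer()))
    ## pairwise matches -> transitive components
    edges <- matrix(integer(), ncol = 2)
    if (n > 1L) {
        pairs <- which(outer(seq_len(n), seq_len(n), "<"), arr.ind = TRUE)
        i <- pairs[, 1]; j <- pairs[, 2]
        ok <- svs$svtype[i] == svs$svtype[j] &
            svs$chrom1[i] == svs$chrom1[j] &
            svs$chrom2[i] == svs$chrom2[j] &
            abs(svs$pos1[i] - svs$pos1[j]) <= slopBp &
            abs(svs$pos2[i] - svs$pos2[j]) <= slopBp
        edges <- cbind(i[ok], j[ok])
    }
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
    nearChangepoint <- function(idx) {
        if (is.null(cnvChangepoints) || !nrow(cnvChangepoints)) return(FALSE)
        any(vapply(idx, function(k) {
            any((cnvChangepoints$chrom == svs$chrom1[k] &
                 abs(cnvChangepoints$pos - svs$pos1[k]) <= slopBp) |
                (cnvChangepoints$chrom == svs$chrom2[k] &
                 abs(cnvChangepoints$pos - svs$pos2[k]) <= slopBp))
        }, logical(1)))
    }
    out <- lapply(seq_len(max(comp)), function(cid) {
        idx <- which(comp == cid)
        ncall <- length(unique(svs$caller[idx]))
        cp <- nearChangepoint(idx)
        if (ncall < 2L && !cp) return(NULL)
        rep1 <- idx[1L]
        data.frame(chrom1 = svs$chrom1[rep1], pos1 = svs$pos1[rep1],
                   chrom2 = svs$chrom2[rep1], pos2 = svs$pos2[rep1],
                   svtype = svs$svtype[rep1], n_callers = ncall,
                   changepoint_support = cp, n_members = length(idx),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(chrom1 = character(), pos1 = integer(),
                          chrom2 = character(), pos2 = integer(),
                          svtype = character(), n_callers = integer(),
                          changepoint_support = logical(),
                          n_members = integer(), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Read copy-number changepoints from a BED file
#'
#' BED intervals are 0-based half-open; each interval start and end is
#' converted to a 1-based changepoint position.
#'
#' @param path BED file (chrom, start, end).
#' @return data.frame with columns chrom, pos.
#' @export
readChangepointsBed <- function(path) {
    bed <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    if (ncol(bed) < 3L) stop("BED needs chrom, start, end")
    data.frame(chrom = rep(bed[[1]], 2L),
               pos = c(bed[[2]] + 1L, bed[[3]]),
               stringsAsFactors = FALSE)
}
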