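## Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
variantType <- function(ref, alt) {
    ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "indel")
}

## Trim a shared allele suffix, then a shared prefix (keeping at least one
## base), adjusting pos for the trimmed prefix. This normalizes redundant
## indel representations (e.g. pos 100 CAA>CA vs pos 100 CA>C) to one key;
## it does not left-align against the reference.
#' @noRd
normalizeAllele <- function(pos, ref, alt) {
    pos <- as.integer(pos)
    for (i in seq_along(pos)) {
        r <- ref[i]; a <- alt[i]
        while (nchar(r) > 1L && nchar(a) > 1L &&
               substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
            r <- substr(r, 1L, nchar(r) - 1L)
            a <- substr(a, 1L, nchar(a) - 1L)
        }
        while (nchar(r) > 1L && nchar(a) > 1L &&
               substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
            r <- substr(r, 2L, nchar(r))
            a <- substr(a, 2L, nchar(a))
            pos[i] <- pos[i] + 1L
        }
        ref[i] <- r; alt[i] <- a
    }
    list(pos = pos, ref = ref, alt = alt)
}

#' @noRd
variantKey <- function(df, matchKey = c("normalized", "literal")) {
    matchKey <- match.arg(matchKey)
    if (!nrow(df)) return(character())
    if (matchKey == "normalized") {
        nm <- normalizeAllele(df$pos, df$ref, df$alt)
        paste(df$chrom, nm$pos, nm$ref, nm$alt, sep = ":")
    } else {
        paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
    }
}

#' @noRd
emptyVariantTable <- function() {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), vtype = character(),
               tumor_alt = integer(), tumor_depth = integer(),
               germline_alt = integer(), germline_depth = integer(),
               stringsAsFactors = FALSE)
}

#' @noRd
assertColumns <- function(df, cols, what = "input") {
    miss <- setdiff(cols, names(df))
    if (length(miss))
        stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
             call. = FALSE)
    invisible(df)
}

## round-half-up (base round() is round-half-even)
#' @noRd
roundHalfUp <- function(x) floor(x + 0.5)

#' @noRd
logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

## md5 of an in-memory character vector, via a temp file (tools::md5sum
## wants a path)
#' @noRd
md5OfLines <- function(lines) {
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(lines, f)
    unname(tools::md5sum(f))
}

## Convert a calendar age given as years, months, days to decimal years.
#' @export
#' @rdname timingConfig
ageToYears <- function(years, months = 0, days = 0) {
    years + months / 12 + days / 365.25
}
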