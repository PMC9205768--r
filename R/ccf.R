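## VAF -> cancer cell fraction conversion and per-mutation statistics.

#' Estimate mutation multiplicity
#'
#' The multiplicity m is the number of mutated chromosome copies per tumor
#' cell. It is estimated from the VAF by inverting the expected-VAF
#' relation at CCF 1:
#' `m = round(vaf * (purity * CN_t + cnNormal * (1 - purity)) / purity)`,
#' rounded half-up and clamped to `[1, CN_t]`. A VAF of exactly zero
#' returns 0. Sites with `CN_t = 0` (homozygous deletion) are unmappable
#' and return NA with a warning; such records are excluded downstream.
#'
#' @param vaf variant allele frequency in [0, 1] (vectorized).
#' @param purity tumor purity in (0, 1].
#' @param cnTotal tumor total copy number at the site.
#' @param cnNormal normal copy number (default 2).
#' @return integer multiplicity, same length as `vaf`.
#' @examples
#' estimateMultiplicity(0.5, 1, 2)   # 1
#' estimateMultiplicity(0.9, 1, 2)   # 2
#' @export
estimateMultiplicity <- function(vaf, purity, cnTotal, cnNormal = 2) {
    if (any(vaf < 0 | vaf > 1)) stop("vaf must be in [0, 1]")
    if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
    n <- max(length(vaf), length(purity), length(cnTotal))
    vaf <- rep_len(vaf, n); purity <- rep_len(purity, n)
    cnTotal <- rep_len(cnTotal, n)
    m <- roundHalfUp(vaf * (purity * cnTotal + cnNormal * (1 - purity)) /
                     purity)
    m <- pmin(pmax(m, 1), cnTotal)
    m[vaf == 0] <- 0
    if (any(cnTotal == 0)) {
        warning("CN_t = 0 at ", sum(cnTotal == 0),
                " site(s): multiplicity unmappable (NA)")
        m[cnTotal == 0] <- NA_integer_
    }
    as.integer(m)
}

#' Convert a VAF to a cancer cell fraction
#'
#' `ccf = vaf * (purity * CN_t + cnNormal * (1 - purity)) /
#' (purity * m)`. For a fully clonal single-copy mutation in a pure
#' diploid sample this reduces to `ccf = 2 * vaf`. Values above 1 are
#' retained (they flag multiplicity or copy-number misestimation), not
#' capped.
#'
#' @param vaf variant allele frequency (vectorized).
#' @param purity tumor purity in (0, 1]; zero is an error.
#' @param cnTotal tumor total copy number.
#' @param multiplicity mutated copies per tumor cell (>= 1).
#' @param cnNormal normal copy number (default 2).
#' @return numeric CCF.
#' @examples
#' computeCcf(0.5, 1, 2, 1)        # 1
#' computeCcf(0.2, 0.8, 3, 1)      # 0.7
#' @export
computeCcf <- function(vaf, purity, cnTotal, multiplicity, cnNormal = 2) {
    if (any(purity <= 0 | purity > 1))
        stop("purity must be in (0, 1]; CCF is undefined at purity 0")
    if (any(multiplicity < 1)) stop("multiplicity must be >= 1")
    vaf * (purity * cnTotal + cnNormal * (1 - purity)) /
        (purity * multiplicity)
}

#' Binomial tail probability and CCF confidence interval for one mutation
#'
#' The tail probability is the binomial CDF of observing `alt` or fewer
#' alt reads out of `depth` at the expected VAF — the per-mutation test
#' used to flag reads inconsistent with a hypothesized CCF. The interval
#' is the equal-tailed (Clopper-Pearson) binomial interval on the VAF,
#' mapped to CCF space through the purity / copy-number adjustment.
#'
#' @param alt,depth observed alt and total read counts.
#' @param expectedVaf hypothesized VAF in [0, 1].
#' @param level confidence level (default 0.95).
#' @param purity,cnTotal,multiplicity,cnNormal adjustment parameters for
#'   the CCF mapping (defaults: pure diploid heterozygous).
#' @return list with `tailProb`, `vafInterval` and `ccfInterval`.
#' @examples
#' binomialCcfInterval(0, 10, 0.5)$tailProb   # 0.5^10
#' @export
binomialCcfInterval <- function(alt, depth, expectedVaf, level = 0.95,
                                purity = 1, cnTotal = 2, multiplicity = 1,
                                cnNormal = 2) {
    if (alt < 0 || alt > depth) stop("need 0 <= alt <= depth")
    if (expectedVaf < 0 || expectedVaf > 1)
        stop("expectedVaf must be in [0, 1]")
    a <- (1 - level) / 2
    lo <- if (alt == 0) 0 else qbeta(a, alt, depth - alt + 1)
    hi <- if (alt == depth) 1 else qbeta(1 - a, alt + 1, depth - alt)
    vafInt <- c(lower = lo, upper = hi)
    ccfInt <- computeCcf(vafInt, purity, cnTotal, multiplicity, cnNormal)
    names(ccfInt) <- c("lower", "upper")
    list(tailProb = pbinom(alt, depth, expectedVaf),
         vafInterval = vafInt, ccfInterval = ccfInt)
}
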