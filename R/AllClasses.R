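#' @import methods
#' @importFrom stats dbinom dexp dpois pbinom pexp pgamma qbeta qexp qgamma
#'   rbinom rmultinom rpois runif rbeta rnorm quantile median sd var
#'   setNames aggregate approx cov qnorm rgamma acf complete.cases
#' @importFrom utils head read.delim write.table packageVersion tail
NULL

## ---------------------------------------------------------------------------
## Core S4 containers
## ---------------------------------------------------------------------------

#' Twin call-set partition
#'
#' Holds the result of comparing the high-confidence somatic call sets of the
#' two twins: variants found in both (`shared`) and variants private to each
#' twin (`uniqueA`, `uniqueB`), together with the match-key mode used for the
#' comparison. The three tables are pairwise disjoint under the match key.
#'
#' @slot shared data.frame of variants called in both twins.
#' @slot uniqueA data.frame of variants private to twin A.
#' @slot uniqueB data.frame of variants private to twin B.
#' @slot matchKey character; `"normalized"` or `"literal"` allele matching.
#'
#' @seealso [classifySharedUnique()]
#' @export
setClass("CallSetPartition",
    representation(shared = "data.frame", uniqueA = "data.frame",
                   uniqueB = "data.frame", matchKey = "character"))

setValidity("CallSetPartition", function(object) {
    key <- function(d) if (nrow(d)) paste(d$chrom, d$pos, d$ref, d$alt) else character()
    ks <- key(object@shared); ka <- key(object@uniqueA); kb <- key(object@uniqueB)
    if (anyDuplicated(c(ks, ka)) || anyDuplicated(c(ks, kb)) || anyDuplicated(c(ka, kb)))
        return("partition lists are not pairwise disjoint under the match key")
    if (!object@matchKey %in% c("normalized", "literal"))
        return("matchKey must be 'normalized' or 'literal'")
    TRUE
})

#' Fitted cancer-cell-fraction mixture
#'
#' Result of Dirichlet-process binomial mixture clustering of mutations by
#' cancer cell fraction (CCF), in one dimension (a single sample) or two
#' (one CCF axis per twin). Cluster locations are CCF coordinates, weights
#' are occupancy fractions, and every mutation is assigned to exactly one
#' cluster. Slots `likTables` and `grid` retain the per-record binomial
#' likelihood lookup used by the sampler so that clusters can be pruned and
#' members reassigned without refitting.
#'
#' @slot locations numeric matrix, clusters x dimensions, CCF coordinates.
#' @slot weights numeric; per-cluster fraction of mutations (sums to 1).
#' @slot assignments integer; cluster index per mutation.
#' @slot nDims integer; 1 or 2.
#' @slot sampleNames character; one name per CCF dimension.
#' @slot locationDraws list of per-draw location matrices (posterior draws).
#' @slot logPostTrace numeric; joint log-score per retained draw.
#' @slot likTables list of per-dimension likelihood lookup matrices.
#' @slot grid numeric; the CCF grid the sampler moved on.
#' @slot params list; sampler settings (iterations, burn-in, seed, ...).
#'
#' @seealso [clusterCcf()], [pruneClusters()], [assignLineagesPigeonhole()]
#' @export
setClass("ClusterSolution",
    representation(locations = "matrix", weights = "numeric",
                   assignments = "integer", nDims = "integer",
                   sampleNames = "character", locationDraws = "list",
                   logPostTrace = "numeric", likTables = "list",
                   grid = "numeric", params = "list"))

setValidity("ClusterSolution", function(object) {
    k <- nrow(object@locations)
    if (length(object@weights) != k)
        return("one weight per cluster required")
    if (abs(sum(object@weights) - 1) > 1e-9)
        return("cluster weights must sum to 1")
    if (length(object@assignments) &&
        (min(object@assignments) < 1L || max(object@assignments) > k))
        return("assignments outside cluster range")
    TRUE
})

#' Lineage-restricted mutation counts
#'
#' The sufficient statistics of the MRCA timing model: the number of
#' mutations shared by the twins on the ancestral lineage (`sShared`) and
#' the numbers private to each twin on its own MPN lineage (`nUniqueA`,
#' `nUniqueB`). `contextClass` records whether the counts cover all clonal
#' mutations or only clock-like N[C>T]pG substitutions; `provenance` keeps
#' the filter trail that produced the counts.
#'
#' @slot sShared integer; shared (pre-MRCA) mutation count.
#' @slot nUniqueA integer; twin-A private (post-MRCA) count.
#' @slot nUniqueB integer; twin-B private (post-MRCA) count.
#' @slot contextClass character; `"all_clonal"` or `"ncptg"`.
#' @slot provenance list; counts retained/removed at each filter step.
#'
#' @seealso [assembleLineageCounts()], [lineageCounts()]
#' @export
setClass("LineageCounts",
    representation(sShared = "integer", nUniqueA = "integer",
                   nUniqueB = "integer", contextClass = "character",
                   provenance = "list"))

setValidity("LineageCounts", function(object) {
    if (any(c(object@sShared, object@nUniqueA, object@nUniqueB) < 0L))
        return("counts must be non-negative")
    if (!object@contextClass %in% c("all_clonal", "ncptg"))
        return("contextClass must be 'all_clonal' or 'ncptg'")
    TRUE
})

#' Configuration of the MRCA timing model
#'
#' Bundles the data (a [LineageCounts-class] triple), the patient ages and
#' gestation offset that define the time axis, the priors, the post-MRCA
#' exposure mode and the sampler settings. All times are years since
#' fertilization; sampling ages are years since birth and have
#' `gestationYears` added internally.
#'
#' @slot counts LineageCounts; the observed count triple.
#' @slot samplingAgeA,samplingAgeB numeric; ages at sampling (years since
#'   birth).
#' @slot gestationYears numeric; gestation length added to every age.
#' @slot ratePriorMean numeric; mean of the exponential prior on the
#'   mutation rate (mutations/genome/year).
#' @slot rateUpperBound numeric; truncation of the rate prior (`Inf` = none).
#' @slot tMrcaPriorUpper numeric; upper end of the uniform prior on the MRCA
#'   time, years since fertilization.
#' @slot exposureMode character; `"latent_endpoint"` (post-MRCA counts accrue
#'   over latent intervals t1, t2) or `"fixed_endpoint"` (they accrue up to
#'   the sampling times).
#' @slot chains,iters,warmup,seed integer; MCMC settings.
#'
#' @seealso [timingConfig()], [fitMcmc()], [posteriorQuadrature()]
#' @export
setClass("TimingConfig",
    representation(counts = "LineageCounts",
                   samplingAgeA = "numeric", samplingAgeB = "numeric",
                   gestationYears = "numeric", ratePriorMean = "numeric",
                   rateUpperBound = "numeric", tMrcaPriorUpper = "numeric",
                   exposureMode = "character", chains = "integer",
                   iters = "integer", warmup = "integer", seed = "integer"))

setValidity("TimingConfig", function(object) {
    if (object@ratePriorMean <= 0) return("ratePriorMean must be positive")
    if (object@rateUpperBound <= 0) return("rateUpperBound must be positive")
    tmax <- min(object@samplingAgeA, object@samplingAgeB) + object@gestationYears
    if (object@tMrcaPriorUpper <= 0 || object@tMrcaPriorUpper >= tmax)
        return("tMrcaPriorUpper must lie in (0, earliest sampling time)")
    if (!object@exposureMode %in% c("latent_endpoint", "fixed_endpoint"))
        return("exposureMode must be 'latent_endpoint' or 'fixed_endpoint'")
    if (object@warmup >= object@iters) return("warmup must be < iters")
    if (object@chains < 1L) return("need at least one chain")
    TRUE
})

#' Posterior summary of the MRCA timing model
#'
#' Posterior draws and summaries for the model parameters (mutation rate
#' lambda, MRCA time, and the two post-MRCA interval endpoints), convergence
#' diagnostics, and the log marginal likelihood with its error estimate.
#'
#' @slot draws numeric array, iterations x chains x parameters
#'   (`lambda`, `t_mrca`, `t1`, `t2`).
#' @slot summary data.frame of mean / median / 95% interval per parameter.
#' @slot diagnostics data.frame of split R-hat and effective sample size.
#' @slot logMarginal numeric; log marginal likelihood.
#' @slot logMarginalError numeric; estimator standard error of
#'   `logMarginal` (0 for quadrature).
#' @slot config TimingConfig that produced the fit.
#' @slot method character; `"mcmc"` or `"quadrature"`.
#'
#' @seealso [fitMcmc()], [posteriorQuadrature()], [compareModels()]
#' @export
setClass("TimingFit",
    representation(draws = "array", summary = "data.frame",
                   diagnostics = "data.frame", logMarginal = "numeric",
                   logMarginalError = "numeric", config = "TimingConfig",
                   method = "character"))

## ---------------------------------------------------------------------------
## show() methods
## ---------------------------------------------------------------------------

setMethod("show", "CallSetPartition", function(object) {
    cat("CallSetPartition (match key:", object@matchKey, ")\n")
    cat("  shared:  ", nrow(object@shared), "\n")
    cat("  unique A:", nrow(object@uniqueA), "\n")
    cat("  unique B:", nrow(object@uniqueB), "\n")
})

setMethod("show", "ClusterSolution", function(object) {
    cat("ClusterSolution:", nrow(object@locations), "cluster(s) in",
        object@nDims, "dimension(s)\n")
    loc <- round(object@locations, 3)
    for (k in seq_len(nrow(loc)))
        cat(sprintf("  cluster %d: location (%s), weight %.3f, n = %d\n", k,
                    paste(loc[k, ], collapse = ", "), object@weights[k],
                    sum(object@assignments == k)))
})

setMethod("show", "LineageCounts", function(object) {
    cat("LineageCounts [", object@contextClass, "]: shared =",
        object@sShared, ", unique A =", object@nUniqueA,
        ", unique B =", object@nUniqueB, "\n")
})

setMethod("show", "TimingConfig", function(object) {
    cat("TimingConfig (", object@exposureMode, ")\n", sep = "")
    cat("  counts: s =", object@counts@sShared, ", n_A =",
        object@counts@nUniqueA, ", n_B =", object@counts@nUniqueB, "\n")
    cat(sprintf("  rate prior mean %.3g (bound %.3g); t_MRCA prior U(0, %.3f)\n",
                object@ratePriorMean, object@rateUpperBound,
                object@tMrcaPriorUpper))
    cat(sprintf("  sampler: %d chain(s) x %d iters (%d warmup), seed %d\n",
                object@chains, object@iters, object@warmup, object@seed))
})

setMethod("show", "TimingFit", function(object) {
    cat("TimingFit (", object@method, ")\n", sep = "")
    print(object@summary, row.names = FALSE, digits = 4)
    cat(sprintf("  log marginal likelihood: %.4f (se %.4g)\n",
                object@logMarginal, object@logMarginalError))
})

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' Accessors for twinclock containers
#'
#' Small accessor family for the S4 containers: partition tables, cluster
#' geometry, count triples and posterior summaries.
#'
#' @param object a twinclock S4 object.
#' @return The requested component; see the individual class pages.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sharedVariants", function(object) standardGeneric("sharedVariants"))
#' @rdname accessors
#' @export
setMethod("sharedVariants", "CallSetPartition", function(object) object@shared)

#' @rdname accessors
#' @export
setGeneric("uniqueVariants", function(object) standardGeneric("uniqueVariants"))
#' @rdname accessors
#' @export
setMethod("uniqueVariants", "CallSetPartition", function(object)
    list(A = object@uniqueA, B = object@uniqueB))

#' @rdname accessors
#' @export
setGeneric("clusterLocations", function(object) standardGeneric("clusterLocations"))
#' @rdname accessors
#' @export
setMethod("clusterLocations", "ClusterSolution", function(object) object@locations)

#' @rdname accessors
#' @export
setGeneric("clusterWeights", function(object) standardGeneric("clusterWeights"))
#' @rdname accessors
#' @export
setMethod("clusterWeights", "ClusterSolution", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("clusterAssignments", function(object) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setMethod("clusterAssignments", "ClusterSolution", function(object) object@assignments)

#' @rdname accessors
#' @export
setGeneric("countTriple", function(object) standardGeneric("countTriple"))
#' @rdname accessors
#' @export
setMethod("countTriple", "LineageCounts", function(object)
    c(s = object@sShared, n_a = object@nUniqueA, n_b = object@nUniqueB))
#' @rdname accessors
#' @export
setMethod("countTriple", "TimingConfig", function(object)
    countTriple(object@counts))

#' @rdname accessors
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))
#' @rdname accessors
#' @export
setMethod("posteriorDraws", "TimingFit", function(object) {
    d <- object@draws
    if (length(dim(d)) == 3L)
        matrix(d, ncol = dim(d)[3L], dimnames = list(NULL, dimnames(d)[[3L]]))
    else d
})

#' @rdname accessors
#' @export
setGeneric("posteriorSummary", function(object) standardGeneric("posteriorSummary"))
#' @rdname accessors
#' @export
setMethod("posteriorSummary", "TimingFit", function(object) object@summary)

#' @rdname accessors
#' @export
setGeneric("logMarginalLikelihood", function(object) standardGeneric("logMarginalLikelihood"))
#' @rdname accessors
#' @export
setMethod("logMarginalLikelihood", "TimingFit", function(object)
    c(logml = object@logMarginal, se = object@logMarginalError))

#' Construct a LineageCounts object
#'
#' @param sShared,nUniqueA,nUniqueB non-negative integer counts: mutations
#'   shared by the twins and private to twin A / twin B on the MPN lineage.
#' @param contextClass `"all_clonal"` or `"ncptg"`.
#' @param provenance optional list describing how the counts were derived.
#' @return A [LineageCounts-class] object.
#' @examples
#' lineageCounts(2, 89, 114, contextClass = "ncptg")
#' @export
lineageCounts <- function(sShared, nUniqueA, nUniqueB,
                          contextClass = c("all_clonal", "ncptg"),
                          provenance = list()) {
    contextClass <- match.arg(contextClass)
    new("LineageCounts", sShared = as.integer(sShared),
        nUniqueA = as.integer(nUniqueA), nUniqueB = as.integer(nUniqueB),
        contextClass = contextClass, provenance = provenance)
}
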