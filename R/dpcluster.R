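## Dirichlet-process binomial mixture clustering of cancer cell fractions.
##
## The emission is binomial on read counts, not Gaussian on CCF: cluster c
## at CCF location l_cd in sample d generates alt reads for record r with
## success probability l_cd * rho_d * m_r / (rho_d * CN_r + 2 (1 - rho_d)),
## so sequencing depth informs assignment uncertainty. The mixture is a
## truncated stick-breaking Dirichlet process fitted by Gibbs sampling;
## cluster locations move on a fixed CCF grid, which lets the whole
## per-record binomial likelihood surface be precomputed once and turns
## every Gibbs sweep into table lookups.

#' Cluster mutations by cancer cell fraction
#'
#' Fits a Dirichlet-process binomial mixture to per-mutation read counts in
#' one dimension (one sample) or two (one CCF axis per twin; mutations
#' absent from one twin are coded as zero alt reads at that twin's local
#' depth). Gibbs sampling alternates stick-breaking weights, cluster
#' locations (sampled over a uniform CCF grid) and assignments; the
#' reported solution is the retained draw with the highest joint log
#' score, with clusters renumbered by decreasing occupancy.
#'
#' @param alt,depth alt and total read counts; vectors (1D) or
#'   n x D matrices.
#' @param purity per-dimension tumor purity in (0, 1].
#' @param cnTotal tumor total copy number per record (vector or n x D
#'   matrix; default 2).
#' @param multiplicity mutated copies per record (default 1).
#' @param concentration Dirichlet-process concentration parameter.
#' @param iters,burnIn MCMC iterations and burn-in discarded from them.
#' @param seed RNG seed.
#' @param truncation stick-breaking truncation (maximum clusters).
#' @param gridMax,gridStep CCF grid upper end and spacing; locations above
#'   1 are allowed so that multiplicity/CN misestimation stays visible.
#' @param sampleNames names for the CCF dimensions.
#' @return A [ClusterSolution-class] object.
#' @examples
#' set.seed(1)
#' d <- rpois(60, 40) + 1L
#' a <- rbinom(60, d, 0.5)          # one clonal cluster, pure diploid
#' clusterCcf(a, d, purity = 1, iters = 200, burnIn = 50, seed = 1)
#' @export
clusterCcf <- function(alt, depth, purity, cnTotal = 2, multiplicity = 1,
                       concentration = 1, iters = 1000, burnIn = 200,
                       seed = 1L, truncation = 20L, gridMax = 1.25,
                       gridStep = 0.01, sampleNames = NULL) {
    alt <- as.matrix(alt); depth <- as.matrix(depth)
    n <- nrow(alt); D <- ncol(alt)
    if (n < 5L) stop("fewer than 5 records: degenerate fit")
    if (!all(dim(depth) == c(n, D))) stop("alt/depth dimension mismatch")
    if (any(depth < 1L)) stop("all records need depth >= 1")
    if (any(alt > depth)) stop("alt exceeds depth")
    if (length(purity) == 1L) purity <- rep(purity, D)
    if (length(purity) != D || any(purity <= 0 | purity > 1))
        stop("need one purity in (0, 1] per dimension")
    if (is.null(sampleNames))
        sampleNames <- if (D == 2L) c("A", "B") else paste0("S", seq_len(D))
    cnTotal <- matrix(rep_len(as.vector(cnTotal), n * D), n, D)
    multiplicity <- matrix(rep_len(as.vector(multiplicity), n * D), n, D)
    if (burnIn >= iters) stop("burnIn must be < iters")
    set.seed(seed)

    grid <- seq(0, gridMax, by = gridStep)
    G <- length(grid)
    K <- as.integer(truncation)
    ## likelihood lookup: L[[d]][r, g] = log P(alt_rd | depth_rd, loc = grid_g)
    L <- lapply(seq_len(D), function(d) {
        f <- purity[d] * multiplicity[, d] /
            (purity[d] * cnTotal[, d] + 2 * (1 - purity[d]))
        p <- pmin(outer(f, grid), 1)
        matrix(dbinom(rep(alt[, d], G), rep(depth[, d], G), as.vector(p),
                      log = TRUE), n, G)
    })

    locIdx <- matrix(sample.int(G, K * D, replace = TRUE), K, D)
    z <- sample.int(K, n, replace = TRUE)
    keep <- iters - burnIn
    zDraws <- matrix(NA_integer_, keep, n)
    locDraws <- vector("list", keep)
    score <- numeric(keep)

    for (it in seq_len(iters)) {
        nk <- tabulate(z, K)
        ## stick-breaking weights
        tailCount <- rev(cumsum(rev(nk))) - nk
        V <- rbeta(K, 1 + nk, concentration + tailCount)
        V[K] <- 1
        logV <- log(V); log1mV <- log1p(-V)
        logw <- logV + c(0, cumsum(log1mV[-K]))
        ## cluster locations (griddy Gibbs; flat prior over the grid)
        for (k in seq_len(K)) {
            idx <- which(z == k)
            for (d in seq_len(D)) {
                lp <- if (length(idx))
                    colSums(L[[d]][idx, , drop = FALSE]) else numeric(G)
                lp <- lp - max(lp)
                locIdx[k, d] <- sample.int(G, 1L, prob = exp(lp))
            }
        }
        ## assignments (Gumbel-max over log weight + log likelihood)
        ll <- L[[1]][, locIdx[, 1]]
        if (D > 1L) for (d in 2:D) ll <- ll + L[[d]][, locIdx[, d]]
        logp <- sweep(ll, 2L, logw, "+")
        gum <- -log(-log(matrix(runif(n * K), n, K)))
        z <- max.col(logp + gum)
        if (it > burnIn) {
            j <- it - burnIn
            zDraws[j, ] <- z
            locDraws[[j]] <- matrix(grid[locIdx], K, D,
                                    dimnames = list(NULL, sampleNames))
            score[j] <- sum(logp[cbind(seq_len(n), z)])
        }
    }

    ## Consensus summary over the retained draws. Within a draw, occupied
    ## components closer than `mergeTol` (single-linkage, max-norm over
    ## CCF dimensions) are one cluster: conditional Gibbs samplers split a
    ## well-populated cluster into near-identical components and re-merge
    ## them only very slowly, so component identity below that resolution
    ## is sampler noise, not structure. Records are then clustered by
    ## their posterior co-assignment frequency (average-linkage on one
    ## minus the posterior similarity matrix, cut at 0.5), which is
    ## additionally robust to label switching across draws.
    mergeTol <- 0.1
    thin <- unique(round(seq(1, keep, length.out = min(200L, keep))))
    psm <- matrix(0, n, n)
    for (j in thin) {
        zj <- zDraws[j, ]
        comps <- sort(unique(zj))
        lcomp <- locDraws[[j]][comps, , drop = FALSE]
        lab <- if (length(comps) > 1L) {
            hcd <- stats::hclust(stats::dist(lcomp, method = "maximum"),
                                 method = "single")
            stats::cutree(hcd, h = mergeTol)
        } else 1L
        zj <- lab[match(zj, comps)]
        for (k in unique(zj)) {
            idx <- which(zj == k)
            psm[idx, idx] <- psm[idx, idx] + 1
        }
    }
    psm <- psm / length(thin)
    remap <- if (n > 1L) {
        hc <- stats::hclust(stats::as.dist(1 - psm), method = "average")
        stats::cutree(hc, h = 0.5)
    } else 1L
    counts <- tabulate(remap)
    ord <- order(counts, decreasing = TRUE)
    remap <- match(remap, ord)
    counts <- counts[ord]
    ## cluster locations: posterior mode on the grid given the consensus
    ## membership
    locations <- matrix(0, length(counts), D,
                        dimnames = list(NULL, NULL))
    for (k in seq_along(counts)) {
        idx <- which(remap == k)
        for (d in seq_len(D)) {
            lp <- colSums(L[[d]][idx, , drop = FALSE])
            locations[k, d] <- grid[which.max(lp)]
        }
    }
    new("ClusterSolution",
        locations = locations, weights = counts / n,
        assignments = as.integer(remap), nDims = as.integer(D),
        sampleNames = sampleNames, locationDraws = locDraws,
        logPostTrace = score, likTables = L, grid = grid,
        params = list(concentration = concentration, iters = iters,
                      burnIn = burnIn, seed = seed, truncation = K,
                      purity = purity))
}

#' Remove minor clusters and reassign their members
#'
#' Clusters holding strictly less than `minFraction` of all mutations are
#' removed; their members are reassigned to the surviving cluster with the
#' highest likelihood for their read counts (using the fitted solution's
#' stored likelihood tables), and weights are recomputed. Membership is
#' conserved: the total number of assigned mutations is unchanged.
#'
#' @param solution a [ClusterSolution-class].
#' @param minFraction removal threshold on cluster weight (strict `<`).
#' @return A pruned [ClusterSolution-class].
#' @export
pruneClusters <- function(solution, minFraction = 0.01) {
    stopifnot(is(solution, "ClusterSolution"))
    keep <- which(solution@weights >= minFraction)
    if (!length(keep))
        stop("all clusters fall below minFraction = ", minFraction)
    if (length(keep) == nrow(solution@locations)) return(solution)
    n <- length(solution@assignments)
    grid <- solution@grid
    ## likelihood of each record under each surviving cluster
    ll <- matrix(0, n, length(keep))
    for (jd in seq_len(solution@nDims)) {
        gIdx <- vapply(solution@locations[keep, jd],
                       function(l) which.min(abs(grid - l)), integer(1))
        ll <- ll + solution@likTables[[jd]][, gIdx, drop = FALSE]
    }
    z <- solution@assignments
    orphan <- !(z %in% keep)
    zNew <- match(z, keep)
    zNew[orphan] <- max.col(ll[orphan, , drop = FALSE], ties.method = "first")
    counts <- tabulate(zNew, length(keep))
    out <- solution
    out@locations <- solution@locations[keep, , drop = FALSE]
    out@weights <- counts / n
    out@assignments <- as.integer(zNew)
    validObject(out)
    out
}

#' Assign clusters to cell lineages by the pigeonhole principle
#'
#' Two clusters each present in more than half of the cells of a sample
#' must overlap, hence lie on the same cell lineage. Within each sample,
#' every cluster with CCF location above `cutoff` is therefore labelled as
#' lying on that sample's MPN lineage; a cluster above `cutoff` in all
#' samples is the ancestral (twin-shared) cluster; clusters at or below
#' `cutoff` everywhere are indeterminate (the pigeonhole argument does not
#' apply). Labels depend only on cluster locations, so they are invariant
#' to cluster reordering.
#'
#' @param solution a (pruned) [ClusterSolution-class].
#' @param cutoff CCF threshold (default 0.5, strict `>`).
#' @return data.frame with one row per cluster: locations, per-sample
#'   on-lineage flags and a `label` column (`"ancestral"`,
#'   `"lineage_<sample>"` or `"indeterminate"`).
#' @export
assignLineagesPigeonhole <- function(solution, cutoff = 0.5) {
    stopifnot(is(solution, "ClusterSolution"))
    loc <- solution@locations
    on <- loc > cutoff
    lab <- apply(on, 1L, function(x) {
        if (all(x)) "ancestral"
        else if (!any(x)) "indeterminate"
        else paste0("lineage_",
                    tolower(paste(solution@sampleNames[x], collapse = "_")))
    })
    out <- data.frame(cluster = seq_len(nrow(loc)), loc,
                      stringsAsFactors = FALSE)
    names(out)[seq_len(ncol(loc)) + 1L] <-
        paste0("ccf_", tolower(solution@sampleNames))
    onDf <- as.data.frame(on)
    names(onDf) <- paste0("on_lineage_", tolower(solution@sampleNames))
    cbind(out, onDf, label = lab, stringsAsFactors = FALSE)
}
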