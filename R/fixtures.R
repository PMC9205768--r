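## Packaged synthetic fixtures.
##
## The shipped tables are synthetic stand-ins that encode the count
## structure of a well-characterized adult twin-MPN case at the scale the timing model
## consumes: an all-clonal lineage-restricted triple of (7, 91, 90)
## mutations and a clock-like N[C>T]pG triple of (2, 89, 114), with a
## three-cluster architecture (one twin-shared ancestral cluster near
## CCF (1,1) and one twin-private cluster per twin along each axis).
## They exist so that the count-assembly and timing stages can be
## exercised against known totals without any protected sequencing data.

#' Load the packaged synthetic twin fixture
#'
#' Returns the synthetic partition table (per-mutation lineage, cluster,
#' reference 3-mer context and per-twin read counts) for the requested
#' context class, the fixture's cluster-location table, and the pigeonhole
#' lineage labels derived from those locations.
#'
#' @param contextClass `"all_clonal"` (lineage-restricted triple 7/91/90)
#'   or `"ncptg"` (clock-mutation triple 2/89/114).
#' @return list with `partition` (data.frame), `clusters` (data.frame of
#'   CCF locations) and `labels` (from [assignLineagesPigeonhole()]).
#' @examples
#' fx <- twinFixture("ncptg")
#' countTriple(assembleLineageCounts(fx$partition, fx$labels, "ncptg"))
#' @export
twinFixture <- function(contextClass = c("all_clonal", "ncptg")) {
    contextClass <- match.arg(contextClass)
    pfile <- system.file("extdata",
        paste0("synthetic_twin_", contextClass, "_partition.tsv"),
        package = "twinclock", mustWork = TRUE)
    cfile <- system.file("extdata", "synthetic_twin_clusters.tsv",
                         package = "twinclock", mustWork = TRUE)
    partition <- read.delim(pfile, stringsAsFactors = FALSE)
    clusters <- read.delim(cfile, stringsAsFactors = FALSE)
    loc <- as.matrix(clusters[, c("ccf_a", "ccf_b")])
    sol <- new("ClusterSolution", locations = loc,
               weights = rep(1 / nrow(loc), nrow(loc)),
               assignments = integer(0), nDims = 2L,
               sampleNames = c("A", "B"), locationDraws = list(),
               logPostTrace = numeric(0), likTables = list(),
               grid = numeric(0), params = list(source = "fixture"))
    labels <- assignLineagesPigeonhole(sol)
    labels$cluster <- clusters$cluster
    list(partition = partition, clusters = clusters, labels = labels)
}
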