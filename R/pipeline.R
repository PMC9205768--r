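## End-to-end orchestration: simulate (or take counts), build the
## consensus, cluster CCFs, assign lineages, count clock mutations, time
## the MRCA, and write a reproducibility manifest.

pipelineDefaults <- function() list(
    seed = 1L,
    scenario = list(mode = "synthetic"),
    synthetic = list(
        rate_per_year = 2.5, t_mrca = 0.8,
        sampling_age_a = 40, sampling_age_b = 40,
        gestation_years = 40 * 7 / 365.25,
        ncptg_fraction = 0.25, depth_mean = 40,
        purity_a = 1, purity_b = 1,
        caller_sensitivity = c(1, 1, 1),
        caller_false_calls = c(0L, 0L, 0L),
        reference_length = 200000L, cpg_density = 0.02),
    consensus = list(
        germline_vaf_max = 0.05, tumor_vaf_min = 0.1, min_depth = 20,
        sv_slop_bp = 200, match_key = "normalized"),
    clustering = list(
        min_cluster_fraction = 0.01, pigeonhole_cutoff = 0.5,
        iters = 1000L, burn_in = 200L, concentration = 1),
    clock = list(context = "ncptg", genome_mb = 3100),
    counts = list(s = NULL, n_a = NULL, n_b = NULL,
                  context_class = "ncptg"),
    timing = list(
        rate_prior_mean = 1.71, rate_upper_bound = Inf,
        t_mrca_prior_upper = 37 + 40 * 7 / 365.25,
        sampling_age_a = NULL, sampling_age_b = NULL,
        gestation_years = 40 * 7 / 365.25,
        exposure_mode = "latent_endpoint",
        chains = 5L, iters = 20000L, warmup = 4000L,
        method = "mcmc"))

#' Validate and normalize a pipeline configuration
#'
#' Merges a configuration (a list, or a path to a YAML file) over the
#' defaults, so that the zero-override run uses the canonical thresholds
#' (germline VAF 0.05, tumor VAF 0.1, depth 20, 1% cluster pruning,
#' 200 bp SV slop, 0.5 pigeonhole cutoff). Unknown keys — including
#' misspellings — are rejected by name; invalid values are collected and
#' reported together.
#'
#' @param config list or YAML path; `NULL` or an empty list yields the
#'   fully defaulted configuration.
#' @return the normalized configuration list.
#' @examples
#' cfg <- validateConfig(list(clock = list(context = "all_clonal")))
#' cfg$consensus$min_depth   # defaulted to 20
#' @export
validateConfig <- function(config = list()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
    defaults <- pipelineDefaults()
    errors <- character(0)
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
        errors <- c(errors, paste0("unknown config key: ", unknown))
    for (sec in intersect(names(config), names(defaults))) {
        if (!is.list(defaults[[sec]])) next
        bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
        if (length(bad))
            errors <- c(errors,
                        paste0("unknown config key: ", sec, ".", bad))
    }
    if (length(errors)) stop(paste(errors, collapse = "\n"), call. = FALSE)
    cfg <- defaults
    for (k in names(config)) {
        if (is.list(defaults[[k]]))
            for (j in names(config[[k]])) cfg[[k]][[j]] <- config[[k]][[j]]
        else cfg[[k]] <- config[[k]]
    }
    chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
    chk(cfg$scenario$mode %in% c("synthetic", "counts"),
        "scenario.mode must be 'synthetic' or 'counts'")
    chk(cfg$consensus$germline_vaf_max >= 0,
        "consensus.germline_vaf_max must be non-negative")
    chk(cfg$consensus$tumor_vaf_min >= 0,
        "consensus.tumor_vaf_min must be non-negative")
    chk(cfg$consensus$min_depth >= 0,
        "consensus.min_depth must be non-negative")
    chk(cfg$consensus$sv_slop_bp >= 0,
        "consensus.sv_slop_bp must be non-negative")
    chk(cfg$clustering$min_cluster_fraction >= 0 &&
        cfg$clustering$min_cluster_fraction < 1,
        "clustering.min_cluster_fraction must be in [0, 1)")
    chk(cfg$clustering$pigeonhole_cutoff > 0 &&
        cfg$clustering$pigeonhole_cutoff < 1,
        "clustering.pigeonhole_cutoff must be in (0, 1)")
    chk(cfg$clock$context %in% c("ncptg", "all_clonal"),
        "clock.context must be 'ncptg' or 'all_clonal'")
    chk(cfg$timing$rate_prior_mean > 0,
        "timing.rate_prior_mean must be positive")
    chk(cfg$timing$method %in% c("mcmc", "quadrature"),
        "timing.method must be 'mcmc' or 'quadrature'")
    if (cfg$scenario$mode == "counts")
        chk(!is.null(cfg$counts$s) && !is.null(cfg$counts$n_a) &&
            !is.null(cfg$counts$n_b),
            "counts mode requires counts.s, counts.n_a, counts.n_b")
    if (length(errors)) stop(paste(errors, collapse = "\n"), call. = FALSE)
    cfg
}

#' Run the full twin-lineage timing pipeline
#'
#' Executes consensus calling, CCF clustering, pigeonhole lineage
#' assignment, clock-mutation counting and MRCA timing, writing every
#' stage's outputs plus a markdown report (with a two-dimensional CCF
#' density plot) and a reproducibility manifest to `outDir`. In
#' `"synthetic"` mode the inputs are generated by the twin simulator; in
#' `"counts"` mode the count triple is taken from the configuration and
#' only the timing stage runs. All stage seeds derive from the single
#' configured seed, so a rerun with the same configuration reproduces the
#' summary files byte for byte. On a stage failure, partial outputs are
#' moved under `outDir/failed/` and the stage's diagnostic is re-raised.
#'
#' @param config configuration list or YAML path (see [validateConfig()]).
#' @param outDir output directory.
#' @return Invisibly, a list with the stage results (`truth`, `partition`,
#'   `solution`, `labels`, `counts`, `fit`, `manifest`).
#' @export
runPipeline <- function(config = list(), outDir) {
    cfg <- validateConfig(config)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    res <- tryCatch(
        runPipelineStages(cfg, outDir),
        error = function(e) {
            faildir <- file.path(outDir, "failed")
            dir.create(faildir, showWarnings = FALSE)
            made <- setdiff(list.files(outDir, full.names = FALSE),
                            "failed")
            for (f in made)
                file.rename(file.path(outDir, f), file.path(faildir, f))
            stop("pipeline stage failed: ", conditionMessage(e),
                 call. = FALSE)
        })
    invisible(res)
}

#' @noRd
runPipelineStages <- function(cfg, outDir) {
    writeJson <- function(x, file)
        jsonlite::write_json(x, file.path(outDir, file), auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    inputChecksums <- character(0)
    truth <- NULL; partition <- NULL; solution <- NULL; labels <- NULL

    if (cfg$scenario$mode == "synthetic") {
        syn <- cfg$synthetic
        params <- simulationParams(
            ratePerYear = syn$rate_per_year, tMrcaTrue = syn$t_mrca,
            samplingAgeA = syn$sampling_age_a,
            samplingAgeB = syn$sampling_age_b,
            gestationYears = syn$gestation_years,
            ncptgFraction = syn$ncptg_fraction,
            depthMean = syn$depth_mean, purityA = syn$purity_a,
            purityB = syn$purity_b,
            callerSensitivity = syn$caller_sensitivity,
            callerFalseCalls = syn$caller_false_calls, seed = cfg$seed)
        reference <- makeReferenceSequence(syn$reference_length,
                                           syn$cpg_density,
                                           seed = cfg$seed + 1L)
        truth <- simulateTwinHistory(params, reference)
        observed <- simulateObservations(truth)
        vcfDir <- file.path(outDir, "vcf")
        paths <- emitCallerCallsets(observed, reference, vcfDir,
                                    callerSensitivity = syn$caller_sensitivity,
                                    callerFalseCalls = syn$caller_false_calls,
                                    seed = cfg$seed + 3L)
        allVcfs <- unlist(paths)
        inputChecksums <- tools::md5sum(allVcfs)
        names(inputChecksums) <- basename(allVcfs)

        ## consensus per twin
        con <- cfg$consensus
        highConf <- lapply(c(A = "A", B = "B"), function(tw) {
            calls <- lapply(paths[[tw]][1:3], readCallerVcf,
                            dialect = "pass_and_somatic")
            hc <- intersectCallers(calls[[1]], calls[[2]], calls[[3]],
                                   matchKey = con$match_key)
            vaf <- ifelse(hc$tumor_depth > 0,
                          hc$tumor_alt / hc$tumor_depth, 0)
            rho <- if (tw == "A") syn$purity_a else syn$purity_b
            hc$multiplicity <- estimateMultiplicity(vaf, rho, 2)
            flt <- filterVafDepth(hc,
                                  germlineVafMax = con$germline_vaf_max,
                                  tumorVafMin = con$tumor_vaf_min,
                                  minDepth = con$min_depth)
            write.table(flt$removed,
                        file.path(outDir,
                                  sprintf("removal_log_%s.tsv", tw)),
                        sep = "\t", row.names = FALSE, quote = FALSE)
            flt$retained
        })
        partition <- classifySharedUnique(highConf$A, highConf$B,
                                          matchKey = con$match_key)

        ## CCF clustering in two dimensions over the union of calls
        cl <- cfg$clustering
        pd <- partitionTable(partition)
        obsKey <- paste(observed$chrom, observed$pos, observed$twin)
        getObs <- function(tw, col) {
            i <- match(paste(pd$chrom, pd$pos, tw), obsKey)
            observed[[col]][i]
        }
        altM <- cbind(getObs("A", "alt_reads"), getObs("B", "alt_reads"))
        depM <- cbind(getObs("A", "depth"), getObs("B", "depth"))
        miss <- is.na(depM)
        depM[miss] <- cfg$synthetic$depth_mean
        altM[is.na(altM)] <- 0L
        solution <- clusterCcf(altM, depM,
                               purity = c(syn$purity_a, syn$purity_b),
                               concentration = cl$concentration,
                               iters = cl$iters, burnIn = cl$burn_in,
                               seed = cfg$seed + 4L)
        solution <- pruneClusters(solution, cl$min_cluster_fraction)
        labels <- assignLineagesPigeonhole(solution,
                                           cutoff = cl$pigeonhole_cutoff)
        pd$cluster <- clusterAssignments(solution)
        pd$depth_a <- depM[, 1]; pd$depth_b <- depM[, 2]
        octx <- match(paste(pd$chrom, pd$pos, "A"), obsKey)
        pd$context <- observed$context[octx]
        write.table(pd, file.path(outDir, "partition.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        write.table(labels, file.path(outDir, "clusters.tsv"), sep = "\t",
                    row.names = FALSE, quote = FALSE)
        counts <- assembleLineageCounts(pd, labels,
                                        contextFilter = cfg$clock$context,
                                        minDepth = con$min_depth)
        ccfPlot(altM, depM, c(syn$purity_a, syn$purity_b),
                file.path(outDir, "ccf_density.png"))
    } else {
        counts <- lineageCounts(cfg$counts$s, cfg$counts$n_a,
                                cfg$counts$n_b,
                                contextClass = cfg$counts$context_class)
    }
    writeJson(c(as.list(countTriple(counts)),
                context_class = counts@contextClass),
              "lineage_counts.json")

    ## timing
    tm <- cfg$timing
    ageA <- if (is.null(tm$sampling_age_a)) {
        if (cfg$scenario$mode == "synthetic") cfg$synthetic$sampling_age_a
        else ageToYears(39, 11, 26)
    } else tm$sampling_age_a
    ageB <- if (is.null(tm$sampling_age_b)) {
        if (cfg$scenario$mode == "synthetic") cfg$synthetic$sampling_age_b
        else ageToYears(38, 5, 14)
    } else tm$sampling_age_b
    tcfg <- timingConfig(counts, samplingAgeA = ageA, samplingAgeB = ageB,
                         gestationYears = tm$gestation_years,
                         ratePriorMean = tm$rate_prior_mean,
                         rateUpperBound = tm$rate_upper_bound,
                         tMrcaPriorUpper = tm$t_mrca_prior_upper,
                         exposureMode = tm$exposure_mode,
                         chains = tm$chains, iters = tm$iters,
                         warmup = tm$warmup, seed = cfg$seed + 5L)
    fit <- if (tm$method == "mcmc") fitMcmc(tcfg)
           else posteriorQuadrature(tcfg)
    summ <- posteriorSummary(fit)
    writeJson(list(method = fit@method,
                   parameters = summ,
                   log_marginal_likelihood = fit@logMarginal,
                   log_marginal_likelihood_se = fit@logMarginalError),
              "timing_summary.json")
    if (fit@method == "mcmc") {
        write.table(posteriorDraws(fit),
                    file.path(outDir, "posterior_draws.csv"), sep = ",",
                    row.names = FALSE, quote = FALSE)
        write.table(fit@diagnostics,
                    file.path(outDir, "timing_diagnostics.tsv"),
                    sep = "\t", row.names = FALSE, quote = FALSE)
    }

    manifest <- buildManifest(cfg, inputChecksums)
    writeJson(manifest, "manifest.json")
    writeReport(cfg, counts, fit, outDir, solution)
    invisible(list(truth = truth, partition = partition,
                   solution = solution, labels = labels, counts = counts,
                   fit = fit, manifest = manifest))
}

## flatten a CallSetPartition into one table with a lineage column
#' @noRd
partitionTable <- function(partition) {
    tag <- function(d, lin) {
        if (!nrow(d)) return(NULL)
        data.frame(chrom = d$chrom, pos = d$pos, ref = d$ref, alt = d$alt,
                   lineage = lin, stringsAsFactors = FALSE)
    }
    out <- rbind(tag(partition@shared, "shared"),
                 tag(partition@uniqueA, "unique_a"),
                 tag(partition@uniqueB, "unique_b"))
    rownames(out) <- NULL
    out
}

#' @noRd
buildManifest <- function(cfg, inputChecksums) {
    ser <- function(x) {
        if (is.list(x))
            paste(vapply(names(x), function(k)
                paste0(k, "={", ser(x[[k]]), "}"), ""), collapse = ";")
        else paste(format(x, digits = 15), collapse = ",")
    }
    deterministic <- list(
        config_hash = md5OfLines(ser(cfg)),
        seed = cfg$seed,
        stage_seeds = list(simulate = cfg$seed, reference = cfg$seed + 1L,
                           observations = cfg$seed + 2L,
                           callers = cfg$seed + 3L,
                           clustering = cfg$seed + 4L,
                           timing = cfg$seed + 5L),
        input_checksums = as.list(inputChecksums),
        package_version = as.character(packageVersion("twinclock")))
    manifestHash <- md5OfLines(ser(deterministic))
    c(deterministic, list(manifest_hash = manifestHash,
                          timestamp = format(Sys.time(), tz = "UTC")))
}

#' @noRd
ccfPlot <- function(altM, depM, purity, path) {
    ccfA <- computeCcf(altM[, 1] / depM[, 1], purity[1], 2, 1)
    ccfB <- computeCcf(altM[, 2] / depM[, 2], purity[2], 2, 1)
    grDevices::png(path, width = 640, height = 640)
    on.exit(grDevices::dev.off())
    graphics::plot(ccfA, ccfB, pch = 16, cex = 0.6,
                   col = grDevices::rgb(0, 0, 0, 0.4),
                   xlab = "CCF twin A", ylab = "CCF twin B",
                   xlim = c(-0.05, 1.3), ylim = c(-0.05, 1.3),
                   main = "Cancer cell fraction density")
    if (length(ccfA) >= 10 && sd(ccfA) > 0 && sd(ccfB) > 0) {
        kd <- MASS::kde2d(ccfA, ccfB, n = 100,
                          lims = c(-0.05, 1.3, -0.05, 1.3))
        graphics::contour(kd, add = TRUE, col = "red", nlevels = 8,
                          drawlabels = FALSE)
    }
    invisible(path)
}

#' @noRd
writeReport <- function(cfg, counts, fit, outDir, solution) {
    summ <- posteriorSummary(fit)
    tmrca <- summ[summ$param == "t_mrca", ]
    lines <- c(
        "# Twin lineage timing report", "",
        sprintf("Scenario mode: %s; seed %d.", cfg$scenario$mode,
                cfg$seed), "",
        "## Lineage-restricted counts", "",
        sprintf("- shared (pre-MRCA): %d", counts@sShared),
        sprintf("- unique twin A: %d", counts@nUniqueA),
        sprintf("- unique twin B: %d", counts@nUniqueB),
        sprintf("- context class: %s", counts@contextClass), "")
    if (!is.null(solution))
        lines <- c(lines, "## CCF clusters", "",
                   "See `clusters.tsv` and `ccf_density.png`.", "")
    lines <- c(lines,
        "## MRCA timing posterior", "",
        sprintf("- method: %s", fit@method),
        sprintf("- t_MRCA posterior mean %.3f years, 95%% CrI [%.3f, %.3f]",
                tmrca$mean, tmrca$q2.5, tmrca$q97.5),
        sprintf("- log marginal likelihood %.3f (se %.3g)",
                fit@logMarginal, fit@logMarginalError), "")
    writeLines(lines, file.path(outDir, "report.md"))
}
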