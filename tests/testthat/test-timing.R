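ncptgCounts <- lineageCounts(2, 89, 114, "ncptg")

test_that("the joint log posterior matches a hand-summed oracle", {
    cfg <- timingConfig(ncptgCounts, ratePriorMean = 1.71,
                        rateUpperBound = 37.766,
                        tMrcaPriorUpper = 37.766,
                        exposureMode = "fixed_endpoint")
    TA <- ageToYears(39, 11, 26) + 40 * 7 / 365.25
    TB <- ageToYears(38, 5, 14) + 40 * 7 / 365.25
    lam <- 2; tm <- 1; t1 <- 20; t2 <- 25
    ## independent term-by-term sum
    oracle <- dexp(lam, 1 / 1.71, log = TRUE) -
        pexp(37.766, 1 / 1.71, log.p = TRUE) -
        log(37.766) - log(TA - tm) - log(TB - tm) +
        dpois(2, lam * tm, log = TRUE) +
        dpois(89, lam * (TA - tm), log = TRUE) +
        dpois(114, lam * (TB - tm), log = TRUE)
    expect_equal(logPosterior(lam, tm, t1, t2, cfg), oracle)
    ## latent mode swaps the private-count exposures
    cfgL <- timingConfig(ncptgCounts, ratePriorMean = 1.71,
                         exposureMode = "latent_endpoint")
    oracleL <- dexp(lam, 1 / 1.71, log = TRUE) -
        log(37 + 40 * 7 / 365.25) - log(TA - tm) - log(TB - tm) +
        dpois(2, lam * tm, log = TRUE) +
        dpois(89, lam * (t1 - tm), log = TRUE) +
        dpois(114, lam * (t2 - tm), log = TRUE)
    expect_equal(logPosterior(lam, tm, t1, t2, cfgL), oracleL)
})

test_that("out-of-support parameters return -Inf, not errors", {
    cfg <- timingConfig(ncptgCounts, ratePriorMean = 1.71,
                        rateUpperBound = 5)
    expect_identical(logPosterior(2, -0.1, 20, 20, cfg), -Inf)
    expect_identical(logPosterior(6, 1, 20, 20, cfg), -Inf)   # above bound
    expect_identical(logPosterior(-1, 1, 20, 20, cfg), -Inf)
    expect_identical(logPosterior(2, 50, 55, 55, cfg), -Inf)
    expect_identical(logPosterior(2, 1, 0.5, 20, cfg), -Inf)  # t1 < t_mrca
    ## inside support: finite
    expect_true(is.finite(logPosterior(2, 1, 20, 20, cfg)))
})

test_that("with fixed times the rate posterior is conjugate Gamma", {
    cfg <- timingConfig(ncptgCounts, ratePriorMean = 1.71)
    g <- 40 * 7 / 365.25
    q <- posteriorQuadrature(cfg, fixedTimes = list(tMrca = g))
    TA <- ageToYears(39, 11, 26) + g
    TB <- ageToYears(38, 5, 14) + g
    shape <- 1 + 2 + 89 + 114
    rate <- 1 / 1.71 + (TA + TB - g)
    s <- posteriorSummary(q)
    expect_lt(abs(s$mean[s$param == "lambda"] - shape / rate), 2e-3)
    expect_lt(abs(s$median[s$param == "lambda"] -
                  qgamma(0.5, shape, rate)), 2e-3)
    expect_lt(abs(s$q97.5[s$param == "lambda"] -
                  qgamma(0.975, shape, rate)), 5e-3)
    ## the worked value: mean ~2.581 mutations/genome/year
    expect_lt(abs(s$mean[s$param == "lambda"] - 2.581), 5e-3)
})

test_that("doubling the quadrature grid leaves the means unchanged", {
    cfg <- timingConfig(ncptgCounts, ratePriorMean = 1.71)
    q1 <- posteriorSummary(posteriorQuadrature(cfg, nGrid = 800))
    q2 <- posteriorSummary(posteriorQuadrature(cfg, nGrid = 1600))
    expect_true(all(abs(q1$mean - q2$mean) / abs(q2$mean) < 1e-3))
    expect_error(posteriorQuadrature(cfg, nGrid = 50), ">= 200")
})

test_that("a flat likelihood returns the uniform MRCA prior", {
    ## all counts zero and the rate pinned near zero by a tight bound
    cfg <- timingConfig(lineageCounts(0, 0, 0), ratePriorMean = 1e-4,
                        rateUpperBound = 1e-4,
                        exposureMode = "fixed_endpoint",
                        chains = 5, iters = 4000, warmup = 1000, seed = 2)
    fit <- fitMcmc(cfg, bridge = FALSE)
    tm <- posteriorDraws(fit)[, "t_mrca"]
    expect_gte(length(tm), 10000)
    U <- 37 + 40 * 7 / 365.25
    ks <- suppressWarnings(stats::ks.test(tm, "punif", 0, U))
    expect_lt(unname(ks$statistic), 0.02)
})

test_that("the posterior MRCA time increases with the shared count", {
    means <- vapply(0:10, function(s) {
        cfg <- timingConfig(lineageCounts(s, 89, 114),
                            ratePriorMean = 1.71)
        su <- posteriorSummary(posteriorQuadrature(cfg, nGrid = 200))
        su$mean[su$param == "t_mrca"]
    }, numeric(1))
    expect_true(all(diff(means) > 0))
})

test_that("the timing conclusion is robust to doubling the rate prior mean", {
    s1 <- posteriorSummary(posteriorQuadrature(
        timingConfig(ncptgCounts, ratePriorMean = 1.71)))
    s2 <- posteriorSummary(posteriorQuadrature(
        timingConfig(ncptgCounts, ratePriorMean = 3.42)))
    shift <- abs(s1$median[s1$param == "t_mrca"] -
                 s2$median[s2$param == "t_mrca"])
    width <- s1$q97.5[s1$param == "t_mrca"] - s1$q2.5[s1$param == "t_mrca"]
    expect_lt(shift, width)
})

test_that("MCMC agrees with the quadrature oracle on a light config", {
    cfg <- timingConfig(ncptgCounts, ratePriorMean = 1.71,
                        exposureMode = "fixed_endpoint",
                        chains = 3, iters = 8000, warmup = 2000, seed = 8)
    fit <- fitMcmc(cfg, bridge = FALSE)
    expect_true(all(fit@diagnostics$rhat < 1.01))
    q <- posteriorSummary(posteriorQuadrature(cfg))
    m <- posteriorSummary(fit)
    expect_lt(abs(m$mean[1] / q$mean[1] - 1), 0.03)
    expect_lt(abs(m$mean[2] - q$mean[2]), 0.05)
    ## reproducible under seed
    fit2 <- fitMcmc(cfg, bridge = FALSE)
    expect_identical(posteriorDraws(fit), posteriorDraws(fit2))
})

test_that("bridge sampling recovers a known conjugate marginal likelihood", {
    ## Exp(mean mu) prior on lambda, y ~ Pois(lambda E):
    ## ML = E^y / mu / (1/mu + E)^(y+1) exactly
    mu <- 2; E <- 10; y <- 18
    ## the Poisson y! cancels against the Gamma(y+1) integral
    logmlTrue <- y * log(E) - log(mu) - (y + 1) * log(1 / mu + E)
    set.seed(4)
    lam <- rgamma(6000, y + 1, 1 / mu + E)      # exact posterior draws
    x <- log(lam)
    logq <- function(X) {
        l <- exp(X[, 1])
        dexp(l, 1 / mu, log = TRUE) + dpois(y, l * E, log = TRUE) + X[, 1]
    }
    br <- marginalLikelihoodBridge(cbind(x), logq, seed = 1)
    expect_lt(abs(br$logml - logmlTrue), 3 * br$se)
    ## two proposal seeds agree within their combined error
    br2 <- marginalLikelihoodBridge(cbind(x), logq, seed = 2)
    expect_lt(abs(br$logml - br2$logml), 3 * sqrt(br$se^2 + br2$se^2))
    expect_error(marginalLikelihoodBridge(cbind(x[1:100]), logq),
                 "4000")
})

test_that("model comparison reports Bayes factors only on identical data", {
    cfgL <- timingConfig(ncptgCounts, ratePriorMean = 1.71)
    cfgF <- timingConfig(ncptgCounts, ratePriorMean = 1.71,
                         exposureMode = "fixed_endpoint")
    qL <- posteriorQuadrature(cfgL, nGrid = 200)
    qF <- posteriorQuadrature(cfgF, nGrid = 200)
    tab <- compareModels(list(latent = qL, fixed = qF))
    expect_equal(tab$logBF[1], 0)
    expect_true(is.finite(tab$logBF[2]))
    ## identical fits give a zero log Bayes factor
    tab0 <- compareModels(list(a = qL, b = qL))
    expect_equal(tab0$logBF[2], 0)
    ## different count data refuse comparison
    qOther <- posteriorQuadrature(
        timingConfig(lineageCounts(7, 91, 90), ratePriorMean = 10.6),
        nGrid = 200)
    expect_error(compareModels(list(qL, qOther)), "different count")
})

test_that("configuration validity guards impossible settings", {
    expect_error(timingConfig(ncptgCounts, ratePriorMean = -1), "positive")
    expect_error(timingConfig(ncptgCounts, ratePriorMean = 1.71,
                              tMrcaPriorUpper = 45), "tMrcaPriorUpper")
    expect_error(timingConfig(ncptgCounts, ratePriorMean = 1.71,
                              iters = 100, warmup = 200), "warmup")
    expect_error(lineageCounts(-1, 2, 3), "non-negative")
})
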