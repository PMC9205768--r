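## Convergence diagnostics for MCMC output.

#' Split R-hat
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so that within-chain trends register as apparent non-convergence.
#'
#' @param x draws matrix, iterations x chains.
#' @return the split R-hat (>= 1 up to Monte Carlo noise; NA for constant
#'   draws).
#' @export
splitRhat <- function(x) {
    x <- as.matrix(x)
    n <- nrow(x)
    half <- floor(n / 2)
    sp <- cbind(x[seq_len(half), , drop = FALSE],
                x[seq(n - half + 1, n), , drop = FALSE])
    m <- ncol(sp); nn <- nrow(sp)
    mu <- colMeans(sp)
    W <- mean(apply(sp, 2, var))
    if (!is.finite(W) || W == 0) return(NA_real_)
    B <- nn * var(mu)
    sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based bulk effective sample size: per-chain
#' autocorrelations are averaged and summed over Geyer initial positive
#' pairs.
#'
#' @param x draws matrix, iterations x chains.
#' @return estimated effective sample size.
#' @export
essBasic <- function(x) {
    x <- as.matrix(x)
    n <- nrow(x); m <- ncol(x)
    maxLag <- min(n - 1L, 2000L)
    rho <- rowMeans(vapply(seq_len(m), function(j)
        as.vector(acf(x[, j], lag.max = maxLag, plot = FALSE,
                      demean = TRUE)$acf),
        numeric(maxLag + 1L)))
    ## Geyer: sum autocorrelation pairs while their sum stays positive
    tau <- 1
    k <- 1L
    while (k + 1L <= maxLag) {
        pair <- rho[k + 1L] + rho[k + 2L]
        if (is.na(pair) || pair < 0) break
        tau <- tau + 2 * pair
        k <- k + 2L
    }
    m * n / tau
}
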