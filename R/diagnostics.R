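## Geweke convergence diagnostic.

#' Geweke convergence diagnostic for a scalar chain
#'
#' Compares the mean of an early window (first `fracFirst` of the chain)
#' with a late window (last `fracLast`) via
#' \deqn{z = (\bar x_A - \bar x_B) / \sqrt{\hat S_A/n_A + \hat S_B/n_B},}
#' where each \eqn{\hat S} is the spectral density of the window at
#' frequency zero, estimated by a Bartlett lag-window sum of empirical
#' autocovariances with the Andrews AR(1) plug-in truncation lag (short
#' for near-white chains, long for sticky ones). |z| < 1.96 is the
#' conventional no-drift verdict at the 5% level.
#'
#' @param chain numeric sample path, length >= 100.
#' @param fracFirst,fracLast window fractions (defaults 0.1 and 0.5;
#'   must not overlap).
#' @return list with `z`, `converged` (|z| < 1.96), and the two window
#'   means.
#' @export
#' @examples
#' set.seed(1)
#' gewekeDiag(rnorm(1000))$converged
gewekeDiag <- function(chain, fracFirst = 0.1, fracLast = 0.5) {
    chain <- as.numeric(chain)
    N <- length(chain)
    if (N < 100) stop("chain too short for the Geweke diagnostic (need >= 100)")
    if (fracFirst + fracLast > 1)
        stop("windows overlap: fracFirst + fracLast must be <= 1")
    nA <- floor(fracFirst * N)
    nB <- floor(fracLast * N)
    a <- chain[seq_len(nA)]
    b <- chain[seq.int(N - nB + 1, N)]
    sA <- spectrum0Bartlett(a)
    sB <- spectrum0Bartlett(b)
    if (sA <= 0 || sB <= 0)
        stop("zero-variance window; Geweke z undefined")
    z <- (mean(a) - mean(b)) / sqrt(sA / nA + sB / nB)
    list(z = z, converged = abs(z) < 1.96,
         meanFirst = mean(a), meanLast = mean(b))
}

## Spectral density at frequency zero: Bartlett lag window over the
## empirical autocovariances. Truncation lag by the Andrews AR(1)
## plug-in, so the window stretches with the chain's autocorrelation.
spectrum0Bartlett <- function(x) {
    n <- length(x)
    m <- bartlettLag(x)
    g <- as.numeric(stats::acf(x, lag.max = m, type = "covariance",
                               demean = TRUE, plot = FALSE)$acf)
    if (m == 0) return(g[1])
    w <- 1 - seq_len(m) / (m + 1)
    g[1] + 2 * sum(w * g[-1])
}

bartlettLag <- function(x) {
    n <- length(x)
    r1 <- stats::acf(x, lag.max = 1, plot = FALSE,
                     demean = TRUE)$acf[2]
    if (!is.finite(r1)) return(floor(n^(1/3)))
    a <- 4 * r1^2 / (1 - r1^2)^2
    min(n - 1L, max(1L, ceiling(1.1447 * (a * n)^(1/3))))
}
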