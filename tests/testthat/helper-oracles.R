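## Independent oracles used by the tests. Each one deliberately takes a
## different computational route from the package implementation it checks.

## Moran's I by the O(n^2) definitional double loop
bruteMoran <- function(x, W, style = c("W", "B")) {
    style <- match.arg(style)
    W <- as.matrix(W)
    n <- length(x)
    if (style == "W") {
        rs <- rowSums(W)
        for (i in seq_len(n)) if (rs[i] > 0) W[i, ] <- W[i, ] / rs[i]
    }
    z <- x - mean(x)
    num <- 0
    for (i in seq_len(n))
        for (j in seq_len(n))
            num <- num + W[i, j] * z[i] * z[j]
    (n / sum(W)) * num / sum(z^2)
}

## dense log-determinant
denseLogDet <- function(M) {
    as.numeric(determinant(as.matrix(M), logarithm = TRUE)$modulus)
}

## VIF via the determinant-ratio identity on standardized columns
vifDetRatio <- function(X) {
    Xs <- scale(X)
    G <- crossprod(Xs)
    Gi <- solve(G)
    diag(Gi) * diag(G)
}

## Geweke z with the spectral density at zero computed by FFT of the
## full (windowed) autocovariance sequence
fftGeweke <- function(chain, fracFirst = 0.1, fracLast = 0.5) {
    s0 <- function(x) {
        n <- length(x)
        ## same Andrews AR(1) plug-in lag as the implementation (the
        ## bandwidth rule is part of the estimator's definition); the
        ## autocovariances themselves come from the FFT route
        npad0 <- 2^ceiling(log2(2 * n))
        f0 <- fft(c(x - mean(x), rep(0, npad0 - n)))
        ac0 <- Re(fft(Mod(f0)^2, inverse = TRUE)) / npad0 / n
        r1 <- ac0[2] / ac0[1]
        aa <- 4 * r1^2 / (1 - r1^2)^2
        m <- min(n - 1, max(1, ceiling(1.1447 * (aa * n)^(1/3))))
        xc <- x - mean(x)
        npad <- 2^ceiling(log2(2 * n))
        f <- fft(c(xc, rep(0, npad - n)))
        ac <- Re(fft(Mod(f)^2, inverse = TRUE)) / npad / n
        g <- ac[seq_len(m + 1)]          # gamma(0..m)
        w <- 1 - seq_len(m) / (m + 1)
        g[1] + 2 * sum(w * g[-1])
    }
    N <- length(chain)
    nA <- floor(fracFirst * N); nB <- floor(fracLast * N)
    a <- chain[seq_len(nA)]
    b <- chain[seq.int(N - nB + 1, N)]
    (mean(a) - mean(b)) / sqrt(s0(a) / nA + s0(b) / nB)
}

## type-7 quantile by explicit sort + interpolation
sortQuantile <- function(x, p) {
    xs <- sort(x)
    n <- length(xs)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    g <- h - lo
    (1 - g) * xs[lo] + g * xs[hi]
}

## random symmetric binary graph (isolated nodes allowed)
randomGraph <- function(n, pEdge = 0.15) {
    W <- matrix(0, n, n)
    up <- upper.tri(W)
    W[up] <- rbinom(sum(up), 1, pEdge)
    W <- W + t(W)
    AreaAdjacency(W, ids = paste0("g", seq_len(n)))
}

## batch-means Monte Carlo standard error of a posterior median proxy
## (uses the mean's SE, conservative for well-mixed chains)
batchSE <- function(x, nBatch = 40) {
    n <- length(x)
    b <- floor(n / nBatch)
    m <- colMeans(matrix(x[seq_len(b * nBatch)], nrow = b))
    sd(m) / sqrt(nBatch)
}

## Plain-R reference sampler for the reduced model: Poisson counts with
## offset and iid Gaussian random intercepts (what the CAR model becomes
## with rho = 0 on an edgeless graph). Same priors as fitLeroux; its own
## fixed-scale Metropolis scheme, no shared code with the package sampler.
refIIDSampler <- function(O, E, X, nIter, nBurnin, seed,
                          vBeta = 1e5, aTau = 1, bTau = 0.01) {
    set.seed(seed)
    n <- length(O); p <- ncol(X) + 1
    Xf <- cbind(1, X)
    beta <- rep(0, p); beta[1] <- log(sum(O) / sum(E))
    phi <- rep(0, n); tau2 <- 0.1
    keep <- matrix(NA_real_, nIter - nBurnin, p)
    logpost <- function(beta, phi) {
        eta <- as.numeric(Xf %*% beta) + phi
        sum(O * eta - E * exp(eta)) - sum(beta^2) / (2 * vBeta)
    }
    for (it in seq_len(nIter)) {
        ## joint random-walk on beta
        prop <- beta + rnorm(p, 0, 0.04)
        if (log(runif(1)) < logpost(prop, phi) - logpost(beta, phi))
            beta <- prop
        ## componentwise random-walk on phi, prior N(0, tau2)
        eta0 <- as.numeric(Xf %*% beta)
        for (i in seq_len(n)) {
            pr <- phi[i] + rnorm(1, 0, 0.3)
            d <- O[i] * (pr - phi[i]) -
                E[i] * (exp(eta0[i] + pr) - exp(eta0[i] + phi[i])) -
                (pr^2 - phi[i]^2) / (2 * tau2)
            if (log(runif(1)) < d) phi[i] <- pr
        }
        ## recentre (same identifiability convention)
        m <- mean(phi); phi <- phi - m; beta[1] <- beta[1] + m
        ## conjugate tau2
        tau2 <- 1 / rgamma(1, aTau + n / 2, rate = bTau + sum(phi^2) / 2)
        if (it > nBurnin) keep[it - nBurnin, ] <- beta
    }
    keep
}

## small stratified table fixture built in code: 2 areas, all 16 strata
tinyTable <- function() {
    st <- defaultStrata()
    n <- matrix(500, nrow(st), 2,
                dimnames = list(rownames(st), c("east", "west")))
    O <- matrix(0, nrow(st), 2, dimnames = dimnames(n))
    O["male_41_50", "east"] <- 2
    O["female_61_70", "west"] <- 3
    AreaCounts(O, n)
}

## write a tiny table to CSV and return the path
tinyTableCSV <- function(dir = tempdir()) {
    path <- file.path(dir, "tiny-areas.csv")
    writeAreaTable(tinyTable(), path)
    path
}
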