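test_that("Leroux precision interpolates identity and graph Laplacian", {
    adj <- makeLattice(3, 3)
    W <- as.matrix(adjacencyMatrix(adj))
    L <- diag(rowSums(W)) - W
    expect_equal(as.matrix(lerouxPrecision(0, adj)), diag(9),
                 ignore_attr = TRUE)
    ## rho -> 1 limit approaches the intrinsic CAR Laplacian
    expect_equal(as.matrix(lerouxPrecision(1 - 1e-10, adj)), L,
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_error(lerouxPrecision(1, adj), "\\[0, 1\\)")
    expect_error(lerouxPrecision(-0.1, adj), "\\[0, 1\\)")
})

test_that("precision is positive definite for rho in [0,1) on random graphs", {
    set.seed(12)
    for (k in 1:5) {
        adj <- randomGraph(sample(5:30, 1), 0.2)
        for (rho in c(0, 0.3, 0.7, 0.95, 0.999)) {
            Q <- as.matrix(lerouxPrecision(rho, adj))
            expect_silent(chol(Q))   # Cholesky succeeds iff PD
        }
    }
})

test_that("eigenvalue log-determinant equals the dense one", {
    set.seed(14)
    for (n in c(5, 17, 40)) {
        adj <- randomGraph(n, 0.25)
        lam <- eigen(diag(rowSums(as.matrix(adjacencyMatrix(adj)))) -
                     as.matrix(adjacencyMatrix(adj)),
                     symmetric = TRUE, only.values = TRUE)$values
        for (rho in c(0, 0.42, 0.9)) {
            expect_equal(lerouxLogDet(rho, adj),
                         denseLogDet(lerouxPrecision(rho, adj)),
                         tolerance = 1e-8)
            expect_equal(lerouxLogDet(rho, eigenvalues = lam),
                         denseLogDet(lerouxPrecision(rho, adj)),
                         tolerance = 1e-8)
        }
    }
})

test_that("isolated areas keep a proper prior: precision (1 - rho)", {
    W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
    adj <- AreaAdjacency(W)
    Q <- as.matrix(lerouxPrecision(0.8, adj))
    expect_equal(Q[3, 3], 0.2)
})

test_that("fit preconditions are enforced", {
    d <- simulateAreaData(simConfig(rows = 3, cols = 3, seed = 5))
    tab <- d$table; adj <- d$adjacency
    O <- colSums(observedCounts(tab))
    expect_error(fitLeroux(O, adj, E = rep(-1, 9)), "negative expected")
    expect_error(fitLeroux(O + 1, adj, E = rep(0, 9)), "non-positive offset")
    X <- cbind(a = rnorm(9), b = rnorm(9))
    expect_error(fitLeroux(O, adj, covariates = cbind(X, c = X[, 1] + X[, 2]),
                           E = rep(5, 9), nIter = 200, nBurnin = 50),
                 "rank-deficient")
    expect_error(fitLeroux(tab, adj, covariates = "nope",
                           nIter = 200, nBurnin = 50), "nope")
    expect_error(fitLeroux(O, adj, E = rep(5, 9), nIter = 100,
                           nBurnin = 200), "nBurnin")
})

test_that("areas with zero expected count are excluded with a warning", {
    d <- simulateAreaData(simConfig(rows = 3, cols = 3, seed = 5))
    O <- colSums(observedCounts(d$table))
    E <- expectedCounts(d$table)
    O[5] <- 0; E[5] <- 0
    expect_warning(
        fit <- fitLeroux(unname(O), d$adjacency, E = unname(E),
                         nIter = 400, nBurnin = 100, seed = 1),
        "excluded")
    expect_equal(length(fit@modelInfo$E), 8)
})

test_that("identical seed and settings give bit-identical chains", {
    d <- simulateAreaData(simConfig(rows = 4, cols = 4, seed = 6))
    f1 <- fitLeroux(d$table, d$adjacency, nIter = 500, nBurnin = 100,
                    seed = 99)
    f2 <- fitLeroux(d$table, d$adjacency, nIter = 500, nBurnin = 100,
                    seed = 99)
    expect_identical(mcmcSamples(f1), mcmcSamples(f2))
    f3 <- fitLeroux(d$table, d$adjacency, nIter = 500, nBurnin = 100,
                    seed = 100)
    expect_false(identical(mcmcSamples(f1)$beta, mcmcSamples(f3)$beta))
})

test_that("a single balanced area has fitted risk near 1", {
    adj1 <- AreaAdjacency(matrix(0, 1, 1), ids = "only")
    fit <- fitLeroux(c(only = 5), adj1, E = c(only = 5),
                     nIter = 20000, nBurnin = 5000, rhoFixed = 0, seed = 2)
    s <- mcmcSamples(fit)
    idx <- attr(s$phi, "keptIndex")
    risk <- exp(s$beta[idx, 1] + s$phi[, 1])
    expect_gt(median(risk), 0.8)
    expect_lt(median(risk), 1.25)
})

test_that("with rho = 0 and no edges the fit matches an independent iid-intercept sampler", {
    set.seed(4)
    n <- 12
    X <- cbind(x = rnorm(n))
    E <- runif(n, 10, 30)
    O <- rpois(n, E * exp(0.3 + 0.2 * X[, 1]))
    adj0 <- AreaAdjacency(matrix(0, n, n), ids = as.character(seq_len(n)))
    fit <- fitLeroux(O, adj0, covariates = X, E = E, nIter = 60000,
                     nBurnin = 10000, rhoFixed = 0, seed = 11)
    beta <- mcmcSamples(fit)$beta
    ref <- refIIDSampler(O, E, X, nIter = 60000, nBurnin = 10000, seed = 12)
    for (j in 1:2) {
        se <- sqrt(batchSE(beta[, j])^2 + batchSE(ref[, j])^2)
        expect_lt(abs(median(beta[, j]) - median(ref[, j])), 3 * se)
    }
})

test_that("smoothed SMR shrinks raw SMR and respects its direction", {
    ## constant-risk lattice with generous E: sSMR hugs 1
    set.seed(21)
    n <- 100
    adj <- makeLattice(10, 10)
    E <- runif(n, 20, 40)
    O <- rpois(n, E)
    ss <- smoothedSMR(setNames(O, areaIds(adj)), adj, E = E,
                      nIter = 6000, nBurnin = 1000, seed = 3)
    expect_true(all(ss$ssmr > 0.8 & ss$ssmr < 1.25))
    ## a wild small-E area is pulled toward its unit-risk neighbors
    ## (neighbors at O = E exactly, so the ambient risk surface is 1)
    E2 <- rep(20, n); E2[45] <- 0.5
    O2 <- E2; O2[45] <- 3               # raw SMR 6
    ss2 <- smoothedSMR(setNames(O2, areaIds(adj)), adj, E = E2,
                       nIter = 6000, nBurnin = 1000, seed = 4)
    expect_gt(ss2$ssmr[45], 1)
    expect_lt(ss2$ssmr[45], 6)
    ## variance shrinkage on simulated datasets
    for (s in 1:2) {
        d <- simulateAreaData(simConfig(rows = 6, cols = 6, seed = s))
        raw <- smr(d$table)
        sm <- smoothedSMR(d$table, d$adjacency, nIter = 4000,
                          nBurnin = 1000, seed = s)
        expect_lte(var(sm$ssmr), var(raw$smr))
    }
})

test_that("shrinkage is stronger where expected counts are smaller", {
    set.seed(31)
    n <- 144
    adj <- makeLattice(12, 12)
    E <- rep(c(2, 50), length.out = n)
    O <- rpois(n, E)
    raw <- O / E
    ss <- smoothedSMR(setNames(O, areaIds(adj)), adj, E = E,
                      nIter = 6000, nBurnin = 1000, seed = 5)
    pull <- abs(ss$ssmr - raw)   # how far each area moved
    expect_gt(median(pull[E == 2]), median(pull[E == 50]))
})
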