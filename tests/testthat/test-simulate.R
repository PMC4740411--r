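test_that("lattice contiguity has the textbook structure", {
    a22 <- makeLattice(2, 2)
    expect_equal(unname(neighborCounts(a22)), rep(2, 4))
    expect_equal(sum(adjacencyMatrix(a22)) / 2, 4)   # 4 edges
    a33q <- makeLattice(3, 3, "queen")
    expect_equal(unname(neighborCounts(a33q))[5], 8)  # center cell
    corner <- unname(neighborCounts(makeLattice(4, 5, "queen")))[1]
    expect_equal(corner, 3)
    expect_error(makeLattice(1, 5), "at least 2 x 2")
})

test_that("rook edge count matches the combinatorial formula", {
    set.seed(25)
    for (k in 1:5) {
        r <- sample(2:30, 1); c <- sample(2:30, 1)
        adj <- makeLattice(r, c)
        expect_equal(sum(adjacencyMatrix(adj)) / 2,
                     r * (c - 1) + c * (r - 1))
    }
})

test_that("null configuration gives unit risk on average", {
    ## tau2 = 0, beta = 0: all true risks are 1; mean O/E within the
    ## CLT bound 3/sqrt(sum(E))
    cfg <- simConfig(rows = 10, cols = 10, seed = 42, tau2 = 0,
                     beta = c(physicians_per_1000 = 0))
    d <- simulateAreaData(cfg)
    expect_true(all(d$truth$risk == 1))
    O <- sum(observedCounts(d$table))
    E <- sum(d$truth$E)
    expect_lt(abs(O / E - 1), 3 / sqrt(E))
})

test_that("the engineered covariate pair hits its target correlation", {
    d <- simulateAreaData(simConfig(rows = 44, cols = 43, seed = 1))  # 1892 areas
    r <- cor(covariates(d$table)$income, covariates(d$table)$university)
    expect_lt(abs(r - 0.829), 0.03)
    ## psychiatrist presence frequency near its configured probability
    p <- mean(covariates(d$table)$psych_presence)
    expect_lt(abs(p - 0.55), 0.05)
})

test_that("spatial dependence shows up as Moran autocorrelation of phi", {
    ## paired over seeds: phi at rho = 0.9 more autocorrelated than rho = 0
    adj <- makeLattice(10, 10)
    Q9 <- chol(as.matrix(lerouxPrecision(0.9, adj)))
    wins <- 0
    for (s in 1:20) {
        set.seed(s)
        phi9 <- backsolve(Q9, rnorm(100))
        phi0 <- rnorm(100)
        i9 <- moransI(phi9, adj, nPerm = 99, seed = s)@statistic
        i0 <- moransI(phi0, adj, nPerm = 99, seed = s)@statistic
        wins <- wins + (i9 > i0)
    }
    expect_gte(wins, 19)
})

test_that("same seed reproduces the dataset byte-for-byte through IO", {
    cfg <- simConfig(rows = 5, cols = 5, seed = 77)
    d1 <- simulateAreaData(cfg)
    d2 <- simulateAreaData(cfg)
    expect_identical(observedCounts(d1$table), observedCounts(d2$table))
    expect_identical(d1$truth, d2$truth)
    f1 <- tempfile(); f2 <- tempfile()
    writeAreaTable(d1$table, f1); writeAreaTable(d2$table, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("the truth record reproduces every intermediate quantity", {
    d <- simulateAreaData(simConfig(rows = 6, cols = 6, seed = 13))
    tr <- d$truth
    ## E recomputable from populations x rates
    E <- as.numeric(crossprod(populations(d$table), tr$rates))
    expect_equal(E, unname(tr$E))
    ## risk recomputable from covariates, beta, phi
    eta <- as.numeric(tr$covariates %*% tr$beta) + tr$phi
    expect_equal(exp(eta), unname(tr$risk))
    expect_equal(sum(observedCounts(d$table)), tr$totalObserved)
})

test_that("expectation mode is deterministic and seed-independent", {
    cfg1 <- simConfig(rows = 5, cols = 5, seed = 1)
    cfg2 <- simConfig(rows = 5, cols = 5, seed = 999)
    e1 <- expectationDataset(cfg1)
    e2 <- expectationDataset(cfg2)
    expect_identical(observedCounts(e1$table), observedCounts(e2$table))
    expect_identical(e1$truth$phi, e2$truth$phi)
})

test_that("expectation mode recovers configured rates and risks", {
    ## with unit risks, pooled rates equal the configured national rates
    ## up to the integer rounding of each cell
    cfg <- simConfig(rows = 10, cols = 10, tau2 = 0,
                     beta = c(physicians_per_1000 = 0))
    e <- expectationDataset(cfg)
    got <- nationalRates(e$table)
    want <- cfg$rates[names(got)]
    expect_equal(unname(got), unname(want), tolerance = 0.02)
    ## with effects on: per-area SMR tracks the true risk
    cfg2 <- simConfig(rows = 10, cols = 10)
    e2 <- expectationDataset(cfg2)
    s <- smr(e2$table, expectedCounts(e2$table, e2$truth$rates))
    keep <- s$expected > 20   # rounding noise negligible only with mass
    expect_equal(s$smr[keep], unname(e2$truth$risk[keep]),
                 tolerance = 0.05)
})

test_that("irregular graphs are valid contiguity structures", {
    set.seed(3)
    cfg <- simConfig(type = "irregular", nAreas = 60, degree = 6, seed = 3)
    d <- simulateAreaData(cfg)
    adj <- d$adjacency
    W <- as.matrix(adjacencyMatrix(adj))
    expect_true(isSymmetric(W))
    expect_true(all(diag(W) == 0))
    expect_equal(length(areaIds(adj)), 60)
    expect_true(validObject(d$table))
})
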