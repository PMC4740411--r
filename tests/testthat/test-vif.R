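## exactly-correlated pair: x = u1, y = r*u1 + sqrt(1-r^2)*u2 with u1,u2
## orthonormal and centered, so the sample correlation is r exactly
exactPair <- function(n, r, seed = 1) {
    set.seed(seed)
    A <- scale(matrix(rnorm(n * 2), n), center = TRUE, scale = FALSE)
    q <- qr.Q(qr(A))
    cbind(x = q[, 1], y = r * q[, 1] + sqrt(1 - r^2) * q[, 2])
}

test_that("orthogonal columns have VIF exactly 1", {
    n <- 40
    set.seed(3)
    A <- scale(matrix(rnorm(n * 3), n), center = TRUE, scale = FALSE)
    X <- qr.Q(qr(A))          # mutually orthogonal, centered
    colnames(X) <- c("a", "b", "c")
    expect_equal(unname(vif(X)), rep(1, 3), tolerance = 1e-10)
})

test_that("the two-covariate closed form 1/(1-r^2) holds exactly", {
    X <- exactPair(200, 0.829)
    v <- vif(X)
    expect_equal(unname(v), rep(1 / (1 - 0.829^2), 2), tolerance = 1e-10)
    expect_equal(unname(round(v, 2)), c(3.2, 3.2))
})

test_that("exact linear dependence is reported as infinite VIF, not an error", {
    set.seed(4)
    x <- rnorm(30)
    X <- cbind(a = x, b = 2 * x, c = rnorm(30))
    v <- vif(X)
    expect_true(is.infinite(v["a"]) && is.infinite(v["b"]))
    expect_true(is.finite(v["c"]))
})

test_that("degenerate designs are refused", {
    expect_error(vif(cbind(a = rnorm(10))), "at least two")
    expect_error(vif(matrix(rnorm(6), 2, 3)), "more areas")
    expect_error(vif(cbind(a = rep(1, 10), b = rnorm(10))), "constant")
})

test_that("VIF agrees with the determinant-ratio identity", {
    set.seed(6)
    for (k in 1:3) {
        n <- 60
        X <- matrix(rnorm(n * 5), n) %*% chol(0.5 * diag(5) + 0.5)
        colnames(X) <- paste0("v", 1:5)
        expect_equal(unname(vif(X)), unname(vifDetRatio(X)),
                     tolerance = 1e-8)
    }
})

test_that("screening below threshold drops nothing and is idempotent", {
    set.seed(7)
    X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
    rep1 <- vifScreen(X, threshold = 2.5)
    expect_length(rep1@dropped, 0)
    expect_true(all(rep1@vif <= 2.5))
    ## idempotence on a screen that did drop something
    Xc <- cbind(exactPair(100, 0.9, seed = 2), z = rnorm(100))
    rep2 <- vifScreen(Xc, threshold = 2.5)
    expect_length(rep2@dropped, 1)
    rep3 <- vifScreen(retainedCovariates(rep2), threshold = 2.5)
    expect_length(rep3@dropped, 0)
    expect_true(all(rep3@vif <= 2.5))
})

test_that("near-duplicate pair: exactly one member dropped, rest clean", {
    set.seed(9)
    n <- 150
    base <- rnorm(n)
    X <- cbind(p = base + rnorm(n, 0, 0.1),
               q = base + rnorm(n, 0, 0.1),
               r = rnorm(n))
    rep <- vifScreen(X, threshold = 2.5)
    expect_length(rep@dropped, 1)
    expect_true(rep@dropped %in% c("p", "q"))
    ## brute-force check of the post-drop VIFs
    expect_true(all(vif(retainedCovariates(rep)) <= 2.5))
    ## the dropped one had the max VIF at step 1
    expect_identical(rep@dropped, names(which.max(rep@steps[[1]])))
})

test_that("the engineered six-covariate scenario drops a single pair member", {
    ## generator scenario: income/university correlated at 0.829 with
    ## modest links to the rest, inflating the pair's VIFs past 2.5
    d <- simulateAreaData(simConfig(rows = 20, cols = 20, seed = 101))
    X <- as.matrix(covariates(d$table)[, c("unemployment", "income",
                                           "density", "crime", "divorce",
                                           "university")])
    v <- vif(X)
    expect_true(all(v[c("income", "university")] > 2.5))
    expect_true(all(v[setdiff(names(v), c("income", "university"))] < 2.5))
    rep <- vifScreen(X, threshold = 2.5)
    expect_length(rep@dropped, 1)
    expect_true(rep@dropped %in% c("income", "university"))
    expect_identical(rep@dropped, names(which.max(rep@steps[[1]])))
    expect_true(all(rep@vif <= 2.5))
    ## the reported pairwise correlation is near its engineered target
    expect_equal(rep@correlations["income", "university"], 0.829,
                 tolerance = 0.03)
})

test_that("ties in the maximal VIF break by column order", {
    ## two identical pairs: (a, b) duplicated; a has the first max
    set.seed(10)
    x <- rnorm(50); y <- rnorm(50)
    X <- cbind(a = x, b = x, c = y)
    rep <- vifScreen(X, threshold = 2.5)
    expect_identical(rep@dropped[1], "a")
})
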