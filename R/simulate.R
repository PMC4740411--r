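## Generative simulator: contiguity graphs and stratified count tables
## drawn from the exact model the package fits.

#' Regular lattice contiguity
#'
#' Rook (4-neighbor) or queen (8-neighbor) contiguity on a rows x cols
#' lattice. Cell (r, c) has index (r-1)*cols + c and id `a<index>`.
#'
#' @param rows,cols lattice dimensions (both >= 2).
#' @param contiguity `"rook"` (default) or `"queen"`.
#' @return an [AreaAdjacency-class] object.
#' @export
#' @examples
#' neighborCounts(makeLattice(2, 2))  # all 2
makeLattice <- function(rows, cols, contiguity = c("rook", "queen")) {
    contiguity <- match.arg(contiguity)
    if (rows < 2 || cols < 2) stop("lattice must be at least 2 x 2")
    idx <- function(r, c) (r - 1) * cols + c
    r <- rep(seq_len(rows), each = cols)
    c <- rep(seq_len(cols), times = rows)
    ii <- c(idx(r[c < cols], c[c < cols]),        # east
            idx(r[r < rows], c[r < rows]))        # south
    jj <- c(idx(r[c < cols], c[c < cols] + 1),
            idx(r[r < rows] + 1, c[r < rows]))
    if (contiguity == "queen") {
        se <- r < rows & c < cols
        sw <- r < rows & c > 1
        ii <- c(ii, idx(r[se], c[se]), idx(r[sw], c[sw]))
        jj <- c(jj, idx(r[se] + 1, c[se] + 1), idx(r[sw] + 1, c[sw] - 1))
    }
    n <- rows * cols
    W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                              dims = c(n, n))
    AreaAdjacency(W, ids = paste0("a", seq_len(n)))
}

#' Simulation configuration
#'
#' Bundles every knob of the generative model. The defaults emulate the
#' statistical structure of a nationwide municipality-level suicide
#' analysis: a 20 x 20 rook lattice (the default test scale; set
#' `rows`/`cols` or the irregular option for other sizes, e.g. ~1,900
#' areas), stratum populations log-uniform over three orders of
#' magnitude, stratum event rates of realistic magnitude (tens per
#' 100,000 person-years, higher for males and older ages), a
#' psychiatrist-presence indicator with presence probability 0.55, one
#' engineered covariate pair (income, university) correlated at 0.829,
#' and Leroux spatial effects with rho = 0.8, tau2 = 0.1.
#'
#' @param rows,cols lattice dimensions.
#' @param contiguity `"rook"` or `"queen"`.
#' @param type `"lattice"` or `"irregular"` (random planar-ish graph).
#' @param nAreas,degree size and mean degree for the irregular graph.
#' @param beta named true coefficients on the generated covariate scale
#'   (continuous covariates are standard normal; `psych_presence` is
#'   0/1).
#' @param rho,tau2 true Leroux dependence and variance.
#' @param popRange log-uniform range for each stratum population.
#' @param rates named national stratum rates (events per person); NULL
#'   for the built-in defaults.
#' @param psychPresenceProb probability an area has >= 1 psychiatrist.
#' @param pairCorrelation target correlation of the engineered
#'   income-university pair.
#' @param seed integer seed.
#' @return a list of class `"simConfig"`.
#' @export
simConfig <- function(rows = 20, cols = 20,
                      contiguity = "rook", type = c("lattice", "irregular"),
                      nAreas = rows * cols, degree = 5,
                      beta = c(physicians_per_1000 = 0.03,
                               psych_presence = -0.10,
                               unemployment = 0.04,
                               income = -0.05,
                               density = -0.05,
                               crime = 0.04,
                               divorce = -0.03,
                               university = 0),
                      rho = 0.8, tau2 = 0.1,
                      popRange = c(100, 1e5),
                      rates = NULL,
                      psychPresenceProb = 0.55,
                      pairCorrelation = 0.829,
                      seed = 1) {
    type <- match.arg(type)
    if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
    if (tau2 < 0) stop("tau2 must be non-negative")
    if (type == "lattice" && (rows < 2 || cols < 2))
        stop("lattice must be at least 2 x 2")
    if (abs(pairCorrelation) >= 1)
        stop("pairCorrelation must be in (-1, 1)")
    if (is.null(rates)) rates <- defaultStratumRates()
    structure(list(rows = rows, cols = cols, contiguity = contiguity,
                   type = type, nAreas = nAreas, degree = degree,
                   beta = beta, rho = rho, tau2 = tau2,
                   popRange = popRange, rates = rates,
                   psychPresenceProb = psychPresenceProb,
                   pairCorrelation = pairCorrelation, seed = seed),
              class = "simConfig")
}

## Plausible national stratum rates (events per person-year): magnitude
## tens per 100,000, male > female, rising with age.
defaultStratumRates <- function() {
    st <- defaultStrata()   # male rows first, then female, ages in order
    male <- c(2.5, 30, 30, 35, 45, 35, 30, 35) / 1e5
    female <- c(1, 12, 12, 12, 15, 15, 15, 20) / 1e5
    stats::setNames(c(male, female), rownames(st))
}

## correlation matrix of the 8 generated covariates; the income (4) /
## university (8) pair is engineered at cfg$pairCorrelation and each
## member leans modestly on other socioeconomic covariates so the pair's
## VIFs land above the pairwise-only value.
covariateCorrelation <- function(pairCorrelation) {
    nm <- c("physicians_per_1000", "psych_presence", "unemployment",
            "income", "density", "crime", "divorce", "university")
    R <- diag(8)
    dimnames(R) <- list(nm, nm)
    set2 <- function(a, b, v) {
        R[a, b] <<- v; R[b, a] <<- v
    }
    set2("income", "university", pairCorrelation)
    set2("income", "density", 0.30)
    set2("university", "density", 0.30)
    set2("income", "unemployment", -0.25)
    set2("university", "unemployment", -0.25)
    set2("physicians_per_1000", "psych_presence", 0.45)
    set2("physicians_per_1000", "density", 0.25)
    set2("crime", "density", 0.35)
    set2("divorce", "unemployment", 0.25)
    R
}

#' Simulate a stratified areal dataset from the generative model
#'
#' Draws covariates from the configured correlation structure (with the
#' psychiatrist indicator thresholded from a latent Gaussian), spatial
#' effects phi ~ MVN(0, tau2 * Q(rho, W)^-1) by Cholesky factorization of
#' the Leroux precision, stratum populations log-uniform, expected
#' counts E_i from populations x national rates, area totals O_i ~
#' Poisson(E_i exp(x_i' beta + phi_i)), and finally allocates each O_i to
#' strata by a multinomial on the stratum expected shares.
#'
#' @param cfg a [simConfig()] list.
#' @return list with `table` ([AreaCounts-class]), `adjacency`
#'   ([AreaAdjacency-class]) and `truth` (beta, rho, tau2, phi, per-area
#'   risk, E, rates, and bookkeeping totals for validation).
#' @export
#' @examples
#' d <- simulateAreaData(simConfig(rows = 4, cols = 4, seed = 7))
#' sum(observedCounts(d$table)) == d$truth$totalObserved
simulateAreaData <- function(cfg) {
    stopifnot(inherits(cfg, "simConfig"))
    set.seed(cfg$seed)
    simulateCore(cfg, expectation = FALSE)
}

#' Deterministic expectation-mode dataset
#'
#' Like [simulateAreaData()] but every stochastic draw is replaced by a
#' deterministic counterpart: covariates, populations and phi come from a
#' fixed internal stream (so the output does not depend on `cfg$seed`),
#' and observed counts are the rounded expectations
#' round(r_s * n_is * risk_i) instead of Poisson draws. This gives exact,
#' reproducible fixtures for downstream value tests.
#'
#' @param cfg a [simConfig()] list (its `seed` is ignored).
#' @return same structure as [simulateAreaData()].
#' @export
expectationDataset <- function(cfg) {
    stopifnot(inherits(cfg, "simConfig"))
    set.seed(20100101L)
    simulateCore(cfg, expectation = TRUE)
}

simulateCore <- function(cfg, expectation) {
    adj <- if (cfg$type == "lattice")
        makeLattice(cfg$rows, cfg$cols, cfg$contiguity)
    else irregularGraph(cfg$nAreas, cfg$degree)
    n <- length(areaIds(adj))
    ids <- areaIds(adj)
    st <- defaultStrata()
    S <- nrow(st)
    rates <- cfg$rates[rownames(st)]
    if (anyNA(rates)) stop("rates must name every stratum")

    ## covariates: latent MVN, psychiatrist indicator thresholded
    R <- covariateCorrelation(cfg$pairCorrelation)
    L <- chol(R)
    Z <- matrix(stats::rnorm(n * ncol(R)), n) %*% L
    colnames(Z) <- colnames(R)
    X <- Z
    X[, "psych_presence"] <-
        as.numeric(Z[, "psych_presence"] >
                   stats::qnorm(1 - cfg$psychPresenceProb))

    ## spatial effects from the Leroux prior
    phi <- if (cfg$tau2 > 0) {
        Q <- as.matrix(lerouxPrecision(cfg$rho, adj))
        Rq <- chol(Q)
        sqrt(cfg$tau2) * backsolve(Rq, stats::rnorm(n))
    } else rep(0, n)

    ## stratum populations, log-uniform
    pop <- matrix(round(exp(stats::runif(S * n, log(cfg$popRange[1]),
                                         log(cfg$popRange[2])))),
                  nrow = S, dimnames = list(rownames(st), ids))

    Emat <- pop * rates          # stratum-level expected counts
    E <- colSums(Emat)
    beta <- cfg$beta[colnames(X)]
    beta[is.na(beta)] <- 0
    eta <- as.numeric(X %*% beta) + phi
    risk <- exp(eta)
    mu <- E * risk

    Omat <- matrix(0, nrow = S, ncol = n, dimnames = dimnames(pop))
    if (expectation) {
        Omat[] <- round(Emat * rep(risk, each = S))
    } else {
        Otot <- stats::rpois(n, mu)
        for (i in seq_len(n)) {
            if (Otot[i] == 0) next
            pr <- Emat[, i] / E[i]
            o <- as.numeric(stats::rmultinom(1, Otot[i], pr))
            o <- capToPopulation(o, pop[, i], pr)
            Omat[, i] <- o
        }
    }
    Omat <- pmin(Omat, pop)      # belt-and-braces for expectation mode

    covDF <- as.data.frame(X)
    tab <- AreaCounts(Omat, pop, covariates = covDF, strata = st)
    truth <- list(beta = beta, rho = cfg$rho, tau2 = cfg$tau2,
                  phi = phi, risk = risk, E = E, rates = rates,
                  covariates = X,
                  totalObserved = sum(Omat),
                  totalPopulation = sum(pop),
                  stratumObserved = rowSums(Omat),
                  stratumPopulation = rowSums(pop))
    list(table = tab, adjacency = adj, truth = truth)
}

## move any multinomial overflow above a stratum's population into
## strata with slack, deterministically
capToPopulation <- function(o, npop, pr) {
    over <- o > npop
    if (!any(over)) return(o)
    excess <- sum(o[over] - npop[over])
    o[over] <- npop[over]
    slack <- npop - o
    ord <- order(pr, decreasing = TRUE)
    for (k in ord) {
        if (excess <= 0) break
        add <- min(excess, slack[k])
        o[k] <- o[k] + add
        excess <- excess - add
    }
    o
}

## random planar-ish contiguity: points in the unit square joined to
## their nearest neighbors, symmetrized
irregularGraph <- function(nAreas, degree) {
    pts <- cbind(stats::runif(nAreas), stats::runif(nAreas))
    d2 <- as.matrix(stats::dist(pts))
    diag(d2) <- Inf
    k <- max(1L, round(degree / 2))
    nbrs <- lapply(seq_len(nAreas), function(i)
        order(d2[i, ])[seq_len(k)])
    AreaAdjacency(nbrs, ids = paste0("a", seq_len(nAreas)))
}
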