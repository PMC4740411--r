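## The Leroux CAR Poisson model: precision structure, MCMC fit, smoothing.

#' Leroux CAR precision matrix
#'
#' Q(rho, W) = rho * (diag(w+) - W) + (1 - rho) * I. For rho in \[0, 1)
#' this is symmetric positive definite on any graph; rho = 0 gives
#' independent random effects (Q = I) and the rho -> 1 limit is the
#' intrinsic CAR graph Laplacian. Isolated areas have marginal precision
#' (1 - rho), so the prior stays proper.
#'
#' @param rho spatial dependence parameter in \[0, 1).
#' @param adj an [AreaAdjacency-class] object.
#' @return sparse symmetric precision matrix (unit variance scale; the
#'   model divides by tau2).
#' @export
#' @examples
#' lerouxPrecision(0, makeLattice(2, 2))  # identity
lerouxPrecision <- function(rho, adj) {
    if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1)
        stop("rho must be a single value in [0, 1)")
    W <- adjacencyMatrix(adj)
    n <- nrow(W)
    D <- Matrix::Diagonal(n, Matrix::rowSums(W))
    rho * (D - W) + (1 - rho) * Matrix::Diagonal(n)
}

#' Log-determinant of the Leroux precision via eigenvalues
#'
#' Uses the spectral identity log det Q(rho) = sum_k log(rho * l_k + 1 -
#' rho), where l_k are the eigenvalues of diag(w+) - W. The eigenvalues
#' are computed once and can be reused across rho values (as the sampler
#' does).
#'
#' @param rho spatial dependence in \[0, 1).
#' @param adj an [AreaAdjacency-class]; ignored if `eigenvalues` given.
#' @param eigenvalues optional precomputed eigenvalues of diag(w+) - W.
#' @return the log determinant (a scalar).
#' @export
lerouxLogDet <- function(rho, adj = NULL, eigenvalues = NULL) {
    if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
    if (is.null(eigenvalues)) {
        if (is.null(adj)) stop("supply 'adj' or 'eigenvalues'")
        eigenvalues <- carLaplacianEigen(adj)
    }
    sum(log(rho * eigenvalues + 1 - rho))
}

## eigenvalues of diag(w+) - W (dense, symmetric)
carLaplacianEigen <- function(adj) {
    W <- as.matrix(adjacencyMatrix(adj))
    M <- diag(rowSums(W), nrow(W)) - W
    eigen(M, symmetric = TRUE, only.values = TRUE)$values
}

#' Fit the Leroux CAR Poisson model by MCMC
#'
#' Hierarchical Bayesian Poisson regression with log expected count as
#' offset and Leroux CAR spatial random effects, sampled by adaptive
#' Metropolis-within-Gibbs (see the package vignette for the model and
#' sampler). Covariates are internally centered and scaled for sampling
#' and the coefficient draws are returned on the original covariate
#' scale, so summaries and relative risks refer to the units of the data
#' supplied. phi is recentred to mean zero every sweep with the mean
#' absorbed into the intercept. Priors: beta_j ~ N(0, priorBetaVar),
#' tau2 ~ inverse-gamma(priorTau2Shape, priorTau2Rate), rho ~ U[0, 1).
#'
#' Areas with zero expected count carry no information about the rate
#' ratio (the offset log E is undefined) and are excluded with a warning.
#'
#' @param x an [AreaCounts-class] object, or a numeric vector of observed
#'   area totals.
#' @param adj an [AreaAdjacency-class] in the same area order.
#' @param covariates covariate columns: a character vector naming columns
#'   of `covariates(x)`, a matrix/data.frame, or NULL for an
#'   intercept-only model.
#' @param E expected counts (offset); defaults to [expectedCounts()] of
#'   `x` when `x` is an AreaCounts.
#' @param nIter,nBurnin,thin MCMC controls (defaults 110000, 10000, 1).
#' @param priorBetaVar Gaussian prior variance for each coefficient
#'   (default 1e5).
#' @param priorTau2Shape,priorTau2Rate inverse-gamma prior for tau2
#'   (default 1 and 0.01).
#' @param rhoFixed fix rho at this value instead of sampling (e.g. 0 for
#'   independent random effects); NULL (default) samples rho.
#' @param seed integer seed; identical seed and settings give
#'   bit-identical chains.
#' @param phiEvery keep every `phiEvery`-th post-thinning phi sweep
#'   (memory control; NULL = automatic, keeping at most ~2e7 values).
#' @return a [LerouxFit-class] object.
#' @export
fitLeroux <- function(x, adj, covariates = NULL, E = NULL,
                      nIter = 110000, nBurnin = 10000, thin = 1,
                      priorBetaVar = 1e5, priorTau2Shape = 1,
                      priorTau2Rate = 0.01, rhoFixed = NULL, seed = 1,
                      phiEvery = NULL) {
    stopifnot(methods::is(adj, "AreaAdjacency"))
    if (nBurnin >= nIter) stop("nBurnin must be smaller than nIter")
    if (priorBetaVar <= 0 || priorTau2Shape <= 0 || priorTau2Rate <= 0)
        stop("prior hyperparameters must be positive")
    if (methods::is(x, "AreaCounts")) {
        O <- colSums(observedCounts(x))
        if (is.null(E)) E <- expectedCounts(x)
        if (is.character(covariates)) {
            cd <- covariates(x)
            missingCov <- setdiff(covariates, names(cd))
            if (length(missingCov))
                stop("covariate column not found: ",
                     paste(missingCov, collapse = ", "))
            covariates <- cd[, covariates, drop = FALSE]
        }
        ids <- areaIds(x)
    } else {
        ids <- if (!is.null(names(x))) names(x)
               else as.character(seq_along(x))
        O <- as.numeric(x)
        if (is.null(E)) stop("E must be supplied when x is a plain vector")
    }
    E <- as.numeric(E)
    if (length(E) != length(O)) stop("O and E lengths differ")
    if (length(areaIds(adj)) != length(O))
        stop("adjacency and area table sizes differ")
    if (any(E < 0)) stop("negative expected count")
    if (any(E == 0 & O > 0))
        stop("non-positive offset: area with E = 0 but observed events")
    keep <- E > 0
    if (!all(keep)) {
        warning(sum(!keep), " area(s) with E = 0 excluded from the fit",
                call. = FALSE)
        adj <- subsetAdjacency(adj, which(keep))
    }
    O <- O[keep]; E <- E[keep]; ids <- ids[keep]
    n <- length(O)

    Xc <- NULL
    covNames <- character()
    if (!is.null(covariates)) {
        Xc <- as.matrix(covariates)[keep, , drop = FALSE]
        if (!is.numeric(Xc)) stop("covariates must be numeric")
        if (is.null(colnames(Xc)))
            colnames(Xc) <- paste0("x", seq_len(ncol(Xc)))
        covNames <- colnames(Xc)
    }
    ctr <- if (!is.null(Xc)) colMeans(Xc) else numeric()
    scl <- if (!is.null(Xc)) apply(Xc, 2, stats::sd) else numeric()
    if (any(scl == 0))
        stop("constant covariate column: ", covNames[scl == 0][1])
    Xs <- cbind(`(Intercept)` = rep(1, n),
                if (!is.null(Xc)) sweep(sweep(Xc, 2, ctr), 2, scl, "/"))
    p <- ncol(Xs)
    if (qr(Xs)$rank < p) stop("rank-deficient design matrix")

    W <- adjacencyMatrix(adj)
    nbr <- lapply(seq_len(n), function(i) which(W[i, ] != 0) - 1L)
    lambda <- carLaplacianEigen(adj)
    sampleRho <- is.null(rhoFixed)
    rhoInit <- if (sampleRho) 0.5 else {
        if (rhoFixed < 0 || rhoFixed >= 1) stop("rhoFixed must be in [0, 1)")
        rhoFixed
    }
    nKeep <- (nIter - nBurnin) %/% thin
    if (nKeep < 1) stop("no post-burn-in draws to keep")
    if (is.null(phiEvery))
        phiEvery <- max(1L, ceiling(nKeep * n / 2e7))

    ## Poisson GLM fit supplies the starting point and a Fisher-scaled
    ## Cholesky to precondition the block proposal for beta
    glmFit <- tryCatch(
        stats::glm.fit(Xs, O, family = stats::poisson(),
                       offset = log(E)),
        error = function(e) NULL)
    betaInit <- rep(0, p)
    betaInit[1] <- log((sum(O) + 0.5) / sum(E))
    propChol <- diag(0.1, p)
    if (!is.null(glmFit) && all(is.finite(glmFit$coefficients))) {
        betaInit <- as.numeric(glmFit$coefficients)
        mu <- pmax(glmFit$fitted.values, 1e-8)
        info <- crossprod(Xs * sqrt(mu))
        V <- tryCatch(solve(info), error = function(e) NULL)
        if (!is.null(V))
            propChol <- t(chol((V + t(V)) / 2)) *
                (2.38 / sqrt(p))   # classic RW scaling, adapted further
    }

    set.seed(seed)
    res <- leroux_mcmc_cpp(O, E, Xs, nbr, lambda, betaInit, propChol,
                           as.integer(nIter), as.integer(nBurnin),
                           as.integer(thin), as.integer(phiEvery),
                           priorBetaVar, priorTau2Shape, priorTau2Rate,
                           sampleRho, rhoInit, 0.1)

    ## back-transform coefficients to the original covariate scale
    beta <- res$beta
    colnames(beta) <- colnames(Xs)
    if (length(covNames)) {
        bstd <- beta[, -1, drop = FALSE]
        borig <- sweep(bstd, 2, scl, "/")
        beta[, 1] <- beta[, 1] - as.numeric(borig %*% ctr)
        beta[, -1] <- borig
    }
    phi <- res$phi
    colnames(phi) <- ids
    attr(phi, "keptIndex") <- as.integer(res$phiIdx)
    attr(phi, "phiEvery") <- as.integer(phiEvery)

    draws <- cbind(beta, tau2 = as.numeric(res$tau2))
    rrFlag <- c(FALSE, rep(TRUE, length(covNames)), FALSE)
    if (sampleRho) {
        draws <- cbind(draws, rho = as.numeric(res$rho))
        rrFlag <- c(rrFlag, FALSE)
    }
    colnames(draws) <- c(colnames(beta), "tau2",
                         if (sampleRho) "rho")
    summ <- summarizeDraws(draws, rr = rrFlag,
                           geweke = nrow(draws) >= 100)

    accept <- res$accept[!is.na(res$accept)]
    samples <- list(beta = beta, tau2 = res$tau2,
                    rho = if (sampleRho) res$rho else rep(rhoInit, nKeep),
                    phi = phi)
    methods::new("LerouxFit", samples = samples, summary = summ,
                 accept = accept,
                 modelInfo = list(O = O, E = E, areaIds = ids,
                                  covariateNames = covNames,
                                  center = ctr, scale = scl,
                                  nIter = nIter, nBurnin = nBurnin,
                                  thin = thin, phiEvery = phiEvery,
                                  seed = seed, rhoFixed = rhoFixed,
                                  excluded = sum(!keep)))
}

#' Spatially smoothed SMR
#'
#' Fits the intercept-only Leroux CAR model and returns, per area, the
#' posterior median of exp(beta0 + phi_i): the model-based risk ratio
#' that borrows strength across neighbors, stabilizing small-population
#' areas. Its empirical variance never exceeds that of the raw SMR on
#' the same data (shrinkage).
#'
#' @inheritParams fitLeroux
#' @param nIter,nBurnin MCMC controls (defaults as [fitLeroux()]).
#' @param ... further arguments passed to [fitLeroux()].
#' @return data.frame with `area_id` and `ssmr` (NA for areas excluded
#'   because E = 0), with the underlying [LerouxFit-class] in attribute
#'   `"fit"`.
#' @export
smoothedSMR <- function(x, adj, E = NULL, nIter = 110000,
                        nBurnin = 10000, seed = 1, ...) {
    fit <- fitLeroux(x, adj, covariates = NULL, E = E, nIter = nIter,
                     nBurnin = nBurnin, seed = seed, ...)
    mi <- fit@modelInfo
    phi <- fit@samples$phi
    b0 <- fit@samples$beta[attr(phi, "keptIndex"), 1]
    risk <- exp(sweep(unclass(phi), 1, b0, "+"))
    sm <- apply(risk, 2, stats::median)
    allIds <- if (methods::is(x, "AreaCounts")) areaIds(x)
              else if (!is.null(names(x))) names(x)
              else as.character(seq_along(x))
    out <- data.frame(area_id = allIds,
                      ssmr = sm[match(allIds, mi$areaIds)],
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "fit") <- fit
    out
}

## keep only the given area indices in an adjacency
subsetAdjacency <- function(adj, keep) {
    W <- adjacencyMatrix(adj)[keep, keep, drop = FALSE]
    AreaAdjacency(W, ids = areaIds(adj)[keep])
}
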