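## Central S4 data model: stratified areal counts, contiguity, fit results.

#' Default sex by age stratification
#'
#' The default stratification crosses two sexes with eight age bands
#' (under 20, 21-30, 31-40, 41-50, 51-60, 61-70, 71-80, over 80),
#' giving 16 strata. Labels use underscores so they are safe as CSV
#' column name fragments, e.g. \code{"male_21_30"}.
#'
#' @return data.frame with columns \code{sex}, \code{age} and rownames the
#'   stratum labels (16 rows).
#' @export
#' @examples
#' defaultStrata()
defaultStrata <- function() {
    sexes <- c("male", "female")
    ages <- c("under20", "21_30", "31_40", "41_50",
              "51_60", "61_70", "71_80", "over80")
    g <- expand.grid(age = ages, sex = sexes, stringsAsFactors = FALSE)
    g <- g[, c("sex", "age")]
    rownames(g) <- paste(g$sex, g$age, sep = "_")
    g
}

#' AreaCounts: stratified observed counts and populations per area
#'
#' `AreaCounts` extends [SummarizedExperiment::SummarizedExperiment] with
#' two assays over strata (rows) by areas (columns): `"observed"` (event
#' counts) and `"population"` (person denominators). Area-level covariates
#' live in `colData`; stratum descriptors (sex, age band) in `rowData`.
#'
#' Validity requires: both assays present with identical dimensions;
#' all entries finite, non-negative and integer-valued; `observed <=
#' population` cellwise; unique, non-missing area ids as column names.
#'
#' @export
setClass("AreaCounts", contains = "SummarizedExperiment")

setValidity("AreaCounts", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("observed", "population") %in% an))
        return("assays 'observed' and 'population' are required")
    O <- SummarizedExperiment::assay(object, "observed")
    n <- SummarizedExperiment::assay(object, "population")
    ids <- colnames(object)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        msg <- c(msg, "area ids (column names) must be present and non-missing")
    else if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate area id: %s",
                              ids[anyDuplicated(ids)]))
    if (anyNA(O) || anyNA(n))
        msg <- c(msg, "counts and populations must not contain NA")
    else {
        if (any(O < 0))
            msg <- c(msg, badCellMsg(O < 0, object, "negative observed count"))
        if (any(n < 0))
            msg <- c(msg, badCellMsg(n < 0, object, "negative population"))
        if (any(O != round(O)) || any(n != round(n)))
            msg <- c(msg, "counts and populations must be integer-valued")
        if (any(O > n))
            msg <- c(msg, badCellMsg(O > n, object,
                                     "observed count exceeds population"))
    }
    if (length(msg)) msg else TRUE
})

## one readable "area X, stratum Y" pointer for the first offending cell
badCellMsg <- function(bad, object, what) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    sprintf("%s (area '%s', stratum '%s')", what,
            colnames(object)[idx[2]], rownames(object)[idx[1]])
}

#' Construct an AreaCounts object
#'
#' @param observed integer matrix of event counts, strata in rows, areas in
#'   columns (rownames = stratum labels, colnames = area ids).
#' @param population integer matrix of populations, same layout.
#' @param covariates optional data.frame of area-level covariates, one row
#'   per area in column order.
#' @param strata optional data.frame describing strata (e.g.
#'   [defaultStrata()]); rownames must match rownames of `observed`.
#' @return an [AreaCounts-class] object.
#' @export
#' @examples
#' st <- defaultStrata()
#' n <- matrix(1000L, nrow(st), 2, dimnames = list(rownames(st), c("a", "b")))
#' O <- matrix(0L, nrow(st), 2, dimnames = dimnames(n))
#' O[1, 1] <- 3L
#' AreaCounts(O, n)
AreaCounts <- function(observed, population, covariates = NULL,
                       strata = NULL) {
    observed <- as.matrix(observed)
    population <- as.matrix(population)
    storage.mode(observed) <- "double"
    storage.mode(population) <- "double"
    if (!identical(dim(observed), dim(population)))
        stop("'observed' and 'population' must have identical dimensions")
    if (is.null(strata)) {
        strata <- if (!is.null(rownames(observed)))
            data.frame(row.names = rownames(observed))
        else defaultStrata()
    }
    if (is.null(rownames(observed)))
        rownames(observed) <- rownames(population) <- rownames(strata)
    cd <- if (is.null(covariates)) S4Vectors::DataFrame(row.names = colnames(observed))
          else S4Vectors::DataFrame(covariates, row.names = colnames(observed))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(observed = observed, population = population),
        rowData = S4Vectors::DataFrame(strata), colData = cd)
    new("AreaCounts", se)
}

#' AreaAdjacency: binary contiguity structure over areas
#'
#' Stores a symmetric, zero-diagonal, binary adjacency (contiguity) matrix
#' as a sparse [Matrix::sparseMatrix], together with the area id order it is
#' indexed by. Isolated areas (no neighbors) are permitted; they are
#' reported by [isolatedAreas()].
#'
#' @slot ids character vector of area ids (defines the order).
#' @slot adj sparse symmetric binary adjacency matrix.
#' @export
setClass("AreaAdjacency",
         representation(ids = "character", adj = "Matrix"))

setValidity("AreaAdjacency", function(object) {
    W <- object@adj
    ids <- object@ids
    msg <- character()
    if (nrow(W) != length(ids) || ncol(W) != length(ids))
        msg <- c(msg, "adjacency dimension does not match number of area ids")
    if (anyDuplicated(ids))
        msg <- c(msg, "area ids must be unique")
    x <- W@x
    if (length(x) && !all(x %in% c(0, 1)))
        msg <- c(msg, "adjacency weights must be binary 0/1")
    if (!Matrix::isSymmetric(W, tol = 0))
        msg <- c(msg, "adjacency must be symmetric")
    if (any(Matrix::diag(W) != 0))
        msg <- c(msg, "adjacency diagonal must be zero")
    if (length(msg)) msg else TRUE
})

#' Construct an AreaAdjacency from a matrix or neighbor list
#'
#' @param x square binary matrix (dense or sparse), or a list of integer
#'   vectors of neighbor indices (1-based), one per area.
#' @param ids character area ids; defaults to names/dimnames of `x`.
#' @return an [AreaAdjacency-class] object.
#' @export
AreaAdjacency <- function(x, ids = NULL) {
    if (is.list(x)) {
        n <- length(x)
        i <- rep.int(seq_len(n), lengths(x))
        j <- unlist(x, use.names = FALSE)
        W <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
        W <- methods::as(Matrix::drop0((W + Matrix::t(W)) > 0), "dMatrix")
        if (is.null(ids)) ids <- names(x)
    } else {
        W <- methods::as(Matrix::Matrix(x, sparse = TRUE), "dMatrix")
        W <- Matrix::drop0(W)
        if (is.null(ids)) ids <- rownames(x)
    }
    if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
    Matrix::diag(W) <- 0
    W <- Matrix::drop0(W)
    dimnames(W) <- list(ids, ids)
    methods::new("AreaAdjacency", ids = as.character(ids),
                 adj = methods::as(W, "generalMatrix"))
}

#' MoranResult: global spatial autocorrelation test result
#'
#' @slot statistic observed Moran's I.
#' @slot expectation analytic null expectation, -1/(n-1).
#' @slot p.value permutation p-value.
#' @slot alternative "two.sided" or "greater".
#' @slot nPerm number of permutations used.
#' @slot style weight style, "W" (row-standardized) or "B" (binary).
#' @export
setClass("MoranResult",
         representation(statistic = "numeric", expectation = "numeric",
                        p.value = "numeric", alternative = "character",
                        nPerm = "integer", style = "character"))

#' VIFReport: variance inflation factor screen result
#'
#' @slot vif named VIFs of the retained covariates.
#' @slot correlations Pearson correlation matrix of the original covariates.
#' @slot dropped covariate names removed, in removal order.
#' @slot threshold the VIF threshold used.
#' @slot steps list of named VIF vectors, one per screening iteration
#'   (including the final state).
#' @export
setClass("VIFReport",
         representation(vif = "numeric", correlations = "matrix",
                        dropped = "character", threshold = "numeric",
                        steps = "list"))

#' LerouxFit: MCMC output of the Leroux CAR Poisson model
#'
#' @slot samples list of post-burn-in draws: `beta` (matrix, original
#'   covariate scale), `tau2`, `rho` (vectors), `phi` (matrix, possibly
#'   extra-thinned; attribute "phiThin" gives the factor).
#' @slot summary posterior summary data.frame (see [posteriorSummary()]).
#' @slot accept named Metropolis acceptance rates.
#' @slot modelInfo list: data (O, E, ids), covariate names, sampler
#'   settings, seed.
#' @export
setClass("LerouxFit",
         representation(samples = "list", summary = "data.frame",
                        accept = "numeric", modelInfo = "list"))
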