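## Accessors and show methods.

#' @rdname lerouxmap-generics
#' @export
setMethod("areaIds", "AreaCounts", function(x, ...) colnames(x))

#' @rdname lerouxmap-generics
#' @export
setMethod("areaIds", "AreaAdjacency", function(x, ...) x@ids)

#' @rdname lerouxmap-generics
#' @export
setMethod("observedCounts", "AreaCounts", function(x, ...)
    SummarizedExperiment::assay(x, "observed"))

#' @rdname lerouxmap-generics
#' @export
setMethod("populations", "AreaCounts", function(x, ...)
    SummarizedExperiment::assay(x, "population"))

#' @rdname lerouxmap-generics
#' @export
setMethod("covariates", "AreaCounts", function(x, ...)
    as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname lerouxmap-generics
#' @export
setMethod("strataLabels", "AreaCounts", function(x, ...) rownames(x))

#' @rdname lerouxmap-generics
#' @export
setMethod("adjacencyMatrix", "AreaAdjacency", function(x, ...) x@adj)

#' @rdname lerouxmap-generics
#' @export
setMethod("neighborCounts", "AreaAdjacency", function(x, ...)
    stats::setNames(as.numeric(Matrix::rowSums(x@adj)), x@ids))

#' @rdname lerouxmap-generics
#' @export
setMethod("isolatedAreas", "AreaAdjacency", function(x, ...)
    x@ids[Matrix::rowSums(x@adj) == 0])

#' Number of areas in an adjacency
#' @param x an AreaAdjacency
#' @export
setMethod("length", "AreaAdjacency", function(x) length(x@ids))

setMethod("show", "AreaAdjacency", function(object) {
    W <- object@adj
    n <- length(object@ids)
    nEdge <- sum(W@x != 0) / 2
    iso <- sum(Matrix::rowSums(W) == 0)
    cat("AreaAdjacency with", n, "areas,", nEdge, "edges")
    if (iso > 0) cat(" (", iso, " isolated)", sep = "")
    cat("\n  mean neighbors:",
        round(mean(Matrix::rowSums(W)), 2), "\n")
})

setMethod("show", "MoranResult", function(object) {
    cat("Moran's I permutation test (style =", object@style, ")\n")
    cat(sprintf("  I = %.4f  (null expectation %.4f)\n",
                object@statistic, object@expectation))
    cat(sprintf("  p = %.4g  (%s, %d permutations)\n",
                object@p.value, object@alternative, object@nPerm))
})

setMethod("show", "VIFReport", function(object) {
    cat("VIF screen (threshold", object@threshold, ")\n")
    cat("  retained:\n")
    print(round(object@vif, 3))
    if (length(object@dropped))
        cat("  dropped:", paste(object@dropped, collapse = ", "), "\n")
    else cat("  dropped: none\n")
})

setMethod("show", "LerouxFit", function(object) {
    mi <- object@modelInfo
    cat("Leroux CAR Poisson fit:", length(mi$E), "areas,",
        length(mi$covariateNames), "covariates\n")
    cat(sprintf("  %d iterations (%d burn-in, thin %d), seed %s\n",
                mi$nIter, mi$nBurnin, mi$thin, format(mi$seed)))
    cat("  acceptance:",
        paste(sprintf("%s %.2f", names(object@accept), object@accept),
              collapse = ", "), "\n")
    print(utils::head(object@summary, 10))
    if (nrow(object@summary) > 10) cat("  ...\n")
})

#' @rdname lerouxmap-generics
#' @export
setMethod("mcmcSamples", "LerouxFit", function(x, ...) x@samples)

#' @rdname lerouxmap-generics
#' @export
setMethod("posteriorSummary", "LerouxFit", function(x, ...) x@summary)

#' @rdname lerouxmap-generics
#' @export
setMethod("acceptanceRates", "LerouxFit", function(x, ...) x@accept)
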