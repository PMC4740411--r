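#' @name lerouxmap-generics
#' @title Generic accessors used across lerouxmap classes
#' @param x,object an object of a lerouxmap class
#' @param ... further arguments for methods
#' @keywords internal
NULL

#' @rdname lerouxmap-generics
#' @export
setGeneric("areaIds", function(x, ...) standardGeneric("areaIds"))

#' @rdname lerouxmap-generics
#' @export
setGeneric("observedCounts", function(x, ...) standardGeneric("observedCounts"))

#' @rdname lerouxmap-generics
#' @export
setGeneric("populations", function(x, ...) standardGeneric("populations"))

#' @rdname lerouxmap-generics
#' @export
setGeneric("covariates", function(x, ...) standardGeneric("covariates"))

#' @rdname lerouxmap-generics
#' @export
setGeneric("strataLabels", function(x, ...) standardGeneric("strataLabels"))

#' @rdname lerouxmap-generics
#' @export
setGeneric("adjacencyMatrix", function(x, ...) standardGeneric("adjacencyMatrix"))

#' @rdname lerouxmap-generics
#' @export
setGeneric("neighborCounts", function(x, ...) standardGeneric("neighborCounts"))

#' @rdname lerouxmap-generics
#' @export
setGeneric("isolatedAreas", function(x, ...) standardGeneric("isolatedAreas"))

#' @rdname lerouxmap-generics
#' @export
setGeneric("mcmcSamples", function(x, ...) standardGeneric("mcmcSamples"))

#' @rdname lerouxmap-generics
#' @export
setGeneric("posteriorSummary", function(x, ...) standardGeneric("posteriorSummary"))

#' @rdname lerouxmap-generics
#' @export
setGeneric("acceptanceRates", function(x, ...) standardGeneric("acceptanceRates"))
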