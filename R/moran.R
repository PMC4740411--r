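## Global Moran's I with permutation inference.

#' Moran's I spatial autocorrelation test
#'
#' Computes global Moran's I,
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} (x_i-\bar x)(x_j-\bar x)}
#'   {\sum_i (x_i-\bar x)^2},}
#' for an area-level vector on a contiguity structure, with inference by
#' random permutation of the values over the areas. Isolated areas
#' contribute nothing to the numerator. The analytic null expectation
#' -1/(n-1) is reported alongside.
#'
#' The default weight style row-standardizes each area's neighbor weights
#' to sum to one (the common convention for irregular lattices); `"B"`
#' keeps binary weights. The permutation p-value is
#' (1 + #\{|I*| >= |I|\}) / (1 + nPerm) for the two-sided test, or the
#' analogous upper-tail count for `alternative = "greater"`.
#'
#' @param x numeric vector, one value per area (same order as `adj`).
#' @param adj an [AreaAdjacency-class] object.
#' @param style `"W"` (row-standardized, default) or `"B"` (binary).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param nPerm number of permutations (>= 99).
#' @param seed optional integer seed for the permutations.
#' @return a [MoranResult-class] object.
#' @export
#' @examples
#' adj <- makeLattice(4, 4)
#' chk <- as.vector(outer(1:4, 1:4, function(r, c) (-1)^(r + c)))
#' moransI(chk, adj, style = "B", nPerm = 99, seed = 1)  # I = -1
moransI <- function(x, adj, style = c("W", "B"),
                    alternative = c("two.sided", "greater"),
                    nPerm = 999, seed = NULL) {
    style <- match.arg(style)
    alternative <- match.arg(alternative)
    stopifnot(methods::is(adj, "AreaAdjacency"))
    n <- length(areaIds(adj))
    if (length(x) != n)
        stop("length(x) must equal the number of areas (", n, ")")
    if (anyNA(x)) stop("x must not contain NA")
    if (nPerm < 99) stop("nPerm must be at least 99")
    z <- x - mean(x)
    if (sum(z^2) == 0) stop("x is constant; Moran's I is undefined")
    W <- adjacencyMatrix(adj)
    trip <- Matrix::summary(methods::as(W, "TsparseMatrix"))
    if (nrow(trip) == 0) stop("adjacency has no edges")
    wi <- trip$i; wj <- trip$j; wx <- trip$x
    if (style == "W") {
        deg <- Matrix::rowSums(W)
        wx <- wx / deg[wi]
    }
    S0 <- sum(wx)
    denom <- sum(z^2)
    iObs <- (n / S0) * sum(wx * z[wi] * z[wj]) / denom
    if (!is.null(seed)) set.seed(seed)
    iPerm <- vapply(seq_len(nPerm), function(b) {
        zp <- z[sample.int(n)]
        (n / S0) * sum(wx * zp[wi] * zp[wj]) / sum(zp^2)
    }, numeric(1))
    p <- if (alternative == "two.sided")
        (1 + sum(abs(iPerm) >= abs(iObs))) / (1 + nPerm)
    else
        (1 + sum(iPerm >= iObs)) / (1 + nPerm)
    methods::new("MoranResult", statistic = iObs,
                 expectation = -1 / (n - 1), p.value = p,
                 alternative = alternative, nPerm = as.integer(nPerm),
                 style = style)
}
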