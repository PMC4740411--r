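## Variance inflation factors and the iterative screening rule.

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) with R^2_j from the least-squares regression of
#' covariate j on all other covariates plus an intercept. Exact linear
#' dependence yields `Inf` (reported, not an error); a constant column is
#' an error since its VIF is undefined.
#'
#' @param X numeric matrix or data.frame of covariates (areas in rows);
#'   at least two columns and more rows than columns.
#' @return named numeric vector of VIFs (all >= 1, possibly Inf).
#' @export
#' @examples
#' X <- cbind(a = c(1, 2, 3, 4), b = c(1, -1, 1, -1))
#' vif(X)  # orthogonal-ish columns, both near 1
vif <- function(X) {
    X <- as.matrix(X)
    if (!is.numeric(X)) stop("covariates must be numeric")
    if (ncol(X) < 2) stop("VIF needs at least two covariates")
    if (nrow(X) <= ncol(X)) stop("need more areas than covariates")
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
        stop("constant covariate column: ", colnames(X)[sds == 0][1])
    out <- vapply(seq_len(ncol(X)), function(j) {
        y <- X[, j]
        fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, -j, drop = FALSE]), y)
        rss <- sum(fit$residuals^2)
        tss <- sum((y - mean(y))^2)
        r2 <- 1 - rss / tss
        if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    stats::setNames(out, colnames(X))
}

#' Iterative VIF screen
#'
#' Repeatedly removes the covariate with the largest VIF while any VIF
#' exceeds `threshold` (default 2.5, a conventional level of concern),
#' recomputing VIFs after every removal. Ties are broken by column order
#' (first wins). Screening its own output removes nothing (idempotence).
#'
#' @param X numeric matrix or data.frame of covariates.
#' @param threshold VIF above which a covariate is eligible for removal.
#' @return a [VIFReport-class]; the retained design is in
#'   `metadata`-style attribute `"reduced"` (matrix of retained columns).
#' @export
vifScreen <- function(X, threshold = 2.5) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    corMat <- stats::cor(X)
    cur <- X
    dropped <- character()
    steps <- list()
    repeat {
        if (ncol(cur) < 2) {
            v <- stats::setNames(rep(1, ncol(cur)), colnames(cur))
            steps[[length(steps) + 1L]] <- v
            break
        }
        v <- vif(cur)
        steps[[length(steps) + 1L]] <- v
        if (max(v) <= threshold) break
        worst <- which.max(v)   # ties: first column wins
        dropped <- c(dropped, colnames(cur)[worst])
        cur <- cur[, -worst, drop = FALSE]
        if (ncol(cur) == 0)
            stop("degenerate screening: all covariates removed")
    }
    rep <- methods::new("VIFReport", vif = steps[[length(steps)]],
                        correlations = corMat, dropped = dropped,
                        threshold = threshold, steps = steps)
    attr(rep, "reduced") <- cur
    rep
}

#' Retained covariate matrix after a VIF screen
#' @param report a [VIFReport-class] from [vifScreen()].
#' @return matrix of the retained covariate columns.
#' @export
retainedCovariates <- function(report) attr(report, "reduced")
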