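## Posterior summaries and relative-risk transforms.

#' Summarize posterior draws
#'
#' Empirical median and central 95% credible interval (2.5% and 97.5%
#' quantiles) per parameter, with a Geweke convergence z per chain.
#'
#' @param draws matrix of draws (iterations in rows, one column per
#'   parameter) or a numeric vector for a single parameter.
#' @param rr logical vector (recycled): for which parameters to attach
#'   relative risks `exp(median)` with exponentiated credible bounds.
#' @param geweke compute the Geweke z per column (needs >= 100 draws).
#' @return data.frame with columns `parameter`, `median`, `lower`,
#'   `upper`, `geweke`, and `rr`, `rr_lower`, `rr_upper` (NA where `rr`
#'   is FALSE).
#' @export
#' @examples
#' summarizeDraws(cbind(theta = 1:10000 / 10000), geweke = FALSE)
summarizeDraws <- function(draws, rr = FALSE, geweke = TRUE) {
    if (is.null(dim(draws)))
        draws <- matrix(draws, ncol = 1,
                        dimnames = list(NULL, "parameter"))
    if (nrow(draws) == 0) stop("no draws to summarize")
    if (is.null(colnames(draws)))
        colnames(draws) <- paste0("par", seq_len(ncol(draws)))
    rr <- rep_len(rr, ncol(draws))
    q <- t(apply(draws, 2, stats::quantile,
                 probs = c(0.5, 0.025, 0.975), names = FALSE))
    z <- if (geweke && nrow(draws) >= 100)
        ## a stuck (zero-variance-window) chain gets NA rather than
        ## derailing the whole summary
        apply(draws, 2, function(x)
            tryCatch(gewekeDiag(x)$z, error = function(e) NA_real_))
    else rep(NA_real_, ncol(draws))
    out <- data.frame(parameter = colnames(draws),
                      median = q[, 1], lower = q[, 2], upper = q[, 3],
                      geweke = z, row.names = NULL,
                      stringsAsFactors = FALSE)
    rrv <- rrFromCoef(out[, c("median", "lower", "upper")])
    out$rr <- ifelse(rr, rrv$rr, NA_real_)
    out$rr_lower <- ifelse(rr, rrv$rr_lower, NA_real_)
    out$rr_upper <- ifelse(rr, rrv$rr_upper, NA_real_)
    out
}

#' Relative risks from log-scale coefficient summaries
#'
#' Exponentiates a coefficient summary (median and credible bounds) into
#' relative risks. Because exp is monotone the bound order is preserved.
#'
#' @param coefSummary data.frame with columns `median`, `lower`, `upper`
#'   (log relative risk scale), or a numeric vector of coefficients.
#' @return data.frame with `rr`, `rr_lower`, `rr_upper` (or a numeric
#'   vector if a vector was given).
#' @export
#' @examples
#' rrFromCoef(0.015)                    # 1.015 to three decimals
#' rrFromCoef(data.frame(median = -0.1, lower = -0.148, upper = -0.053))
rrFromCoef <- function(coefSummary) {
    if (is.numeric(coefSummary)) return(exp(coefSummary))
    stopifnot(all(c("median", "lower", "upper") %in% names(coefSummary)))
    data.frame(rr = exp(coefSummary$median),
               rr_lower = exp(coefSummary$lower),
               rr_upper = exp(coefSummary$upper),
               row.names = NULL)
}
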