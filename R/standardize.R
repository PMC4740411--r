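## Indirect standardization: national stratum rates, expected counts, SMR.

#' National event rates per stratum
#'
#' Pools all areas: for stratum s, rate r\[s\] = sum_i O\[i,s\] / sum_i
#' n\[i,s\]. A stratum with zero population and zero events gets rate 0; a
#' stratum with events but no population is an error.
#'
#' @param x an [AreaCounts-class] object.
#' @return named numeric vector of rates (events per person), one per
#'   stratum.
#' @export
#' @examples
#' st <- defaultStrata()
#' n <- matrix(1000, nrow(st), 1, dimnames = list(rownames(st), "a"))
#' O <- matrix(0, nrow(st), 1, dimnames = dimnames(n)); O[1, 1] <- 5
#' nationalRates(AreaCounts(O, n))[1]  # 0.005
nationalRates <- function(x) {
    stopifnot(methods::is(x, "AreaCounts"))
    Osum <- rowSums(observedCounts(x))
    nsum <- rowSums(populations(x))
    bad <- Osum > 0 & nsum == 0
    if (any(bad))
        stop("stratum '", names(Osum)[bad][1],
             "' has events but zero national population")
    r <- ifelse(nsum > 0, Osum / nsum, 0)
    stats::setNames(r, rownames(x))
}

#' Expected counts by indirect standardization
#'
#' E\[i\] = sum_s r\[s\] * n\[i,s\]. When the rates come from
#' [nationalRates()] on the same table, sum(E) equals the total observed
#' count (conservation).
#'
#' @param x an [AreaCounts-class] object.
#' @param rates named stratum rates; defaults to [nationalRates()] of `x`.
#'   External (e.g. published vital-statistics) rates may be supplied, in
#'   which case conservation need not hold.
#' @return named numeric vector of expected counts, one per area. Areas
#'   with zero population in every stratum get E = 0 and are listed in the
#'   `"zeroPopulation"` attribute.
#' @export
expectedCounts <- function(x, rates = nationalRates(x)) {
    stopifnot(methods::is(x, "AreaCounts"))
    labs <- strataLabels(x)
    if (is.null(names(rates)) || !setequal(names(rates), labs))
        stop("stratum mismatch between rates and table")
    r <- rates[labs]
    E <- as.numeric(crossprod(populations(x), r))
    names(E) <- areaIds(x)
    zero <- areaIds(x)[colSums(populations(x)) == 0]
    attr(E, "zeroPopulation") <- zero
    E
}

#' Raw standardized mortality ratios
#'
#' SMR\[i\] = O\[i\] / E\[i\] with O\[i\] the area total over strata. An
#' area with E = 0 and O = 0 is flagged `undefined` (SMR NA, never
#' silently 0); E = 0 with O > 0 indicates an inconsistent
#' standardization and is an error.
#'
#' @param x an [AreaCounts-class] object.
#' @param E expected counts from [expectedCounts()] (defaults to
#'   self-computed national rates).
#' @return data.frame with columns `area_id`, `observed`, `expected`,
#'   `smr`, `flag`.
#' @export
smr <- function(x, E = expectedCounts(x)) {
    stopifnot(methods::is(x, "AreaCounts"))
    ids <- areaIds(x)
    if (is.null(names(E)) || !identical(names(E), ids))
        stop("expected counts do not match the table's areas")
    O <- colSums(observedCounts(x))
    if (any(E == 0 & O > 0))
        stop("area '", ids[E == 0 & O > 0][1],
             "' has observed events but zero expected count")
    s <- ifelse(E > 0, O / E, NA_real_)
    data.frame(area_id = ids, observed = as.numeric(O),
               expected = as.numeric(E), smr = s,
               flag = ifelse(E == 0, "undefined", ""),
               row.names = NULL, stringsAsFactors = FALSE)
}
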