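## Reading and writing area tables, GAL contiguity files, result JSON.

#' Default column schema for stratified area tables
#'
#' Describes how CSV columns map onto the data model: an area id column,
#' one observed-count and one population column per stratum (named
#' `<prefix>_<stratum>`, e.g. `O_male_21_30`, `n_male_21_30`), and
#' covariate columns.
#'
#' @param strata data.frame of strata as in [defaultStrata()].
#' @param id name of the area id column.
#' @param observedPrefix,populationPrefix column-name prefixes.
#' @param covariates covariate column names, or NULL to take every column
#'   not otherwise claimed.
#' @return a schema list understood by [readAreaTable()].
#' @export
areaTableSchema <- function(strata = defaultStrata(), id = "area_id",
                            observedPrefix = "O", populationPrefix = "n",
                            covariates = NULL) {
    list(strata = strata, id = id,
         observedPrefix = observedPrefix,
         populationPrefix = populationPrefix,
         covariates = covariates)
}

#' Read a stratified area table from CSV
#'
#' Reads a UTF-8 CSV with a header row and validates it into an
#' [AreaCounts-class] object. Row order in the file defines the area order
#' used throughout an analysis.
#'
#' @param path CSV file path.
#' @param schema column mapping from [areaTableSchema()].
#' @return an [AreaCounts-class] object.
#' @export
readAreaTable <- function(path, schema = areaTableSchema()) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
    areaTableFromDF(df, schema)
}

## shared by readAreaTable and the simulator's in-memory path
areaTableFromDF <- function(df, schema = areaTableSchema()) {
    st <- schema$strata
    labs <- rownames(st)
    oCols <- paste(schema$observedPrefix, labs, sep = "_")
    nCols <- paste(schema$populationPrefix, labs, sep = "_")
    need <- c(schema$id, oCols, nCols, schema$covariates)
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("schema error: missing column(s): ",
             paste(missing, collapse = ", "))
    ids <- as.character(df[[schema$id]])
    if (anyNA(ids) || any(ids == ""))
        stop("validation error: missing area id")
    if (anyDuplicated(ids))
        stop("validation error: duplicate area id '",
             ids[anyDuplicated(ids)], "'")
    O <- t(as.matrix(df[, oCols, drop = FALSE]))
    n <- t(as.matrix(df[, nCols, drop = FALSE]))
    rownames(O) <- rownames(n) <- labs
    colnames(O) <- colnames(n) <- ids
    covNames <- schema$covariates
    if (is.null(covNames))
        covNames <- setdiff(names(df), c(schema$id, oCols, nCols))
    covs <- if (length(covNames)) df[, covNames, drop = FALSE] else NULL
    out <- try(AreaCounts(O, n, covariates = covs, strata = st),
               silent = TRUE)
    if (inherits(out, "try-error"))
        stop("validation error: ",
             sub("^.*[Ee]rror[^:]*: *", "", attr(out, "condition")$message))
    out
}

#' Write an AreaCounts object to CSV
#'
#' Inverse of [readAreaTable()] under the same schema.
#'
#' @param x an [AreaCounts-class] object.
#' @param path output CSV path.
#' @param schema column mapping from [areaTableSchema()].
#' @return `path`, invisibly.
#' @export
writeAreaTable <- function(x, path, schema = areaTableSchema()) {
    labs <- strataLabels(x)
    df <- data.frame(check.names = FALSE, row.names = NULL,
                     stats::setNames(list(areaIds(x)), schema$id))
    O <- t(observedCounts(x)); n <- t(populations(x))
    colnames(O) <- paste(schema$observedPrefix, labs, sep = "_")
    colnames(n) <- paste(schema$populationPrefix, labs, sep = "_")
    df <- cbind(df, as.data.frame(O), as.data.frame(n),
                covariates(x))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a GAL neighbor-list file
#'
#' Parses the GAL contiguity format: a header line whose last numeric
#' token is the number of areas, then for each area a line `id k`
#' followed by a line with its `k` neighbor ids. Asymmetric listings
#' (A names B but not vice versa) are symmetrized by union, with a
#' warning.
#'
#' @param path GAL file path.
#' @param areaIds optional ordered area ids; the adjacency is re-indexed
#'   to this order. Ids declared in the file must all appear here; ids
#'   present here but absent from the file become isolated areas.
#' @return an [AreaAdjacency-class] object.
#' @export
readGAL <- function(path, areaIds = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*$", lines)]
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    nDecl <- suppressWarnings(as.integer(header[min(length(header), 2)]))
    if (length(header) == 1)
        nDecl <- suppressWarnings(as.integer(header[1]))
    if (is.na(nDecl) || nDecl < 0)
        stop("malformed GAL header: ", lines[1])
    ids <- character(nDecl)
    nbrs <- vector("list", nDecl)
    pos <- 2
    for (k in seq_len(nDecl)) {
        if (pos > length(lines)) stop("malformed GAL file: truncated at area ", k)
        hd <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
        if (length(hd) != 2) stop("malformed GAL area header: ", lines[pos])
        ids[k] <- hd[1]
        deg <- suppressWarnings(as.integer(hd[2]))
        if (is.na(deg) || deg < 0) stop("malformed GAL degree: ", lines[pos])
        pos <- pos + 1
        if (deg > 0) {
            if (pos > length(lines)) stop("malformed GAL file: truncated neighbor list")
            nb <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
            if (length(nb) != deg)
                stop("malformed GAL file: area '", ids[k], "' declares ", deg,
                     " neighbors but lists ", length(nb))
            nbrs[[k]] <- nb
            pos <- pos + 1
        } else {
            nbrs[[k]] <- character()
        }
    }
    if (anyDuplicated(ids)) stop("duplicate area id in GAL file")
    if (is.null(areaIds)) areaIds <- ids
    areaIds <- as.character(areaIds)
    unknownDecl <- setdiff(ids, areaIds)
    if (length(unknownDecl))
        stop("GAL area id not in area table: ", unknownDecl[1])
    idx <- match(ids, areaIds)
    n <- length(areaIds)
    ii <- jj <- integer()
    for (k in seq_len(nDecl)) {
        if (!length(nbrs[[k]])) next
        j <- match(nbrs[[k]], areaIds)
        if (anyNA(j))
            stop("GAL neighbor id not in area table: ",
                 nbrs[[k]][which(is.na(j))[1]])
        ii <- c(ii, rep.int(idx[k], length(j)))
        jj <- c(jj, j)
    }
    W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
    if (!Matrix::isSymmetric(W, tol = 0)) {
        warning("asymmetric GAL neighbor lists; symmetrized by union",
                call. = FALSE)
        W <- (W + Matrix::t(W)) > 0
    }
    AreaAdjacency(as.matrix(W) * 1, ids = areaIds)
}

#' Write an adjacency to a GAL file
#'
#' Lossless inverse of [readGAL()]: `readGAL(writeGAL(x, f))` reproduces
#' `x` exactly.
#'
#' @param adj an [AreaAdjacency-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGAL <- function(adj, path) {
    ids <- areaIds(adj)
    W <- adjacencyMatrix(adj)
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(as.character(length(ids)), con)
    for (k in seq_along(ids)) {
        nb <- ids[which(W[k, ] != 0)]
        writeLines(paste(ids[k], length(nb)), con)
        if (length(nb)) writeLines(paste(nb, collapse = " "), con)
    }
    invisible(path)
}

#' Write fit summaries to JSON
#'
#' Serializes the posterior summary of a [LerouxFit-class] (medians,
#' credible bounds, relative risks, Geweke z per parameter) together with
#' sampler settings, at full floating precision.
#'
#' @param fit a [LerouxFit-class] object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(fit, path) {
    stopifnot(methods::is(fit, "LerouxFit"))
    mi <- fit@modelInfo
    out <- list(
        parameters = fit@summary,
        acceptance = as.list(fit@accept),
        settings = list(nIter = mi$nIter, nBurnin = mi$nBurnin,
                        thin = mi$thin, seed = mi$seed,
                        nAreas = length(mi$E),
                        covariates = mi$covariateNames))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    invisible(path)
}

#' Read back a results JSON written by [writeResults()]
#' @param path JSON path.
#' @return list with `parameters` (data.frame), `acceptance`, `settings`.
#' @export
readResults <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    x$parameters <- as.data.frame(x$parameters)
    x
}
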