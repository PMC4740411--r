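## End-to-end orchestration: SMR -> sSMR -> Moran -> VIF -> CAR fit.

#' Run the full disease-mapping pipeline
#'
#' Executes, in order: read and validate inputs; indirect
#' standardization (SMR); spatially smoothed SMR from the intercept-only
#' Leroux model; Moran's I permutation test on the smoothed SMR; VIF
#' screen of the covariates; covariate-adjusted Leroux fit using the
#' covariates the screen retained. Each stage's output is written to
#' `outDir` (`smr.csv`, `ssmr.csv`, `moran.json`, `vif.json`,
#' `fit.json`) along with `manifest.json` recording the seed, package
#' version, per-stage timings and all warnings. A stage failure aborts
#' with the stage name; outputs of completed stages are kept and the
#' manifest carries a FAILED marker.
#'
#' Every stage is a pure function of (inputs, config, seed): re-running
#' with the same config and seed reproduces all artifacts exactly.
#'
#' @param config list (or path to a JSON file) with elements:
#'   `table` (CSV path or [AreaCounts-class]), `gal` (GAL path or
#'   [AreaAdjacency-class]), `outDir`, `covariates` (character vector of
#'   covariate column names for the adjusted model), and optionally
#'   `moranPerm` (default 999), `vifThreshold` (default 2.5), `seed`
#'   (default 1), and `model` (list of [fitLeroux()] controls: `nIter`,
#'   `nBurnin`, `thin`, priors, `phiEvery`).
#' @return invisibly, a list with the stage results (`smr`, `ssmr`,
#'   `moran`, `vif`, `fit`), the artifact `paths`, and the `manifest`.
#' @export
runPipeline <- function(config) {
    if (is.character(config))
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    cfg <- config
    cfg$moranPerm <- cfg$moranPerm %||% 999
    cfg$vifThreshold <- cfg$vifThreshold %||% 2.5
    cfg$seed <- cfg$seed %||% 1
    cfg$model <- cfg$model %||% list()
    mdl <- list(nIter = cfg$model$nIter %||% 110000,
                nBurnin = cfg$model$nBurnin %||% 10000,
                thin = cfg$model$thin %||% 1,
                phiEvery = cfg$model$phiEvery)
    if (is.null(cfg$outDir)) stop("config must name an output directory")
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)

    manifest <- list(seed = cfg$seed,
                     package = as.character(utils::packageVersion("lerouxmap")),
                     started = format(Sys.time(), tz = "UTC"),
                     moranPerm = cfg$moranPerm,
                     vifThreshold = cfg$vifThreshold,
                     model = mdl[!vapply(mdl, is.null, logical(1))],
                     stages = list(), warnings = character())
    paths <- list(manifest = file.path(cfg$outDir, "manifest.json"))
    res <- list()
    warnBox <- character()

    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        out <- withCallingHandlers(
            tryCatch(expr, error = function(e) {
                manifest$stages[[name]] <<- list(status = "FAILED",
                                                 error = conditionMessage(e))
                manifest$warnings <<- warnBox
                writeManifest(manifest, paths$manifest)
                stop("stage '", name, "' failed: ", conditionMessage(e),
                     call. = FALSE)
            }),
            warning = function(w) {
                warnBox <<- c(warnBox, paste0(name, ": ",
                                              conditionMessage(w)))
                invokeRestart("muffleWarning")
            })
        manifest$stages[[name]] <<- list(
            status = "ok",
            seconds = round(proc.time()[["elapsed"]] - t0, 3))
        out
    }

    inputs <- stage("read", {
        tab <- if (methods::is(cfg$table, "AreaCounts")) cfg$table
               else readAreaTable(cfg$table)
        adj <- if (methods::is(cfg$gal, "AreaAdjacency")) cfg$gal
               else readGAL(cfg$gal, areaIds = areaIds(tab))
        if (!identical(areaIds(adj), areaIds(tab)))
            stop("adjacency areas do not match the table")
        covNames <- as.character(cfg$covariates %||% character())
        missingCov <- setdiff(covNames, names(covariates(tab)))
        if (length(missingCov))
            stop("missing covariate column: ",
                 paste(missingCov, collapse = ", "))
        list(tab = tab, adj = adj, covNames = covNames)
    })
    tab <- inputs$tab; adj <- inputs$adj

    res$smr <- stage("smr", {
        s <- smr(tab)
        paths$smr <- file.path(cfg$outDir, "smr.csv")
        utils::write.csv(s, paths$smr, row.names = FALSE)
        s
    })

    res$ssmr <- stage("ssmr", {
        s <- smoothedSMR(tab, adj, nIter = mdl$nIter,
                         nBurnin = mdl$nBurnin, thin = mdl$thin,
                         phiEvery = mdl$phiEvery, seed = cfg$seed)
        paths$ssmr <- file.path(cfg$outDir, "ssmr.csv")
        utils::write.csv(s, paths$ssmr, row.names = FALSE)
        s
    })

    res$moran <- stage("moran", {
        ok <- !is.na(res$ssmr$ssmr)
        m <- moransI(res$ssmr$ssmr[ok],
                     subsetAdjacency(adj, which(ok)),
                     nPerm = cfg$moranPerm, seed = cfg$seed + 1)
        paths$moran <- file.path(cfg$outDir, "moran.json")
        jsonlite::write_json(
            list(I = m@statistic, expectation = m@expectation,
                 p_value = m@p.value, alternative = m@alternative,
                 n_permutations = m@nPerm, style = m@style),
            paths$moran, auto_unbox = TRUE, digits = NA)
        m
    })

    res$vif <- stage("vif", {
        if (length(inputs$covNames) < 2) NULL
        else {
            X <- as.matrix(covariates(tab)[, inputs$covNames,
                                           drop = FALSE])
            v <- vifScreen(X, threshold = cfg$vifThreshold)
            paths$vif <- file.path(cfg$outDir, "vif.json")
            jsonlite::write_json(
                list(vif = as.list(v@vif), dropped = v@dropped,
                     threshold = v@threshold,
                     correlations = as.data.frame(v@correlations)),
                paths$vif, auto_unbox = TRUE, digits = NA)
            v
        }
    })

    res$fit <- stage("fit", {
        keepCov <- if (is.null(res$vif)) inputs$covNames
                   else setdiff(inputs$covNames, res$vif@dropped)
        fit <- fitLeroux(tab, adj,
                         covariates = if (length(keepCov)) keepCov,
                         nIter = mdl$nIter, nBurnin = mdl$nBurnin,
                         thin = mdl$thin, phiEvery = mdl$phiEvery,
                         seed = cfg$seed)
        paths$fit <- file.path(cfg$outDir, "fit.json")
        writeResults(fit, paths$fit)
        fit
    })

    manifest$warnings <- warnBox
    manifest$vifDropped <- if (!is.null(res$vif)) res$vif@dropped
                           else character()
    manifest$finished <- format(Sys.time(), tz = "UTC")
    writeManifest(manifest, paths$manifest)
    invisible(list(results = res, paths = paths, manifest = manifest))
}

writeManifest <- function(manifest, path) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
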