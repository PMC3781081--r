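## Readers and writers.  Data files carry integer counts plus nMax, never
## proportions: the likelihood is defined on counts, and storing derived
## proportions would invite rounding drift.

#' Read a plot census table
#'
#' Expects a CSV with header \code{plot_id, year, count, n_max} and one
#' row per (plot, year) census; missed censuses are simply absent.
#' Malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return a [MusselStudy-class].
#' @seealso [writePlots()]
#' @export
readPlots <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("plot_id", "year", "count", "n_max")
    if (!all(need %in% names(df)))
        stop("plot CSV must have columns: ", paste(need, collapse = ", "))
    lineNo <- seq_len(nrow(df)) + 1L   # header is line 1
    bad <- which(df$count != round(df$count) | df$count < 0)
    if (length(bad))
        stop("non-integer or negative count at line ", lineNo[bad[1]],
             " (plot '", df$plot_id[bad[1]], "', year ", df$year[bad[1]], ")")
    bad <- which(df$count > df$n_max)
    if (length(bad))
        stop("count ", df$count[bad[1]], " exceeds n_max ", df$n_max[bad[1]],
             " at line ", lineNo[bad[1]], " (plot '", df$plot_id[bad[1]],
             "', year ", df$year[bad[1]], ")")
    dup <- duplicated(df[c("plot_id", "year")])
    if (any(dup))
        stop("duplicate (plot, year) at line ", lineNo[which(dup)[1]],
             " (plot '", df$plot_id[which(dup)[1]], "', year ",
             df$year[which(dup)[1]], ")")
    nmaxTab <- unique(df[c("plot_id", "n_max")])
    if (anyDuplicated(nmaxTab$plot_id))
        stop("inconsistent n_max within a plot: '",
             nmaxTab$plot_id[duplicated(nmaxTab$plot_id)][1], "'")
    plots <- unique(df$plot_id)
    years <- sort(unique(df$year))
    cnt <- matrix(NA_integer_, length(plots), length(years),
                  dimnames = list(plots, years))
    cnt[cbind(match(df$plot_id, plots), match(df$year, years))] <-
        as.integer(df$count)
    musselStudy(cnt, years, nmaxTab$n_max[match(plots, nmaxTab$plot_id)],
                plotIds = plots)
}

#' Write a plot census table
#'
#' Inverse of [readPlots()]: long CSV with one row per observed census.
#'
#' @param study a [MusselStudy-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePlots <- function(study, path) {
    stopifnot(is(study, "MusselStudy"))
    cnt <- censusCounts(study)
    yrs <- censusYears(study)
    nm <- nMax(study)
    rows <- which(!is.na(cnt), arr.ind = TRUE)
    rows <- rows[order(rows[, 1L], rows[, 2L]), , drop = FALSE]
    df <- data.frame(plot_id = rownames(cnt)[rows[, 1L]],
                     year = yrs[rows[, 2L]],
                     count = cnt[rows],
                     n_max = nm[rows[, 1L]])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Serialize / deserialize a model specification as JSON
#'
#' The JSON carries the structural choices (mean form, order, linearity,
#' variance mode, mixture) together with current parameter values and the
#' fixed-parameter mask, and round-trips through [readModelSpec()]
#' unchanged.
#'
#' @param model a [PopModel-class].
#' @param path JSON file path.
#' @return \code{writeModelSpec}: \code{path}, invisibly;
#'   \code{readModelSpec}: a [PopModel-class].
#' @export
writeModelSpec <- function(model, path) {
    stopifnot(is(model, "PopModel"))
    spec <- list(mean = model@meanForm, order = model@order,
                 linear = model@linear,
                 variance = model@variance@mode,
                 mixture = !is.null(model@disturbance),
                 params = as.list(model@params),
                 fixed = names(model@fixed)[model@fixed],
                 label = model@label)
    if (model@variance@mode == "constant")
        spec$varianceParams <- list(sigma2 = model@variance@sigma2)
    if (model@variance@mode == "dls")
        spec$varianceParams <- list(x = model@variance@x,
                                    y = model@variance@y,
                                    z = model@variance@z)
    if (!is.null(model@disturbance))
        spec$disturbanceParams <- list(
            muD = model@disturbance@muD, sigma2D = model@disturbance@sigma2D,
            j = model@disturbance@j, k = model@disturbance@k)
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeModelSpec
#' @export
readModelSpec <- function(path) {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    vp <- spec$varianceParams
    variance <- switch(spec$variance,
        constant = varianceModel("constant", sigma2 = vp$sigma2),
        dls = varianceModel("dls", x = vp$x, y = vp$y, z = vp$z),
        none = varianceModel("none"))
    disturbance <- if (isTRUE(spec$mixture)) {
        dp <- spec$disturbanceParams
        disturbanceModel(dp$muD, dp$sigma2D, dp$j, dp$k)
    } else NULL
    popModel(spec$mean, order = spec$order, linear = spec$linear,
             params = unlist(spec$params), variance = variance,
             disturbance = disturbance, label = spec$label)
}

#' Write a model-comparison report
#'
#' Tab-separated report mirroring the layout of a model-selection table:
#' one column per model; parameter rows first (values of fixed-a-priori
#' parameters carry a trailing \code{*} marker rather than posing as
#' estimates), then the estimated variance / DLS / disturbance parameters,
#' then \code{-LL}, \code{k}, \code{AIC}, \code{dAIC}, \code{w} and
#' \code{ER}.
#'
#' @param comparison a comparison data.frame from [compareModels()].
#' @param path output TSV path.
#' @param fits optional list of the compared [PopFit-class] objects, used
#'   to add the parameter rows.
#' @param digits significant digits written.
#' @return \code{path}, invisibly.
#' @seealso [readComparison()]
#' @export
reportComparison <- function(comparison, path, fits = NULL, digits = 6L) {
    fmt <- function(v) as.character(signif(v, digits))
    labels <- comparison$label
    block <- list()
    if (!is.null(fits)) {
        fitLabels <- vapply(fits, function(f) f@label, character(1))
        fits <- fits[match(labels, fitLabels)]
        universe <- unique(unlist(lapply(fits,
                                         function(f) names(f@estimates))))
        for (nm in universe) {
            block[[nm]] <- vapply(fits, function(f) {
                if (!nm %in% names(f@estimates)) return("")
                v <- fmt(f@estimates[[nm]])
                if (nm %in% names(f@model@fixed)[f@model@fixed])
                    paste0(v, "*") else v
            }, character(1))
        }
    }
    block[["-LL"]] <- fmt(comparison$negLogLik)
    block[["k"]] <- as.character(comparison$k)
    block[["AIC"]] <- fmt(comparison$AIC)
    block[["dAIC"]] <- fmt(comparison$dAIC)
    block[["w"]] <- fmt(comparison$weight)
    block[["ER"]] <- fmt(comparison$ER)
    block[["supported"]] <- as.character(comparison$supported)
    out <- cbind(quantity = names(block),
                 do.call(rbind, block))
    colnames(out) <- c("quantity", labels)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Re-read a model-comparison report
#'
#' Parses a TSV written by [reportComparison()] back into its comparison
#' table (and, when present, a numeric parameter matrix with the fixed
#' markers stripped).
#'
#' @param path TSV path.
#' @return list with elements \code{comparison} (data.frame) and
#'   \code{parameters} (numeric matrix or \code{NULL}).
#' @export
readComparison <- function(path) {
    raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE, colClasses = "character")
    labels <- colnames(raw)[-1L]
    get <- function(q) raw[raw$quantity == q, -1L, drop = TRUE]
    comparison <- data.frame(
        label = labels,
        k = as.integer(unlist(get("k"))),
        negLogLik = as.numeric(unlist(get("-LL"))),
        AIC = as.numeric(unlist(get("AIC"))),
        dAIC = as.numeric(unlist(get("dAIC"))),
        weight = as.numeric(unlist(get("w"))),
        ER = as.numeric(unlist(get("ER"))),
        supported = as.logical(unlist(get("supported"))),
        stringsAsFactors = FALSE)
    statRows <- c("-LL", "k", "AIC", "dAIC", "w", "ER", "supported")
    parRows <- setdiff(raw$quantity, statRows)
    parameters <- NULL
    if (length(parRows)) {
        parameters <- sapply(raw[match(parRows, raw$quantity), -1L,
                                 drop = FALSE],
                             function(col) as.numeric(sub("\\*$", "", col)))
        parameters <- matrix(parameters, nrow = length(parRows),
                             dimnames = list(parRows, labels))
    }
    list(comparison = comparison, parameters = parameters)
}
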