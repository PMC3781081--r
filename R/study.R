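## The census study container and the lagged transition dataset.

#' Construct a census study
#'
#' @param counts plots x years matrix of occupied-unit counts (\code{NA}
#'   for missed censuses).
#' @param years calendar census years (column order of \code{counts}).
#' @param nMax per-plot number of sample units.
#' @param plotIds plot identifiers; defaults to \code{plot01, ...}.
#' @return a [MusselStudy-class].
#' @examples
#' cnt <- matrix(c(10L, 50L, 120L, 200L), nrow = 1)
#' musselStudy(cnt, years = 1993:1996, nMax = 484)
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
musselStudy <- function(counts, years, nMax, plotIds = NULL) {
    counts <- as.matrix(counts)
    if (is.null(plotIds))
        plotIds <- sprintf("plot%02d", seq_len(nrow(counts)))
    nMax <- as.integer(rep_len(nMax, nrow(counts)))
    years <- as.integer(years)
    if (length(years) != ncol(counts))
        stop("'years' must match the number of count columns")
    if (any(diff(years) <= 0))
        stop("'years' must be strictly increasing")
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(plotIds, years)
    bad <- which(counts < 0 | counts > nMax, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("count %d exceeds nMax %d for plot '%s', year %d",
                     counts[bad[1, , drop = FALSE]], nMax[bad[1, 1]],
                     plotIds[bad[1, 1]], years[bad[1, 2]]))
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(nMax = nMax, row.names = plotIds))
    new("MusselStudy", se)
}

#' Accessors for a census study
#'
#' @param study a [MusselStudy-class].
#' @return \code{censusCounts}: the plots x years integer count matrix;
#'   \code{censusProportions}: counts divided by the per-plot \code{nMax};
#'   \code{censusYears}: integer census years; \code{nMax}: per-plot
#'   sample sizes; \code{plotIds}: plot identifiers.
#' @export
#' @importFrom SummarizedExperiment assay rowData
censusCounts <- function(study) assay(study, "counts")

#' @rdname censusCounts
#' @export
censusProportions <- function(study)
    sweep(censusCounts(study), 1L, nMax(study), "/")

#' @rdname censusCounts
#' @export
censusYears <- function(study) as.integer(colnames(study))

#' @rdname censusCounts
#' @export
nMax <- function(study) rowData(study)$nMax

#' @rdname censusCounts
#' @export
plotIds <- function(study) rownames(study)

#' @describeIn MusselStudy-class compact display
#' @param object a \code{MusselStudy}.
#' @export
setMethod("show", "MusselStudy", function(object) {
    yrs <- censusYears(object)
    cnt <- censusCounts(object)
    cat(sprintf("MusselStudy: %d plots, censuses %d-%d (%d missing)\n",
                nrow(object), min(yrs), max(yrs), sum(is.na(cnt))))
    cat("  sample units per plot:",
        paste(sprintf("%dx%d", table(nMax(object)),
                      as.integer(names(table(nMax(object))))),
              collapse = ", "), "\n")
})

## cheap deterministic fingerprint of the transition rows
.fingerprint <- function(df, maxLag) {
    lagCols <- grep("^p[0-9]+$", names(df), value = TRUE)
    sprintf("L%d-n%d-c%d-s%.6f", maxLag, nrow(df), sum(df$count),
            sum(as.matrix(df[lagCols])) + sum(df$year %% 97))
}

#' Build a lagged transition dataset
#'
#' Assembles one row per observed transition across all plots: the target
#' census count together with the previous \code{maxLag} proportional
#' covers (most recent first).  A row requires all \code{maxLag} lags to be
#' observed in consecutive calendar years, so a missed census breaks the
#' transition chains that touch it.
#'
#' @param study a [MusselStudy-class].
#' @param maxLag maximum lag (1 for the full first-order dataset, 4 for
#'   the reduced dataset on which first- and fourth-order models are
#'   compared).
#' @return a [LagDataset-class].
#' @examples
#' study <- generateStudy(model = dlsPreset("constant_table1")$model, seed = 1)
#' buildLagDataset(study, maxLag = 1)
#' @export
buildLagDataset <- function(study, maxLag = 1L) {
    stopifnot(is(study, "MusselStudy"), maxLag %in% c(1L, 2L, 3L, 4L))
    maxLag <- as.integer(maxLag)
    cnt <- censusCounts(study)
    yrs <- censusYears(study)
    nm <- nMax(study)
    rows <- vector("list", nrow(cnt))
    for (q in seq_len(nrow(cnt))) {
        obs <- !is.na(cnt[q, ])
        for (tix in seq_along(yrs)) {
            if (tix <= maxLag || !obs[tix]) next
            lagIdx <- tix - seq_len(maxLag)
            if (!all(obs[lagIdx])) next
            lags <- cnt[q, lagIdx] / nm[q]
            row <- data.frame(plot = rownames(cnt)[q], year = yrs[tix],
                              count = cnt[q, tix], nMax = nm[q])
            row[paste0("p", seq_len(maxLag))] <- as.list(unname(lags))
            rows[[q]] <- rbind(rows[[q]], row)
        }
    }
    df <- do.call(rbind, rows)
    if (is.null(df) || nrow(df) == 0L)
        stop("no usable transitions: need a plot with at least maxLag+1 consecutive censuses")
    rownames(df) <- NULL
    new("LagDataset", data = df, maxLag = maxLag,
        fingerprint = .fingerprint(df, maxLag))
}

#' Accessors for a lagged dataset
#'
#' @param dataset a [LagDataset-class].
#' @return \code{lagData}: the transition data.frame; \code{maxLag}: the
#'   maximum lag; \code{datasetFingerprint}: the fingerprint used to guard
#'   model comparisons.
#' @export
lagData <- function(dataset) dataset@data

#' @rdname lagData
#' @export
maxLag <- function(dataset) dataset@maxLag

#' @rdname lagData
#' @export
datasetFingerprint <- function(dataset) dataset@fingerprint

#' @describeIn LagDataset-class compact display
#' @param object a \code{LagDataset}.
#' @export
setMethod("show", "LagDataset", function(object) {
    cat(sprintf("LagDataset: %d transitions, maxLag %d, %d plots\n",
                nrow(object@data), object@maxLag,
                length(unique(object@data$plot))))
})
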