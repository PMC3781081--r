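## Nonparametric diagnosis of the order of density dependence (ODD):
## leave-one-out cross-validation of kernel autoregressions of increasing
## order, standardized within plot and averaged across plots.

## embedding of a (possibly gappy) proportion series: rows are eligible
## targets whose `order` immediate predecessors are all observed
.embedSeries <- function(p, order) {
    n <- length(p)
    keep <- which(vapply(seq_len(n), function(t)
        t > order && all(is.finite(p[(t - order):t])), TRUE))
    x <- matrix(NA_real_, length(keep), order)
    for (l in seq_len(order)) x[, l] <- p[keep - l]
    list(x = x, y = p[keep], t = keep)
}

## leave-one-out Nadaraya-Watson CV error at one bandwidth; predictions are
## made for the target rows only, but all embedded pairs serve as training
## neighbours (minus the left-out target itself)
.nwLooCv <- function(d2, y, h, targets = seq_along(y)) {
    w <- exp(-d2 / (2 * h^2))
    diag(w) <- 0
    sw <- rowSums(w)
    pred <- ifelse(sw > 1e-300, as.vector(w %*% y) / sw, NA_real_)
    if (anyNA(pred)) {
        ## degenerate bandwidth: fall back to the nearest neighbour
        for (i in which(is.na(pred))) {
            dd <- d2[i, ]
            dd[i] <- Inf
            pred[i] <- y[which.min(dd)]
        }
    }
    mean((y[targets] - pred[targets])^2)
}

#' Cross-validation score of a given order of density dependence
#'
#' Fits a nonparametric (Nadaraya-Watson, Gaussian-kernel) autoregression
#' of the given order to one plot's proportional-cover series and scores
#' it by leave-one-out cross-validation: how well do lagged densities
#' project the next census?  The kernel bandwidth is itself chosen by
#' minimizing the same leave-one-out criterion over a geometric grid, so
#' the returned score is the best achievable CV error at that order.
#' Targets or predictors touching a missing census are excluded.
#'
#' When scores of different orders are to be compared, they must be
#' computed over the same prediction targets; \code{minLags} restricts the
#' scored targets to censuses with at least that many observed
#' predecessors (all valid embeddings still serve as training neighbours).
#' [oddProfile()] sets \code{minLags = maxOrder} for exactly this reason.
#'
#' @param series numeric proportional covers of one plot, in census order
#'   (\code{NA} marks a missed census).
#' @param order order of density dependence (number of lagged predictors).
#' @param nBandwidths size of the bandwidth grid.
#' @param minLags minimum number of observed predecessors a census needs
#'   to be scored as a prediction target; defaults to \code{order}.
#' @return the minimized leave-one-out mean squared prediction error.
#' @examples
#' oddCvScore(rep(0.5, 12), order = 1)    # a constant series scores 0
#' @export
oddCvScore <- function(series, order, nBandwidths = 25L, minLags = order) {
    stopifnot(order >= 1L, minLags >= order)
    if (sum(is.finite(series)) <= minLags + 2L)
        stop("series too short for order ", order,
             ": need more than minLags + 2 observed censuses")
    emb <- .embedSeries(series, order)
    tEligible <- .embedSeries(series, minLags)$t
    targets <- which(emb$t %in% tEligible)
    if (length(targets) < 3L)
        stop("series too short for order ", order,
             " after gap handling: only ", length(targets),
             " usable targets")
    d2 <- as.matrix(stats::dist(emb$x))^2
    dmax <- sqrt(max(d2))
    if (dmax == 0) return(.nwLooCv(d2, emb$y, 1, targets))
    hGrid <- exp(seq(log(max(dmax * 0.01, 1e-4)), log(dmax * 2),
                     length.out = nBandwidths))
    min(vapply(hGrid, function(h) .nwLooCv(d2, emb$y, h, targets),
               numeric(1)))
}

#' Order-of-density-dependence profile across plots
#'
#' Computes [oddCvScore()] for each plot and each order \code{1..maxOrder},
#' standardizes the scores within each plot by setting its minimum to 0,
#' and averages the standardized index across plots: a lower average index
#' indicates greater support for that order.  All orders are scored over
#' the same prediction targets (censuses with \code{maxOrder} observed
#' predecessors), so the comparison is not biased by the early, transient
#' censuses that only low orders could otherwise attempt.  Plots too short
#' for some order are skipped for that order with a warning.
#'
#' @param study a [MusselStudy-class].
#' @param maxOrder highest order assessed (default 5).
#' @param nBandwidths bandwidth grid size passed to [oddCvScore()].
#' @return an [OddProfile-class].
#' @export
oddProfile <- function(study, maxOrder = 5L, nBandwidths = 25L) {
    stopifnot(is(study, "MusselStudy"))
    props <- censusProportions(study)
    orders <- seq_len(maxOrder)
    raw <- matrix(NA_real_, nrow(props), maxOrder,
                  dimnames = list(rownames(props),
                                  paste0("order", orders)))
    for (q in seq_len(nrow(props))) {
        for (o in orders) {
            raw[q, o] <- tryCatch(
                oddCvScore(props[q, ], o, nBandwidths = nBandwidths,
                           minLags = maxOrder),
                error = function(e) {
                    warning(sprintf("plot '%s', order %d skipped: %s",
                                    rownames(props)[q], o,
                                    conditionMessage(e)), call. = FALSE)
                    NA_real_
                })
        }
    }
    rowMin <- apply(raw, 1L, function(r)
        if (all(is.na(r))) NA_real_ else min(r, na.rm = TRUE))
    std <- raw - rowMin
    new("OddProfile", raw = raw, standardized = std,
        meanScore = colMeans(std, na.rm = TRUE), orders = orders)
}

#' Accessors for an ODD profile
#'
#' @param profile an [OddProfile-class].
#' @return \code{oddMeanScore}: per-order mean standardized CV score;
#'   \code{oddStandardized}: the plots x orders standardized score matrix;
#'   \code{oddBestOrder}: the order with the lowest mean score.
#' @export
oddMeanScore <- function(profile) profile@meanScore

#' @rdname oddMeanScore
#' @export
oddStandardized <- function(profile) profile@standardized

#' @rdname oddMeanScore
#' @export
oddBestOrder <- function(profile)
    profile@orders[which.min(profile@meanScore)]

#' @describeIn OddProfile-class compact display
#' @param object an \code{OddProfile}.
#' @export
setMethod("show", "OddProfile", function(object) {
    cat(sprintf("OddProfile over %d plots, orders 1-%d\n",
                nrow(object@raw), max(object@orders)))
    cat("  mean standardized CV score (lower = more support):\n")
    print(round(object@meanScore, 4))
    cat(sprintf("  best-supported order: %d\n", oddBestOrder(object)))
})
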