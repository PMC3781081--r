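## Forward simulation, deterministic attractor analysis, Monte-Carlo
## prediction envelopes and spectral diagnostics.

## advance the lag state (most recent first) by one deterministic step
.stepLags <- function(lags, newP) c(newP, lags)[seq_along(lags)]

#' Iterate the deterministic skeleton
#'
#' @param model a [PopModel-class]; only its mean map is used.
#' @param p0 initial proportional cover (orders > 1 start with all lags at
#'   \code{p0}).
#' @param steps number of iterations.
#' @return numeric trajectory of length \code{steps + 1} (including
#'   \code{p0}).
#' @examples
#' m <- dlsPreset("deterministic_table1")$model
#' tail(iterateDeterministic(m, 0.1, 200), 1)   # ~0.829
#' @export
iterateDeterministic <- function(model, p0, steps) {
    stopifnot(is(model, "PopModel"), p0 >= 0, p0 <= 1)
    out <- numeric(steps + 1L)
    out[1L] <- p0
    lags <- rep(p0, model@order)
    for (t in seq_len(steps)) {
        out[t + 1L] <- meanMap(model, lags)
        lags <- .stepLags(lags, out[t + 1L])
    }
    out
}

#' Find the attractor of the deterministic skeleton
#'
#' Iterates the mean map from \code{p0} until successive iterates differ
#' by less than \code{tol} (a fixed point) or a cycle of period at most
#' \code{maxPeriod} recurs.
#'
#' @param model a [PopModel-class].
#' @param p0 initial proportional cover.
#' @param tol convergence tolerance on successive iterates.
#' @param maxIter iteration budget.
#' @param maxPeriod longest cycle searched for.
#' @return a list with \code{type} (\code{"fixed-point"}, \code{"cycle"} or
#'   \code{"none"}), \code{points} (the fixed point or the cycle states),
#'   and \code{period}.
#' @export
findAttractor <- function(model, p0, tol = 1e-10, maxIter = 1e5,
                          maxPeriod = 50L) {
    stopifnot(is(model, "PopModel"))
    lags <- rep(p0, model@order)
    p <- p0
    history <- numeric(0)
    for (t in seq_len(maxIter)) {
        pn <- meanMap(model, lags)
        if (abs(pn - p) < tol)
            return(list(type = "fixed-point", points = pn, period = 1L))
        lags <- .stepLags(lags, pn)
        p <- pn
        if (t > maxIter - 4L * maxPeriod)
            history <- c(history, pn)
    }
    ## look for a short cycle in the tail
    for (m in seq_len(maxPeriod)[-1L]) {
        n <- length(history)
        if (n < 2L * m) next
        if (all(abs(history[(n - m + 1L):n] -
                    history[(n - 2L * m + 1L):(n - m)]) < tol * 10))
            return(list(type = "cycle",
                        points = history[(n - m + 1L):n], period = m))
    }
    list(type = "none", points = history, period = NA_integer_)
}

#' Simulate an ensemble of stochastic trajectories
#'
#' Each replicate starts from its own initial cover and is iterated by
#' drawing the next census count from the model's one-step transition
#' distribution, then converting back to a proportion.  Models with
#' variance mode \code{"none"} iterate deterministically, rounded to the
#' count lattice.
#'
#' @param model a [PopModel-class].
#' @param inits initial proportional covers, one per replicate.
#' @param steps number of census intervals to simulate (trajectories have
#'   \code{steps + 1} points).
#' @param nTrials number of sample units (a scalar or one per replicate).
#' @param seed integer seed for reproducibility.
#' @return an [Ensemble-class].
#' @export
simulateEnsemble <- function(model, inits, steps = 17L, nTrials = 484L,
                             seed = NULL) {
    stopifnot(is(model, "PopModel"), all(inits >= 0 & inits <= 1))
    if (!is.null(seed)) set.seed(seed)
    nRep <- length(inits)
    nTrials <- as.integer(rep_len(nTrials, nRep))
    props <- matrix(NA_real_, nRep, steps + 1L)
    deterministic <- model@variance@mode == "none"
    for (i in seq_len(nRep)) {
        lags <- rep(inits[i], model@order)
        props[i, 1L] <- inits[i]
        for (t in seq_len(steps)) {
            if (deterministic) {
                cnt <- round(meanMap(model, lags) * nTrials[i])
            } else {
                td <- transitionDistribution(model, lags, nTrials[i])
                cnt <- sampleTransition(td)
            }
            pn <- cnt / nTrials[i]
            props[i, t + 1L] <- pn
            lags <- .stepLags(lags, pn)
        }
    }
    new("Ensemble", props = props, nTrials = nTrials,
        inits = as.numeric(inits),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        label = model@label)
}

#' Trajectories of an ensemble
#'
#' @param ensemble an [Ensemble-class].
#' @return the replicates x time matrix of proportional covers.
#' @export
ensembleProps <- function(ensemble) ensemble@props

#' @describeIn Ensemble-class compact display
#' @param object an \code{Ensemble}.
#' @export
setMethod("show", "Ensemble", function(object) {
    cat(sprintf("Ensemble '%s': %d replicates x %d censuses (seed %s)\n",
                object@label, nrow(object@props), ncol(object@props),
                ifelse(is.na(object@seed), "none", object@seed)))
})

#' Monte-Carlo prediction envelope
#'
#' For every starting density on a regular grid, draws \code{iters}
#' one-step transitions from the model, histograms the outcomes on the
#' count lattice \code{0..nTrials}, and accumulates bins from the highest
#' probability downward until the target coverage is reached.  The
#' resulting highest-probability region remains valid when the outcome
#' distribution is multimodal (as under a disturbance mixture), unlike a
#' central quantile interval.
#'
#' @param model a first-order [PopModel-class].
#' @param nTrials size of the count lattice.
#' @param increment grid spacing of starting densities (default 0.002).
#' @param iters Monte-Carlo iterations per grid point (default \code{1e6};
#'   reduce for quick diagnostics).
#' @param coverage target retained probability mass (default 0.95).
#' @param seed integer seed.
#' @param startProps explicit starting densities, overriding the
#'   \code{increment} grid.
#' @return a [PredictionEnvelope-class].
#' @export
predictionEnvelope <- function(model, nTrials = 484L, increment = 0.002,
                               iters = 1e6, coverage = 0.95, seed = NULL,
                               startProps = NULL) {
    stopifnot(is(model, "PopModel"))
    if (model@order != 1L)
        stop("prediction envelopes are defined for first-order models")
    if (iters < 20 / (1 - coverage))
        warning("too few iterations to resolve the requested coverage")
    if (!is.null(seed)) set.seed(seed)
    grid <- if (is.null(startProps)) seq(0, 1, by = increment)
            else as.numeric(startProps)
    nBins <- nTrials + 1L
    hist <- matrix(0L, length(grid), nBins)
    env <- matrix(FALSE, length(grid), nBins)
    retained <- numeric(length(grid))
    deterministic <- model@variance@mode == "none"
    for (g in seq_along(grid)) {
        if (deterministic) {
            cnt <- rep(round(meanMap(model, grid[g]) * nTrials), iters)
        } else {
            td <- transitionDistribution(model, grid[g], nTrials)
            cnt <- sampleTransition(td, iters)
        }
        h <- tabulate(cnt + 1L, nbins = nBins)
        hist[g, ] <- h
        ord <- order(h, decreasing = TRUE)
        cum <- cumsum(h[ord])
        take <- ord[seq_len(which(cum >= coverage * iters)[1])]
        env[g, take] <- TRUE
        retained[g] <- sum(h[take]) / iters
    }
    new("PredictionEnvelope", startProps = grid, histogram = hist,
        envelope = env, retainedMass = retained, coverage = coverage,
        iters = iters, nTrials = as.integer(nTrials),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Is an observed transition inside the envelope?
#'
#' @param envelope a [PredictionEnvelope-class].
#' @param p0 starting density (snapped to the nearest grid point).
#' @param count observed next-census count(s).
#' @return logical vector.
#' @export
inEnvelope <- function(envelope, p0, count) {
    g <- which.min(abs(envelope@startProps - p0))
    envelope@envelope[g, count + 1L]
}

#' @describeIn PredictionEnvelope-class compact display
#' @param object a \code{PredictionEnvelope}.
#' @export
setMethod("show", "PredictionEnvelope", function(object) {
    cat(sprintf(
        "PredictionEnvelope: %d starting densities x lattice 0..%d\n  coverage >= %.2f (achieved %.3f-%.3f), %g iterations per point\n",
        length(object@startProps), object@nTrials, object@coverage,
        min(object@retainedMass), max(object@retainedMass), object@iters))
})

## one-sided mean-removed periodogram; power normalized so that
## sum(power) equals the biased series variance (Parseval)
.periodogram <- function(x) {
    n <- length(x)
    xm <- x - mean(x)
    X <- stats::fft(xm)
    m <- n %/% 2L
    pw <- 2 * Mod(X[2L:(m + 1L)])^2 / n^2
    if (n %% 2L == 0L) pw[m] <- pw[m] / 2    # Nyquist bin is not folded
    list(frequency = seq_len(m) / n, power = pw)
}

#' Power spectrum of a census series
#'
#' Mean-removed, untapered one-sided periodogram.  Frequencies are in
#' cycles per census interval up to the Nyquist limit 0.5; the power
#' normalization is chosen so that the spectrum sums exactly to the
#' (biased) series variance.  Odd-length series are handled without
#' padding.
#'
#' @param series numeric series of proportional covers (length >= 8, no
#'   missing values).
#' @return a [Spectrum-class].
#' @export
powerSpectrum <- function(series) {
    if (length(series) < 8L || anyNA(series))
        stop("'series' must have length >= 8 with no missing values")
    pg <- .periodogram(series)
    new("Spectrum", frequency = pg$frequency,
        power = matrix(pg$power, 1L), meanPower = pg$power,
        sePower = rep(NA_real_, length(pg$power)))
}

#' Averaged power spectrum of an ensemble
#'
#' Periodogram of each replicate trajectory plus the across-replicate mean
#' and standard error per frequency.
#'
#' @param ensemble an [Ensemble-class] (equal-length replicates).
#' @return a [Spectrum-class].
#' @export
ensembleSpectrum <- function(ensemble) {
    stopifnot(is(ensemble, "Ensemble"))
    props <- ensemble@props
    if (anyNA(props)) stop("ensemble trajectories contain missing values")
    pgs <- apply(props, 1L, .periodogram, simplify = FALSE)
    pw <- do.call(rbind, lapply(pgs, `[[`, "power"))
    new("Spectrum", frequency = pgs[[1L]]$frequency, power = pw,
        meanPower = colMeans(pw),
        sePower = apply(pw, 2L, stats::sd) / sqrt(nrow(pw)))
}

#' Accessors for a spectrum
#'
#' @param spectrum a [Spectrum-class].
#' @return \code{spectrumFrequency}: frequencies in cycles per census;
#'   \code{spectrumPower}: the replicates x frequency power matrix;
#'   \code{spectrumMean} / \code{spectrumSE}: across-replicate mean and
#'   standard error.
#' @export
spectrumFrequency <- function(spectrum) spectrum@frequency

#' @rdname spectrumFrequency
#' @export
spectrumPower <- function(spectrum) spectrum@power

#' @rdname spectrumFrequency
#' @export
spectrumMean <- function(spectrum) spectrum@meanPower

#' @rdname spectrumFrequency
#' @export
spectrumSE <- function(spectrum) spectrum@sePower

#' @describeIn Spectrum-class compact display
#' @param object a \code{Spectrum}.
#' @export
setMethod("show", "Spectrum", function(object) {
    cat(sprintf(
        "Spectrum: %d frequencies (%.3f-%.3f cycles/census), %d replicate(s)\n",
        length(object@frequency), min(object@frequency),
        max(object@frequency), nrow(object@power)))
})
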