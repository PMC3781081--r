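#' @import methods
NULL

## ---------------------------------------------------------------------------
## Beta-binomial
## ---------------------------------------------------------------------------

#' Beta-binomial specification
#'
#' A count distribution on \code{0..nTrials} arising from a binomial whose
#' success probability is beta-distributed with shape parameters \code{a}
#' and \code{b}.  The beta component has mean \eqn{\mu = a/(a+b)}, and its
#' spread is governed by the overdispersion \eqn{\phi = a + b}: the beta
#' variance is \eqn{\mu(1-\mu)/(\phi + 1)}.
#'
#' @slot a positive beta shape parameter.
#' @slot b positive beta shape parameter.
#' @slot nTrials positive integer number of sampled units.
#'
#' @seealso [betaBinomSpec()], [dbetabinom()], [bbFromMoments()]
#' @export
setClass("BetaBinomSpec",
    representation(a = "numeric", b = "numeric", nTrials = "integer"))

setValidity("BetaBinomSpec", function(object) {
    msg <- NULL
    if (length(object@a) != 1L || !is.finite(object@a) || object@a <= 0)
        msg <- c(msg, "'a' must be a single positive finite number")
    if (length(object@b) != 1L || !is.finite(object@b) || object@b <= 0)
        msg <- c(msg, "'b' must be a single positive finite number")
    if (length(object@nTrials) != 1L || is.na(object@nTrials) ||
        object@nTrials < 1L)
        msg <- c(msg, "'nTrials' must be a positive integer")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Model components
## ---------------------------------------------------------------------------

#' Transition variance model
#'
#' Describes how the spread of the one-step transition distribution behaves
#' with density.  Three modes are supported:
#' \describe{
#'   \item{\code{"constant"}}{a single variance \code{sigma2} on the
#'     proportion scale, independent of density;}
#'   \item{\code{"dls"}}{density-linked stochasticity: the beta-binomial
#'     overdispersion is a log-linear function of current density,
#'     \eqn{\phi(p) = \exp(x + y \log p + z p)}, so the transition variance
#'     \eqn{\mu(1-\mu)/(\phi(p)+1)} varies with abundance while remaining
#'     automatically inside the feasible beta range;}
#'   \item{\code{"none"}}{a deterministic skeleton (no process noise).}
#' }
#'
#' @slot mode one of \code{"constant"}, \code{"dls"}, \code{"none"}.
#' @slot sigma2 constant-mode variance (proportion scale).
#' @slot x,y,z DLS overdispersion parameters.
#' @export
setClass("VarianceModel",
    representation(mode = "character", sigma2 = "numeric",
                   x = "numeric", y = "numeric", z = "numeric"),
    prototype(mode = "constant", sigma2 = 0.04, x = 0, y = 0, z = 0))

setValidity("VarianceModel", function(object) {
    msg <- NULL
    if (!object@mode %in% c("constant", "dls", "none"))
        msg <- c(msg, "'mode' must be \"constant\", \"dls\" or \"none\"")
    if (object@mode == "constant" &&
        (!is.finite(object@sigma2) || object@sigma2 <= 0))
        msg <- c(msg, "constant mode needs a positive 'sigma2'")
    if (object@mode == "dls" &&
        !all(is.finite(c(object@x, object@y, object@z))))
        msg <- c(msg, "dls mode needs finite 'x', 'y', 'z'")
    if (is.null(msg)) TRUE else msg
})

#' Disturbance mixture component
#'
#' With probability \eqn{\Psi_d(p)} the next census is drawn from a
#' post-disturbance beta-binomial with mean proportional cover \code{muD}
#' and variance \code{sigma2D} instead of the growth model.  The
#' disturbance probability is logistic in current density:
#' \eqn{\Psi_d(p) = 1/(1 + e^{-(j + k p)})}.
#'
#' The disturbed beta-binomial is constrained to have a single mode: its
#' beta shape parameters satisfy \eqn{b_d > 1} (and \eqn{a_d > 0}), ruling
#' out U-shaped outcome distributions while allowing the mode to sit at
#' zero cover.
#'
#' @slot muD mean post-disturbance proportional cover, in (0,1).
#' @slot sigma2D variance of post-disturbance cover (proportion scale).
#' @slot j,k intercept and slope of the logistic disturbance probability.
#' @export
setClass("DisturbanceModel",
    representation(muD = "numeric", sigma2D = "numeric",
                   j = "numeric", k = "numeric"))

setValidity("DisturbanceModel", function(object) {
    msg <- NULL
    if (!is.finite(object@muD) || object@muD <= 0 || object@muD >= 1)
        msg <- c(msg, "'muD' must lie in (0, 1)")
    bound <- object@muD * (1 - object@muD)
    if (!is.finite(object@sigma2D) || object@sigma2D <= 0 ||
        object@sigma2D >= bound)
        msg <- c(msg, sprintf(
            "'sigma2D' must lie in (0, muD*(1-muD)) = (0, %.4g)", bound))
    if (!all(is.finite(c(object@j, object@k))))
        msg <- c(msg, "'j' and 'k' must be finite")
    if (is.null(msg)) {
        phi <- object@muD * (1 - object@muD) / object@sigma2D - 1
        bD <- (1 - object@muD) * phi
        aD <- object@muD * phi
        if (aD < 1 && bD < 1)
            return("disturbed state is U-shaped (both shape parameters < 1)")
        TRUE
    } else msg
})

setClassUnion("DisturbanceModelOrNULL", c("DisturbanceModel", "NULL"))

#' Population dynamics model
#'
#' Bundles a deterministic mean map (modified Ricker or modified Hassell,
#' order 1--4), a transition [VarianceModel], and an optional
#' [DisturbanceModel] mixture.  Parameters fixed a priori (for example the
#' non-linear terms of a linear variant) are carried in the model with a
#' fixed-parameter mask rather than removed, so the free-parameter count
#' used by AIC is derived from the mask.
#'
#' @slot meanForm \code{"ricker"} or \code{"hassell"}.
#' @slot order integer order of density dependence (number of lags), 1--4.
#' @slot linear logical; if \code{TRUE} the non-linear terms
#'   (\code{beta}, \code{c}) are fixed a priori at 0 and 1.
#' @slot params named numeric vector of mean-map parameters.
#' @slot fixed named logical mask over \code{params}; \code{TRUE} entries
#'   are fixed a priori and not counted as free parameters.
#' @slot variance a [VarianceModel].
#' @slot disturbance a [DisturbanceModel] or \code{NULL} (no mixture).
#' @slot label character label used in comparison tables.
#' @export
setClass("PopModel",
    representation(meanForm = "character", order = "integer",
                   linear = "logical", params = "numeric",
                   fixed = "logical", variance = "VarianceModel",
                   disturbance = "DisturbanceModelOrNULL",
                   label = "character"))

setValidity("PopModel", function(object) {
    msg <- NULL
    if (!object@meanForm %in% c("ricker", "hassell"))
        msg <- c(msg, "'meanForm' must be \"ricker\" or \"hassell\"")
    if (object@order < 1L || object@order > 4L)
        msg <- c(msg, "'order' must be in 1..4")
    wanted <- meanParamNames(object@meanForm, object@order)
    if (!identical(names(object@params), wanted))
        msg <- c(msg, paste0("'params' must be named: ",
                             paste(wanted, collapse = ", ")))
    if (!identical(names(object@fixed), wanted))
        msg <- c(msg, "'fixed' must have the same names as 'params'")
    cx <- object@params[grepl("^c[0-9]$", names(object@params))]
    if (length(cx) && any(!is.finite(cx) | cx <= 0))
        msg <- c(msg, "non-linearity exponents 'c' must be positive")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' Multi-plot census study
#'
#' A \linkS4class{SummarizedExperiment} holding annual census counts for a
#' set of permanent plots.  Rows are plots, columns are census years, and
#' the single \code{"counts"} assay holds the number of occupied sample
#' units (\code{NA} marks a missed census).  \code{rowData} carries the
#' per-plot number of sample units \code{nMax} (e.g. 484 quarter-squares
#' or 100 fixed points).
#'
#' @seealso [musselStudy()], [readPlots()], [generateStudy()]
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("MusselStudy", contains = "SummarizedExperiment")

#' Lagged transition dataset
#'
#' Row-wise transitions built from a [MusselStudy]: each row holds an
#' observed next-census count together with the previous \code{maxLag}
#' proportional covers (most recent lag first).  Rows never span a missing
#' census.  A dataset fingerprint guards against comparing fits obtained
#' on different data.
#'
#' @slot data data.frame with columns \code{plot}, \code{year},
#'   \code{count}, \code{nMax}, and \code{p1..p<maxLag>}.
#' @slot maxLag integer maximum lag (1 or 4).
#' @slot fingerprint character dataset fingerprint.
#' @export
setClass("LagDataset",
    representation(data = "data.frame", maxLag = "integer",
                   fingerprint = "character"))

#' Study design for the synthetic-data generator
#'
#' @slot nPlots number of plots.
#' @slot years contiguous calendar census years.
#' @slot nMax per-plot number of sample units.
#' @slot firstYear per-plot year of plot establishment.
#' @slot initRange range of the uniform initial-cover distribution.
#' @slot missing data.frame with columns \code{plot}, \code{year}: censuses
#'   that were missed (recorded as \code{NA}).
#' @slot errorRate per-unit measurement error (state-flip) probability.
#' @export
setClass("StudyDesign",
    representation(nPlots = "integer", years = "integer", nMax = "integer",
                   firstYear = "integer", initRange = "numeric",
                   missing = "data.frame", errorRate = "numeric"))

setValidity("StudyDesign", function(object) {
    msg <- NULL
    if (length(object@nMax) != object@nPlots)
        msg <- c(msg, "'nMax' must have one entry per plot")
    if (length(object@firstYear) != object@nPlots)
        msg <- c(msg, "'firstYear' must have one entry per plot")
    if (any(diff(object@years) != 1L))
        msg <- c(msg, "'years' must be contiguous calendar years")
    if (!all(object@firstYear %in% object@years))
        msg <- c(msg, "'firstYear' entries must be census years")
    if (length(object@initRange) != 2L || object@initRange[1] <= 0 ||
        object@initRange[2] >= 1 || diff(object@initRange) < 0)
        msg <- c(msg, "'initRange' must be an increasing range inside (0,1)")
    if (object@errorRate < 0 || object@errorRate >= 1)
        msg <- c(msg, "'errorRate' must be in [0, 1)")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## Results
## ---------------------------------------------------------------------------

#' Maximum-likelihood fit of a population model
#'
#' @slot model the fitted [PopModel] (parameters at the optimum).
#' @slot estimates named numeric vector of all model parameters at the
#'   optimum (fixed entries included at their fixed values).
#' @slot negLogLik minimized negative log-likelihood.
#' @slot k number of free (estimated) parameters.
#' @slot aic Akaike information criterion, \code{2k + 2(-LL)}.
#' @slot fingerprint fingerprint of the [LagDataset] used.
#' @slot nStarts number of multistart optimizations performed.
#' @slot convergence convergence codes of the multistarts.
#' @slot label model label.
#' @export
setClass("PopFit",
    representation(model = "PopModel", estimates = "numeric",
                   negLogLik = "numeric", k = "integer", aic = "numeric",
                   fingerprint = "character", nStarts = "integer",
                   convergence = "integer", label = "character"))

#' Order-of-density-dependence profile
#'
#' Per-plot leave-one-out cross-validation errors of nonparametric
#' autoregressions of order 1..maxOrder, standardized within plot so the
#' best order scores 0, plus the cross-plot mean standardized score per
#' order (lower means greater support).
#'
#' @slot raw plots x orders matrix of raw CV errors.
#' @slot standardized same matrix with each plot's minimum set to 0.
#' @slot meanScore per-order mean standardized score across plots.
#' @slot orders the orders assessed.
#' @export
setClass("OddProfile",
    representation(raw = "matrix", standardized = "matrix",
                   meanScore = "numeric", orders = "integer"))

#' Ensemble of simulated trajectories
#'
#' @slot props replicates x time matrix of proportional covers.
#' @slot nTrials per-replicate number of sample units.
#' @slot inits initial proportional covers.
#' @slot seed seed used (NA if none).
#' @slot label model label.
#' @export
setClass("Ensemble",
    representation(props = "matrix", nTrials = "integer", inits = "numeric",
                   seed = "integer", label = "character"))

#' Monte-Carlo prediction envelope
#'
#' For a grid of starting densities, the Monte-Carlo outcome histogram on
#' the count lattice \code{0..nTrials} and the smallest set of outcome
#' bins, accumulated in decreasing probability, whose mass reaches the
#' coverage level (a highest-probability-density region, valid for
#' multimodal outcome distributions).
#'
#' @slot startProps grid of starting proportional covers.
#' @slot histogram grid x (nTrials+1) matrix of outcome counts.
#' @slot envelope logical matrix of the same shape; \code{TRUE} bins belong
#'   to the envelope.
#' @slot retainedMass per-grid-point probability mass retained (>= coverage).
#' @slot coverage nominal coverage level.
#' @slot iters Monte-Carlo iterations per grid point.
#' @slot nTrials size of the count lattice.
#' @slot seed seed used (NA if none).
#' @export
setClass("PredictionEnvelope",
    representation(startProps = "numeric", histogram = "matrix",
                   envelope = "matrix", retainedMass = "numeric",
                   coverage = "numeric", iters = "numeric",
                   nTrials = "integer", seed = "integer"))

#' One-sided power spectrum
#'
#' Mean-removed, untapered periodogram; frequencies run to the Nyquist
#' limit of 0.5 cycles per census.  Power is normalized so that the sum of
#' the one-sided spectrum equals the (biased) series variance.  For
#' ensembles, rows of \code{power} are replicates and \code{meanPower} /
#' \code{sePower} give the across-replicate mean and standard error.
#'
#' @slot frequency frequencies in cycles per census interval.
#' @slot power replicates x frequency matrix of power.
#' @slot meanPower per-frequency mean across replicates.
#' @slot sePower per-frequency standard error (NA for a single series).
#' @export
setClass("Spectrum",
    representation(frequency = "numeric", power = "matrix",
                   meanPower = "numeric", sePower = "numeric"))
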