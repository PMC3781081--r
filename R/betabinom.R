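## Beta-binomial core.  All pmf evaluation goes through log-gamma
## differences (lchoose/lbeta), never factorials: the study's sample sizes
## (up to 484 units) overflow naive binomial coefficients.

## overdispersion values are capped so that lbeta() stays accurate; beyond
## ~1e8 the distribution is numerically binomial anyway.
.PHI_MIN <- 1e-8
.PHI_MAX <- 1e8

## workhorse: vectorized log pmf on the count lattice
.dbb <- function(x, size, a, b, log = FALSE) {
    lp <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
    lp[x < 0 | x > size | x != round(x)] <- -Inf
    if (log) lp else exp(lp)
}

#' Construct a beta-binomial specification
#'
#' @param a,b positive beta shape parameters.
#' @param nTrials positive integer number of sampled units.
#' @return a [BetaBinomSpec-class] object.
#' @examples
#' spec <- betaBinomSpec(2, 5, 100)
#' betaMean(spec)
#' @export
betaBinomSpec <- function(a, b, nTrials) {
    new("BetaBinomSpec", a = as.numeric(a), b = as.numeric(b),
        nTrials = as.integer(nTrials))
}

#' Beta-binomial probability mass function
#'
#' Computed in log space via log-gamma differences, so counts out of a
#' sample of 484 units do not underflow.
#'
#' @param x integer count(s) in \code{0..nTrials(spec)}.
#' @param spec a [BetaBinomSpec-class].
#' @param log logical; return log probabilities?
#' @return probabilities (or log probabilities) of \code{x}.
#' @export
dbetabinom <- function(x, spec, log = FALSE) {
    stopifnot(is(spec, "BetaBinomSpec"))
    if (any(x < 0 | x > spec@nTrials | x != round(x)))
        stop("'x' must be integer counts in [0, ", spec@nTrials, "]")
    .dbb(x, spec@nTrials, spec@a, spec@b, log = log)
}

#' Sample beta-binomial counts
#'
#' Two-stage draw: a beta success probability, then a binomial count.
#'
#' @param n number of draws.
#' @param spec a [BetaBinomSpec-class].
#' @return integer counts in \code{0..nTrials(spec)}.
#' @export
rbetabinom <- function(n, spec) {
    stopifnot(is(spec, "BetaBinomSpec"))
    stats::rbinom(n, spec@nTrials, stats::rbeta(n, spec@a, spec@b))
}

#' Mean, variance and overdispersion of the beta component
#'
#' \code{betaMean} returns \eqn{\mu = a/(a+b)}; \code{betaVariance} returns
#' \eqn{\mu(1-\mu)/(\phi+1)} with overdispersion \eqn{\phi = a+b};
#' \code{bbVariance} returns the variance of the beta-binomial count.
#'
#' @param spec a [BetaBinomSpec-class].
#' @return a numeric scalar.
#' @export
betaMean <- function(spec) spec@a / (spec@a + spec@b)

#' @rdname betaMean
#' @export
betaVariance <- function(spec) {
    mu <- betaMean(spec)
    mu * (1 - mu) / (overdispersion(spec) + 1)
}

#' @rdname betaMean
#' @export
overdispersion <- function(spec) spec@a + spec@b

#' @rdname betaMean
#' @export
bbVariance <- function(spec) {
    n <- spec@nTrials
    mu <- betaMean(spec)
    phi <- overdispersion(spec)
    n * mu * (1 - mu) * (n + phi) / (phi + 1)
}

#' Invert beta moments to shape parameters
#'
#' Given the beta mean and variance, recovers the shape parameters via
#' \eqn{\phi = \mu(1-\mu)/\sigma^2 - 1}, \eqn{a = \mu\phi},
#' \eqn{b = (1-\mu)\phi}.  The variance must be strictly inside the
#' feasible beta range \eqn{(0, \mu(1-\mu))}; a tiny margin is enforced to
#' avoid the \eqn{\phi \to 0} degeneracy.
#'
#' @param mean beta mean in (0,1).
#' @param variance beta variance.
#' @param nTrials number of sampled units for the resulting spec.
#' @return a [BetaBinomSpec-class] whose derived moments reproduce the
#'   inputs.
#' @export
bbFromMoments <- function(mean, variance, nTrials) {
    stopifnot(length(mean) == 1L, length(variance) == 1L)
    if (!is.finite(mean) || mean <= 0 || mean >= 1)
        stop("'mean' must lie in (0, 1)")
    bound <- mean * (1 - mean)
    if (!is.finite(variance) || variance <= 0 ||
        variance > (1 - 1e-9) * bound)
        stop(sprintf(
            "infeasible variance %.6g: must lie in (0, mean*(1-mean)) = (0, %.6g)",
            variance, bound))
    phi <- bound / variance - 1
    betaBinomSpec(mean * phi, (1 - mean) * phi, nTrials)
}

#' Is the beta component unimodal (interior mode)?
#'
#' \code{TRUE} iff the beta mixing density has a strictly interior mode,
#' i.e. \code{a > 1} and \code{b > 1}.  The flat and boundary cases
#' (\code{a = 1} or \code{b = 1}) are counted as not unimodal.
#'
#' @param spec a [BetaBinomSpec-class].
#' @return logical.
#' @export
isUnimodal <- function(spec) {
    stopifnot(is(spec, "BetaBinomSpec"))
    spec@a > 1 && spec@b > 1
}

#' @describeIn BetaBinomSpec-class compact display
#' @param object a \code{BetaBinomSpec}.
#' @export
setMethod("show", "BetaBinomSpec", function(object) {
    cat(sprintf(
        "BetaBinomSpec: a = %.4g, b = %.4g, nTrials = %d\n  beta mean = %.4g, beta variance = %.4g, overdispersion = %.4g\n",
        object@a, object@b, object@nTrials, betaMean(object),
        betaVariance(object), overdispersion(object)))
})
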