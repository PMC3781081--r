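## Deterministic skeletons, the density-linked variance function, and the
## disturbance mixture.  Each functional form is isolated as a single pure
## function so the model equations live in exactly one place.

## mean maps are clamped to the open unit interval before beta-binomial
## construction: the beta mean must be interior.
.MU_EPS <- 1e-9
## floor on the density entering the log-density overdispersion term; an
## empty plot behaves as (numerically) binomial sampling around the mean.
.P_FLOOR <- 1e-4

.clampMu <- function(mu) pmin(pmax(mu, .MU_EPS), 1 - .MU_EPS)

meanParamNames <- function(meanForm, order) {
    lags <- seq_len(order)
    if (meanForm == "ricker")
        c("I", "r", paste0("alpha", lags), paste0("beta", lags),
          paste0("c", lags))
    else
        c("I", "r", paste0("d", lags), "h", paste0("beta", lags),
          paste0("c", lags))
}

.asLagMatrix <- function(lagProps, order) {
    m <- if (is.matrix(lagProps)) lagProps else matrix(lagProps, nrow = 1L)
    if (ncol(m) < order)
        stop("need ", order, " lagged proportions, got ", ncol(m))
    m <- m[, seq_len(order), drop = FALSE]
    if (any(!is.finite(m) | m < 0 | m > 1))
        stop("lagged proportions must lie in [0, 1]")
    m
}

#' Modified Ricker mean map
#'
#' Expected proportional cover after one census interval,
#' \deqn{\mu_t = I\,(1 - p_{t-1}) + p_{t-1}\exp\!\big(r + \sum_{x=1}^{L}
#'   (\alpha_x p_{t-x} + \beta_x p_{t-x}^{c_x})\big),}
#' a Ricker map modified so that immigration \code{I} acts only on space
#' unoccupied by mussels, with optional power-law non-linearity per lag.
#' Linear variants fix \eqn{\beta_x = 0} and \eqn{c_x = 1} a priori.  The
#' result is clamped into the open unit interval.
#'
#' @param lagProps lagged proportional covers, most recent first: a vector
#'   \code{p[t-1], ..., p[t-order]} or a matrix with one row per
#'   transition.
#' @param params named numeric vector with entries \code{I}, \code{r},
#'   \code{alpha1..alphaL}, \code{beta1..betaL}, \code{c1..cL}.
#' @param order number of lags used.
#' @return expected proportion(s) in \eqn{[0,1]}.
#' @examples
#' # neutral parameters give the identity map
#' rickerMean(0.3, c(I = 0, r = 0, alpha1 = 0, beta1 = 0, c1 = 1), 1)
#' @export
rickerMean <- function(lagProps, params, order = 1L) {
    m <- .asLagMatrix(lagProps, order)
    lags <- seq_len(order)
    expo <- rep(params[["r"]], nrow(m))
    for (x in lags) {
        px <- m[, x]
        expo <- expo + params[[paste0("alpha", x)]] * px +
            params[[paste0("beta", x)]] * px^params[[paste0("c", x)]]
    }
    p1 <- m[, 1L]
    .clampMu(params[["I"]] * (1 - p1) + p1 * exp(expo))
}

#' Modified Hassell mean map
#'
#' A Hassell-type competition map modified in the same spirit as
#' [rickerMean()]: immigration into unoccupied space and an extra
#' power-law non-linearity,
#' \deqn{\mu_t = I\,(1 - p_{t-1}) + \frac{p_{t-1}\exp\!\big(r + \sum_x
#'   \beta_x p_{t-x}^{c_x}\big)}{\big(1 + \sum_x d_x p_{t-x}\big)^{h}}.}
#'
#' @inheritParams rickerMean
#' @param params named numeric vector with entries \code{I}, \code{r},
#'   \code{d1..dL} (density-dependence coefficients, non-negative),
#'   \code{h} (competition exponent, positive), \code{beta1..betaL},
#'   \code{c1..cL}.
#' @return expected proportion(s) in \eqn{[0,1]}.
#' @export
hassellMean <- function(lagProps, params, order = 1L) {
    m <- .asLagMatrix(lagProps, order)
    lags <- seq_len(order)
    expo <- rep(params[["r"]], nrow(m))
    dens <- rep(1, nrow(m))
    for (x in lags) {
        px <- m[, x]
        expo <- expo + params[[paste0("beta", x)]] * px^params[[paste0("c", x)]]
        dens <- dens + params[[paste0("d", x)]] * px
    }
    p1 <- m[, 1L]
    .clampMu(params[["I"]] * (1 - p1) +
             p1 * exp(expo) / dens^params[["h"]])
}

#' Construct a variance model
#'
#' @param mode \code{"constant"}, \code{"dls"} or \code{"none"}.
#' @param sigma2 constant-mode variance (proportion scale).
#' @param x,y,z DLS overdispersion parameters (see
#'   [VarianceModel-class]).
#' @return a [VarianceModel-class].
#' @export
varianceModel <- function(mode = c("constant", "dls", "none"),
                          sigma2 = 0.04, x = 0, y = 0, z = 0) {
    mode <- match.arg(mode)
    new("VarianceModel", mode = mode, sigma2 = sigma2, x = x, y = y, z = z)
}

#' Density-linked overdispersion function
#'
#' The DLS overdispersion is log-linear in density and log-density,
#' \eqn{\phi(p) = \exp(x + y \log p + z p)}, capped to a numerically safe
#' range.  Parameterizing the overdispersion (rather than the variance
#' itself) keeps the implied beta variance automatically inside its
#' feasible range at every density.
#'
#' @param p current proportional cover(s) in \eqn{[0,1]}.
#' @param model a [VarianceModel-class] in \code{"dls"} mode.
#' @return overdispersion \eqn{\phi(p) > 0}.
#' @export
dlsOverdispersion <- function(p, model) {
    stopifnot(is(model, "VarianceModel"), model@mode == "dls")
    pc <- pmax(p, .P_FLOOR)
    pmin(pmax(exp(model@x + model@y * log(pc) + model@z * pc),
              .PHI_MIN), .PHI_MAX)
}

## overdispersion of the undisturbed transition from density p with
## conditional mean mu; errors (or returns NA) on infeasibility
.transitionPhi <- function(p, mu, model, onInfeasible = c("error", "na")) {
    onInfeasible <- match.arg(onInfeasible)
    switch(model@mode,
        dls = dlsOverdispersion(p, model),
        constant = {
            phi <- mu * (1 - mu) / model@sigma2 - 1
            bad <- !is.finite(phi) | phi <= 0
            if (any(bad)) {
                if (onInfeasible == "error")
                    stop(sprintf(
                        "constant variance %.4g infeasible at density %.4g (mean %.4g): must be < mu*(1-mu) = %.4g",
                        model@sigma2, p[bad][1], mu[bad][1],
                        (mu * (1 - mu))[bad][1]))
                phi[bad] <- NA_real_
            }
            pmin(phi, .PHI_MAX)
        },
        none = stop("a deterministic skeleton has no transition variance"))
}

#' Undisturbed transition variance
#'
#' Variance (proportion scale) of the undisturbed one-step transition from
#' density \code{p}.  In \code{"constant"} mode this is \code{sigma2}
#' independent of density; in \code{"dls"} mode it is
#' \eqn{\mu(1-\mu)/(\phi(p)+1)} with the density-linked overdispersion
#' \eqn{\phi(p)}.  By default the conditional mean \code{mu} is taken equal
#' to \code{p}, which traces the variance profile over density.
#'
#' @param p current proportional cover(s).
#' @param model a [VarianceModel-class].
#' @param mu conditional mean(s) of the transition; defaults to \code{p}.
#' @return strictly positive variance(s).
#' @export
undisturbedVariance <- function(p, model, mu = p) {
    stopifnot(is(model, "VarianceModel"))
    if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
    mu <- .clampMu(mu)
    phi <- .transitionPhi(p, mu, model)
    ## in constant mode this recovers sigma2 exactly, after the
    ## feasibility check has had its say
    mu * (1 - mu) / (phi + 1)
}

#' Construct a disturbance mixture component
#'
#' @param muD mean post-disturbance proportional cover, in (0,1).
#' @param sigma2D variance of post-disturbance cover; must be feasible for
#'   a beta with mean \code{muD} and must not give a U-shaped (bimodal at
#'   both boundaries) disturbed state.
#' @param j,k intercept and slope of the logistic disturbance probability
#'   \eqn{\Psi_d(p) = 1/(1+e^{-(j + k p)})}.
#' @return a [DisturbanceModel-class].
#' @export
disturbanceModel <- function(muD, sigma2D, j, k) {
    new("DisturbanceModel", muD = muD, sigma2D = sigma2D,
        j = as.numeric(j), k = as.numeric(k))
}

#' Disturbance probability as a function of abundance
#'
#' @param p current proportional cover(s) in \eqn{[0,1]}.
#' @param model a [DisturbanceModel-class].
#' @return \eqn{\Psi_d(p) \in [0,1]}.
#' @export
disturbanceProbability <- function(p, model) {
    stopifnot(is(model, "DisturbanceModel"))
    if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
    stats::plogis(model@j + model@k * p)
}

## beta-binomial spec of the disturbed state
.disturbedSpec <- function(model, nTrials)
    bbFromMoments(model@muD, model@sigma2D, nTrials)

#' Construct a population dynamics model
#'
#' Assembles a [PopModel-class] from a mean-map form, a variance model and
#' an optional disturbance mixture.  Parameters not supplied default to the
#' neutral values (\code{I = 0}, \code{r = 0}, \code{alpha = d = beta = 0},
#' \code{c = h = 1}), under which the mean map is the identity.  For linear
#' variants the non-linear terms \code{beta} and \code{c} are fixed a
#' priori (at 0 and 1) and are excluded from the free-parameter count.
#'
#' @param meanForm \code{"ricker"} or \code{"hassell"}.
#' @param order order of density dependence (1--4).
#' @param linear logical; fix the non-linear terms a priori?
#' @param params named numeric overrides for mean-map parameters.
#' @param variance a [VarianceModel-class].
#' @param disturbance a [DisturbanceModel-class], or \code{NULL} for no
#'   mixture.
#' @param label model label used in reports; a descriptive default is
#'   derived from the structure.
#' @return a [PopModel-class].
#' @examples
#' popModel(order = 1, linear = TRUE,
#'          params = c(I = 0.242, r = 0.122, alpha1 = -0.209),
#'          variance = varianceModel("constant", sigma2 = 0.036))
#' @export
popModel <- function(meanForm = c("ricker", "hassell"), order = 1L,
                     linear = TRUE, params = NULL,
                     variance = varianceModel("constant"),
                     disturbance = NULL, label = NULL) {
    meanForm <- match.arg(meanForm)
    order <- as.integer(order)
    nm <- meanParamNames(meanForm, order)
    full <- stats::setNames(numeric(length(nm)), nm)
    full[grepl("^c[0-9]$", nm)] <- 1
    if (meanForm == "hassell") full[["h"]] <- 1
    if (!is.null(params)) {
        bad <- setdiff(names(params), nm)
        if (length(bad))
            stop("unknown parameter(s): ", paste(bad, collapse = ", "))
        full[names(params)] <- params
    }
    fixed <- stats::setNames(rep(FALSE, length(nm)), nm)
    if (linear)
        fixed[grepl("^(beta|c)[0-9]$", nm)] <- TRUE
    if (is.null(label))
        label <- paste0(meanForm, "-o", order,
                        if (linear) "-linear" else "-nonlinear",
                        "-", variance@mode,
                        if (!is.null(disturbance)) "-mixture" else "")
    new("PopModel", meanForm = meanForm, order = order, linear = linear,
        params = full, fixed = fixed, variance = variance,
        disturbance = disturbance, label = label)
}

#' Evaluate a model's mean map
#'
#' @param model a [PopModel-class].
#' @param lagProps lagged proportions (vector, most recent first, or a
#'   matrix with one row per transition).
#' @return expected proportion(s).
#' @export
meanMap <- function(model, lagProps) {
    stopifnot(is(model, "PopModel"))
    if (model@meanForm == "ricker")
        rickerMean(lagProps, model@params, model@order)
    else
        hassellMean(lagProps, model@params, model@order)
}

#' Number of free parameters of a model
#'
#' Fixed-a-priori mean-map parameters are excluded; the variance model
#' contributes 1 (constant) or 3 (DLS) parameters and a disturbance
#' mixture contributes 4.
#'
#' @param model a [PopModel-class].
#' @return integer free-parameter count \code{k}.
#' @export
freeParamCount <- function(model) {
    k <- sum(!model@fixed)
    k <- k + switch(model@variance@mode, constant = 1L, dls = 3L, none = 0L)
    if (!is.null(model@disturbance)) k <- k + 4L
    as.integer(k)
}

#' One-step transition distribution
#'
#' The mixture distribution of the next census count given lagged
#' proportional covers: with probability \eqn{1-\Psi_d(p_{t-1})} a
#' beta-binomial around the mean map with the undisturbed variance, and
#' with probability \eqn{\Psi_d(p_{t-1})} the post-disturbance
#' beta-binomial.
#'
#' @param model a [PopModel-class] with a stochastic variance mode.
#' @param lagProps lagged proportions, most recent first.
#' @param nTrials number of sampled units of the target census.
#' @return a list with elements \code{muT}, \code{sigma2T}, \code{psiD},
#'   \code{undisturbed} and \code{disturbed} ([BetaBinomSpec-class] or
#'   \code{NULL}), and \code{nTrials}.
#' @seealso [transitionPmf()], [sampleTransition()]
#' @export
transitionDistribution <- function(model, lagProps, nTrials) {
    stopifnot(is(model, "PopModel"))
    if (model@variance@mode == "none")
        stop("deterministic skeleton: no transition distribution; use iterateDeterministic()")
    lp <- .asLagMatrix(lagProps, model@order)
    stopifnot(nrow(lp) == 1L)
    mu <- meanMap(model, lp)
    p1 <- lp[, 1L]
    phi <- .transitionPhi(p1, mu, model@variance)
    und <- betaBinomSpec(mu * phi, (1 - mu) * phi, nTrials)
    if (is.null(model@disturbance)) {
        psi <- 0
        dis <- NULL
    } else {
        psi <- disturbanceProbability(p1, model@disturbance)
        dis <- .disturbedSpec(model@disturbance, nTrials)
    }
    list(muT = mu, sigma2T = betaVariance(und), psiD = psi,
         undisturbed = und, disturbed = dis, nTrials = as.integer(nTrials))
}

#' Probability mass function of a transition distribution
#'
#' @param td a transition distribution from [transitionDistribution()].
#' @param log logical; return log probabilities?
#' @return numeric vector of length \code{nTrials + 1} over counts
#'   \code{0..nTrials}.
#' @export
transitionPmf <- function(td, log = FALSE) {
    x <- 0:td$nTrials
    pu <- dbetabinom(x, td$undisturbed)
    pm <- if (td$psiD > 0)
        (1 - td$psiD) * pu + td$psiD * dbetabinom(x, td$disturbed)
    else pu
    if (log) base::log(pm) else pm
}

#' Sample counts from a transition distribution
#'
#' @param td a transition distribution from [transitionDistribution()].
#' @param n number of draws.
#' @return integer counts.
#' @export
sampleTransition <- function(td, n = 1L) {
    disturbed <- if (td$psiD > 0) stats::runif(n) < td$psiD else rep(FALSE, n)
    out <- integer(n)
    if (any(!disturbed))
        out[!disturbed] <- rbetabinom(sum(!disturbed), td$undisturbed)
    if (any(disturbed))
        out[disturbed] <- rbetabinom(sum(disturbed), td$disturbed)
    out
}

#' @describeIn PopModel-class compact display
#' @param object a \code{PopModel}.
#' @export
setMethod("show", "PopModel", function(object) {
    cat(sprintf("PopModel '%s'\n", object@label))
    cat(sprintf("  mean: %s, order %d, %s\n", object@meanForm, object@order,
                if (object@linear) "linear" else "non-linear"))
    est <- object@params[!object@fixed]
    if (length(est))
        cat("  mean parameters:",
            paste(sprintf("%s = %.4g", names(est), est), collapse = ", "),
            "\n")
    cat(sprintf("  variance: %s", object@variance@mode))
    if (object@variance@mode == "constant")
        cat(sprintf(" (sigma2 = %.4g)", object@variance@sigma2))
    if (object@variance@mode == "dls")
        cat(sprintf(" (x = %.4g, y = %.4g, z = %.4g)",
                    object@variance@x, object@variance@y, object@variance@z))
    cat("\n")
    if (!is.null(object@disturbance))
        cat(sprintf(
            "  disturbance: muD = %.4g, sigma2D = %.4g, j = %.4g, k = %.4g\n",
            object@disturbance@muD, object@disturbance@sigma2D,
            object@disturbance@j, object@disturbance@k))
    cat(sprintf("  free parameters: %d\n", freeParamCount(object)))
})
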