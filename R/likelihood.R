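## Mixture log-likelihood, maximum-likelihood fitting with multistart
## optimization, and AIC-based comparison / model averaging.

.NLL_PENALTY <- 1e7

## ---------------------------------------------------------------------------
## likelihood
## ---------------------------------------------------------------------------

## natural-parameter representation used by the optimizer (avoids S4
## construction in the inner loop):
##   list(meanForm, order, params (full named mean vector), varMode,
##        sigma2 | x,y,z, mix = NULL | list(aD, bD, j, k))
.naturalFromModel <- function(model) {
    nat <- list(meanForm = model@meanForm, order = model@order,
                params = model@params, varMode = model@variance@mode,
                sigma2 = model@variance@sigma2, x = model@variance@x,
                y = model@variance@y, z = model@variance@z, mix = NULL)
    if (!is.null(model@disturbance)) {
        d <- model@disturbance
        phi <- d@muD * (1 - d@muD) / d@sigma2D - 1
        nat$mix <- list(aD = d@muD * phi, bD = (1 - d@muD) * phi,
                        j = d@j, k = d@k)
    }
    nat
}

## vectorized per-row negative log-likelihood; returns +Inf (with a "row"
## attribute) on infeasibility instead of erroring
.nllNatural <- function(df, nat) {
    lagMat <- as.matrix(df[paste0("p", seq_len(nat$order))])
    mu <- if (nat$meanForm == "ricker")
        rickerMean(lagMat, nat$params, nat$order)
    else hassellMean(lagMat, nat$params, nat$order)
    p1 <- lagMat[, 1L]
    if (nat$varMode == "constant") {
        phi <- mu * (1 - mu) / nat$sigma2 - 1
    } else {
        pc <- pmax(p1, .P_FLOOR)
        phi <- pmin(exp(nat$x + nat$y * log(pc) + nat$z * pc), .PHI_MAX)
    }
    bad <- !is.finite(phi) | phi <= 0
    if (any(bad)) {
        out <- Inf
        attr(out, "row") <- which(bad)[1]
        attr(out, "why") <- "non-positive overdispersion (infeasible variance)"
        ## violation magnitude lets the optimizer descend back into the
        ## feasible region instead of stalling on a flat penalty plateau
        attr(out, "viol") <- mean(bad) +
            if (nat$varMode == "constant")
                sum(pmax(nat$sigma2 - mu * (1 - mu), 0)) else 0
        return(out)
    }
    phi <- pmin(pmax(phi, .PHI_MIN), .PHI_MAX)
    lu <- .dbb(df$count, df$nMax, mu * phi, (1 - mu) * phi, log = TRUE)
    if (is.null(nat$mix)) {
        lp <- lu
    } else {
        ld <- .dbb(df$count, df$nMax, nat$mix$aD, nat$mix$bD, log = TRUE)
        psi <- stats::plogis(nat$mix$j + nat$mix$k * p1)
        m <- pmax(lu, ld)
        lp <- m + log((1 - psi) * exp(lu - m) + psi * exp(ld - m))
    }
    if (any(!is.finite(lp)) || any(lp > 1e-6)) {
        badRow <- !is.finite(lp) | lp > 1e-6
        out <- Inf
        attr(out, "row") <- which(badRow)[1]
        attr(out, "why") <- "log-likelihood not finite"
        attr(out, "viol") <- mean(badRow)
        return(out)
    }
    -sum(lp)
}

#' Negative log-likelihood of a model on a transition dataset
#'
#' Sums, over transition rows, the negative log of the mixture likelihood
#' \eqn{(1-\Psi_d)\,L + \Psi_d\,L_d}, where \eqn{L} is the undisturbed
#' beta-binomial likelihood of the observed count and \eqn{L_d} the
#' disturbed one.  Models without a disturbance component use
#' \eqn{\Psi_d \equiv 0}.
#'
#' @param dataset a [LagDataset-class] with \code{maxLag >= order(model)}.
#' @param model a [PopModel-class] with a stochastic variance mode.
#' @return the negative log-likelihood (a single number).
#' @export
negLogLik <- function(dataset, model) {
    stopifnot(is(dataset, "LagDataset"), is(model, "PopModel"))
    if (model@variance@mode == "none")
        stop("a deterministic skeleton has no likelihood")
    if (maxLag(dataset) < model@order)
        stop("dataset holds ", maxLag(dataset), " lags but the model needs ",
             model@order)
    val <- .nllNatural(lagData(dataset), .naturalFromModel(model))
    if (!is.finite(val))
        stop(sprintf("infeasible parameters at row %d (%s): %s",
                     attr(val, "row"),
                     paste0("density ",
                            signif(lagData(dataset)$p1[attr(val, "row")], 4)),
                     attr(val, "why")))
    as.numeric(val)
}

## ---------------------------------------------------------------------------
## parameter transforms
## ---------------------------------------------------------------------------

## table of free coordinates: name, transform, optimizer bounds and
## multistart ranges, all on the unconstrained (theta) scale
.paramTable <- function(model) {
    rows <- list()
    add <- function(name, trans, lo, hi, slo, shi)
        rows[[length(rows) + 1L]] <<- data.frame(
            name = name, trans = trans, lo = lo, hi = hi,
            slo = slo, shi = shi, stringsAsFactors = FALSE)
    for (nm in names(model@params)[!model@fixed]) {
        if (nm == "I") add("I", "logit", -13, 13, stats::qlogis(0.02),
                           stats::qlogis(0.6))
        else if (nm == "r") add("r", "identity", -10, 10, -1, 1.5)
        else if (grepl("^alpha", nm)) add(nm, "identity", -20, 20, -2, 0.5)
        else if (grepl("^beta", nm)) add(nm, "identity", -20, 20, -0.5, 0.5)
        else if (grepl("^c", nm)) add(nm, "log", log(1e-3), log(200),
                                      log(0.5), log(60))
        else if (grepl("^d", nm)) add(nm, "log", log(1e-8), log(1e3),
                                      log(0.01), log(10))
        else if (nm == "h") add("h", "log", log(1e-3), log(50),
                                log(0.2), log(5))
        else stop("no transform for parameter ", nm)
    }
    if (model@variance@mode == "constant")
        add("sigma2", "log", log(1e-8), log(0.25), log(0.003), log(0.15))
    if (model@variance@mode == "dls") {
        add("x", "identity", -30, 30, -6, 1)
        add("y", "identity", -30, 30, -5, 2)
        add("z", "identity", -60, 60, 0, 20)
    }
    if (!is.null(model@disturbance)) {
        add("aD", "log", -7, 7, log(0.3), log(4))       # theta = log(aD)
        add("bD", "log1shift", -16, 8, -7, 1)           # theta = log(bD - 1)
        add("j", "identity", -20, 12, -6, 0)
        add("k", "identity", -20, 20, -1, 5)
    }
    do.call(rbind, rows)
}

.thetaToValue <- function(theta, trans) {
    switch(trans,
        identity = theta,
        log = exp(theta),
        log1shift = 1 + exp(theta),
        logit = stats::plogis(theta))
}

.valueToTheta <- function(value, trans) {
    switch(trans,
        identity = value,
        log = log(value),
        log1shift = log(value - 1),
        logit = stats::qlogis(value))
}

.thetaToNatural <- function(theta, pt, nat0) {
    nat <- nat0
    mixPars <- list()
    for (i in seq_len(nrow(pt))) {
        nm <- pt$name[i]
        v <- .thetaToValue(theta[i], pt$trans[i])
        if (nm %in% names(nat$params)) nat$params[[nm]] <- v
        else if (nm %in% c("sigma2", "x", "y", "z")) nat[[nm]] <- v
        else mixPars[[nm]] <- v
    }
    if (!is.null(nat$mix)) nat$mix[names(mixPars)] <- mixPars
    nat
}

.naturalToTheta <- function(nat, pt) {
    vapply(seq_len(nrow(pt)), function(i) {
        nm <- pt$name[i]
        v <- if (nm %in% names(nat$params)) nat$params[[nm]]
        else if (nm %in% c("sigma2", "x", "y", "z")) nat[[nm]]
        else nat$mix[[nm]]
        th <- .valueToTheta(v, pt$trans[i])
        min(max(th, pt$lo[i] + 1e-9), pt$hi[i] - 1e-9)
    }, numeric(1))
}

## rebuild a PopModel from a fitted natural representation
.modelFromNatural <- function(model, nat) {
    model@params <- nat$params
    model@variance <- if (nat$varMode == "constant")
        varianceModel("constant", sigma2 = nat$sigma2)
    else if (nat$varMode == "dls")
        varianceModel("dls", x = nat$x, y = nat$y, z = nat$z)
    else model@variance
    if (!is.null(nat$mix)) {
        aD <- nat$mix$aD; bD <- nat$mix$bD
        muD <- aD / (aD + bD)
        s2D <- muD * (1 - muD) / (aD + bD + 1)
        model@disturbance <- disturbanceModel(muD, s2D, nat$mix$j, nat$mix$k)
    }
    model
}

## ---------------------------------------------------------------------------
## fitting
## ---------------------------------------------------------------------------

#' Fit a population model by maximum likelihood
#'
#' Minimizes the mixture negative log-likelihood by bounded quasi-Newton
#' (L-BFGS-B) optimization on transformed parameters (logit for
#' proportions, log for positive quantities), launched from a seeded
#' Latin-hypercube set of scattered starting points: the mixture surface
#' is multimodal, so a single local search is not trusted.  The model's
#' own current parameters are always included as one additional start, so
#' re-fitting from a previous optimum is idempotent.
#'
#' @param dataset a [LagDataset-class].
#' @param model a [PopModel-class] defining the structure to fit; its
#'   current parameter values serve as one starting point.
#' @param nStarts number of scattered multistarts (in addition to the
#'   model's own parameters).
#' @param seed integer seed making the multistart set reproducible.
#' @param start optional extra starting point: a [PopModel-class] or
#'   [PopFit-class] (typically a previous optimum).
#' @param control passed to [stats::optim()].
#' @return a [PopFit-class].
#' @examples
#' preset <- dlsPreset("constant_table1")
#' study <- generateStudy(model = preset$model, seed = 1)
#' fit <- fitML(buildLagDataset(study, 1), preset$model, nStarts = 4, seed = 1)
#' @export
fitML <- function(dataset, model, nStarts = 20L, seed = NULL, start = NULL,
                  control = list(maxit = 400)) {
    stopifnot(is(dataset, "LagDataset"), is(model, "PopModel"))
    df <- lagData(dataset)
    pt <- .paramTable(model)
    nat0 <- .naturalFromModel(model)
    k <- freeParamCount(model)
    if (nrow(df) < 3L * k)
        warning(sprintf(
            "only %d transitions for %d free parameters; estimates may be poorly identified",
            nrow(df), k))
    obj <- function(theta) {
        v <- .nllNatural(df, .thetaToNatural(theta, pt, nat0))
        if (!is.finite(v)) {
            viol <- attr(v, "viol")
            if (is.null(viol) || !is.finite(viol)) viol <- 1
            .NLL_PENALTY * (1 + viol)
        } else as.numeric(v)
    }
    if (!is.null(seed)) set.seed(seed)
    starts <- list(.naturalToTheta(nat0, pt))
    ## a conservative start that is feasible on any dataset: a gently
    ## stabilizing mean map, with the constant variance placed safely
    ## inside the tightest per-row feasibility bound
    natSafe <- nat0
    natSafe$params[] <- 0
    natSafe$params[grepl("^c[0-9]$", names(natSafe$params))] <- 1
    natSafe$params[["I"]] <- 0.1
    natSafe$params[["r"]] <- 0.1
    if (nat0$meanForm == "ricker") {
        natSafe$params[["alpha1"]] <- -0.2
    } else {
        natSafe$params[["d1"]] <- 0.5
        natSafe$params[["h"]] <- 1
    }
    if (nat0$varMode == "constant") {
        lagMat <- as.matrix(df[paste0("p", seq_len(nat0$order))])
        muSafe <- if (nat0$meanForm == "ricker")
            rickerMean(lagMat, natSafe$params, nat0$order)
        else hassellMean(lagMat, natSafe$params, nat0$order)
        natSafe$sigma2 <- max(0.5 * min(muSafe * (1 - muSafe)), 2e-8)
    } else {
        natSafe$x <- 1; natSafe$y <- 0; natSafe$z <- 2
    }
    if (!is.null(natSafe$mix))
        natSafe$mix <- list(aD = 1.2, bD = 2, j = -3, k = 2)
    starts[[length(starts) + 1L]] <- .naturalToTheta(natSafe, pt)
    if (nStarts > 0L) {
        u <- lhs::randomLHS(as.integer(nStarts), nrow(pt))
        for (i in seq_len(nrow(u)))
            starts[[length(starts) + 1L]] <-
                pt$slo + u[i, ] * (pt$shi - pt$slo)
    }
    if (!is.null(start)) {
        sm <- if (is(start, "PopFit")) start@model else start
        starts[[length(starts) + 1L]] <-
            .naturalToTheta(.naturalFromModel(sm), pt)
    }
    best <- NULL
    conv <- integer(0)
    for (th0 in starts) {
        o <- tryCatch(
            stats::optim(th0, obj, method = "L-BFGS-B",
                         lower = pt$lo, upper = pt$hi, control = control),
            error = function(e) NULL)
        if (is.null(o)) next
        conv <- c(conv, o$convergence)
        if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best) || best$value >= .NLL_PENALTY)
        stop("all optimization starts failed or were infeasible (",
             length(starts), " starts; convergence codes: ",
             paste(conv, collapse = ","), ")")
    ## polish the incumbent: a simplex pass escapes the flat spots that
    ## box-constrained quasi-Newton steps can wedge against, then a final
    ## quasi-Newton pass tightens the optimum
    nm <- tryCatch(
        stats::optim(best$par, obj, method = "Nelder-Mead",
                     control = list(maxit = 500)),
        error = function(e) NULL)
    if (!is.null(nm) && nm$value < best$value) {
        nm$par <- pmin(pmax(nm$par, pt$lo), pt$hi)
        best <- nm
    }
    o <- tryCatch(
        stats::optim(best$par, obj, method = "L-BFGS-B",
                     lower = pt$lo, upper = pt$hi, control = control),
        error = function(e) NULL)
    if (!is.null(o) && o$value < best$value) best <- o
    natHat <- .thetaToNatural(best$par, pt, nat0)
    fitted <- .modelFromNatural(model, natHat)
    est <- fitted@params
    if (fitted@variance@mode == "constant")
        est <- c(est, sigma2 = fitted@variance@sigma2)
    if (fitted@variance@mode == "dls")
        est <- c(est, x = fitted@variance@x, y = fitted@variance@y,
                 z = fitted@variance@z)
    if (!is.null(fitted@disturbance))
        est <- c(est, muD = fitted@disturbance@muD,
                 sigma2D = fitted@disturbance@sigma2D,
                 j = fitted@disturbance@j, k = fitted@disturbance@k)
    new("PopFit", model = fitted, estimates = est,
        negLogLik = best$value, k = k, aic = aic(best$value, k),
        fingerprint = datasetFingerprint(dataset),
        nStarts = length(starts), convergence = conv, label = model@label)
}

#' Akaike information criterion
#'
#' @param negLogLik minimized negative log-likelihood.
#' @param k number of estimated (free) parameters.
#' @return \code{2k + 2*negLogLik}.
#' @examples
#' aic(1043.25, 4)
#' @export
aic <- function(negLogLik, k) {
    stopifnot(all(k >= 0))
    2 * k + 2 * negLogLik
}

## ---------------------------------------------------------------------------
## comparison and averaging
## ---------------------------------------------------------------------------

#' Akaike weights and evidence ratios from AIC values
#'
#' @param aic numeric AIC values.
#' @param k optional free-parameter counts, used to break ties in the
#'   minimum (smaller k preferred, then position).
#' @param labels optional model labels.
#' @return data.frame with columns \code{label}, \code{AIC}, \code{dAIC}
#'   (difference from the minimum), \code{weight} (normalized
#'   \eqn{e^{-\Delta/2}}) and \code{ER} (evidence ratio, best weight over
#'   each weight).
#' @examples
#' aicTable(c(2110.92, 2097.49, 2094.49))
#' @export
aicTable <- function(aic, k = NULL, labels = NULL) {
    n <- length(aic)
    if (is.null(labels)) labels <- sprintf("model%d", seq_len(n))
    if (is.null(k)) k <- rep(NA_integer_, n)
    ord <- order(aic, k, labels)
    best <- ord[1]
    d <- aic - aic[best]
    w <- exp(-d / 2)
    w <- w / sum(w)
    data.frame(label = labels, AIC = aic, dAIC = d, weight = w,
               ER = w[best] / w, stringsAsFactors = FALSE)
}

#' Compare fitted models by AIC
#'
#' Computes \eqn{\Delta}AIC, Akaike weights and evidence ratios across a
#' set of fits of the \emph{same} dataset (enforced via the dataset
#' fingerprint), and flags each model as supported when its
#' \eqn{\Delta}AIC is below 6 \emph{and} no simpler model nested within it
#' achieves a lower AIC (the nested-simpler-model veto).  Ties in the
#' minimum AIC are broken by smaller \code{k}, then label order.
#'
#' @param fits a list of [PopFit-class] objects (or several fits passed
#'   individually).
#' @param nesting optional named list declaring, for each model label, the
#'   labels of strictly simpler models nested within it (e.g. the linear
#'   variant inside the non-linear one).
#' @param deltaMax support threshold on \eqn{\Delta}AIC (default 6).
#' @return data.frame with one row per model: \code{label}, \code{k},
#'   \code{negLogLik}, \code{AIC}, \code{dAIC}, \code{weight}, \code{ER},
#'   \code{supported}; the dataset fingerprint is attached as an
#'   attribute.
#' @export
compareModels <- function(fits, nesting = NULL, deltaMax = 6) {
    if (is(fits, "PopFit")) fits <- list(fits)
    stopifnot(length(fits) >= 1L, all(vapply(fits, is, TRUE, "PopFit")))
    fp <- unique(vapply(fits, function(f) f@fingerprint, character(1)))
    if (length(fp) != 1L)
        stop("fits were obtained on different datasets (fingerprints: ",
             paste(fp, collapse = " vs "), ")")
    labels <- vapply(fits, function(f) f@label, character(1))
    if (anyDuplicated(labels))
        stop("model labels must be unique for comparison")
    kk <- vapply(fits, function(f) f@k, integer(1))
    nll <- vapply(fits, function(f) f@negLogLik, numeric(1))
    tab <- aicTable(vapply(fits, function(f) f@aic, numeric(1)),
                    k = kk, labels = labels)
    supported <- tab$dAIC < deltaMax
    if (!is.null(nesting)) {
        for (i in seq_along(labels)) {
            simpler <- intersect(nesting[[labels[i]]], labels)
            if (length(simpler) &&
                any(tab$AIC[match(simpler, labels)] < tab$AIC[i]))
                supported[i] <- FALSE
        }
    }
    out <- data.frame(label = labels, k = kk, negLogLik = nll,
                      AIC = tab$AIC, dAIC = tab$dAIC, weight = tab$weight,
                      ER = tab$ER, supported = supported,
                      stringsAsFactors = FALSE)
    attr(out, "fingerprint") <- fp
    out
}

#' Model-averaged parameter estimates
#'
#' Averages each parameter across fits using Akaike weights, with
#' fixed-a-priori parameters contributing their fixed values.  A parameter
#' absent from a model's universe (e.g. the DLS terms of a
#' constant-variance fit) is averaged over the models that define it, with
#' weights renormalized within that subset.
#'
#' @param fits a list of [PopFit-class] objects on the same dataset.
#' @param weights optional weights; defaults to the Akaike weights of the
#'   fits.
#' @return named numeric vector of averaged parameters.
#' @export
modelAverage <- function(fits, weights = NULL) {
    if (is(fits, "PopFit")) fits <- list(fits)
    stopifnot(all(vapply(fits, is, TRUE, "PopFit")))
    if (is.null(weights)) {
        cmp <- compareModels(fits)
        weights <- cmp$weight[match(vapply(fits, function(f) f@label,
                                           character(1)), cmp$label)]
    }
    stopifnot(length(weights) == length(fits), all(weights >= 0))
    weights <- weights / sum(weights)
    universe <- unique(unlist(lapply(fits, function(f) names(f@estimates))))
    out <- stats::setNames(numeric(length(universe)), universe)
    for (nm in universe) {
        has <- vapply(fits, function(f) nm %in% names(f@estimates), TRUE)
        w <- weights[has] / sum(weights[has])
        out[[nm]] <- sum(w * vapply(fits[has],
                                    function(f) f@estimates[[nm]],
                                    numeric(1)))
    }
    out
}

#' @describeIn PopFit-class compact display
#' @param object a \code{PopFit}.
#' @export
setMethod("show", "PopFit", function(object) {
    cat(sprintf("PopFit '%s': -LL = %.3f, k = %d, AIC = %.3f\n",
                object@label, object@negLogLik, object@k, object@aic))
    cat("  estimates:\n")
    est <- object@estimates
    fixedNames <- names(object@model@fixed)[object@model@fixed]
    marks <- ifelse(names(est) %in% fixedNames, "*", "")
    cat(paste0("    ", names(est), marks, " = ", signif(est, 5),
               collapse = "\n"), "\n")
    if (length(fixedNames)) cat("  (* fixed a priori)\n")
})
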