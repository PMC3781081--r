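## Independent oracles used across tests.  These deliberately avoid the
## package's own code paths: the pmf oracle integrates the beta mixing
## density numerically, and the likelihood oracle recomputes the mixture
## row by row from scratch.

## beta-binomial pmf by numerical quadrature over the mixing density;
## the integrand has integrable endpoint singularities when a < 1 or
## b < 1, so the tolerance backs off if the tight request fails
quadraturePmf <- function(x, n, a, b) {
    vapply(x, function(xi) {
        f <- function(th) stats::dbinom(xi, n, th) * stats::dbeta(th, a, b)
        for (tol in c(1e-12, 1e-10)) {
            v <- tryCatch(
                stats::integrate(f, 0, 1, rel.tol = tol,
                                 subdivisions = 500L)$value,
                error = function(e) NULL)
            if (!is.null(v)) return(v)
        }
        ## split at the mean to isolate the endpoint singularities
        m <- a / (a + b)
        stats::integrate(f, 0, m, rel.tol = 1e-10,
                         subdivisions = 500L)$value +
            stats::integrate(f, m, 1, rel.tol = 1e-10,
                             subdivisions = 500L)$value
    }, numeric(1))
}

## mixture negative log-likelihood computed row by row with its own pmf
bruteForceNll <- function(df, I, r, alpha1, varMode,
                          sigma2 = NULL, x = NULL, y = NULL, z = NULL,
                          mix = NULL) {
    pmfOne <- function(cnt, n, a, b)
        exp(lgamma(n + 1) - lgamma(cnt + 1) - lgamma(n - cnt + 1) +
            lbeta(cnt + a, n - cnt + b) - lbeta(a, b))
    total <- 0
    for (i in seq_len(nrow(df))) {
        p <- df$p1[i]
        mu <- I * (1 - p) + p * exp(r + alpha1 * p)
        mu <- min(max(mu, 1e-9), 1 - 1e-9)
        phi <- if (varMode == "constant") mu * (1 - mu) / sigma2 - 1
               else exp(x + y * log(max(p, 1e-4)) + z * p)
        lik <- pmfOne(df$count[i], df$nMax[i], mu * phi, (1 - mu) * phi)
        if (!is.null(mix)) {
            phiD <- mix$muD * (1 - mix$muD) / mix$sigma2D - 1
            likD <- pmfOne(df$count[i], df$nMax[i], mix$muD * phiD,
                           (1 - mix$muD) * phiD)
            psi <- 1 / (1 + exp(-(mix$j + mix$k * p)))
            lik <- (1 - psi) * lik + psi * likD
        }
        total <- total - log(lik)
    }
    total
}

## a small study with fully consecutive censuses, built directly
makeTinyStudy <- function(nPlots = 2L, nYears = 10L, nMaxVals = c(484L, 100L),
                          seed = 1L) {
    set.seed(seed)
    nm <- rep_len(nMaxVals, nPlots)
    cnt <- matrix(NA_integer_, nPlots, nYears)
    for (q in seq_len(nPlots)) {
        p <- runif(1, 0.1, 0.4)
        for (t in seq_len(nYears)) {
            cnt[q, t] <- rbinom(1, nm[q], p)
            p <- min(max(p + runif(1, -0.1, 0.15), 0.02), 0.98)
        }
    }
    musselStudy(cnt, years = 2000L + seq_len(nYears) - 1L, nMax = nm)
}
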