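tbl1Linear <- c(I = 0.242, r = 0.122, alpha1 = -0.209, beta1 = 0, c1 = 1)

test_that("Ricker mean map: neutral identity, immigration, fixed point", {
    neutral <- c(I = 0, r = 0, alpha1 = 0, beta1 = 0, c1 = 1)
    for (p in c(0, 0.17, 0.5, 0.93, 1))
        expect_equal(rickerMean(p, neutral, 1L), min(max(p, 1e-9), 1 - 1e-9))

    ## an empty plot is colonized only through immigration
    expect_equal(rickerMean(0, tbl1Linear, 1L), 0.242)

    ## the observed equilibrium cover is a fixed point of the fitted map
    expect_equal(rickerMean(0.829, tbl1Linear, 1L), 0.829, tolerance = 6e-4)

    ## double transcription of the first-order form
    set.seed(3)
    for (p in runif(20)) {
        expected <- 0.242 * (1 - p) + p * exp(0.122 - 0.209 * p)
        expect_equal(rickerMean(p, tbl1Linear, 1L), expected,
                     tolerance = 1e-12)
    }
})

test_that("Ricker mean map handles higher orders and missing lags", {
    full <- c(I = 0.234, r = 0.121,
              alpha1 = -0.116, alpha2 = -0.038, alpha3 = -0.021,
              alpha4 = -0.004,
              beta1 = 0.011, beta2 = 0.005, beta3 = -0.010, beta4 = -0.003,
              c1 = 18.89, c2 = 0.176, c3 = 0.351, c4 = 0.536)
    set.seed(4)
    grid <- matrix(runif(200), ncol = 4)
    mu <- rickerMean(grid, full, 4L)
    expect_true(all(mu >= 0 & mu <= 1))

    expect_error(rickerMean(c(0.4, 0.5), full, 4L), "lagged proportions")
    expect_error(rickerMean(c(0.4, -0.1), full[1:8], 2L), "must lie in")
})

test_that("Hassell mean map: immigration-only and neutral limits", {
    pars <- c(I = 0.242, r = 0.3, d1 = 2, h = 1.5, beta1 = 0.1, c1 = 3)
    expect_equal(hassellMean(0, pars, 1L), 0.242)

    neutral <- c(I = 0, r = 0, d1 = 0, h = 1, beta1 = 0, c1 = 1)
    for (p in c(0.1, 0.4, 0.8))
        expect_equal(hassellMean(p, neutral, 1L), p)

    ## double transcription
    set.seed(5)
    for (p in runif(10)) {
        expected <- 0.242 * (1 - p) +
            p * exp(0.3 + 0.1 * p^3) / (1 + 2 * p)^1.5
        expect_equal(hassellMean(p, pars, 1L), expected, tolerance = 1e-12)
    }

    ## a competition-dominated parameterization has a stable interior
    ## fixed point, like the Ricker skeleton it mirrors
    m <- popModel("hassell", linear = FALSE,
                  params = c(I = 0.2, r = 0.5, d1 = 1.2, h = 2,
                             beta1 = 0, c1 = 1),
                  variance = varianceModel("none"))
    att <- findAttractor(m, 0.1)
    expect_identical(att$type, "fixed-point")
    expect_gt(att$points, 0)
    expect_lt(att$points, 1)
})

test_that("undisturbed variance: constant mode and DLS profile", {
    vc <- varianceModel("constant", sigma2 = 0.037)
    expect_equal(undisturbedVariance(c(0.1, 0.5, 0.9), vc),
                 rep(0.037, 3))

    vd <- varianceModel("dls", x = -2.959, y = -2.023, z = 13.133)
    ## declining undisturbed variance with abundance
    expect_gt(undisturbedVariance(0.1, vd), undisturbedVariance(0.9, vd))

    ## double transcription of the overdispersion form
    for (p in c(0.05, 0.2, 0.5, 0.77, 0.99)) {
        phi <- exp(-2.959 - 2.023 * log(p) + 13.133 * p)
        expect_equal(dlsOverdispersion(p, vd), phi, tolerance = 1e-12)
        expect_equal(undisturbedVariance(p, vd), p * (1 - p) / (phi + 1),
                     tolerance = 1e-12)
    }
    expect_true(all(undisturbedVariance(seq(0.01, 0.99, 0.01), vd) > 0))
})

test_that("infeasible constant variance is reported with the density", {
    vc <- varianceModel("constant", sigma2 = 0.1)
    expect_error(undisturbedVariance(0.99, vc, mu = 0.99), "infeasible")
})

test_that("disturbance probability is a bounded increasing logistic", {
    dm <- disturbanceModel(muD = 0.393, sigma2D = 0.090,
                           j = -3.143, k = 2.225)
    grid <- seq(0, 1, 0.01)
    psi <- disturbanceProbability(grid, dm)
    expect_true(all(psi >= 0 & psi <= 1))
    expect_true(all(diff(psi) > 0))

    ## double transcription
    expect_equal(psi, 1 / (1 + exp(-(-3.143 + 2.225 * grid))),
                 tolerance = 1e-12)

    ## arbitrary (j, k) stay bounded
    set.seed(6)
    for (i in 1:10) {
        dm2 <- disturbanceModel(0.4, 0.05, j = runif(1, -10, 10),
                                k = runif(1, -10, 10))
        psi2 <- disturbanceProbability(grid, dm2)
        expect_true(all(psi2 >= 0 & psi2 <= 1))
    }
})

test_that("a U-shaped disturbed state is rejected", {
    ## mean 0.5 with variance close to the feasible bound gives a, b < 1
    expect_error(disturbanceModel(0.5, 0.2, -3, 2), "U-shaped")
    ## the printed post-disturbance moments are accepted (mode at zero)
    expect_s4_class(disturbanceModel(0.393, 0.090, -3.143, 2.225),
                    "DisturbanceModel")
})

test_that("transition distribution mixes the two components correctly", {
    dls <- dlsPreset("dls_table2")$model

    ## no-disturbance model: mixture equals the undisturbed pmf
    und <- popModel("ricker", params = c(I = 0.053, r = 0.522,
                                         alpha1 = -0.524),
                    variance = dls@variance)
    td0 <- transitionDistribution(und, 0.5, 484L)
    expect_equal(td0$psiD, 0)
    expect_equal(transitionPmf(td0), dbetabinom(0:484, td0$undisturbed))

    ## psi -> 1: mixture equals the disturbed pmf
    m1 <- popModel("ricker", params = c(I = 0.053, r = 0.522,
                                        alpha1 = -0.524),
                   variance = dls@variance,
                   disturbance = disturbanceModel(0.393, 0.090, 60, 0))
    td1 <- transitionDistribution(m1, 0.5, 484L)
    expect_equal(td1$psiD, 1, tolerance = 1e-12)
    expect_equal(transitionPmf(td1), dbetabinom(0:484, td1$disturbed),
                 tolerance = 1e-12)

    ## printed parameters at p = 0.5: pmf sums to 1 on 0..484
    td <- transitionDistribution(dls, 0.5, 484L)
    expect_equal(sum(transitionPmf(td)), 1, tolerance = 1e-10)
    expect_gt(td$psiD, 0)
    expect_lt(td$psiD, 1)
})

test_that("linear variants are exactly nested in non-linear variants", {
    st <- makeTinyStudy(nPlots = 3L, nYears = 12L, seed = 8)
    ld <- buildLagDataset(st, 1L)
    lin <- popModel("ricker", linear = TRUE,
                    params = c(I = 0.2, r = 0.1, alpha1 = -0.3),
                    variance = varianceModel("constant", sigma2 = 0.03))
    nonlin <- popModel("ricker", linear = FALSE,
                       params = c(I = 0.2, r = 0.1, alpha1 = -0.3,
                                  beta1 = 0, c1 = 1),
                       variance = varianceModel("constant", sigma2 = 0.03))
    expect_equal(negLogLik(ld, lin), negLogLik(ld, nonlin))
    ## but the non-linear variant estimates two more parameters
    expect_equal(freeParamCount(nonlin) - freeParamCount(lin), 2L)
})

test_that("the fitted constant-model skeleton has one attracting fixed point", {
    m <- dlsPreset("deterministic_table1")$model
    fps <- vapply(seq(0.05, 0.95, 0.1),
                  function(p0) findAttractor(m, p0)$points, numeric(1))
    expect_lt(diff(range(fps)), 1e-8)
    p <- fps[1]
    ## numeric slope at the fixed point is inside the unit circle
    slope <- (meanMap(m, p + 1e-6) - meanMap(m, p - 1e-6)) / 2e-6
    expect_lt(abs(slope), 1)
})

test_that("free-parameter counts match the model structure", {
    expect_equal(freeParamCount(dlsPreset("constant_table1")$model), 4L)
    expect_equal(freeParamCount(dlsPreset("dls_table2")$model), 10L)
    expect_equal(freeParamCount(
        popModel("ricker", order = 1, linear = FALSE,
                 variance = varianceModel("constant"))), 6L)
    expect_equal(freeParamCount(
        popModel("ricker", order = 4, linear = FALSE,
                 variance = varianceModel("constant"))), 15L)
    expect_equal(freeParamCount(
        popModel("ricker", order = 1, linear = FALSE,
                 variance = varianceModel("dls"),
                 disturbance = disturbanceModel(0.4, 0.05, -3, 2))), 12L)
    ## the full fourth-order DLS mixture model: 14 mean + 3 + 4
    expect_equal(freeParamCount(
        popModel("ricker", order = 4, linear = FALSE,
                 variance = varianceModel("dls"),
                 disturbance = disturbanceModel(0.4, 0.05, -3, 2))), 21L)
})
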