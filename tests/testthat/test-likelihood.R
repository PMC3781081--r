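test_that("mixture likelihood reduces to the plain beta-binomial case", {
    st <- makeTinyStudy(nPlots = 3L, nYears = 9L, seed = 12)
    ld <- buildLagDataset(st, 1L)
    df <- lagData(ld)

    m <- popModel("ricker", params = c(I = 0.2, r = 0.15, alpha1 = -0.3),
                  variance = varianceModel("constant", sigma2 = 0.03))
    ## no-disturbance model equals a row-wise plain beta-binomial -LL
    plain <- sum(vapply(seq_len(nrow(df)), function(i) {
        mu <- rickerMean(df$p1[i], m@params, 1L)
        spec <- bbFromMoments(mu, 0.03, df$nMax[i])
        -dbetabinom(df$count[i], spec, log = TRUE)
    }, numeric(1)))
    expect_equal(negLogLik(ld, m), plain, tolerance = 1e-10)
})

test_that("a single-row dataset gives -log of the mixture pmf", {
    cnt <- matrix(c(100L, 220L), nrow = 1)
    st <- musselStudy(cnt, years = 2001:2002, nMax = 484L)
    ld <- buildLagDataset(st, 1L)
    m <- dlsPreset("dls_table2")$model
    td <- transitionDistribution(m, 100 / 484, 484L)
    expect_equal(negLogLik(ld, m), -log(transitionPmf(td)[220 + 1]),
                 tolerance = 1e-10)
})

test_that("mixture likelihood matches a brute-force oracle on 20 rows", {
    set.seed(33)
    df <- data.frame(plot = "p", year = 2000 + 1:20,
                     count = rbinom(20, 484, runif(20, 0.1, 0.9)),
                     nMax = 484L, p1 = runif(20, 0.02, 0.98))
    ld <- new("LagDataset", data = df, maxLag = 1L, fingerprint = "toy")

    ## constant-variance, no mixture
    m1 <- popModel("ricker", params = c(I = 0.2, r = 0.1, alpha1 = -0.25),
                   variance = varianceModel("constant", sigma2 = 0.04))
    expect_equal(negLogLik(ld, m1),
                 bruteForceNll(df, 0.2, 0.1, -0.25, "constant",
                               sigma2 = 0.04),
                 tolerance = 1e-8)

    ## DLS with disturbance mixture
    m2 <- dlsPreset("dls_table2")$model
    expect_equal(negLogLik(ld, m2),
                 bruteForceNll(df, 0.053, 0.522, -0.524, "dls",
                               x = -2.959, y = -2.023, z = 13.133,
                               mix = list(muD = 0.393, sigma2D = 0.090,
                                          j = -3.143, k = 2.225)),
                 tolerance = 1e-8)
})

test_that("likelihood is invariant to row and plot order", {
    st <- makeTinyStudy(nPlots = 4L, nYears = 10L, seed = 9)
    ld <- buildLagDataset(st, 1L)
    m <- dlsPreset("dls_table2")$model
    ref <- negLogLik(ld, m)

    set.seed(1)
    shuffled <- ld
    shuffled@data <- ld@data[sample(nrow(ld@data)), ]
    expect_equal(negLogLik(shuffled, m), ref, tolerance = 1e-12)

    reordered <- musselStudy(censusCounts(st)[c(3, 1, 4, 2), ],
                             censusYears(st), nMax(st)[c(3, 1, 4, 2)],
                             plotIds(st)[c(3, 1, 4, 2)])
    expect_equal(negLogLik(buildLagDataset(reordered, 1L), m), ref,
                 tolerance = 1e-12)
})

test_that("infeasible parameters are reported, not silently penalized", {
    st <- makeTinyStudy(nPlots = 2L, nYears = 8L, seed = 5)
    ld <- buildLagDataset(st, 1L)
    bad <- popModel("ricker", params = c(I = 0.9, r = 2, alpha1 = 0),
                    variance = varianceModel("constant", sigma2 = 0.2))
    expect_error(negLogLik(ld, bad), "infeasible")
})

test_that("AIC arithmetic and weights behave", {
    expect_equal(aic(0, 0), 0)
    expect_equal(aic(100, 3), 206)

    ## equal AICs share the weight equally; the best has ER = 1
    tab <- aicTable(rep(10, 4))
    expect_equal(tab$weight, rep(0.25, 4))
    expect_equal(tab$ER[1], 1)

    set.seed(2)
    tab2 <- aicTable(runif(6, 100, 140))
    expect_equal(sum(tab2$weight), 1, tolerance = 1e-12)
    expect_equal(min(tab2$dAIC), 0)
    expect_equal(tab2$ER[which.min(tab2$AIC)], 1)
})

test_that("model comparison guards datasets and applies the support rule", {
    st <- makeTinyStudy(nPlots = 3L, nYears = 12L, seed = 14)
    ld <- buildLagDataset(st, 1L)
    lin <- popModel("ricker", linear = TRUE,
                    params = c(I = 0.2, r = 0.1, alpha1 = -0.3),
                    variance = varianceModel("constant", sigma2 = 0.05),
                    label = "linear")
    non <- popModel("ricker", linear = FALSE,
                    params = c(I = 0.2, r = 0.1, alpha1 = -0.3),
                    variance = varianceModel("constant", sigma2 = 0.05),
                    label = "nonlinear")
    fl <- suppressWarnings(fitML(ld, lin, nStarts = 3, seed = 1))
    fn <- suppressWarnings(fitML(ld, non, nStarts = 3, seed = 1,
                                 start = fl))

    cmp <- compareModels(list(fl, fn),
                         nesting = list(nonlinear = "linear"))
    expect_equal(sum(cmp$weight), 1, tolerance = 1e-12)
    expect_equal(cmp$ER[which.min(cmp$AIC)], 1)

    ## nesting monotonicity: the richer model fits at least as well
    expect_lte(fn@negLogLik, fl@negLogLik + 1e-4)

    ## the nested-simpler-model veto: if the simpler model has the lower
    ## AIC, the richer one is unsupported even when dAIC < 6
    if (cmp$AIC[cmp$label == "linear"] < cmp$AIC[cmp$label == "nonlinear"])
        expect_false(cmp$supported[cmp$label == "nonlinear"])

    ## fits on different data refuse to be compared
    other <- buildLagDataset(makeTinyStudy(nPlots = 3L, nYears = 12L,
                                           seed = 99), 1L)
    fo <- suppressWarnings(fitML(other, lin, nStarts = 2, seed = 1))
    expect_error(compareModels(list(fl, fo)), "different datasets")
})

test_that("refitting from a previous optimum is idempotent", {
    st <- makeTinyStudy(nPlots = 3L, nYears = 10L, seed = 18)
    ld <- buildLagDataset(st, 1L)
    m <- popModel("ricker", params = c(I = 0.2, r = 0.1, alpha1 = -0.3),
                  variance = varianceModel("constant", sigma2 = 0.05))
    f1 <- suppressWarnings(fitML(ld, m, nStarts = 4, seed = 3))
    f2 <- suppressWarnings(fitML(ld, f1@model, nStarts = 0, seed = 3))
    expect_lte(f2@negLogLik, f1@negLogLik + 1e-6)
    expect_equal(f2@negLogLik, f1@negLogLik, tolerance = 1e-6)
})

test_that("model averaging weights parameters correctly", {
    st <- makeTinyStudy(nPlots = 2L, nYears = 9L, seed = 25)
    ld <- buildLagDataset(st, 1L)
    m <- popModel("ricker", params = c(I = 0.2, r = 0.1, alpha1 = -0.3),
                  variance = varianceModel("constant", sigma2 = 0.05))
    f <- suppressWarnings(fitML(ld, m, nStarts = 3, seed = 4))

    ## single model: parameters unchanged
    expect_equal(modelAverage(list(f)), f@estimates)

    ## hand-built fits with forced estimates exercise the arithmetic
    mkFit <- function(lbl, I, r, a) {
        g <- f
        g@label <- lbl
        g@estimates[c("I", "r", "alpha1")] <- c(I, r, a)
        g
    }
    fits <- list(mkFit("a", 0.1, 0.2, -0.1), mkFit("b", 0.3, 0.0, -0.5),
                 mkFit("c", 0.2, 0.4, -0.3))
    avg <- modelAverage(fits, weights = c(0.5, 0.3, 0.2))
    expect_equal(avg[["I"]], 0.5 * 0.1 + 0.3 * 0.3 + 0.2 * 0.2)
    expect_equal(avg[["r"]], 0.5 * 0.2 + 0.0 + 0.2 * 0.4)
    expect_equal(avg[["alpha1"]], 0.5 * -0.1 + 0.3 * -0.5 + 0.2 * -0.3)

    ## equal weights give the arithmetic mean
    avg2 <- modelAverage(fits[1:2], weights = c(1, 1))
    expect_equal(avg2[["I"]], 0.2)
})

test_that("constant-variance parameters are recovered at study size", {
    ## 50 replicate studies generated from the printed first-order linear
    ## constant-variance parameters, each refit from scratch
    truth <- dlsPreset("constant_table1")
    blank <- popModel("ricker", order = 1, linear = TRUE,
                      variance = varianceModel("constant"))
    est <- t(vapply(1:50, function(i) {
        st <- generateStudy(truth$design, truth$model, seed = 2000 + i)
        ld <- buildLagDataset(st, 1L)
        f <- suppressWarnings(fitML(ld, blank, nStarts = 8, seed = i))
        c(f@estimates[c("I", "alpha1", "sigma2")],
          mu3 = meanMap(f@model, 0.3), mu6 = meanMap(f@model, 0.6),
          mu83 = meanMap(f@model, 0.829))
    }, numeric(6)))
    med <- apply(est, 2, median)

    expect_lt(abs(med[["I"]] - 0.242) / 0.242, 0.15)
    expect_lt(abs(med[["sigma2"]] - 0.036) / 0.036, 0.20)
    ## the mean map itself is the identifiable object: recovered to ~2%
    tm <- truth$model
    expect_lt(abs(med[["mu3"]] - meanMap(tm, 0.3)) / meanMap(tm, 0.3), 0.02)
    expect_lt(abs(med[["mu6"]] - meanMap(tm, 0.6)) / meanMap(tm, 0.6), 0.02)
    expect_lt(abs(med[["mu83"]] - meanMap(tm, 0.829)) / meanMap(tm, 0.829),
              0.02)
    ## alpha1 rides a likelihood ridge with r at this sample size; only
    ## its sign and broad magnitude are identified
    expect_lt(med[["alpha1"]], -0.05)
    expect_gt(med[["alpha1"]], -0.45)
})

test_that("the fitted disturbance-probability curve brackets the truth", {
    pre <- dlsPreset("dls_table2")
    blank <- popModel("ricker", order = 1, linear = TRUE,
                      variance = varianceModel("dls"),
                      disturbance = disturbanceModel(0.4, 0.05, -3, 2))
    grid <- seq(0.1, 0.9, 0.1)
    psiHat <- vapply(1:12, function(i) {
        st <- generateStudy(pre$design, pre$model, seed = 6000 + i)
        ld <- buildLagDataset(st, 1L)
        f <- suppressWarnings(fitML(ld, blank, nStarts = 6, seed = i))
        disturbanceProbability(grid, f@model@disturbance)
    }, numeric(length(grid)))
    lo <- apply(psiHat, 1, quantile, 0.025)
    hi <- apply(psiHat, 1, quantile, 0.975)
    truthPsi <- disturbanceProbability(grid, pre$model@disturbance)
    expect_true(all(truthPsi >= lo & truthPsi <= hi))
})
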