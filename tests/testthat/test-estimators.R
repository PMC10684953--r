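test_that("the Wald ratio matches the delta-method hand calculation", {
    e <- waldRatio(0.1, 0.01, 0.02, 0.005)
    expect_equal(e@beta, 0.2)
    expect_equal(e@se, 0.05)
    e0 <- waldRatio(0.1, 0.01, 0, 0.005)
    expect_equal(e0@beta, 0)
    expect_equal(e0@pval, 1)
    expect_equal(waldRatio(-0.1, 0.01, 0.02, 0.005)@beta, -0.2)
    expect_error(waldRatio(0, 0.01, 0.02, 0.005), "nonzero")
    # second-order variance adds beta_y^2 se_x^2 / beta_x^4
    e2 <- waldRatio(0.1, 0.01, 0.02, 0.005, secondOrder = TRUE)
    expect_equal(e2@se, sqrt(0.005^2 / 0.01 + 0.02^2 * 0.01^2 / 1e-4))
})

test_that("IVW reproduces the weighted-mean hand calculation and Q inflation", {
    h <- harmonizedFromRatios(c(0.2, 0.4), c(0.0025, 0.01))
    fe <- mrIVW(h, "fixed")
    expect_equal(fe@beta, 0.24)
    expect_equal(fe@se, sqrt(1 / 500), tolerance = 1e-12)  # 0.04472
    expect_equal(round(fe@se, 5), 0.04472)
    mre <- mrIVW(h, "mre")
    # Q = 3.2 on 1 df -> inflation sqrt(3.2)
    expect_equal(mre@se, fe@se * sqrt(3.2), tolerance = 1e-12)
    expect_error(mrIVW(harmonizedFromRatios(0.1, 0.01)), ">= 2")
})

test_that("the two IVW routes (weighted mean, origin regression) agree to 1e-10", {
    set.seed(21)
    for (i in 1:50) {
        k <- sample(3:40, 1)
        bx <- rnorm(k, 0.1, 0.05); bx[abs(bx) < 1e-3] <- 0.05
        sey <- runif(k, 0.005, 0.05)
        by <- 0.3 * bx + rnorm(k, 0, sey)
        h <- makeHarmonized(bx, rep(0.01, k), by, sey)
        # regression-through-origin route, computed independently
        w <- 1 / sey^2
        beta_reg <- sum(w * by * bx) / sum(w * bx^2)
        se_reg <- sqrt(1 / sum(w * bx^2))
        fe <- mrIVW(h, "fixed")
        expect_equal(fe@beta, beta_reg, tolerance = 1e-10)
        expect_equal(fe@se, se_reg, tolerance = 1e-10)
    }
})

test_that("Egger recovers a perfect linear fit exactly and proportional data give zero intercept", {
    h <- makeHarmonized(bx = c(1, 2, 3), sex = rep(0.01, 3),
                        by = c(0.3, 0.5, 0.7), sey = rep(1, 3))
    eg <- mrEgger(h)
    expect_equal(eg$slope@beta, 0.2, tolerance = 1e-12)
    expect_equal(eg$intercept@beta, 0.1, tolerance = 1e-12)
    h2 <- makeHarmonized(bx = c(0.5, 1, 2, 4), sex = rep(0.01, 4),
                         by = 0.37 * c(0.5, 1, 2, 4), sey = rep(0.02, 4))
    eg2 <- mrEgger(h2)
    expect_equal(eg2$slope@beta, 0.37, tolerance = 1e-10)
    expect_equal(eg2$intercept@beta, 0, tolerance = 1e-10)
    # rows with negative exposure effects are re-oriented first
    h3 <- makeHarmonized(bx = c(-1, 2, 3), sex = rep(0.01, 3),
                         by = c(-0.3, 0.5, 0.7), sey = rep(1, 3))
    eg3 <- mrEgger(h3)
    expect_equal(eg3$slope@beta, 0.2, tolerance = 1e-12)
    expect_error(mrEgger(harmonizedFromRatios(c(0.1, 0.2), c(1, 1))),
                 ">= 3")
})

test_that("the weighted median interpolates standardized cumulative weights", {
    expect_equal(mrWeightedMedian(
        harmonizedFromRatios(c(0.1, 0.2, 0.3), c(1, 1, 1)))@beta, 0.2)
    # hand-interpolated instance: s = {0.0833, 0.25, 0.6667} -> 0.26
    h <- harmonizedFromRatios(c(0.1, 0.2, 0.3), c(1, 1, 0.25))
    expect_equal(mrWeightedMedian(h)@beta, 0.26, tolerance = 1e-12)
    # bootstrap se is deterministic under a fixed seed
    e1 <- mrWeightedMedian(h, nBoot = 50, seed = 9)
    e2 <- mrWeightedMedian(h, nBoot = 50, seed = 9)
    expect_identical(e1@se, e2@se)
})

test_that("mode estimators sit at the dominant ratio cluster, not the mean", {
    h <- harmonizedFromRatios(rep(0.2, 3), rep(1, 3))
    expect_equal(mrMode(h, "simple", nBoot = 20)@beta, 0.2)
    h2 <- harmonizedFromRatios(c(0.2, 0.2, 0.2, 0.9), rep(1, 4))
    m <- mrMode(h2, "simple", nBoot = 20)@beta
    expect_lt(abs(m - 0.2), abs(m - 0.375))
    # weighting down the outlier pulls the weighted mode closer to 0.2
    h3 <- harmonizedFromRatios(c(0.2, 0.25, 0.15, 0.9),
                               c(0.01, 0.01, 0.01, 1))
    mw <- mrMode(h3, "weighted", nBoot = 20)@beta
    ms <- mrMode(h3, "simple", nBoot = 20)@beta
    expect_lte(abs(mw - 0.2), abs(ms - 0.2))
})

test_that("every estimator returns c on degenerate all-equal-ratio input", {
    h <- harmonizedFromRatios(rep(0.31, 5), rep(0.01, 5))
    expect_equal(mrIVW(h, "fixed")@beta, 0.31)
    expect_equal(mrIVW(h, "mre")@beta, 0.31)
    expect_equal(mrIVW(h, "fixed")@se, mrIVW(h, "mre")@se)  # Q = 0
    expect_equal(mrWeightedMedian(h, nBoot = 20)@beta, 0.31)
    expect_equal(mrMode(h, "weighted", nBoot = 20)@beta, 0.31)
    expect_equal(mrMode(h, "simple", nBoot = 20)@beta, 0.31)
    # Egger needs spread in bx; proportional construction gives slope c
    hp <- makeHarmonized(bx = c(1, 2, 3, 4), sex = rep(0.01, 4),
                         by = 0.31 * c(1, 2, 3, 4), sey = rep(0.01, 4))
    expect_equal(mrEgger(hp)$slope@beta, 0.31, tolerance = 1e-10)
})

test_that("estimates are scale-equivariant in the outcome", {
    set.seed(31)
    k <- 12
    bx <- rnorm(k, 0.1, 0.03)
    sey <- runif(k, 0.01, 0.03)
    by <- 0.25 * bx + rnorm(k, 0, sey)
    lambda <- 3.7
    h1 <- makeHarmonized(bx, rep(0.01, k), by, sey)
    h2 <- makeHarmonized(bx, rep(0.01, k), lambda * by, lambda * sey)
    for (model in c("fixed", "mre")) {
        expect_equal(mrIVW(h2, model)@beta, lambda * mrIVW(h1, model)@beta,
                     tolerance = 1e-10)
        expect_equal(mrIVW(h2, model)@se, lambda * mrIVW(h1, model)@se,
                     tolerance = 1e-10)
    }
    expect_equal(mrEgger(h2)$slope@beta, lambda * mrEgger(h1)$slope@beta,
                 tolerance = 1e-10)
    expect_equal(mrWeightedMedian(h2, nBoot = 30, seed = 2)@beta,
                 lambda * mrWeightedMedian(h1, nBoot = 30, seed = 2)@beta,
                 tolerance = 1e-10)
})

test_that("fixed-effect IVW standard error never exceeds the multiplicative one", {
    set.seed(41)
    for (i in 1:20) {
        k <- sample(3:30, 1)
        h <- harmonizedFromRatios(rnorm(k, 0.2, 0.3),
                                  runif(k, 1e-4, 1e-2))
        expect_lte(mrIVW(h, "fixed")@se, mrIVW(h, "mre")@se)
    }
})

test_that("mrAllEstimates picks the method set from the instrument count", {
    d1 <- harmonizedFromRatios(0.2, 0.01)
    expect_named(mrAllEstimates(d1), "wald_ratio")
    d2 <- harmonizedFromRatios(c(0.2, 0.3), c(0.01, 0.01))
    expect_named(mrAllEstimates(d2), c("ivw_fe", "ivw_mre"))
    d5 <- makeHarmonized(bx = seq(0.05, 0.25, 0.05), sex = rep(0.01, 5),
                         by = seq(0.01, 0.05, 0.01), sey = rep(0.01, 5))
    expect_named(mrAllEstimates(d5, nBoot = 10),
                 c("ivw_fe", "ivw_mre", "egger_slope", "egger_intercept",
                   "weighted_median", "weighted_mode", "simple_mode"))
})
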