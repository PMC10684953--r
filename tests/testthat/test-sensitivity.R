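test_that("Cochran's Q and I-squared match the hand calculation", {
    h <- harmonizedFromRatios(c(0.2, 0.4), c(0.0025, 0.01))
    q <- cochranQ(h)
    expect_equal(q$q_stat, 3.2, tolerance = 1e-12)
    expect_equal(q$q_df, 1)
    expect_equal(q$i2, 68.75, tolerance = 1e-10)
    expect_equal(q$q_pval, pchisq(3.2, 1, lower.tail = FALSE))
    # identical ratios: no heterogeneity
    q0 <- cochranQ(harmonizedFromRatios(rep(0.3, 4), rep(0.01, 4)))
    expect_equal(q0$q_stat, 0)
    expect_equal(q0$i2, 0)
    expect_error(cochranQ(harmonizedFromRatios(0.1, 1)), ">= 2")
})

test_that("Q averages its degrees of freedom under homogeneity and I2 stays in [0,100]", {
    set.seed(51)
    k <- 10
    qs <- replicate(300, {
        sey <- runif(k, 0.01, 0.05)
        h <- makeHarmonized(bx = rep(1, k), sex = rep(1e-6, k),
                            by = 0.2 + rnorm(k, 0, sey), sey = sey)
        q <- cochranQ(h)
        expect_gte(q$i2, 0); expect_lte(q$i2, 100)
        if (q$q_stat <= q$q_df) expect_equal(q$i2, 0)
        q$q_stat
    })
    expect_equal(mean(qs), k - 1, tolerance = 0.1)
})

test_that("MR-PRESSO flags a planted outlier and corrects toward the truth", {
    set.seed(61)
    k <- 20
    sey <- rep(0.02, k)
    bx <- runif(k, 0.05, 0.2)
    by <- 0.2 * bx + rnorm(k, 0, sey)
    by[7] <- 0.2 * bx[7] + 5 * sey[7] + rnorm(1, 0, sey[7] / 10)
    h <- makeHarmonized(bx, rep(0.005, k), by, sey)
    pr <- mrPresso(h, nSim = 500, seed = 3)
    expect_s4_class(pr, "PressoReport")
    expect_true(pr@outlierFlags[["rs7"]])
    raw <- pr@rawEstimate@beta
    corr <- pr@correctedEstimate@beta
    expect_lt(abs(corr - 0.2), abs(raw - 0.2))
    expect_false(is.na(pr@distortionPval))
    expect_error(mrPresso(harmonizedFromRatios(c(1, 2, 3), rep(1, 3))),
                 ">= 4")
})

test_that("MR-PRESSO leaves clean data uncorrected and is seed-deterministic", {
    set.seed(62)
    k <- 15
    sey <- runif(k, 0.01, 0.03)
    bx <- runif(k, 0.08, 0.2)
    by <- 0.15 * bx + rnorm(k, 0, sey)
    h <- makeHarmonized(bx, rep(0.005, k), by, sey)
    p1 <- mrPresso(h, nSim = 400, seed = 11)
    p2 <- mrPresso(h, nSim = 400, seed = 11)
    expect_identical(p1@globalPval, p2@globalPval)
    expect_identical(p1@outlierPvals, p2@outlierPvals)
    if (!any(p1@outlierFlags)) {
        expect_true(is.na(p1@distortionPval))
        expect_true(is.na(p1@correctedEstimate@beta))
    }
})

test_that("leave-one-out produces k+1 rows and isolates an influential SNP", {
    h <- harmonizedFromRatios(rep(0.25, 5), rep(0.01, 5))
    tab <- leaveOneOut(h)
    expect_equal(nrow(tab), 6)
    expect_equal(tab$snp_id[6], "ALL")
    expect_true(all(abs(tab$beta - 0.25) < 1e-12))
    # one outlying ratio: its omission row is the most extreme
    h2 <- harmonizedFromRatios(c(0.2, 0.21, 0.19, 0.8), rep(0.01, 4))
    tab2 <- leaveOneOut(h2)
    body <- tab2[tab2$snp_id != "ALL", ]
    expect_equal(body$snp_id[which.min(body$beta)], "rs4")
})

test_that("the Steiger test keeps exposure-dominant SNPs and calls the direction", {
    # r2_x = 0.01 vs r2_y = 0.001 via explicit frequencies and betas
    h <- makeHarmonized(bx = 0.1414214, sex = 0.01, by = 0.04472136,
                        sey = 0.01, eafx = 0.5, eafy = 0.5,
                        nExposure = 1e5, nOutcome = 1e5)
    st <- steigerTest(h)
    expect_true(all(st$keep))
    expect_equal(st$direction, "exposure_to_outcome")
    expect_equal(unname(st$r2_exposure), 0.01, tolerance = 1e-6)
    expect_equal(unname(st$r2_outcome), 0.001, tolerance = 1e-6)
    # equality is not kept (strict inequality) and the direction is undetermined
    h2 <- makeHarmonized(bx = 0.1, sex = 0.01, by = 0.1, sey = 0.01,
                         eafx = 0.3, eafy = 0.3)
    st2 <- steigerTest(h2)
    expect_false(any(st2$keep))
    expect_equal(st2$direction, "undetermined")
    expect_equal(st2$steiger_pval, 1)
    # inflating outcome r2 can only shrink the keep set
    base_keep <- sum(steigerTest(makeHarmonized(
        bx = c(0.1, 0.12), sex = 0.01, by = c(0.01, 0.02), sey = 0.01,
        eafx = 0.3, eafy = 0.3))$keep)
    infl_keep <- sum(steigerTest(makeHarmonized(
        bx = c(0.1, 0.12), sex = 0.01, by = c(0.09, 0.13), sey = 0.01,
        eafx = 0.3, eafy = 0.3))$keep)
    expect_lte(infl_keep, base_keep)
})

test_that("binary outcomes use the observed-scale K(1-K) adjustment", {
    h <- makeHarmonized(bx = 0.1, sex = 0.01, by = 0.1, sey = 0.01,
                        eafx = 0.3, eafy = 0.3, binary = TRUE, K = 0.1)
    st <- steigerTest(h)
    # r2_y shrinks by K(1-K) = 0.09, so the SNP is kept
    expect_true(all(st$keep))
    expect_equal(unname(st$r2_outcome / st$r2_exposure), 0.09,
                 tolerance = 1e-10)
})

test_that("the funnel table pairs each ratio with its precision", {
    h <- makeHarmonized(bx = c(0.1, 0.2), sex = 0.01, by = c(0.02, 0.05),
                        sey = c(0.01, 0.02))
    f <- funnelTable(h)
    expect_equal(nrow(f), 2)
    expect_equal(f$ratio, c(0.2, 0.25))
    expect_equal(f$precision, c(0.1 / 0.01, 0.2 / 0.02))
})

test_that("the sensitivity suite degrades gracefully with few instruments", {
    s1 <- sensitivitySuite(makeHarmonized(0.1, 0.01, 0.02, 0.01,
                                          eafx = 0.3, eafy = 0.3))
    expect_null(s1$q); expect_null(s1$presso); expect_null(s1$loo)
    expect_false(is.null(s1$steiger))
    s4 <- sensitivitySuite(makeHarmonized(
        bx = c(0.1, 0.12, 0.15, 0.2), sex = 0.01,
        by = c(0.02, 0.02, 0.03, 0.04), sey = 0.01,
        eafx = 0.3, eafy = 0.3), nSim = 100)
    expect_false(is.null(s4$presso))
    expect_equal(nrow(s4$loo), 5)
})
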