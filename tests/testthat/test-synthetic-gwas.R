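test_that("the LD reference has block-diagonal structure with exact LD scores", {
    # independent variants: every LD score is 1
    ld1 <- simulateLDReference(nBlock = 5, blockSize = 1, seed = 1)
    expect_true(all(variants(ld1)$ld_score == 1))
    expect_equal(nrow(ld1@r2pairs), 0)
    # constant within-block r2 = 0.5, block size 3: score = 1 + 2 * 0.5 = 2
    ld2 <- simulateLDReference(nBlock = 2, blockSize = 3,
                               withinBlockR2 = 0.5, decay = 1, seed = 2)
    expect_true(all(variants(ld2)$ld_score == 2))
    v <- variants(ld2)$snp_id
    # symmetry with unit diagonal and zero across blocks
    expect_equal(ldR2(ld2, v[1], v[2]), ldR2(ld2, v[2], v[1]))
    expect_equal(ldR2(ld2, v[1], v[1]), 1)
    expect_equal(ldR2(ld2, v[1], v[4]), 0)
    expect_equal(ldR2(ld2, v[1], v[3]), 0.5)
    # geometric decay halves the next-neighbour correlation
    ld3 <- simulateLDReference(nBlock = 1, blockSize = 3,
                               withinBlockR2 = 0.4, decay = 0.5, seed = 3)
    w <- variants(ld3)$snp_id
    expect_equal(ldR2(ld3, w[1], w[2]), 0.4)
    expect_equal(ldR2(ld3, w[1], w[3]), 0.2)
    # unknown variants yield NA
    expect_true(is.na(ldR2(ld3, w[1], "rsUNKNOWN")))
})

test_that("LD reference round-trips through its delimited files", {
    ld <- simulateLDReference(nBlock = 3, blockSize = 2,
                              withinBlockR2 = 0.3, seed = 4)
    ip <- tempfile(fileext = ".tsv"); pp <- tempfile(fileext = ".tsv")
    writeLDReference(ld, ip, pp)
    back <- readLDReference(ip, pp)
    expect_equal(variants(back)$ld_score, variants(ld)$ld_score,
                 tolerance = 1e-12)
    expect_equal(back@r2pairs$r2, ld@r2pairs$r2, tolerance = 1e-12)
})

test_that("generators are pure functions of config and seed", {
    cfg <- mrSimConfig(nSnp = 30, seed = 99)
    s1 <- simulateMRSumstats(cfg)
    s2 <- simulateMRSumstats(cfg)
    expect_identical(variants(s1$exposure), variants(s2$exposure))
    expect_identical(variants(s1$outcome), variants(s2$outcome))
    expect_identical(s1$truth, s2$truth)
    s3 <- simulateMRSumstats(mrSimConfig(nSnp = 30, seed = 100))
    expect_false(identical(variants(s3$exposure)$beta,
                           variants(s1$exposure)$beta))
    l1 <- simulateLDSCZscores(ldscSimConfig(mVariants = 500, seed = 5))
    l2 <- simulateLDSCZscores(ldscSimConfig(mVariants = 500, seed = 5))
    expect_identical(l1, l2)
})

test_that("simulated instruments explain the configured exposure variance", {
    for (s in 1:5) {
        cfg <- mrSimConfig(nSnp = 60, exposureR2Total = 0.08, seed = s)
        sim <- simulateMRSumstats(cfg)
        v <- variants(sim$exposure)
        maf <- pmin(v$eaf, 1 - v$eaf)
        # truth exactly matches by construction
        expect_equal(sum(2 * sim$truth$maf * (1 - sim$truth$maf) *
                         sim$truth$gamma^2), 0.08, tolerance = 1e-12)
        # observed effects match within 10% relative error
        emp <- sum(2 * maf * (1 - maf) * v$beta^2)
        expect_lt(abs(emp - 0.08) / 0.08, 0.10)
    }
})

test_that("invalid-instrument flags and pleiotropy modes follow the config", {
    cfg <- mrSimConfig(nSnp = 50, propInvalid = 0.4,
                       pleiotropyMode = "directional",
                       pleiotropyMean = 0.05, pleiotropySd = 0.01,
                       seed = 6)
    sim <- simulateMRSumstats(cfg)
    expect_equal(sum(sim$truth$invalid), 20)
    expect_true(all(sim$truth$alpha[!sim$truth$invalid] == 0))
    expect_gt(mean(sim$truth$alpha[sim$truth$invalid]), 0)
    # correlated mode ties pleiotropy to instrument strength (InSIDE broken)
    cfgc <- mrSimConfig(nSnp = 80, propInvalid = 0.5,
                        pleiotropyMode = "correlated", pleiotropySd = 0.05,
                        seed = 7)
    simc <- simulateMRSumstats(cfgc)
    inv <- simc$truth$invalid
    expect_gt(cor(simc$truth$alpha[inv], simc$truth$gamma[inv]), 0.9)
    # none mode leaves all pleiotropy at zero even with invalid flags
    cfg0 <- mrSimConfig(nSnp = 20, propInvalid = 0.3, seed = 8)
    expect_true(all(simulateMRSumstats(cfg0)$truth$alpha == 0))
})

test_that("a null causal effect yields an unbiased, calibrated IVW estimate", {
    ests <- vapply(1:200, function(s) {
        sim <- simulateMRSumstats(mrSimConfig(nSnp = 50, causalBeta = 0,
                                              seed = s))
        mrIVW(simToHarmonized(sim), "fixed")@beta
    }, numeric(1))
    mc_se <- sd(ests) / sqrt(length(ests))
    expect_lt(abs(mean(ests)), 3 * mc_se)
})

test_that("the binary-outcome standard error carries the case-fraction scaling", {
    cfg <- mrSimConfig(nSnp = 10, outcomeCaseFraction = 0.1, seed = 9)
    sim <- simulateMRSumstats(cfg)
    v <- variants(sim$outcome)
    het <- 2 * v$eaf * (1 - v$eaf)
    expect_equal(v$se, 1 / sqrt(het * cfg@nOutcome * 0.1 * 0.9),
                 tolerance = 1e-12)
    expect_true(isBinary(sim$outcome))
    expect_equal(sim$outcome@nCase + sim$outcome@nControl,
                 sim$outcome@sampleN)
})

test_that("LDSC z-scores match their model moments", {
    cfg <- ldscSimConfig(mVariants = 20000, h2Trait1 = 0, h2Trait2 = 0,
                         rgTrue = 0, seed = 10)
    z <- simulateLDSCZscores(cfg)
    expect_equal(mean(z$z1$z^2), 1, tolerance = 0.05)
    expect_lt(abs(cor(z$z1$z, z$z2$z)), 0.02)
    expect_true(all(z$ld_scores$ld_score >= 1))
    # nonzero heritability inflates mean chi-square by n h2 mean(l) / m
    cfg2 <- ldscSimConfig(mVariants = 20000, h2Trait1 = 0.2, n1 = 50000,
                          seed = 11)
    z2 <- simulateLDSCZscores(cfg2)
    expected <- 1 + 50000 * 0.2 * mean(z2$ld_scores$ld_score) / 20000
    expect_equal(mean(z2$z1$z^2), expected, tolerance = 0.05)
})

test_that("infeasible variance-explained targets are rejected", {
    expect_error(mrSimConfig(exposureR2Total = 1.5), "exposureR2Total")
    expect_error(mrSimConfig(propInvalid = 1), "propInvalid")
    expect_error(mrSimConfig(mafRange = c(0, 0.6)), "mafRange")
})
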