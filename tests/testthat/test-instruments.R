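test_that("F-statistic and variance explained follow their closed forms", {
    expect_equal(fStatistic(0.1, 0.01), 100)
    expect_equal(fStatistic(0, 0.01), 0)
    expect_equal(fStatistic(-0.05, 0.005), 100)   # sign-invariant
    expect_error(fStatistic(0.1, 0), "se")
    expect_equal(varianceExplained(0.5, 0.1), 0.005)
    expect_equal(varianceExplained(0.3, 0), 0)
    expect_equal(sum(rep(varianceExplained(0.5, 0.1), 10)), 0.05)
    expect_error(varianceExplained(0.6, 0.1), "maf")
    expect_error(varianceExplained(0, 0.1), "maf")
})

test_that("significance selection uses strict inequality and deterministic ordering", {
    df <- toyVariants(3)
    df$pval <- c(4e-8, 5e-8, 6e-8)
    ss <- SummaryStats(df)
    expect_equal(selectSignificant(ss), "rs1")
    expect_equal(selectSignificant(SummaryStats(toyVariants(1)[0, ])),
                 character(0))
    # ties order lexicographically by snp_id
    df2 <- toyVariants(2)
    df2$snp_id <- c("rsB", "rsA")
    df2$pval <- 1e-9
    expect_equal(selectSignificant(SummaryStats(df2)), c("rsA", "rsB"))
    # monotone: raising the threshold never removes a selected variant
    set.seed(11)
    df3 <- toyVariants(30)
    df3$pval <- 10^runif(30, -12, -4)
    ss3 <- SummaryStats(df3)
    prev <- character(0)
    for (thr in c(1e-10, 1e-8, 1e-6, 1e-4)) {
        cur <- selectSignificant(ss3, thr)
        expect_true(all(prev %in% cur))
        prev <- cur
    }
})

test_that("greedy clumping dominates by p within window and r2 threshold", {
    df <- toyVariants(2, pos = c(100000L, 101000L))   # 1 kb apart
    df$pval <- c(1e-10, 1e-9)
    ss <- SummaryStats(df)
    r2 <- matrix(c(1, 0.5, 0.5, 1), 2)
    ld <- ldFromMatrix(r2, chrom = "1", pos = df$pos)
    expect_equal(as.character(ldClump(df$snp_id, ss, ld)), "rs1")
    # r2 below the threshold keeps both
    ld2 <- ldFromMatrix(matrix(c(1, 5e-4, 5e-4, 1), 2), "1", df$pos)
    expect_equal(sort(as.character(ldClump(df$snp_id, ss, ld2))), c("rs1", "rs2"))
    # distant same-chromosome variants survive regardless of r2
    df3 <- toyVariants(2, pos = c(100000L, 100000L + 2e7))
    df3$pval <- c(1e-10, 1e-9)
    ld3 <- ldFromMatrix(matrix(c(1, 0.9, 0.9, 1), 2), "1", df3$pos)
    expect_equal(sort(as.character(ldClump(df3$snp_id, SummaryStats(df3), ld3))),
                 c("rs1", "rs2"))
})

test_that("clumping equals the brute-force greedy oracle on every small instance", {
    set.seed(101)
    for (rep in 1:40) {
        n <- sample(2:8, 1)
        pos <- sort(sample.int(3e7, n))
        pval <- 10^runif(n, -12, -6)
        r2 <- matrix(0, n, n)
        r2[upper.tri(r2)] <- runif(n * (n - 1) / 2)^2
        r2 <- r2 + t(r2); diag(r2) <- 1
        df <- toyVariants(n, pos = as.integer(pos))
        df$pval <- pval
        ss <- SummaryStats(df)
        ld <- ldFromMatrix(r2, "1", pos)
        got <- ldClump(df$snp_id, ss, ld, r2Max = 0.1, windowKb = 5000)
        want <- clumpOracle(df$snp_id, rep("1", n), pos, pval, r2,
                            r2Max = 0.1, windowKb = 5000)
        expect_equal(as.character(got), want)
        # pairwise independence of the output
        if (length(got) > 1) {
            combos <- combn(got, 2)
            for (j in seq_len(ncol(combos))) {
                a <- combos[1, j]; b <- combos[2, j]
                pa <- pos[match(a, df$snp_id)]
                pb <- pos[match(b, df$snp_id)]
                expect_true(abs(pa - pb) > 5000 * 1000 ||
                            ldR2(ld, a, b) < 0.1)
            }
        }
    }
})

test_that("candidates missing from the LD reference are kept and logged", {
    df <- toyVariants(3, pos = c(1e5L, 2e5L, 3e5L))
    df$pval <- c(1e-10, 1e-9, 1e-8)
    ss <- SummaryStats(df)
    ld <- ldFromMatrix(matrix(1, 1, 1), "1", 1e5L, ids = "rs1")
    kept <- ldClump(df$snp_id, ss, ld)
    expect_setequal(as.character(kept), df$snp_id)
    expect_setequal(attr(kept, "logged"), c("rs2", "rs3"))
})

test_that("proxy lookup takes the argmax with position and id tie-breaks", {
    pos <- c(120L, 100L, 500L, 900L)
    r2 <- diag(4)
    r2[1, 2] <- r2[2, 1] <- 0.9
    r2[1, 3] <- r2[3, 1] <- 0.85
    r2[1, 4] <- r2[4, 1] <- 0.5
    ld <- ldFromMatrix(r2, "1", pos,
                       ids = c("target", "p100", "p500", "far"))
    expect_equal(findProxy("target", c("p100", "p500", "far"), ld), "p100")
    # strict threshold: r2 == 0.8 does not qualify
    r2b <- diag(2); r2b[1, 2] <- r2b[2, 1] <- 0.8
    ldb <- ldFromMatrix(r2b, "1", c(100L, 200L), ids = c("t", "c"))
    expect_true(is.na(findProxy("t", "c", ldb)))
    # tie on r2 resolves to nearest position
    r2c <- diag(3)
    r2c[1, 2] <- r2c[2, 1] <- 0.9
    r2c[1, 3] <- r2c[3, 1] <- 0.9
    ldc <- ldFromMatrix(r2c, "1", c(120L, 100L, 500L),
                        ids = c("t", "near", "farther"))
    expect_equal(findProxy("t", c("near", "farther"), ldc), "near")
    expect_warning(miss <- findProxy("absent", "near", ldc), "absent")
    expect_true(is.na(miss))
})

test_that("the filter composition removes weak instruments and audits each stage", {
    df <- toyVariants(3, pos = c(1e5L, 3e7L, 6e7L))
    df$pval <- c(1e-10, 1e-10, 1e-10)
    df$beta <- c(0.1, 0.1, 0.03)
    df$se <- c(0.01, 0.01, 0.01)       # F = 100, 100, 9
    ss <- SummaryStats(df)
    ld <- ldFromMatrix(diag(3), "1", df$pos, ids = df$snp_id)
    res <- applyInstrumentFilters(ss, ld)
    expect_setequal(res$instruments, c("rs1", "rs2"))
    expect_equal(unname(res$audit[["weak_f"]]), 1)
    expect_equal(nSnp(ss),
                 length(res$instruments) + sum(res$audit))
    # no significant SNP at all -> explicit empty-instrument error
    df$pval <- rep(0.5, 3)
    expect_error(applyInstrumentFilters(SummaryStats(df), ld),
                 "no instruments")
})

test_that("planted independent instruments are recovered by the filter chain", {
    # strong planted instruments; selection should recover nearly all
    recovered <- vapply(1:5, function(s) {
        sim <- simulateMRSumstats(mrSimConfig(nSnp = 100, seed = s,
                                              exposureR2Total = 0.3,
                                              nExposure = 3e6))
        ld <- ldFromMatrix(diag(100), variants(sim$exposure)$chrom,
                           variants(sim$exposure)$pos,
                           ids = variants(sim$exposure)$snp_id)
        length(applyInstrumentFilters(sim$exposure, ld)$instruments)
    }, numeric(1))
    expect_gte(mean(recovered), 95)
})
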