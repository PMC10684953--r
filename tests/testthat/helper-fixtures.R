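# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no binary fixtures.

# A minimal well-formed variant table.
toyVariants <- function(n = 3, chrom = "1", pos = seq_len(n) * 1000L,
                        ea = "A", oa = "G", eaf = 0.3, beta = 0.1,
                        se = 0.01, pval = 1e-9, nsamp = 10000) {
    data.frame(snp_id = sprintf("rs%d", seq_len(n)), chrom = chrom,
               pos = pos, effect_allele = ea, other_allele = oa,
               eaf = eaf, beta = beta, se = se, pval = pval, n = nsamp,
               stringsAsFactors = FALSE)
}

toyStats <- function(..., traitName = "toy") {
    SummaryStats(toyVariants(...), traitName = traitName)
}

# HarmonizedSet straight from vectors (bypasses allele harmonization so
# estimator tests are isolated from it).
makeHarmonized <- function(bx, sex, by, sey, eafx = NA_real_,
                           eafy = NA_real_, nExposure = 1e5,
                           nOutcome = 1e5, binary = FALSE, K = NA_real_) {
    k <- length(bx)
    d <- data.frame(snp_id = sprintf("rs%d", seq_len(k)),
                    beta_exposure = bx, se_exposure = sex,
                    beta_outcome = by, se_outcome = sey,
                    eaf_exposure = eafx, eaf_outcome = eafy,
                    pval_exposure = 2 * pnorm(-abs(bx / sex)),
                    pval_outcome = 2 * pnorm(-abs(by / sey)),
                    stringsAsFactors = FALSE)
    new("HarmonizedSet", data = d, exposureName = "X", outcomeName = "Y",
        outcomeIsBinary = binary, nExposure = nExposure,
        nOutcome = nOutcome, outcomeCaseFraction = K,
        exclusions = data.frame(snp_id = character(),
                                reason = character(),
                                stringsAsFactors = FALSE))
}

# HarmonizedSet with prescribed Wald ratios and ratio variances:
# beta_x = 1 so ratio = beta_y and v = se_y^2.
harmonizedFromRatios <- function(r, v) {
    makeHarmonized(bx = rep(1, length(r)), sex = rep(1e-6, length(r)),
                   by = r, sey = sqrt(v))
}

# Convert one simulateMRSumstats() draw into a HarmonizedSet directly
# (identical alleles by construction, so harmonization would be the
# identity; skipping it keeps Monte-Carlo loops fast).
simToHarmonized <- function(sim) {
    vx <- variants(sim$exposure)
    vy <- variants(sim$outcome)
    makeHarmonized(bx = vx$beta, sex = vx$se, by = vy$beta, sey = vy$se,
                   eafx = vx$eaf, eafy = vy$eaf,
                   nExposure = sampleN(sim$exposure),
                   nOutcome = sampleN(sim$outcome),
                   binary = isBinary(sim$outcome),
                   K = if (isBinary(sim$outcome))
                           sim$outcome@nCase / sim$outcome@sampleN
                       else NA_real_)
}

# Build an LDReference from a dense symmetric r2 matrix.
ldFromMatrix <- function(r2mat, chrom, pos, ids = NULL) {
    n <- nrow(r2mat)
    if (is.null(ids)) ids <- sprintf("rs%d", seq_len(n))
    pairs <- which(upper.tri(r2mat) & r2mat > 0, arr.ind = TRUE)
    new("LDReference",
        variants = data.frame(snp_id = ids, chrom = chrom, pos = pos,
                              ld_score = 1 + rowSums(r2mat) - 1,
                              stringsAsFactors = FALSE),
        r2pairs = data.frame(snp_a = ids[pairs[, 1]],
                             snp_b = ids[pairs[, 2]],
                             r2 = r2mat[pairs],
                             stringsAsFactors = FALSE))
}

# Independent brute-force greedy clumping oracle working on the dense r2
# matrix: literal step-by-step enumeration of removals.
clumpOracle <- function(ids, chrom, pos, pval, r2mat, r2Max, windowKb) {
    remaining <- order(pval, pos, ids)
    kept <- integer()
    while (length(remaining)) {
        idx <- remaining[1]
        kept <- c(kept, idx)
        remaining <- remaining[-1]
        if (!length(remaining)) break
        drop <- vapply(remaining, function(j) {
            chrom[j] == chrom[idx] &&
                abs(pos[j] - pos[idx]) <= windowKb * 1000 &&
                r2mat[idx, j] >= r2Max
        }, logical(1))
        remaining <- remaining[!drop]
    }
    ids[kept]
}

# Independent IVW oracle: explicit weighted mean of the ratios.
ivwOracle <- function(r, v) {
    w <- 1 / v
    list(beta = sum(w * r) / sum(w), se = sqrt(1 / sum(w)),
         q = sum(w * (r - sum(w * r) / sum(w))^2))
}

# Independent power oracle: Poisson-mixture expansion of the non-central
# chi-square upper tail, integrated numerically term by term.
powerOracle <- function(nTotal, K, r2, orv, alpha = 0.05) {
    b <- K * (orv / (1 + K * (orv - 1)) - 1)
    v <- (K * (1 - K) - b^2) / (nTotal * r2)
    ncp <- b^2 / v
    crit <- qchisq(1 - alpha, 1)
    dens <- function(x) {
        j <- 0:200
        vapply(x, function(xi)
            sum(exp(-ncp / 2) * (ncp / 2)^j / factorial(j) *
                dchisq(xi, df = 1 + 2 * j)), numeric(1))
    }
    integrate(dens, crit, Inf, rel.tol = 1e-10)$value
}

writeTempSumstats <- function(df, sep = "\t", ext = ".tsv") {
    path <- tempfile(fileext = ext)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    path
}
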