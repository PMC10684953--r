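#' @include sumstats-io.R
NULL

#' Simulate a block-diagonal LD reference
#'
#' Builds an [LDReference-class] with `nBlock` blocks of `blockSize`
#' variants: r-squared between variants in different blocks is exactly 0;
#' within a block, `r2(i, j) = withinBlockR2 * decay^(|i - j| - 1)`, so
#' `decay = 1` gives a constant within-block r-squared and `decay < 1` a
#' geometric decay with index distance.  Per-variant LD scores are
#' 1 + the row sum of r-squared over the block.  Blocks are placed 20 Mb
#' apart (1 kb spacing within a block) across chromosomes 1-22, so
#' variants in different blocks are also distant in clumping terms.
#'
#' @param nBlock number of LD blocks.
#' @param blockSize variants per block (>= 1).
#' @param withinBlockR2 adjacent-variant r-squared in [0, 1].
#' @param decay geometric decay rate per index step (default 1: constant).
#' @param mafRange interval minor allele frequencies are drawn from; stored
#'   in the variant index as column `maf`.
#' @param seed integer RNG seed.
#' @return an [LDReference-class].
#' @export
simulateLDReference <- function(nBlock, blockSize, withinBlockR2 = 0,
                                decay = 1, mafRange = c(0.05, 0.5),
                                seed = 1L) {
    stopifnot(blockSize >= 1, nBlock >= 1,
              withinBlockR2 >= 0, withinBlockR2 <= 1)
    set.seed(seed)
    m <- nBlock * blockSize
    block <- rep(seq_len(nBlock), each = blockSize)
    within <- rep(seq_len(blockSize), times = nBlock)
    chrom <- as.character((block - 1L) %% 22L + 1L)
    pos <- as.integer(((block - 1L) %/% 22L) * 2e7 + 1e5 +
                      (within - 1L) * 1000L)
    snp_id <- sprintf("rs%06d", seq_len(m))
    maf <- stats::runif(m, mafRange[1], mafRange[2])
    pairs <- NULL
    ld_score <- rep(1, m)
    if (blockSize > 1 && withinBlockR2 > 0) {
        ij <- utils::combn(seq_len(blockSize), 2)
        r2_block <- withinBlockR2 * decay^(abs(ij[1, ] - ij[2, ]) - 1)
        pairs <- do.call(rbind, lapply(seq_len(nBlock), function(b) {
            off <- (b - 1L) * blockSize
            data.frame(snp_a = snp_id[ij[1, ] + off],
                       snp_b = snp_id[ij[2, ] + off],
                       r2 = r2_block, stringsAsFactors = FALSE)
        }))
        score_within <- vapply(seq_len(blockSize), function(i)
            sum(r2_block[ij[1, ] == i | ij[2, ] == i]), numeric(1))
        ld_score <- 1 + rep(score_within, times = nBlock)
    }
    new("LDReference",
        variants = data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                              ld_score = ld_score, maf = maf,
                              stringsAsFactors = FALSE),
        r2pairs = if (is.null(pairs))
                      data.frame(snp_a = character(), snp_b = character(),
                                 r2 = numeric(), stringsAsFactors = FALSE)
                  else pairs)
}

#' Settings for the MR summary-statistics generator
#'
#' Constructor for [MRSimConfig-class].  The defaults reproduce the scale
#' of a urate-to-diabetic-neuropathy style analysis: 89 independent
#' instruments explaining 7.92\% of a continuous exposure measured in
#' 288,649 people, a binary outcome GWAS of 274,660 people with case
#' fraction 2,843/274,660, and a true causal effect of log(1.17) per
#' exposure unit on the log-odds scale.
#'
#' @param nSnp planted instrument count.
#' @param causalBeta true causal effect (log-odds per exposure unit).
#' @param nExposure,nOutcome GWAS sample sizes.
#' @param mafRange minor-allele-frequency interval within (0, 0.5].
#' @param exposureR2Total total exposure variance explained by the planted
#'   instruments, in (0, 1).
#' @param propInvalid fraction of instruments given pleiotropic effects.
#' @param pleiotropyMode `none`, `balanced` (zero-mean), `directional`
#'   (nonzero mean), or `correlated` (pleiotropy proportional to
#'   instrument strength; violates InSIDE).
#' @param pleiotropySd,pleiotropyMean pleiotropic-effect scale and mean on
#'   the outcome log-odds scale.
#' @param outcomeBinary binary outcome flag (default TRUE).
#' @param outcomeCaseFraction case fraction K of the outcome GWAS (used in
#'   the binary se scaling 1/sqrt(K(1-K))); default 0.5, i.e. a balanced
#'   case-control design.
#' @param seed integer RNG seed.
#' @return an [MRSimConfig-class].
#' @export
mrSimConfig <- function(nSnp = 89, causalBeta = log(1.17),
                        nExposure = 288649, nOutcome = 274660,
                        mafRange = c(0.05, 0.5), exposureR2Total = 0.0792,
                        propInvalid = 0, pleiotropyMode = "none",
                        pleiotropySd = 0, pleiotropyMean = 0,
                        outcomeBinary = TRUE, outcomeCaseFraction = 0.5,
                        seed = 1L) {
    new("MRSimConfig", nSnp = as.integer(nSnp), causalBeta = causalBeta,
        nExposure = nExposure, nOutcome = nOutcome, mafRange = mafRange,
        exposureR2Total = exposureR2Total, propInvalid = propInvalid,
        pleiotropyMode = pleiotropyMode, pleiotropySd = pleiotropySd,
        pleiotropyMean = pleiotropyMean, outcomeBinary = outcomeBinary,
        outcomeCaseFraction = outcomeCaseFraction, seed = as.integer(seed))
}

#' Simulate exposure/outcome GWAS summary statistics with known truth
#'
#' Generates a two-trait summary-statistics pair under the standard
#' two-sample MR data-generating model.  True instrument effects are drawn
#' half-normal — positive, i.e. reported for the exposure-increasing
#' allele, the usual GWAS convention — and rescaled so their summed
#' variance explained
#' (2 maf (1-maf) gamma^2) matches `exposureR2Total`; observed exposure
#' effects add sampling noise with se = 1/sqrt(2 maf (1-maf) n_exposure).
#' True outcome effects are `causalBeta * gamma` plus per-variant
#' pleiotropy on the invalid subset (per `pleiotropyMode`); observed
#' outcome effects add noise on the outcome se scale, which for binary
#' outcomes carries the additional 1/sqrt(K(1-K)) factor.  Instruments are
#' LD-independent (one per block of `ld`) unless the caller picks
#' correlated variants explicitly.  Pure function of (config, seed).
#'
#' @param config an [MRSimConfig-class].
#' @param ld optional [LDReference-class]; when supplied, the first variant
#'   of each of the first `nSnp` blocks provides ids/positions, otherwise
#'   synthetic independent variants are created.
#' @return list with `exposure` and `outcome` ([SummaryStats-class]) and
#'   `truth` (list: `causal_beta`, `gamma` true exposure effects, `alpha`
#'   pleiotropic effects, `invalid` flags, `maf`).
#' @export
simulateMRSumstats <- function(config, ld = NULL) {
    validObject(config)
    set.seed(config@seed)
    k <- config@nSnp
    if (!is.null(ld)) {
        v <- variants(ld)
        first <- !duplicated(paste(v$chrom, v$pos %/% 2e7))
        idx <- which(first)
        if (length(idx) < k)
            stop("LD reference has fewer blocks than nSnp")
        vi <- v[idx[seq_len(k)], , drop = FALSE]
        snp_id <- vi$snp_id; chrom <- vi$chrom; pos <- vi$pos
        maf <- if ("maf" %in% names(vi)) vi$maf
               else stats::runif(k, config@mafRange[1], config@mafRange[2])
    } else {
        snp_id <- sprintf("rs%06d", seq_len(k))
        chrom <- as.character((seq_len(k) - 1L) %% 22L + 1L)
        pos <- as.integer(((seq_len(k) - 1L) %/% 22L) * 2e7 + 1e5)
        maf <- stats::runif(k, config@mafRange[1], config@mafRange[2])
    }
    het <- 2 * maf * (1 - maf)
    # half-normal magnitudes: instruments reported aligned to the
    # exposure-increasing allele, the usual GWAS orientation (and the
    # convention under which directional pleiotropy does not cancel)
    gamma_raw <- abs(stats::rnorm(k))
    scale <- sqrt(config@exposureR2Total / sum(het * gamma_raw^2))
    gamma <- gamma_raw * scale
    if (any(het * gamma^2 >= 1))
        stop("infeasible exposureR2Total: a single variant would explain ",
             ">= 100% of the exposure")
    se_x <- 1 / sqrt(het * config@nExposure)
    beta_x <- gamma + stats::rnorm(k, 0, se_x)

    n_invalid <- round(config@propInvalid * k)
    invalid <- rep(FALSE, k)
    if (n_invalid > 0) invalid[sample.int(k, n_invalid)] <- TRUE
    alpha <- numeric(k)
    if (any(invalid) && config@pleiotropyMode != "none") {
        ninv <- sum(invalid)
        alpha[invalid] <- switch(
            config@pleiotropyMode,
            balanced = stats::rnorm(ninv, 0, config@pleiotropySd),
            directional = stats::rnorm(ninv, config@pleiotropyMean,
                                       config@pleiotropySd),
            correlated = config@pleiotropyMean +
                config@pleiotropySd * gamma[invalid] / stats::sd(gamma))
    }
    K <- config@outcomeCaseFraction
    se_y <- 1 / sqrt(het * config@nOutcome *
                     if (config@outcomeBinary) K * (1 - K) else 1)
    beta_y <- config@causalBeta * gamma + alpha + stats::rnorm(k, 0, se_y)

    alleles <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                      byrow = TRUE)
    ai <- (seq_len(k) - 1L) %% 4L + 1L
    mk <- function(beta, se, pclamp = TRUE) {
        p <- 2 * stats::pnorm(-abs(beta / se))
        p[p == 0] <- .Machine$double.xmin
        p
    }
    tab_x <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                        effect_allele = alleles[ai, 1],
                        other_allele = alleles[ai, 2],
                        eaf = maf, beta = beta_x, se = se_x,
                        pval = mk(beta_x, se_x), n = config@nExposure,
                        stringsAsFactors = FALSE)
    tab_y <- tab_x
    tab_y$beta <- beta_y; tab_y$se <- se_y
    tab_y$pval <- mk(beta_y, se_y); tab_y$n <- config@nOutcome
    exposure <- SummaryStats(tab_x, traitName = "sim_exposure",
                             isBinary = FALSE, sampleN = config@nExposure)
    outcome <- if (config@outcomeBinary)
        SummaryStats(tab_y, traitName = "sim_outcome", isBinary = TRUE,
                     nCase = round(K * config@nOutcome),
                     nControl = config@nOutcome - round(K * config@nOutcome),
                     sampleN = config@nOutcome)
    else SummaryStats(tab_y, traitName = "sim_outcome", isBinary = FALSE,
                      sampleN = config@nOutcome)
    list(exposure = exposure, outcome = outcome,
         truth = list(causal_beta = config@causalBeta, gamma = gamma,
                      alpha = alpha, invalid = invalid, maf = maf))
}

#' Settings for the LDSC z-score generator
#'
#' Constructor for [LDSCSimConfig-class].  Defaults mirror the scale of a
#' urate/diabetic-neuropathy style trait pair: heritabilities 9.64\% and
#' 1.05\%, genetic correlation 0.293, GWAS sizes 288,649 and 274,660, and
#' m = 20,000 variants (a desk-scale variant count; LD scores are drawn
#' from 1 + Gamma(shape, scale)).
#'
#' @param mVariants variant count m.
#' @param h2Trait1,h2Trait2 SNP heritabilities in [0, 1].
#' @param rgTrue genetic correlation in [-1, 1].
#' @param n1,n2 GWAS sample sizes.
#' @param nOverlap shared individuals between the two GWAS.
#' @param ldScoreShape,ldScoreScale gamma parameters of the LD-score draw.
#' @param seed integer RNG seed.
#' @return an [LDSCSimConfig-class].
#' @export
ldscSimConfig <- function(mVariants = 20000, h2Trait1 = 0.0964,
                          h2Trait2 = 0.0105, rgTrue = 0.293,
                          n1 = 288649, n2 = 274660, nOverlap = 0,
                          ldScoreShape = 2, ldScoreScale = 15, seed = 1L) {
    new("LDSCSimConfig", mVariants = as.integer(mVariants),
        h2Trait1 = h2Trait1, h2Trait2 = h2Trait2, rgTrue = rgTrue,
        n1 = n1, n2 = n2, nOverlap = nOverlap,
        ldScoreShape = ldScoreShape, ldScoreScale = ldScoreScale,
        seed = as.integer(seed))
}

#' Simulate per-variant z-scores under the LD score regression model
#'
#' Draws, per variant j with LD score l_j, a bivariate normal pair
#' (z1, z2) with `Var(z1) = 1 + n1 h2_1 l_j / m`,
#' `Var(z2) = 1 + n2 h2_2 l_j / m`, and covariance
#' `rg sqrt(h2_1 h2_2) sqrt(n1 n2) l_j / m + n_overlap rho / sqrt(n1 n2)`
#' where the phenotypic correlation rho inside the overlapping subsample is
#' taken equal to `rgTrue`.  Pure function of (config, seed).
#'
#' @param config an [LDSCSimConfig-class].
#' @return list with `z1`, `z2` (data.frames: `snp_id`, `z`, `n`) and
#'   `ld_scores` (data.frame: `snp_id`, `ld_score`).
#' @export
simulateLDSCZscores <- function(config) {
    validObject(config)
    set.seed(config@seed)
    m <- config@mVariants
    ell <- 1 + stats::rgamma(m, shape = config@ldScoreShape,
                             scale = config@ldScoreScale)
    v1 <- 1 + config@n1 * config@h2Trait1 * ell / m
    v2 <- 1 + config@n2 * config@h2Trait2 * ell / m
    c12 <- config@rgTrue * sqrt(config@h2Trait1 * config@h2Trait2) *
        sqrt(config@n1 * config@n2) * ell / m +
        config@nOverlap * config@rgTrue / sqrt(config@n1 * config@n2)
    # Cholesky of the 2x2 covariance, vectorised; clip to keep it PD
    c12 <- pmin(pmax(c12, -sqrt(v1 * v2) * 0.999), sqrt(v1 * v2) * 0.999)
    u1 <- stats::rnorm(m)
    u2 <- stats::rnorm(m)
    z1 <- sqrt(v1) * u1
    z2 <- (c12 / sqrt(v1)) * u1 + sqrt(v2 - c12^2 / v1) * u2
    snp_id <- sprintf("rs%06d", seq_len(m))
    list(z1 = data.frame(snp_id = snp_id, z = z1, n = config@n1,
                         stringsAsFactors = FALSE),
         z2 = data.frame(snp_id = snp_id, z = z2, n = config@n2,
                         stringsAsFactors = FALSE),
         ld_scores = data.frame(snp_id = snp_id, ld_score = ell,
                                stringsAsFactors = FALSE))
}
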