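#' @include mr-estimators.R
NULL

#' Cochran's Q heterogeneity test
#'
#' Q = sum_i w_i (r_i - beta_IVW)^2 over the per-SNP Wald ratios r_i with
#' inverse-variance weights w_i = 1/v_i, referred to a chi-square with
#' k - 1 degrees of freedom.  I-squared = max(0, (Q - df)/Q) * 100 is the
#' percentage of variation attributable to heterogeneity; the usual
#' model-selection convention reports fixed-effects IVW as primary when
#' I-squared < 50.
#'
#' @param h a [HarmonizedSet-class] with at least 2 instruments.
#' @return list with `q_stat`, `q_df`, `q_pval`, `i2`.
#' @export
cochranQ <- function(h) {
    k <- nSnp(h)
    if (k < 2) stop("Cochran's Q needs >= 2 instruments")
    rt <- .ratios(h)
    w <- 1 / rt$v
    beta <- sum(w * rt$r) / sum(w)
    q <- sum(w * (rt$r - beta)^2)
    df <- k - 1
    i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
    list(q_stat = q, q_df = df,
         q_pval = stats::pchisq(q, df, lower.tail = FALSE), i2 = i2)
}

# IVW point estimate in regression form (identical to the ratio form):
# beta = sum(w by bx) / sum(w bx^2), w = 1/se_y^2.
.ivwPoint <- function(bx, by, w) sum(w * by * bx) / sum(w * bx^2)

# Leave-one-out IVW points via totals.
.looPoints <- function(bx, by, w) {
    s1 <- sum(w * by * bx)
    s2 <- sum(w * bx^2)
    (s1 - w * by * bx) / (s2 - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based residual-sum-of-squares (RSS) test for horizontal
#' pleiotropy.  The observed RSS sums, over SNPs, the weighted squared
#' residual of each SNP from the leave-one-out IVW prediction; its null
#' distribution comes from `nSim` parametric simulations drawing
#' `beta_x* ~ N(beta_x, se_x)` and `beta_y* ~ N(b_loo * beta_x, se_y)`
#' under the no-pleiotropy model.  Global p-value: the exceedance fraction.
#' Outlier test: each SNP's observed weighted squared residual against its
#' own simulated null, Bonferroni-flagged at `outlierAlpha / k`.
#' Distortion test: the shift between the outlier-free and the full IVW
#' estimate, compared with a null of the same-size random-subset shifts.
#' The corrected estimate is IVW after removing flagged outliers; it is
#' only populated when at least one outlier is flagged.
#'
#' @param h a [HarmonizedSet-class] with at least 4 instruments.
#' @param nSim parametric simulations (default 1000).
#' @param seed RNG seed.
#' @param outlierAlpha familywise level of the outlier test (default 0.05).
#' @return a [PressoReport-class].
#' @export
mrPresso <- function(h, nSim = 1000, seed = 1L, outlierAlpha = 0.05) {
    k <- nSnp(h)
    if (k < 4) stop("MR-PRESSO needs >= 4 instruments")
    d <- harmonizedData(h)
    bx <- d$beta_exposure; by <- d$beta_outcome
    sx <- d$se_exposure; sy <- d$se_outcome
    w <- 1 / sy^2
    set.seed(seed)
    loo <- .looPoints(bx, by, w)
    res2_obs <- w * (by - loo * bx)^2
    rss_obs <- sum(res2_obs)

    # parametric null: nSim x k draws, LOO residuals computed per draw
    bxs <- matrix(stats::rnorm(nSim * k, rep(bx, each = nSim),
                               rep(sx, each = nSim)), nSim, k)
    bys <- matrix(stats::rnorm(nSim * k, rep(loo * bx, each = nSim),
                               rep(sy, each = nSim)), nSim, k)
    W <- matrix(w, nSim, k, byrow = TRUE)
    s1 <- rowSums(W * bys * bxs)
    s2 <- rowSums(W * bxs^2)
    loo_sim <- (s1 - W * bys * bxs) / (s2 - W * bxs^2)
    res2_sim <- W * (bys - loo_sim * bxs)^2
    rss_sim <- rowSums(res2_sim)

    global_p <- (1 + sum(rss_sim >= rss_obs)) / (nSim + 1)
    outlier_p <- (1 + colSums(res2_sim >=
                              matrix(res2_obs, nSim, k, byrow = TRUE))) /
        (nSim + 1)
    names(outlier_p) <- d$snp_id
    flags <- outlier_p < outlierAlpha / k
    names(flags) <- d$snp_id

    raw <- mrIVW(h, "mre")
    raw@method <- "presso_raw"
    if (any(flags) && sum(!flags) >= 2) {
        corrected <- mrIVW(subsetHarmonized(h, !flags), "mre")
        corrected@method <- "presso_corrected"
        # distortion null: shift of random same-size subsets from the full
        # estimate
        b_all <- .ivwPoint(bx, by, w)
        b_no <- .ivwPoint(bx[!flags], by[!flags], w[!flags])
        m <- sum(!flags)
        shifts <- vapply(seq_len(nSim), function(i) {
            idx <- sample.int(k, m)
            .ivwPoint(bx[idx], by[idx], w[idx]) - b_all
        }, numeric(1))
        dist_p <- (1 + sum(abs(shifts) >= abs(b_no - b_all))) / (nSim + 1)
    } else {
        corrected <- new("MREstimate", method = "presso_corrected")
        dist_p <- NA_real_
    }
    new("PressoReport", globalPval = global_p, outlierPvals = outlier_p,
        outlierFlags = flags, distortionPval = dist_p,
        rawEstimate = raw, correctedEstimate = corrected,
        nSim = as.integer(nSim))
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the IVW (multiplicative random effects) estimate omitting one
#' instrument at a time; the final row (`snp_id = "ALL"`) is the all-SNP
#' reference estimate.
#'
#' @param h a [HarmonizedSet-class] with at least 3 instruments.
#' @return data.frame with columns `snp_id`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pval` (k + 1 rows).
#' @export
leaveOneOut <- function(h) {
    k <- nSnp(h)
    if (k < 3) stop("leave-one-out needs >= 3 instruments")
    rows <- lapply(seq_len(k), function(i) {
        e <- mrIVW(subsetHarmonized(h, -i), "mre")
        data.frame(snp_id = harmonizedData(h)$snp_id[i], beta = e@beta,
                   se = e@se, ci_low = e@ciLow, ci_high = e@ciHigh,
                   pval = e@pval, stringsAsFactors = FALSE)
    })
    eAll <- mrIVW(h, "mre")
    rows[[k + 1L]] <- data.frame(snp_id = "ALL", beta = eAll@beta,
                                 se = eAll@se, ci_low = eAll@ciLow,
                                 ci_high = eAll@ciHigh, pval = eAll@pval,
                                 stringsAsFactors = FALSE)
    do.call(rbind, rows)
}

# Per-SNP variance explained on each side.  With allele frequencies, uses
# 2*maf*(1-maf)*beta^2 (standardized trait), scaled by K(1-K) on the
# observed scale for binary outcomes; otherwise falls back to the
# F-statistic identity r2 = F / (F + n - 2).
.steigerR2 <- function(beta, se, eaf, n, binary = FALSE, K = NA_real_) {
    f <- beta^2 / se^2
    fallback <- f / (f + n - 2)
    if (all(is.na(eaf))) return(fallback)
    maf <- pmin(eaf, 1 - eaf)
    r2 <- 2 * maf * (1 - maf) * beta^2
    if (binary && !is.na(K)) r2 <- r2 * K * (1 - K)
    ifelse(is.na(maf) | maf <= 0, fallback, r2)
}

#' Steiger directionality test and filter
#'
#' Compares, per SNP, the variance explained in the exposure with the
#' variance explained in the outcome (binary outcomes on the observed
#' log-odds scale, scaled by K(1-K) with K the case fraction).  A SNP is
#' kept when it explains strictly more variance in the exposure.  The
#' overall direction is `exposure_to_outcome` when the summed r2 over kept
#' SNPs is larger on the exposure side; its p-value is the two-correlation
#' z-test on the Fisher-transformed square roots of the summed r2.
#'
#' @param h a [HarmonizedSet-class]; sample sizes are taken from the set.
#' @return list with `keep` (named logical vector), `direction` (one of
#'   `exposure_to_outcome`, `outcome_to_exposure`, `undetermined`),
#'   `steiger_pval`, and the per-SNP r2 tables `r2_exposure`, `r2_outcome`.
#' @export
steigerTest <- function(h) {
    d <- harmonizedData(h)
    nx <- h@nExposure; ny <- h@nOutcome
    if (is.na(nx) || is.na(ny))
        stop("Steiger test needs exposure and outcome sample sizes")
    r2x <- .steigerR2(d$beta_exposure, d$se_exposure, d$eaf_exposure, nx)
    r2y <- .steigerR2(d$beta_outcome, d$se_outcome, d$eaf_outcome, ny,
                      binary = h@outcomeIsBinary,
                      K = h@outcomeCaseFraction)
    keep <- stats::setNames(r2x > r2y, d$snp_id)
    use <- if (any(keep)) keep else rep(TRUE, length(keep))
    sx <- min(sum(r2x[use]), 0.999)
    sy <- min(sum(r2y[use]), 0.999)
    if (sx == sy) {
        direction <- "undetermined"; p <- 1
    } else {
        direction <- if (sx > sy) "exposure_to_outcome"
                     else "outcome_to_exposure"
        z <- (atanh(sqrt(sx)) - atanh(sqrt(sy))) /
            sqrt(1 / (nx - 3) + 1 / (ny - 3))
        p <- 2 * stats::pnorm(-abs(z))
    }
    list(keep = keep, direction = direction, steiger_pval = p,
         r2_exposure = r2x, r2_outcome = r2y)
}

#' Funnel-plot table
#'
#' Per-SNP Wald ratio and its precision (1/se of the ratio), the
#' coordinates of the standard MR funnel plot; asymmetry suggests
#' directional pleiotropy.  No statistic is computed here.
#'
#' @param h a [HarmonizedSet-class].
#' @return data.frame with `snp_id`, `ratio`, `precision`.
#' @export
funnelTable <- function(h) {
    rt <- .ratios(h)
    data.frame(snp_id = rt$snp_id, ratio = rt$r,
               precision = 1 / sqrt(rt$v), stringsAsFactors = FALSE)
}

#' Full sensitivity suite
#'
#' Runs Cochran's Q / I-squared, the Egger intercept test, MR-PRESSO,
#' leave-one-out, the Steiger directionality test and the funnel table for
#' one harmonized set.  Components whose instrument-count preconditions are
#' not met are reported as NULL rather than aborting the suite.
#'
#' @param h a [HarmonizedSet-class].
#' @param nSim MR-PRESSO simulation count (default 1000).
#' @param seed RNG seed.
#' @return named list: `q` (Cochran's Q list), `egger_intercept`
#'   ([MREstimate-class]), `presso` ([PressoReport-class]), `loo`
#'   (data.frame), `steiger` (list), `funnel` (data.frame).
#' @export
sensitivitySuite <- function(h, nSim = 1000, seed = 1L) {
    k <- nSnp(h)
    list(q = if (k >= 2) cochranQ(h),
         egger_intercept = if (k >= 3) mrEgger(h)$intercept,
         presso = if (k >= 4) mrPresso(h, nSim = nSim, seed = seed),
         loo = if (k >= 3) leaveOneOut(h),
         steiger = steigerTest(h),
         funnel = funnelTable(h))
}
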