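#' @include harmonization.R
NULL

# Per-SNP Wald ratios and their first-order variances from a HarmonizedSet.
.ratios <- function(h) {
    d <- harmonizedData(h)
    if (any(d$beta_exposure == 0))
        stop("zero exposure effect: Wald ratio undefined")
    list(r = d$beta_outcome / d$beta_exposure,
         v = d$se_outcome^2 / d$beta_exposure^2,
         snp_id = d$snp_id)
}

#' Wald ratio estimate for a single instrument
#'
#' Causal estimate from one variant: beta = beta_y / beta_x with the
#' first-order delta-method standard error se_y / |beta_x|.  The
#' second-order term beta_y^2 * se_x^2 / beta_x^4 can be added to the
#' variance via `secondOrder = TRUE`.
#'
#' @param betaX,seX exposure effect and standard error.
#' @param betaY,seY outcome effect and standard error.
#' @param secondOrder include the second-order delta-method variance term.
#' @return an [MREstimate-class] with method `wald_ratio`.
#' @export
waldRatio <- function(betaX, seX, betaY, seY, secondOrder = FALSE) {
    if (betaX == 0) stop("betaX must be nonzero")
    beta <- betaY / betaX
    v <- seY^2 / betaX^2
    if (secondOrder) v <- v + betaY^2 * seX^2 / betaX^4
    .mrEstimate("wald_ratio", beta, sqrt(v), 1L)
}

#' Inverse-variance-weighted estimate
#'
#' The IVW estimate is the 1/variance-weighted mean of the per-SNP Wald
#' ratios (first-order variances v_i = se_y^2 / beta_x^2).  The fixed-effect
#' standard error is 1/sqrt(sum 1/v_i); the multiplicative random-effects
#' model (`model = "mre"`) inflates it by sqrt(max(1, Q/(k-1))) where Q is
#' Cochran's Q over the k ratios — overdispersion widens the interval,
#' under-dispersion is floored at 1.  Identical, by algebra, to the
#' weighted regression of beta_y on beta_x through the origin with weights
#' 1/se_y^2.
#'
#' @param h a [HarmonizedSet-class] with at least 2 instruments.
#' @param model `"mre"` (default; matches primary multiplicative
#'   random-effects reporting) or `"fixed"`.
#' @return an [MREstimate-class] with method `ivw_mre` or `ivw_fe`.
#' @export
mrIVW <- function(h, model = c("mre", "fixed")) {
    model <- match.arg(model)
    k <- nSnp(h)
    if (k < 2) stop("IVW needs >= 2 instruments; use waldRatio")
    rt <- .ratios(h)
    w <- 1 / rt$v
    beta <- sum(w * rt$r) / sum(w)
    se_fe <- sqrt(1 / sum(w))
    if (model == "fixed")
        return(.mrEstimate("ivw_fe", beta, se_fe, k))
    q <- sum(w * (rt$r - beta)^2)
    infl <- sqrt(max(1, q / (k - 1)))
    .mrEstimate("ivw_mre", beta, se_fe * infl, k)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with a
#' free intercept (weights 1/se_y^2), after orienting every row so that the
#' exposure effect is non-negative.  The slope is the pleiotropy-robust
#' causal estimate under the InSIDE assumption; the intercept estimates the
#' average directional pleiotropy, and its p-value is the standard
#' directional-pleiotropy test.  Standard errors carry the multiplicative
#' random-effects inflation sqrt(max(1, residual variance)); p-values use
#' the t distribution with k - 2 degrees of freedom.
#'
#' @param h a [HarmonizedSet-class] with at least 3 instruments.
#' @return list with elements `slope` and `intercept`, both
#'   [MREstimate-class] (methods `egger_slope`, `egger_intercept`).
#' @export
mrEgger <- function(h) {
    k <- nSnp(h)
    if (k < 3) stop("MR-Egger needs >= 3 instruments")
    d <- harmonizedData(h)
    sgn <- ifelse(d$beta_exposure < 0, -1, 1)
    bx <- d$beta_exposure * sgn
    by <- d$beta_outcome * sgn
    w <- 1 / d$se_outcome^2
    if (stats::sd(bx) < .Machine$double.eps^0.5 * max(abs(bx)))
        stop("exposure effects have no spread: Egger slope and intercept ",
             "are not separately identifiable")
    fit <- stats::lm.wfit(cbind(intercept = 1, slope = bx), by, w)
    coefs <- fit$coefficients
    rss <- sum(w * fit$residuals^2)
    sigma2 <- rss / (k - 2)
    XtWX_inv <- chol2inv(chol(crossprod(cbind(1, bx) * sqrt(w))))
    ses <- sqrt(diag(XtWX_inv) * max(1, sigma2))
    list(slope = .mrEstimate("egger_slope", unname(coefs["slope"]), ses[2],
                             k, df = k - 2),
         intercept = .mrEstimate("egger_intercept",
                                 unname(coefs["intercept"]), ses[1], k,
                                 df = k - 2))
}

# Weighted median of values r with weights w via the standardized
# cumulative weights s_i = (cumsum(w) - w/2) / sum(w), linearly
# interpolating r against s at s = 0.5.
.weightedMedianPoint <- function(r, w) {
    o <- order(r)
    r <- r[o]; w <- w[o]
    s <- (cumsum(w) - w / 2) / sum(w)
    if (0.5 <= s[1]) return(r[1])
    if (0.5 >= s[length(s)]) return(r[length(s)])
    stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE shared by median/mode estimators: resample
# per-SNP betas from their sampling distributions, recompute the point
# estimator, return the SD over replicates.
.bootstrapSe <- function(h, pointFun, nBoot, seed) {
    d <- harmonizedData(h)
    k <- nrow(d)
    set.seed(seed)
    bx <- matrix(stats::rnorm(nBoot * k, d$beta_exposure, d$se_exposure),
                 nrow = nBoot, byrow = TRUE)
    by <- matrix(stats::rnorm(nBoot * k, d$beta_outcome, d$se_outcome),
                 nrow = nBoot, byrow = TRUE)
    est <- vapply(seq_len(nBoot), function(i) {
        pointFun(by[i, ] / bx[i, ], d$se_outcome^2 / bx[i, ]^2)
    }, numeric(1))
    stats::sd(est)
}

#' Weighted-median estimate
#'
#' Consistent causal estimate when at least half of the weight comes from
#' valid instruments: the inverse-variance-weighted median of the per-SNP
#' Wald ratios, computed by linear interpolation of the ordered ratios
#' against standardized cumulative weights.  The standard error comes from
#' a parametric bootstrap (per-SNP betas resampled from their normal
#' sampling distributions), deterministic under `seed`.
#'
#' @param h a [HarmonizedSet-class] with at least 3 instruments.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an [MREstimate-class] with method `weighted_median`.
#' @export
mrWeightedMedian <- function(h, nBoot = 1000, seed = 1L) {
    if (nSnp(h) < 3) stop("weighted median needs >= 3 instruments")
    rt <- .ratios(h)
    beta <- .weightedMedianPoint(rt$r, 1 / rt$v)
    se <- .bootstrapSe(h, function(r, v) .weightedMedianPoint(r, 1 / v),
                       nBoot, seed)
    .mrEstimate("weighted_median", beta, se, nSnp(h))
}

# Mode of the (optionally weighted) ratio distribution via a normal-kernel
# density with a MAD-based rule-of-thumb bandwidth:
#   bw = phi * 0.9 * min(sd(r), mad(r)) * k^(-1/5)
# evaluated on a fine grid over the ratio range.
.modePoint <- function(r, w, phi) {
    if (max(r) - min(r) < .Machine$double.eps * max(1, abs(r))) return(r[1])
    spread <- min(stats::sd(r), stats::mad(r))
    if (spread == 0) spread <- stats::sd(r)
    bw <- phi * 0.9 * spread * length(r)^(-1 / 5)
    grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = 2048)
    dens <- vapply(grid, function(g)
        sum(w * stats::dnorm((g - r) / bw)), numeric(1))
    grid[which.max(dens)]
}

#' Mode-based estimate (simple and weighted)
#'
#' The mode of the per-SNP Wald-ratio distribution, estimated as the
#' maximum of a normal-kernel density with bandwidth
#' `phi * 0.9 * min(sd, mad) * k^(-1/5)`.  The simple variant weights every
#' ratio equally; the weighted variant uses inverse-variance weights.
#' Consistent when the largest group of instruments sharing a ratio value
#' is valid (ZEMPA).  Bootstrap standard error as in [mrWeightedMedian()].
#'
#' @param h a [HarmonizedSet-class] with at least 3 instruments.
#' @param variant `"weighted"` (default) or `"simple"`.
#' @param phi bandwidth multiplier (default 1).
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return an [MREstimate-class] with method `weighted_mode` or
#'   `simple_mode`.
#' @export
mrMode <- function(h, variant = c("weighted", "simple"), phi = 1,
                   nBoot = 1000, seed = 1L) {
    variant <- match.arg(variant)
    if (nSnp(h) < 3) stop("mode estimator needs >= 3 instruments")
    if (phi <= 0) stop("phi must be > 0")
    rt <- .ratios(h)
    wfun <- if (variant == "weighted") function(v) 1 / v
            else function(v) rep(1, length(v))
    beta <- .modePoint(rt$r, wfun(rt$v), phi)
    se <- .bootstrapSe(h, function(r, v) .modePoint(r, wfun(v), phi),
                       nBoot, seed)
    .mrEstimate(paste0(variant, "_mode"), beta, se, nSnp(h))
}

#' All univariable estimates for one harmonized set
#'
#' Convenience wrapper running the full estimator battery: with a single
#' instrument only the Wald ratio is defined; with two instruments both IVW
#' variants are added; with three or more the Egger slope and intercept,
#' weighted median, and the two mode estimators complete the set.
#'
#' @param h a [HarmonizedSet-class].
#' @param nBoot bootstrap replicates for median/mode (default 1000).
#' @param seed RNG seed.
#' @return named list of [MREstimate-class] objects.
#' @export
mrAllEstimates <- function(h, nBoot = 1000, seed = 1L) {
    d <- harmonizedData(h)
    k <- nrow(d)
    if (k == 1)
        return(list(wald_ratio = waldRatio(d$beta_exposure, d$se_exposure,
                                           d$beta_outcome, d$se_outcome)))
    out <- list(ivw_fe = mrIVW(h, "fixed"), ivw_mre = mrIVW(h, "mre"))
    if (k >= 3) {
        eg <- mrEgger(h)
        out$egger_slope <- eg$slope
        out$egger_intercept <- eg$intercept
        out$weighted_median <- mrWeightedMedian(h, nBoot, seed)
        out$weighted_mode <- mrMode(h, "weighted", 1, nBoot, seed)
        out$simple_mode <- mrMode(h, "simple", 1, nBoot, seed)
    }
    out
}
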