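#' @include AllClasses.R
NULL

#' Power of an MR analysis with a binary outcome
#'
#' Non-centrality-parameter power calculation for a two-sample MR study of
#' a binary outcome (the Brion-style formulation).  With case fraction K,
#' odds ratio OR per exposure unit, instrument variance explained R2 and
#' total outcome-GWAS size N:
#' \deqn{b = K (OR / (1 + K (OR - 1)) - 1)}
#' \deqn{v = (K (1 - K) - b^2) / (N R2)}
#' \deqn{NCP = b^2 / v}
#' and power is the upper-tail probability of a non-central chi-square
#' with 1 degree of freedom and non-centrality NCP beyond the central
#' 1 - alpha quantile.  At OR = 1 the NCP is 0 and power equals alpha
#' exactly; power is monotone non-decreasing in N, R2 and |log OR|.
#'
#' @param nTotal total outcome sample size N.
#' @param caseFraction case fraction K in (0, 1).
#' @param r2 instrument variance explained, in (0, 1).
#' @param oddsRatio odds ratio per exposure unit (> 0).
#' @param alpha two-sided significance level (default 0.05).
#' @return power, a proportion in [alpha, 1].
#' @export
mrPowerBinary <- function(nTotal, caseFraction, r2, oddsRatio,
                          alpha = 0.05) {
    if (caseFraction <= 0 || caseFraction >= 1)
        stop("caseFraction must lie in (0, 1)")
    if (r2 <= 0 || r2 >= 1) stop("r2 must lie in (0, 1)")
    if (oddsRatio <= 0) stop("oddsRatio must be > 0")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    if (nTotal <= 0) stop("nTotal must be > 0")
    K <- caseFraction
    b <- K * (oddsRatio / (1 + K * (oddsRatio - 1)) - 1)
    if (b == 0) return(alpha)      # null effect: NCP = 0, power = alpha
    v <- (K * (1 - K) - b^2) / (nTotal * r2)
    if (v <= 0) return(1)
    ncp <- b^2 / v
    crit <- stats::qchisq(1 - alpha, df = 1)
    stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}
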