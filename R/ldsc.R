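#' @include AllClasses.R
NULL

# Weighted simple linear regression y ~ 1 + x via per-block sufficient
# statistics, enabling O(1) delete-one-block jackknife refits.
# Returns function(drop) -> c(intercept, slope); drop = 0 keeps all blocks.
.blockWLS <- function(x, y, w, blocks) {
    agg <- function(v) as.numeric(tapply(v, blocks, sum))
    sw <- agg(w); swx <- agg(w * x); swy <- agg(w * y)
    swxx <- agg(w * x * x); swxy <- agg(w * x * y)
    function(drop = 0L) {
        keep <- if (drop == 0L) seq_along(sw) else seq_along(sw)[-drop]
        SW <- sum(sw[keep]); SWX <- sum(swx[keep]); SWY <- sum(swy[keep])
        SWXX <- sum(swxx[keep]); SWXY <- sum(swxy[keep])
        det <- SW * SWXX - SWX^2
        slope <- (SW * SWXY - SWX * SWY) / det
        intercept <- (SWY - slope * SWX) / SW
        c(intercept = intercept, slope = slope)
    }
}

.jackknifeSe <- function(thetas) {
    B <- length(thetas)
    sqrt((B - 1) / B * sum((thetas - mean(thetas))^2))
}

.resolveBlocks <- function(mv, nBlocks) {
    while (mv < 2 * nBlocks && nBlocks > 2) nBlocks <- floor(mv / 2)
    if (mv < nBlocks || nBlocks < 2)
        stop("too few variants for ", nBlocks, " jackknife blocks")
    nBlocks
}

# Two-pass heteroskedasticity + oversampling weights for the univariate
# regression of z^2 on n*l/m: w = 1/l * 1/(2 (1 + n h2 l / m)^2),
# with h2 = 0 on the first pass and the first-pass slope on the second.
# Returns the second-pass fit closure plus the first-pass slope (reused by
# the cross-trait weights).
.h2Fit <- function(z, n, ell, m, blocks) {
    x <- n * ell / m
    y <- z^2
    wgt <- function(h2) 1 / pmax(ell, 1) /
        (2 * (1 + n * pmax(h2, 0) * ell / m)^2)
    f1 <- .blockWLS(x, y, wgt(0), blocks)
    h2_pass1 <- f1()[["slope"]]
    list(fit = .blockWLS(x, y, wgt(h2_pass1), blocks),
         h2_pass1 = h2_pass1)
}

#' SNP heritability by LD score regression
#'
#' Regresses per-variant chi-square statistics (z^2) on `n * l / m` with a
#' free intercept; under the polygenic model E[z^2] = 1 + n h2 l / m, so
#' the slope estimates h2 and the intercept (expected 1) absorbs
#' confounding.  Weights combine the 1/l oversampling correction with the
#' heteroskedasticity weight 1/(2 (1 + n h2 l/m)^2), applied in two passes
#' (first pass h2 = 0, second pass the first-pass slope).  Uncertainty by
#' delete-one block jackknife over `nBlocks` contiguous variant blocks
#' (reduced automatically when fewer than `2 * nBlocks` variants).
#'
#' @param z per-variant z-scores.
#' @param n GWAS sample size.
#' @param ldScores per-variant LD scores l (aligned with `z`).
#' @param m total variant count in the reference (defaults to
#'   `length(z)`).
#' @param nBlocks jackknife blocks (default 200).
#' @return list with `h2`, `h2_se`, `intercept`, `intercept_se`,
#'   `n_blocks`, `degenerate` (TRUE when the LD scores are constant and
#'   slope/intercept are not separately identifiable).
#' @export
estimateH2 <- function(z, n, ldScores, m = length(z), nBlocks = 200) {
    mv <- length(z)
    stopifnot(length(ldScores) == mv)
    nBlocks <- .resolveBlocks(mv, nBlocks)
    if (stats::sd(ldScores) < 1e-12) {
        warning("constant LD scores: h2 not identifiable from the intercept")
        return(list(h2 = NA_real_, h2_se = NA_real_, intercept = NA_real_,
                    intercept_se = NA_real_, n_blocks = nBlocks,
                    degenerate = TRUE))
    }
    blocks <- ceiling(seq_len(mv) / (mv / nBlocks))
    fit <- .h2Fit(z, n, ldScores, m, blocks)$fit
    full <- fit()
    jk <- vapply(seq_len(nBlocks), function(b) fit(b), numeric(2))
    list(h2 = unname(full[["slope"]]),
         h2_se = .jackknifeSe(jk[2, ]),
         intercept = unname(full[["intercept"]]),
         intercept_se = .jackknifeSe(jk[1, ]),
         n_blocks = nBlocks, degenerate = FALSE)
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Bivariate LDSC: regresses the per-variant z-score product on
#' `sqrt(n1 n2) l / m` with a free intercept (which absorbs sample
#' overlap); the slope estimates the genetic covariance, and
#' `rg = cov_g / sqrt(h2_1 h2_2)` with the univariate heritabilities from
#' the same two-pass fits as [estimateH2()].  Cross-regression weights are
#' `1/l * 1/(v1 v2)` with `v_i = 1 + n_i h2_i l / m` from each trait's
#' first-pass heritability — proportional to the univariate second-pass
#' weights when the two traits coincide, so a trait against itself returns
#' exactly rg = 1.  The standard error and p-value come from a delete-one
#' block jackknife of the full ratio statistic (heritabilities and
#' covariance refitted per deleted block).  `rg` is clamped to [-1, 1]
#' with a flag; non-positive heritability makes `rg` undefined and sets
#' the degenerate flag instead of reporting a number.
#'
#' @param z1,z2 per-variant z-scores of the two traits on the same variant
#'   universe, same order.
#' @param n1,n2 the two GWAS sample sizes.
#' @param ldScores per-variant LD scores.
#' @param m total variant count (defaults to `length(z1)`).
#' @param nBlocks jackknife blocks (default 200).
#' @return an [LDSCResult-class].
#' @export
estimateRg <- function(z1, z2, n1, n2, ldScores, m = length(z1),
                       nBlocks = 200) {
    mv <- length(z1)
    stopifnot(length(z2) == mv, length(ldScores) == mv)
    nBlocks <- .resolveBlocks(mv, nBlocks)
    blocks <- ceiling(seq_len(mv) / (mv / nBlocks))
    ell <- ldScores

    u1 <- .h2Fit(z1, n1, ell, m, blocks)
    u2 <- .h2Fit(z2, n2, ell, m, blocks)
    fit1 <- u1$fit; fit2 <- u2$fit
    h2_1 <- fit1()[["slope"]]; h2_2 <- fit2()[["slope"]]

    # cross regression; variance weights 1/l * 1/(v1 v2) built from each
    # trait's first-pass heritability, so that estimateRg(t, t) reduces to
    # exactly the univariate fit (weights proportional) and rg(t, t) = 1
    x <- sqrt(n1 * n2) * ell / m
    y <- z1 * z2
    v1 <- 1 + n1 * pmax(u1$h2_pass1, 0) * ell / m
    v2 <- 1 + n2 * pmax(u2$h2_pass1, 0) * ell / m
    fitc <- .blockWLS(x, y, 1 / pmax(ell, 1) / (v1 * v2), blocks)
    fullc <- fitc()
    covg <- fullc[["slope"]]

    h2_jk1 <- vapply(seq_len(nBlocks), function(b) fit1(b)[["slope"]],
                     numeric(1))
    h2_jk2 <- vapply(seq_len(nBlocks), function(b) fit2(b)[["slope"]],
                     numeric(1))
    covg_jk <- vapply(seq_len(nBlocks), function(b) fitc(b)[["slope"]],
                      numeric(1))

    res <- new("LDSCResult", h2_1 = h2_1, h2_1_se = .jackknifeSe(h2_jk1),
               h2_2 = h2_2, h2_2_se = .jackknifeSe(h2_jk2),
               intercept1 = fit1()[["intercept"]],
               intercept2 = fit2()[["intercept"]],
               interceptCross = fullc[["intercept"]],
               nBlocks = as.integer(nBlocks))
    if (h2_1 <= 0 || h2_2 <= 0) {
        res@degenerate <- TRUE
        warning("non-positive heritability estimate: rg undefined")
        return(res)
    }
    rg_raw <- covg / sqrt(h2_1 * h2_2)
    ok <- h2_jk1 > 0 & h2_jk2 > 0
    rg_jk <- covg_jk[ok] / sqrt(h2_jk1[ok] * h2_jk2[ok])
    rg_se <- .jackknifeSe(rg_jk)
    res@rg <- max(-1, min(1, rg_raw))
    res@rgClamped <- abs(rg_raw) > 1
    res@rgSe <- rg_se
    res@rgPval <- if (rg_se > 0) 2 * stats::pnorm(-abs(rg_raw / rg_se))
                  else as.numeric(rg_raw == 0)
    res
}
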