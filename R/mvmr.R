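#' @include harmonization.R mr-estimators.R instruments.R
NULL

#' Joint instrument selection for multivariable MR
#'
#' Takes the union of each exposure's genome-wide-significant variants and
#' jointly LD-clumps it, ranking candidates by the minimum p-value across
#' exposures (position and snp_id as deterministic tie-breaks).
#'
#' @param exposures list of [SummaryStats-class] objects (>= 2).
#' @param ld an [LDReference-class].
#' @param pThreshold,r2Max,windowKb selection thresholds (defaults 5e-8,
#'   0.001, 10000).
#' @return character vector of snp_ids.
#' @export
mvmrSelectInstruments <- function(exposures, ld, pThreshold = 5e-8,
                                  r2Max = 0.001, windowKb = 10000) {
    if (length(exposures) < 2) stop("need at least 2 exposures")
    sig <- unique(unlist(lapply(exposures, selectSignificant, pThreshold)))
    if (!length(sig)) stop("no variant reaches significance in any exposure")
    # min p across exposures (and a position) for the joint ranking
    minp <- rep(Inf, length(sig))
    chrom <- rep(NA_character_, length(sig))
    pos <- rep(NA_integer_, length(sig))
    for (ex in exposures) {
        v <- variants(ex)
        i <- match(sig, v$snp_id)
        hit <- !is.na(i)
        minp[hit] <- pmin(minp[hit], v$pval[i[hit]])
        fill <- hit & is.na(chrom)
        chrom[fill] <- v$chrom[i[fill]]
        pos[fill] <- v$pos[i[fill]]
    }
    pool <- SummaryStats(data.frame(
        snp_id = sig, chrom = chrom, pos = pos,
        effect_allele = "A", other_allele = "G", eaf = NA_real_,
        beta = 1, se = 1, pval = minp, n = NA_real_,
        stringsAsFactors = FALSE), traitName = "mvmr_pool")
    ldClump(sig, pool, ld, r2Max = r2Max, windowKb = windowKb)
}

#' Harmonize several exposures and one outcome
#'
#' Aligns every exposure and the outcome to the first exposure's
#' effect-allele orientation by pairwise harmonization against it; a
#' variant must survive in every dataset to be retained.
#'
#' @param instrumentIds character vector of snp_ids.
#' @param exposures named list of [SummaryStats-class] objects.
#' @param outcome a [SummaryStats-class].
#' @param ... passed to [harmonize()] (palindrome policy etc.).
#' @return an [MVHarmonizedSet-class].
#' @export
harmonizeMV <- function(instrumentIds, exposures, outcome, ...) {
    if (is.null(names(exposures)) || any(!nzchar(names(exposures))))
        names(exposures) <- vapply(exposures, traitName, character(1))
    ref <- exposures[[1]]
    tabs <- lapply(exposures, function(ex) {
        h <- harmonize(instrumentIds, ref, ex, ...)
        d <- harmonizedData(h)
        data.frame(snp_id = d$snp_id, beta = d$beta_outcome,
                   se = d$se_outcome, stringsAsFactors = FALSE)
    })
    hy <- harmonize(instrumentIds, ref, outcome, ...)
    dy <- harmonizedData(hy)
    keep <- Reduce(intersect, c(lapply(tabs, `[[`, "snp_id"),
                                list(dy$snp_id)))
    if (length(keep) < length(exposures) + 2)
        stop("too few jointly harmonized variants for MVMR")
    out <- data.frame(snp_id = keep, stringsAsFactors = FALSE)
    for (nm in names(exposures)) {
        t <- tabs[[nm]]
        i <- match(keep, t$snp_id)
        out[[paste0("beta_", nm)]] <- t$beta[i]
        out[[paste0("se_", nm)]] <- t$se[i]
    }
    i <- match(keep, dy$snp_id)
    out$beta_outcome <- dy$beta_outcome[i]
    out$se_outcome <- dy$se_outcome[i]
    new("MVHarmonizedSet", data = out, exposures = names(exposures),
        outcomeName = traitName(outcome))
}

#' Multivariable IVW regression
#'
#' Weighted multiple regression of the outcome effects on the matrix of
#' exposure effects with no intercept (weights 1/se_y^2).  Per-exposure
#' slopes are the direct (conditional) causal effects; standard errors
#' carry the multiplicative random-effects inflation
#' sqrt(max(1, RSS/(rows - exposures))).  Per-exposure instrument-strength
#' diagnostics (the Wald chi-square (slope/se)^2 from the same weighted
#' fit) are attached as attribute `conditional_f`.
#'
#' @param m an [MVHarmonizedSet-class].
#' @return named list of [MREstimate-class] objects, one per exposure, in
#'   the exposure order of `m`.
#' @export
mvmrIVW <- function(m) {
    validObject(m)
    d <- harmonizedData(m)
    p <- length(m@exposures)
    k <- nrow(d)
    if (k < p + 2) stop("need at least (exposures + 2) variants")
    X <- as.matrix(d[paste0("beta_", m@exposures)])
    y <- d$beta_outcome
    w <- 1 / d$se_outcome^2
    # an exposure with all-zero effects carries no information: direct
    # effect 0 by convention, excluded from the fit
    zero_col <- colSums(X != 0) == 0L
    Xa <- X[, !zero_col, drop = FALSE]
    pa <- ncol(Xa)
    if (pa == 0) stop("all exposure effects are zero")
    if (qr(Xa * sqrt(w))$rank < pa) {
        cors <- abs(suppressWarnings(stats::cor(Xa)))
        diag(cors) <- 0
        cors[is.na(cors)] <- 1
        worst <- which(cors == max(cors), arr.ind = TRUE)[1, ]
        nm <- colnames(Xa)
        stop("collinear exposures: ", sub("^beta_", "", nm[worst[1]]),
             " vs ", sub("^beta_", "", nm[worst[2]]))
    }
    fit <- stats::lm.wfit(Xa, y, w)
    rss <- sum(w * fit$residuals^2)
    df <- k - pa
    sigma2 <- max(1, rss / df)
    XtWX_inv <- chol2inv(chol(crossprod(Xa * sqrt(w))))
    ses_a <- sqrt(diag(XtWX_inv) * sigma2)
    beta_full <- ses_full <- stats::setNames(numeric(p), m@exposures)
    beta_full[!zero_col] <- fit$coefficients
    ses_full[!zero_col] <- ses_a
    ses_full[zero_col] <- Inf
    est <- lapply(seq_len(p), function(j)
        .mrEstimate("mvmr_ivw", unname(beta_full[j]), unname(ses_full[j]),
                    k))
    names(est) <- m@exposures
    attr(est, "conditional_f") <-
        stats::setNames(unname((beta_full / ses_full)^2), m@exposures)
    est
}
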