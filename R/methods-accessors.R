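#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("variants", "SummaryStats", function(x) x@variants)

#' @rdname accessors
setMethod("variants", "LDReference", function(x) x@variants)

#' @rdname accessors
setMethod("traitName", "SummaryStats", function(x) x@traitName)

#' @rdname accessors
setMethod("sampleN", "SummaryStats", function(x) x@sampleN)

#' @rdname accessors
setMethod("isBinary", "SummaryStats", function(x) x@isBinary)

#' @rdname accessors
setMethod("nSnp", "SummaryStats", function(x) nrow(x@variants))

#' @rdname accessors
setMethod("nSnp", "HarmonizedSet", function(x) nrow(x@data))

#' @rdname accessors
setMethod("nSnp", "MVHarmonizedSet", function(x) nrow(x@data))

#' @rdname accessors
setMethod("nSnp", "MREstimate", function(x) x@nSnp)

#' @rdname accessors
setMethod("harmonizedData", "HarmonizedSet", function(x) x@data)

#' @rdname accessors
setMethod("harmonizedData", "MVHarmonizedSet", function(x) x@data)

#' @rdname accessors
setMethod("exclusions", "HarmonizedSet", function(x) x@exclusions)

#' @rdname accessors
setMethod("ldScores", "LDReference", function(x) {
    stats::setNames(x@variants$ld_score, x@variants$snp_id)
})

setMethod("ldR2", "LDReference", function(ld, a, b) {
    n <- max(length(a), length(b))
    a <- rep_len(as.character(a), n)
    b <- rep_len(as.character(b), n)
    known <- ld@variants$snp_id
    out <- numeric(n)
    out[!(a %in% known) | !(b %in% known)] <- NA_real_
    out[a == b & !is.na(out)] <- 1
    todo <- which(a != b & !is.na(out))
    if (length(todo)) {
        tbl <- .ldPairTable(ld)
        k1 <- paste(a[todo], b[todo], sep = "\r")
        k2 <- paste(b[todo], a[todo], sep = "\r")
        hit <- tbl[k1]
        miss <- is.na(hit)
        hit[miss] <- tbl[k2[miss]]
        hit[is.na(hit)] <- 0
        out[todo] <- unname(hit)
    }
    out
})

# Named-vector lookup for the sparse pair table.
.ldPairTable <- function(ld) {
    p <- ld@r2pairs
    stats::setNames(p$r2, paste(p$snp_a, p$snp_b, sep = "\r"))
}

setMethod("show", "SummaryStats", function(object) {
    cat(sprintf("SummaryStats '%s': %d variants, %s\n",
                object@traitName, nrow(object@variants),
                if (object@isBinary)
                    sprintf("binary (%s cases / %s controls)",
                            format(object@nCase, big.mark = ","),
                            format(object@nControl, big.mark = ","))
                else sprintf("continuous (n = %s)",
                             format(object@sampleN, big.mark = ","))))
    if (nrow(object@variants))
        print(utils::head(object@variants, 3L))
})

setMethod("show", "LDReference", function(object) {
    cat(sprintf("LDReference: %d variants, %d stored r2 pairs\n",
                nrow(object@variants), nrow(object@r2pairs)))
})

setMethod("show", "HarmonizedSet", function(object) {
    cat(sprintf("HarmonizedSet: %s -> %s, %d variants (%d excluded)\n",
                object@exposureName, object@outcomeName,
                nrow(object@data), nrow(object@exclusions)))
})

setMethod("show", "MREstimate", function(object) {
    cat(sprintf(
        "MREstimate [%s] beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, OR = %.3f, nSnp = %d\n",
        object@method, object@beta, object@se, object@ciLow, object@ciHigh,
        object@pval, exp(object@beta), object@nSnp))
})

setMethod("show", "PressoReport", function(object) {
    cat(sprintf("MR-PRESSO: global p = %.4g; %d/%d outlier(s) flagged",
                object@globalPval, sum(object@outlierFlags),
                length(object@outlierFlags)))
    if (any(object@outlierFlags))
        cat(sprintf("; distortion p = %.4g", object@distortionPval))
    cat("\n")
})

setMethod("show", "LDSCResult", function(object) {
    cat(sprintf("LDSC: h2_1 = %.4f (se %.4f), intercept %.3f\n",
                object@h2_1, object@h2_1_se, object@intercept1))
    if (!is.na(object@h2_2))
        cat(sprintf("      h2_2 = %.4f (se %.4f), intercept %.3f\n",
                    object@h2_2, object@h2_2_se, object@intercept2))
    if (!is.na(object@rg))
        cat(sprintf("      rg = %.4f (se %.4f), p = %.3g%s\n",
                    object@rg, object@rgSe, object@rgPval,
                    if (object@rgClamped) " [clamped]" else ""))
    if (object@degenerate)
        cat("      rg undefined (non-positive heritability)\n")
})

#' Collect MREstimate objects into a results table
#'
#' Serializes a list of [MREstimate-class] objects to the delimited results
#' layout used in forest-plot style reporting: method, instrument count,
#' effect and 95\% CI on the log-odds scale, p-value, and the odds-ratio
#' view (exp of effect and CI bounds).
#'
#' @param estimates list of [MREstimate-class] objects.
#' @return data.frame with columns `method`, `n_snp`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `or_value`, `or_low`, `or_high`.
#' @export
estimateTable <- function(estimates) {
    if (is(estimates, "MREstimate")) estimates <- list(estimates)
    do.call(rbind, lapply(estimates, function(e) {
        data.frame(method = e@method, n_snp = e@nSnp, beta = e@beta,
                   se = e@se, ci_low = e@ciLow, ci_high = e@ciHigh,
                   pval = e@pval, or_value = exp(e@beta),
                   or_low = exp(e@ciLow), or_high = exp(e@ciHigh),
                   stringsAsFactors = FALSE)
    }))
}

# Internal constructor: normal-theory CI/p around (beta, se).
.mrEstimate <- function(method, beta, se, nSnp, pval = NULL, df = NULL) {
    z <- if (is.null(df)) stats::qnorm(0.975) else stats::qt(0.975, df)
    if (is.null(pval)) {
        pval <- if (is.null(df)) 2 * stats::pnorm(-abs(beta / se))
                else 2 * stats::pt(-abs(beta / se), df)
    }
    pval <- max(min(pval, 1), .Machine$double.xmin)
    new("MREstimate", method = method, beta = beta, se = se,
        ciLow = beta - z * se, ciHigh = beta + z * se,
        pval = pval, nSnp = as.integer(nSnp))
}
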