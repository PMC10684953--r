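#' @include sumstats-io.R
NULL

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize exposure and outcome effects to a shared effect allele
#'
#' For every instrument present in both datasets, aligns the outcome effect
#' to the exposure's effect-allele orientation:
#' \itemize{
#'   \item same allele pair, same orientation: kept as-is;
#'   \item same pair, swapped orientation: outcome beta negated, outcome
#'     eaf replaced by 1 - eaf;
#'   \item pair matches only after strand complement (A<->T, C<->G): the
#'     outcome alleles are complemented, then the two rules above apply;
#'   \item palindromic variants (A/T, C/G): strand cannot be resolved from
#'     alleles.  Under policy `"infer"`, the variant is kept when both
#'     effect-allele frequencies are on the same side of 0.5 and both lie
#'     outside the ambiguity zone; otherwise dropped.  Policy `"drop"`
#'     always drops palindromic variants.
#'   \item irreconcilable allele pairs (or alleles outside A/C/G/T, i.e.
#'     indels/multi-allelic rows): dropped.
#' }
#' Instruments absent from the outcome are dropped, or replaced by a proxy
#' in high LD when `ld` is supplied and `useProxies = TRUE`.  Every dropped
#' instrument is recorded with its reason in the exclusion audit, so that
#' retained rows + exclusions = input instruments.
#'
#' @param instruments character vector of snp_ids (from the exposure).
#' @param exposure,outcome [SummaryStats-class] objects.
#' @param palindromePolicy `"infer"` (default) or `"drop"`.
#' @param ambiguityZone eaf interval treated as unresolvable for
#'   palindromic inference (default `c(0.42, 0.58)`).
#' @param useProxies replace outcome-missing instruments by LD proxies
#'   (default FALSE, the primary-analysis behaviour).
#' @param ld [LDReference-class], needed when `useProxies = TRUE`.
#' @param proxyR2Min minimum (exclusive) proxy r-squared (default 0.8).
#' @return a [HarmonizedSet-class].
#' @export
harmonize <- function(instruments, exposure, outcome,
                      palindromePolicy = c("infer", "drop"),
                      ambiguityZone = c(0.42, 0.58),
                      useProxies = FALSE, ld = NULL, proxyR2Min = 0.8) {
    palindromePolicy <- match.arg(palindromePolicy)
    if (!length(instruments)) stop("no instruments supplied")
    vx <- variants(exposure)
    vy <- variants(outcome)
    rows <- vector("list", length(instruments))
    excl <- list()
    dropRow <- function(id, reason)
        data.frame(snp_id = id, reason = reason, stringsAsFactors = FALSE)
    base <- c("A", "C", "G", "T")

    for (i in seq_along(instruments)) {
        id <- instruments[[i]]
        ex <- vx[vx$snp_id == id, , drop = FALSE]
        if (nrow(ex) != 1L) {
            excl[[length(excl) + 1L]] <- dropRow(id, "absent from exposure")
            next
        }
        oid <- id
        if (!oid %in% vy$snp_id) {
            if (useProxies && !is.null(ld)) {
                proxy <- findProxy(id, vy$snp_id, ld, r2Min = proxyR2Min)
                if (is.na(proxy)) {
                    excl[[length(excl) + 1L]] <-
                        dropRow(id, "absent from outcome (no proxy)")
                    next
                }
                oid <- proxy
            } else {
                excl[[length(excl) + 1L]] <- dropRow(id, "absent from outcome")
                next
            }
        }
        oy <- vy[vy$snp_id == oid, , drop = FALSE][1, ]
        ea_x <- ex$effect_allele; oa_x <- ex$other_allele
        ea_y <- oy$effect_allele; oa_y <- oy$other_allele
        if (!all(c(ea_x, oa_x, ea_y, oa_y) %in% base)) {
            excl[[length(excl) + 1L]] <- dropRow(id, "indel/multi-allelic")
            next
        }
        pal <- unname(.COMPLEMENT[ea_x] == oa_x)
        if (pal) {
            if (palindromePolicy == "drop") {
                excl[[length(excl) + 1L]] <- dropRow(id, "palindromic (policy drop)")
                next
            }
            # palindromic: alleles can never distinguish strand; use eaf
            if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
                excl[[length(excl) + 1L]] <- dropRow(id, "allele mismatch")
                next
            }
            fx <- ex$eaf
            fy <- if (ea_y == ea_x) oy$eaf else 1 - oy$eaf
            if (is.na(fx) || is.na(fy) ||
                (fx >= ambiguityZone[1] && fx <= ambiguityZone[2]) ||
                (fy >= ambiguityZone[1] && fy <= ambiguityZone[2])) {
                excl[[length(excl) + 1L]] <- dropRow(id, "palindromic ambiguous")
                next
            }
            if ((fx - 0.5) * (fy - 0.5) > 0) {
                flip <- ea_y != ea_x        # same strand reading
            } else {
                # frequencies on opposite sides: the outcome is reported on
                # the other strand, which for a palindrome swaps the alleles
                flip <- ea_y == ea_x
            }
        } else {
            if (setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
                flip <- ea_y != ea_x
            } else {
                cy <- unname(.COMPLEMENT[c(ea_y, oa_y)])
                if (setequal(cy, c(ea_x, oa_x))) {
                    ea_y <- cy[1]
                    flip <- ea_y != ea_x
                } else {
                    excl[[length(excl) + 1L]] <- dropRow(id, "allele mismatch")
                    next
                }
            }
        }
        beta_y <- if (flip) -oy$beta else oy$beta
        eaf_y <- if (flip) 1 - oy$eaf else oy$eaf
        rows[[i]] <- data.frame(
            snp_id = id,
            beta_exposure = ex$beta, se_exposure = ex$se,
            beta_outcome = beta_y, se_outcome = oy$se,
            eaf_exposure = ex$eaf, eaf_outcome = eaf_y,
            pval_exposure = ex$pval, pval_outcome = oy$pval,
            stringsAsFactors = FALSE)
    }
    dat <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    exclusions <- if (length(excl)) do.call(rbind, excl)
                  else data.frame(snp_id = character(), reason = character(),
                                  stringsAsFactors = FALSE)
    if (is.null(dat) || !nrow(dat))
        stop("harmonization dropped every instrument (",
             paste(exclusions$reason, collapse = "; "), ")")
    rownames(dat) <- NULL
    K <- if (isBinary(outcome)) outcome@nCase / outcome@sampleN else NA_real_
    new("HarmonizedSet", data = dat,
        exposureName = traitName(exposure), outcomeName = traitName(outcome),
        outcomeIsBinary = isBinary(outcome),
        nExposure = sampleN(exposure), nOutcome = sampleN(outcome),
        outcomeCaseFraction = K, exclusions = exclusions)
}

#' Subset a HarmonizedSet by row
#'
#' @param x a [HarmonizedSet-class].
#' @param i logical or integer row index.
#' @return a [HarmonizedSet-class] with the selected rows.
#' @export
subsetHarmonized <- function(x, i) {
    x@data <- x@data[i, , drop = FALSE]
    rownames(x@data) <- NULL
    validObject(x)
    x
}
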