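#' @include methods-accessors.R
NULL

#' Instrument strength: per-variant F-statistic
#'
#' F = beta^2 / se^2, the conventional single-SNP instrument-strength
#' statistic; F > 10 is the usual weak-instrument cut-off.
#'
#' @param beta,se per-allele effect and its standard error (vectorised).
#' @return numeric vector of F-statistics.
#' @export
fStatistic <- function(beta, se) {
    if (any(se <= 0)) stop("se must be > 0")
    beta^2 / se^2
}

#' Variance explained by one variant
#'
#' R2 = 2 * MAF * (1 - MAF) * beta^2, with `beta` on a standardized-trait
#' scale (caller's responsibility).  Total instrument R2 is the sum over
#' instruments.  Fold effect-allele frequencies above 0.5 to 1 - eaf before
#' calling.
#'
#' @param maf minor allele frequency in (0, 0.5].
#' @param beta standardized per-allele effect.
#' @return numeric vector of variance-explained proportions.
#' @export
varianceExplained <- function(maf, beta) {
    if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
    2 * maf * (1 - maf) * beta^2
}

#' Genome-wide significant variants
#'
#' Variants with p strictly below the threshold, sorted by ascending
#' p-value with lexicographic snp_id as the deterministic tie-break.
#'
#' @param stats a [SummaryStats-class].
#' @param pThreshold significance threshold (default 5e-8).
#' @return character vector of snp_ids (possibly empty).
#' @export
selectSignificant <- function(stats, pThreshold = 5e-8) {
    stopifnot(pThreshold > 0, pThreshold < 1)
    v <- variants(stats)
    hit <- v[!is.na(v$pval) & v$pval < pThreshold, , drop = FALSE]
    hit$snp_id[order(hit$pval, hit$snp_id)]
}

#' Greedy LD clumping
#'
#' Standard p-value-ranked greedy clumping: repeatedly take the
#' lowest-p remaining candidate as an index variant, then remove every
#' remaining candidate on the same chromosome within `windowKb` of it whose
#' r-squared against it is at least `r2Max`.  Ties on p keep the smaller
#' genomic coordinate, then the lexicographically smaller snp_id.
#' Candidates absent from the LD reference are treated as independent and
#' reported in the `logged` attribute.
#'
#' @param candidates character vector of snp_ids, a subset of `stats`.
#' @param stats the [SummaryStats-class] carrying p-values and positions.
#' @param ld an [LDReference-class].
#' @param r2Max removal threshold on r-squared (default 0.001).
#' @param windowKb half-window in kb around each index variant
#'   (default 10000).
#' @return character vector of index snp_ids in selection order; attribute
#'   `logged` lists candidates missing from the LD reference.
#' @export
ldClump <- function(candidates, stats, ld, r2Max = 0.001, windowKb = 10000) {
    v <- variants(stats)
    if (!all(candidates %in% v$snp_id))
        stop("candidates must be a subset of the summary statistics")
    tab <- v[match(candidates, v$snp_id),
             c("snp_id", "chrom", "pos", "pval"), drop = FALSE]
    in_ref <- tab$snp_id %in% variants(ld)$snp_id
    missing_ref <- tab$snp_id[!in_ref]
    ord <- order(tab$pval, tab$pos, tab$snp_id)
    tab <- tab[ord, , drop = FALSE]
    kept <- character()
    while (nrow(tab)) {
        idx <- tab[1, ]
        kept <- c(kept, idx$snp_id)
        tab <- tab[-1, , drop = FALSE]
        if (!nrow(tab)) break
        near <- !is.na(tab$chrom) & !is.na(idx$chrom) &
            tab$chrom == idx$chrom &
            abs(tab$pos - idx$pos) <= windowKb * 1000
        if (any(near)) {
            r2 <- ldR2(ld, idx$snp_id, tab$snp_id[near])
            r2[is.na(r2)] <- 0        # absent from reference: independent
            drop <- near
            drop[near] <- r2 >= r2Max
            tab <- tab[!drop, , drop = FALSE]
        }
    }
    attr(kept, "logged") <- missing_ref
    kept
}

#' Proxy variant lookup
#'
#' Among `available` variants with r-squared strictly above `r2Min` against
#' `target`, returns the one with the highest r-squared; ties break to the
#' nearest genomic position, then lexicographic snp_id.  Returns `NA` when
#' nothing qualifies or the target is absent from the reference.
#'
#' @param target snp_id to proxy.
#' @param available character vector of candidate snp_ids.
#' @param ld an [LDReference-class].
#' @param r2Min minimum (exclusive) r-squared (default 0.8).
#' @return a single snp_id, or `NA_character_`.
#' @export
findProxy <- function(target, available, ld, r2Min = 0.8) {
    vref <- variants(ld)
    if (!target %in% vref$snp_id) {
        warning("proxy target absent from LD reference: ", target)
        return(NA_character_)
    }
    available <- setdiff(intersect(available, vref$snp_id), target)
    if (!length(available)) return(NA_character_)
    r2 <- ldR2(ld, target, available)
    ok <- which(!is.na(r2) & r2 > r2Min)
    if (!length(ok)) return(NA_character_)
    pos <- vref$pos[match(available[ok], vref$snp_id)]
    tpos <- vref$pos[match(target, vref$snp_id)]
    pick <- order(-r2[ok], abs(pos - tpos), available[ok])[1]
    available[ok][pick]
}

#' Compose the instrument-selection filters
#'
#' Applies, in order: genome-wide significance, greedy LD clumping, and the
#' weak-instrument F filter (keep F strictly above `fMin`).  Steiger
#' filtering needs outcome data and therefore runs later, after
#' harmonization.  The audit log records the count removed at each stage so
#' the selection chain is conservative (input = output + removals).
#'
#' @param stats exposure [SummaryStats-class].
#' @param ld an [LDReference-class].
#' @param pThreshold,r2Max,windowKb,fMin filter thresholds (defaults 5e-8,
#'   0.001, 10000 kb, 10).
#' @return list with `instruments` (character vector), `metrics`
#'   (data.frame: snp_id, f_stat, r2_explained, passed_filters) and `audit`
#'   (named integer vector of per-stage removal counts).
#' @export
applyInstrumentFilters <- function(stats, ld, pThreshold = 5e-8,
                                   r2Max = 0.001, windowKb = 10000,
                                   fMin = 10) {
    v <- variants(stats)
    sig <- selectSignificant(stats, pThreshold)
    clumped <- ldClump(sig, stats, ld, r2Max = r2Max, windowKb = windowKb)
    rows <- v[match(clumped, v$snp_id), , drop = FALSE]
    f <- fStatistic(rows$beta, rows$se)
    keep <- f > fMin
    instruments <- clumped[keep]
    audit <- c(not_significant = nrow(v) - length(sig),
               clumped = length(sig) - length(clumped),
               weak_f = sum(!keep))
    if (!length(instruments))
        stop("no instruments survive the selection filters ",
             "(stage counts: ", paste(names(audit), audit, sep = "=",
                                      collapse = ", "), ")")
    maf <- pmin(rows$eaf, 1 - rows$eaf)
    r2 <- ifelse(!is.na(maf) & maf > 0,
                 varianceExplained(pmax(pmin(maf, 0.5), 1e-12), rows$beta),
                 NA_real_)
    metrics <- data.frame(snp_id = clumped, f_stat = f, r2_explained = r2,
                          passed_filters = ifelse(keep,
                                                  "significance;clump;f_stat",
                                                  "significance;clump"),
                          stringsAsFactors = FALSE)
    list(instruments = instruments, metrics = metrics, audit = audit)
}
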