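#' @include sensitivity.R mvmr.R power.R
NULL

#' Run configuration for the MR pipeline
#'
#' Bundles every threshold and budget of the analysis: instrument
#' selection (significance threshold, clumping r-squared and window,
#' minimum F), proxy lookup (disabled by default: the primary analysis
#' uses no proxies, but criterion-style proxy search can be enabled),
#' harmonization palindrome policy, estimator bootstrap sizes, MR-PRESSO
#' simulation count, and the global seed.
#'
#' @param pThreshold genome-wide significance threshold (default 5e-8,
#'   strict inequality).
#' @param r2Max clumping r-squared threshold (default 0.001).
#' @param windowKb clumping half-window in kb (default 10000).
#' @param fMin weak-instrument F cut-off (default 10, strict inequality).
#' @param useProxies enable LD-proxy lookup for outcome-missing
#'   instruments (default FALSE).
#' @param proxyR2Min minimum proxy r-squared (default 0.8).
#' @param palindromePolicy `"infer"` or `"drop"` (default `"infer"`).
#' @param steigerFilter drop instruments explaining more outcome than
#'   exposure variance (default TRUE).
#' @param nBoot bootstrap replicates for median/mode (default 1000).
#' @param pressoNSim MR-PRESSO simulations (default 1000).
#' @param alpha nominal two-sided level (default 0.05).
#' @param seed global RNG seed, recorded in every report.
#' @return a list of class `mrRunConfig`.
#' @export
mrRunConfig <- function(pThreshold = 5e-8, r2Max = 0.001, windowKb = 10000,
                        fMin = 10, useProxies = FALSE, proxyR2Min = 0.8,
                        palindromePolicy = "infer", steigerFilter = TRUE,
                        nBoot = 1000, pressoNSim = 1000, alpha = 0.05,
                        seed = 1L) {
    stopifnot(pThreshold > 0, pThreshold < 1, r2Max >= 0, r2Max <= 1,
              windowKb > 0, fMin >= 0, proxyR2Min > 0, proxyR2Min <= 1,
              alpha > 0, alpha < 1)
    structure(list(pThreshold = pThreshold, r2Max = r2Max,
                   windowKb = windowKb, fMin = fMin,
                   useProxies = useProxies, proxyR2Min = proxyR2Min,
                   palindromePolicy = palindromePolicy,
                   steigerFilter = steigerFilter, nBoot = nBoot,
                   pressoNSim = pressoNSim, alpha = alpha,
                   seed = as.integer(seed)),
              class = "mrRunConfig")
}

#' Univariable bidirectional MR pipeline
#'
#' End-to-end analysis of one direction: munge (MR arm, palindromes kept
#' for harmonization to resolve) -> instrument filters (significance, LD
#' clumping, F) -> harmonization -> Steiger filter -> estimators ->
#' sensitivity suite -> power.  With a single surviving instrument only
#' the Wald ratio is reported; with two or more, both IVW variants, and
#' from three instruments the Egger slope/intercept, weighted median and
#' the two modes; from four instruments the MR-PRESSO raw (and, when
#' outliers are flagged, corrected) rows complete the forest-style table.
#' The primary IVW is labelled fixed-effects when
#' I-squared < 50 and multiplicative random-effects otherwise; both are
#' always reported.  `direction = "reverse"` swaps the two datasets.
#' Every stage logs its input/output/removal counts, and the audit chain
#' is conservative at each stage.
#'
#' @param exposure,outcome [SummaryStats-class] objects.
#' @param ld an [LDReference-class].
#' @param config an [mrRunConfig()] list.
#' @param direction `"forward"` (exposure -> outcome) or `"reverse"`.
#' @param outputDir optional directory; when given, the report bundle
#'   (config snapshot, stage log, estimates and sensitivity tables) is
#'   written there as delimited text via [writeReportBundle()].
#' @return list of class `mrReport`: `direction`, `config`, `stages`
#'   (data.frame of per-stage counts), `instruments`, `metrics`,
#'   `harmonized` ([HarmonizedSet-class]), `estimates` (named list of
#'   [MREstimate-class]), `estimate_table`, `primary_model`
#'   (`"fixed"`/`"mre"`), `sensitivity`, `power` (list or NULL), `steiger`.
#' @export
runUnivariable <- function(exposure, outcome, ld,
                           config = mrRunConfig(),
                           direction = c("forward", "reverse"),
                           outputDir = NULL) {
    direction <- match.arg(direction)
    if (direction == "reverse") {
        tmp <- exposure; exposure <- outcome; outcome <- tmp
    }
    exposure <- mungeSumstats(exposure, dropPalindromic = FALSE)
    sel <- applyInstrumentFilters(exposure, ld,
                                  pThreshold = config$pThreshold,
                                  r2Max = config$r2Max,
                                  windowKb = config$windowKb,
                                  fMin = config$fMin)
    h <- harmonize(sel$instruments, exposure, outcome,
                   palindromePolicy = config$palindromePolicy,
                   useProxies = config$useProxies, ld = ld,
                   proxyR2Min = config$proxyR2Min)
    n_harmonized <- nSnp(h)
    st <- steigerTest(h)
    n_steiger_removed <- 0L
    if (config$steigerFilter && any(!st$keep)) {
        n_steiger_removed <- sum(!st$keep)
        if (all(!st$keep))
            stop("Steiger filter removed every instrument")
        h <- subsetHarmonized(h, unname(st$keep))
        st <- steigerTest(h)
    }
    k <- nSnp(h)
    estimates <- mrAllEstimates(h, nBoot = config$nBoot, seed = config$seed)
    sens <- sensitivitySuite(h, nSim = config$pressoNSim,
                             seed = config$seed)
    if (!is.null(sens$presso)) {
        estimates$presso_raw <- sens$presso@rawEstimate
        if (any(sens$presso@outlierFlags))
            estimates$presso_corrected <- sens$presso@correctedEstimate
    }
    primary_model <- if (!is.null(sens$q) && sens$q$i2 >= 50) "mre"
                     else "fixed"
    power <- NULL
    if (h@outcomeIsBinary && "ivw_mre" %in% names(estimates)) {
        d <- harmonizedData(h)
        maf <- pmin(d$eaf_exposure, 1 - d$eaf_exposure)
        if (!any(is.na(maf))) {
            r2_total <- sum(varianceExplained(pmax(pmin(maf, 0.5), 1e-12),
                                              d$beta_exposure))
            orv <- exp(estimates[[if (primary_model == "fixed") "ivw_fe"
                                  else "ivw_mre"]]@beta)
            power <- list(
                n_total = h@nOutcome, case_fraction = h@outcomeCaseFraction,
                r2_instruments = r2_total, odds_ratio = orv,
                alpha = config$alpha,
                power = mrPowerBinary(h@nOutcome, h@outcomeCaseFraction,
                                      r2_total, orv, config$alpha))
        }
    }
    stages <- data.frame(
        stage = c("munged_exposure", "significant", "clumped", "f_filter",
                  "harmonized", "steiger"),
        n_out = c(nSnp(exposure),
                  nSnp(exposure) - sel$audit[["not_significant"]],
                  nSnp(exposure) - sel$audit[["not_significant"]] -
                      sel$audit[["clumped"]],
                  length(sel$instruments), n_harmonized, k),
        n_removed = c(NA_integer_, sel$audit[["not_significant"]],
                      sel$audit[["clumped"]], sel$audit[["weak_f"]],
                      length(sel$instruments) - n_harmonized,
                      n_steiger_removed),
        stringsAsFactors = FALSE)
    report <- structure(
        list(direction = direction, config = config, stages = stages,
             instruments = sel$instruments, metrics = sel$metrics,
             harmonized = h, estimates = estimates,
             estimate_table = estimateTable(estimates),
             primary_model = primary_model, sensitivity = sens,
             power = power, steiger = st),
        class = "mrReport")
    if (!is.null(outputDir)) writeReportBundle(report, outputDir)
    report
}

#' Write an mrReport bundle to a directory
#'
#' Serializes a [runUnivariable()] report as diffable delimited text: the
#' config snapshot (key/value), the stage log, the estimates table
#' (including odds-ratio columns), the harmonized set with its exclusion
#' audit, and the sensitivity sub-tables (leave-one-out, funnel, per-SNP
#' PRESSO p-values, summary statistics of the tests).  Content depends
#' only on the report, so identical config + seed reproduces the bundle
#' byte for byte.
#'
#' @param report an `mrReport` from [runUnivariable()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReportBundle <- function(report, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    wtab <- function(d, f)
        utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                           row.names = FALSE)
    cfg <- report$config
    writeLines(paste(names(cfg), vapply(cfg, format, character(1)),
                     sep = "\t"),
               file.path(dir, "config.tsv"))
    wtab(report$stages, "stages.tsv")
    wtab(report$estimate_table, "estimates.tsv")
    wtab(harmonizedData(report$harmonized), "harmonized.tsv")
    wtab(exclusions(report$harmonized), "exclusions.tsv")
    wtab(report$metrics, "instrument_metrics.tsv")
    sens <- report$sensitivity
    if (!is.null(sens$loo)) wtab(sens$loo, "leave_one_out.tsv")
    if (!is.null(sens$funnel)) wtab(sens$funnel, "funnel.tsv")
    if (!is.null(sens$presso))
        wtab(data.frame(snp_id = names(sens$presso@outlierPvals),
                        outlier_pval = sens$presso@outlierPvals,
                        outlier_flag = sens$presso@outlierFlags,
                        stringsAsFactors = FALSE),
             "presso_snps.tsv")
    summary_lines <- c(
        paste0("direction\t", report$direction),
        paste0("primary_model\t", report$primary_model),
        if (!is.null(sens$q))
            c(sprintf("q_stat\t%.10g", sens$q$q_stat),
              sprintf("q_df\t%d", sens$q$q_df),
              sprintf("q_pval\t%.10g", sens$q$q_pval),
              sprintf("i2\t%.10g", sens$q$i2)),
        if (!is.null(sens$egger_intercept))
            c(sprintf("egger_intercept\t%.10g", sens$egger_intercept@beta),
              sprintf("egger_intercept_pval\t%.10g",
                      sens$egger_intercept@pval)),
        if (!is.null(sens$presso))
            sprintf("presso_global_pval\t%.10g", sens$presso@globalPval),
        sprintf("steiger_direction\t%s", report$steiger$direction),
        sprintf("steiger_pval\t%.10g", report$steiger$steiger_pval),
        if (!is.null(report$power))
            sprintf("power\t%.10g", report$power$power))
    writeLines(summary_lines, file.path(dir, "sensitivity_summary.tsv"))
    invisible(dir)
}

#' Multivariable MR, one covariate at a time
#'
#' For each covariate independently: joint instrument selection over
#' (exposure, covariate), joint harmonization to the exposure orientation,
#' and multivariable IVW.  The returned table has one row per covariate
#' with the exposure's conditional (direct) effect.  Per-covariate
#' failures are isolated: a failing covariate yields an NA row carrying
#' the error message, and the remaining covariates still run.  A joint
#' all-covariate model is available via `joint = TRUE`.
#'
#' @param exposure [SummaryStats-class] primary exposure.
#' @param covariates named list of [SummaryStats-class] covariate
#'   exposures.
#' @param outcome [SummaryStats-class].
#' @param ld an [LDReference-class].
#' @param config an [mrRunConfig()] list.
#' @param joint fit one model adjusting all covariates simultaneously
#'   instead of one at a time (default FALSE).
#' @return data.frame: `covariate`, `n_snp`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pval`, `or_value`, `or_low`, `or_high`, `error`.
#' @export
runMVMR <- function(exposure, covariates, outcome, ld,
                    config = mrRunConfig(), joint = FALSE) {
    if (is.null(names(covariates)) || any(!nzchar(names(covariates))))
        names(covariates) <- vapply(covariates, traitName, character(1))
    oneFit <- function(covs, label) {
        tryCatch({
            exps <- c(list(exposure = exposure), covs)
            ids <- mvmrSelectInstruments(exps, ld,
                                         pThreshold = config$pThreshold,
                                         r2Max = config$r2Max,
                                         windowKb = config$windowKb)
            mset <- harmonizeMV(ids, exps, outcome,
                                palindromePolicy = config$palindromePolicy)
            est <- mvmrIVW(mset)[["exposure"]]
            data.frame(covariate = label, n_snp = est@nSnp,
                       beta = est@beta, se = est@se, ci_low = est@ciLow,
                       ci_high = est@ciHigh, pval = est@pval,
                       or_value = exp(est@beta), or_low = exp(est@ciLow),
                       or_high = exp(est@ciHigh), error = NA_character_,
                       stringsAsFactors = FALSE)
        }, error = function(e)
            data.frame(covariate = label, n_snp = NA_integer_,
                       beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, pval = NA_real_,
                       or_value = NA_real_, or_low = NA_real_,
                       or_high = NA_real_, error = conditionMessage(e),
                       stringsAsFactors = FALSE))
    }
    if (joint)
        return(oneFit(covariates, paste(names(covariates), collapse = "+")))
    do.call(rbind, lapply(names(covariates), function(nm)
        oneFit(covariates[nm], nm)))
}

#' @export
print.mrReport <- function(x, ...) {
    cat(sprintf("MR report (%s): %s -> %s\n", x$direction,
                x$harmonized@exposureName, x$harmonized@outcomeName))
    cat(sprintf("  %d instruments after all filters; primary IVW model: %s\n",
                nSnp(x$harmonized), x$primary_model))
    print(x$estimate_table, digits = 4)
    if (!is.null(x$sensitivity$q))
        cat(sprintf("  Q = %.3f (df %d, p = %.3g), I2 = %.1f%%\n",
                    x$sensitivity$q$q_stat, x$sensitivity$q$q_df,
                    x$sensitivity$q$q_pval, x$sensitivity$q$i2))
    if (!is.null(x$power))
        cat(sprintf("  power at alpha %.2f: %.3f\n", x$power$alpha,
                    x$power$power))
    invisible(x)
}
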