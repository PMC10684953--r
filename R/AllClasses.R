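#' @import methods
NULL

.SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n")

#' SummaryStats: one trait's GWAS summary statistics
#'
#' Container for per-variant association summaries of a single trait
#' (one row per variant: identifier, position, alleles, effect-allele
#' frequency, effect size, standard error, p-value, sample size) plus the
#' trait metadata needed downstream (binary flag, case/control counts).
#' Effects for binary traits are on the log-odds scale.
#'
#' @slot variants data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @slot traitName single character.
#' @slot isBinary logical flag; when TRUE `nCase`/`nControl` must be set and
#'   sum to `sampleN`.
#' @slot nCase,nControl case/control counts (NA for continuous traits).
#' @slot sampleN overall sample size.
#' @slot metadata free-form list (audit logs, provenance).
#'
#' @aliases SummaryStats-class
#' @exportClass SummaryStats
setClass("SummaryStats",
         representation(variants = "data.frame",
                        traitName = "character",
                        isBinary = "logical",
                        nCase = "numeric",
                        nControl = "numeric",
                        sampleN = "numeric",
                        metadata = "list"),
         prototype(variants = data.frame(),
                   traitName = NA_character_,
                   isBinary = FALSE,
                   nCase = NA_real_, nControl = NA_real_,
                   sampleN = NA_real_, metadata = list()))

setValidity("SummaryStats", function(object) {
    v <- object@variants
    msgs <- character()
    missing_cols <- setdiff(.SUMSTATS_COLS, names(v))
    if (length(missing_cols))
        msgs <- c(msgs, paste0("variants lacks column(s): ",
                               paste(missing_cols, collapse = ", ")))
    if (!length(msgs) && nrow(v)) {
        if (any(!is.na(v$se) & v$se <= 0))
            msgs <- c(msgs, "all se must be > 0")
        if (any(!is.na(v$pval) & (v$pval <= 0 | v$pval > 1)))
            msgs <- c(msgs, "pval must lie in (0, 1]")
        if (any(!is.na(v$pos) & v$pos < 1))
            msgs <- c(msgs, "pos must be >= 1 (1-based)")
        if (any(v$effect_allele == v$other_allele, na.rm = TRUE))
            msgs <- c(msgs, "effect_allele must differ from other_allele")
        bad_eaf <- !is.na(v$eaf) & (v$eaf < 0 | v$eaf > 1)
        if (any(bad_eaf))
            msgs <- c(msgs, "eaf must lie in [0, 1] or be NA")
    }
    if (isTRUE(object@isBinary)) {
        if (is.na(object@nCase) || is.na(object@nControl))
            msgs <- c(msgs, "binary trait requires nCase and nControl")
        else if (!is.na(object@sampleN) &&
                 object@nCase + object@nControl != object@sampleN)
            msgs <- c(msgs, "nCase + nControl must equal sampleN")
    }
    if (length(msgs)) msgs else TRUE
})

#' LDReference: variant index plus pairwise r-squared and LD scores
#'
#' Holds a variant index (`snp_id`, `chrom`, `pos`, `ld_score`) and a sparse
#' table of pairwise squared correlations.  Pairs not listed have r2 = 0;
#' r2(a, a) = 1 by definition.  The per-variant LD score is
#' 1 + sum of r2 against all other variants.
#'
#' @slot variants data.frame with `snp_id`, `chrom`, `pos`, `ld_score`.
#' @slot r2pairs data.frame with `snp_a`, `snp_b`, `r2` (each unordered pair
#'   stored once).
#'
#' @aliases LDReference-class
#' @exportClass LDReference
setClass("LDReference",
         representation(variants = "data.frame", r2pairs = "data.frame"),
         prototype(variants = data.frame(snp_id = character(),
                                         chrom = character(),
                                         pos = integer(),
                                         ld_score = numeric()),
                   r2pairs = data.frame(snp_a = character(),
                                        snp_b = character(),
                                        r2 = numeric())))

setValidity("LDReference", function(object) {
    msgs <- character()
    v <- object@variants
    if (!all(c("snp_id", "chrom", "pos", "ld_score") %in% names(v)))
        msgs <- c(msgs, "variants needs snp_id, chrom, pos, ld_score")
    else {
        if (anyDuplicated(v$snp_id))
            msgs <- c(msgs, "duplicated snp_id in variant index")
        if (any(v$ld_score < 1 - 1e-9))
            msgs <- c(msgs, "LD scores must be >= 1")
    }
    p <- object@r2pairs
    if (!all(c("snp_a", "snp_b", "r2") %in% names(p)))
        msgs <- c(msgs, "r2pairs needs snp_a, snp_b, r2")
    else if (nrow(p) && any(p$r2 < 0 | p$r2 > 1))
        msgs <- c(msgs, "r2 values must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' HarmonizedSet: allele-aligned exposure/outcome effects
#'
#' Per-variant exposure and outcome effects after allele harmonization: all
#' rows share the exposure's effect-allele orientation, so the per-variant
#' Wald ratio beta_outcome / beta_exposure is directly interpretable.  The
#' estimator input for every univariable MR method in the package.
#'
#' @slot data data.frame with columns `snp_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `eaf_exposure`,
#'   `eaf_outcome`, `pval_exposure`, `pval_outcome`.
#' @slot exposureName,outcomeName trait labels.
#' @slot outcomeIsBinary logical; TRUE when outcome effects are log-odds.
#' @slot nExposure,nOutcome GWAS sample sizes (needed by the Steiger test).
#' @slot outcomeCaseFraction case fraction K of the outcome GWAS (NA for
#'   continuous outcomes).
#' @slot exclusions data.frame (`snp_id`, `reason`) auditing every
#'   instrument dropped during harmonization.
#'
#' @aliases HarmonizedSet-class
#' @exportClass HarmonizedSet
setClass("HarmonizedSet",
         representation(data = "data.frame",
                        exposureName = "character",
                        outcomeName = "character",
                        outcomeIsBinary = "logical",
                        nExposure = "numeric",
                        nOutcome = "numeric",
                        outcomeCaseFraction = "numeric",
                        exclusions = "data.frame"),
         prototype(data = data.frame(),
                   exposureName = NA_character_, outcomeName = NA_character_,
                   outcomeIsBinary = FALSE,
                   nExposure = NA_real_, nOutcome = NA_real_,
                   outcomeCaseFraction = NA_real_,
                   exclusions = data.frame(snp_id = character(),
                                           reason = character())))

.HARMONIZED_COLS <- c("snp_id", "beta_exposure", "se_exposure",
                      "beta_outcome", "se_outcome", "eaf_exposure",
                      "eaf_outcome", "pval_exposure", "pval_outcome")

setValidity("HarmonizedSet", function(object) {
    d <- object@data
    msgs <- character()
    miss <- setdiff(.HARMONIZED_COLS, names(d))
    if (length(miss))
        msgs <- c(msgs, paste0("data lacks column(s): ",
                               paste(miss, collapse = ", ")))
    else if (nrow(d)) {
        if (anyDuplicated(d$snp_id))
            msgs <- c(msgs, "duplicated snp_id")
        if (any(d$se_exposure <= 0) || any(d$se_outcome <= 0))
            msgs <- c(msgs, "standard errors must be > 0")
    }
    if (length(msgs)) msgs else TRUE
})

#' MREstimate: one causal-effect estimate
#'
#' A single Mendelian-randomization estimate: the method, the effect on the
#' log-odds (or trait-unit) scale with its standard error, 95\% confidence
#' interval and p-value, and the number of instruments used.  Odds ratios
#' are derived views (`exp(beta)`), computed by the accessors/serializers
#' rather than stored.
#'
#' @slot method one of `wald_ratio`, `ivw_fe`, `ivw_mre`, `egger_slope`,
#'   `egger_intercept`, `weighted_median`, `weighted_mode`, `simple_mode`,
#'   `mvmr_ivw`, `presso_raw`, `presso_corrected`.
#' @slot beta,se point estimate and standard error.
#' @slot ciLow,ciHigh 95\% confidence bounds.
#' @slot pval two-sided p-value.
#' @slot nSnp instrument count.
#'
#' @aliases MREstimate-class
#' @exportClass MREstimate
setClass("MREstimate",
         representation(method = "character", beta = "numeric",
                        se = "numeric", ciLow = "numeric", ciHigh = "numeric",
                        pval = "numeric", nSnp = "integer"),
         prototype(method = NA_character_, beta = NA_real_, se = NA_real_,
                   ciLow = NA_real_, ciHigh = NA_real_, pval = NA_real_,
                   nSnp = NA_integer_))

setValidity("MREstimate", function(object) {
    msgs <- character()
    if (!is.na(object@beta) && !is.na(object@ciLow) && !is.na(object@ciHigh) &&
        (object@ciLow > object@beta + 1e-12 ||
         object@ciHigh < object@beta - 1e-12))
        msgs <- c(msgs, "need ciLow <= beta <= ciHigh")
    if (!is.na(object@pval) && (object@pval <= 0 || object@pval > 1))
        msgs <- c(msgs, "pval must lie in (0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' MVHarmonizedSet: multi-exposure harmonized effects
#'
#' Allele-aligned effects for several exposures and one outcome, the input
#' to multivariable MR.  Exposure effect/se columns are named
#' `beta_<exposure>` / `se_<exposure>`.
#'
#' @slot data data.frame with `snp_id`, one `beta_`/`se_` pair per exposure,
#'   and `beta_outcome`, `se_outcome`.
#' @slot exposures character vector of exposure names (column-order
#'   authority).
#' @slot outcomeName outcome trait label.
#'
#' @aliases MVHarmonizedSet-class
#' @exportClass MVHarmonizedSet
setClass("MVHarmonizedSet",
         representation(data = "data.frame", exposures = "character",
                        outcomeName = "character"),
         prototype(data = data.frame(), exposures = character(),
                   outcomeName = NA_character_))

setValidity("MVHarmonizedSet", function(object) {
    msgs <- character()
    need <- c("snp_id", paste0("beta_", object@exposures),
              paste0("se_", object@exposures), "beta_outcome", "se_outcome")
    miss <- setdiff(need, names(object@data))
    if (length(miss))
        msgs <- c(msgs, paste0("data lacks column(s): ",
                               paste(miss, collapse = ", ")))
    if (length(object@exposures) &&
        nrow(object@data) < length(object@exposures) + 2)
        msgs <- c(msgs, "need at least (number of exposures + 2) rows")
    if (length(msgs)) msgs else TRUE
})

#' PressoReport: MR-PRESSO global, outlier and distortion tests
#'
#' @slot globalPval p-value of the global residual-sum-of-squares test for
#'   horizontal pleiotropy.
#' @slot outlierPvals per-SNP outlier p-values (named by snp_id).
#' @slot outlierFlags per-SNP logical flags (Bonferroni at alpha / k).
#' @slot distortionPval distortion-test p-value; NA when no outlier flagged.
#' @slot rawEstimate,correctedEstimate IVW before/after outlier removal;
#'   `correctedEstimate` is present only when at least one outlier is
#'   flagged (otherwise a placeholder with NA fields).
#' @slot nSim number of parametric simulations used.
#'
#' @aliases PressoReport-class
#' @exportClass PressoReport
setClass("PressoReport",
         representation(globalPval = "numeric", outlierPvals = "numeric",
                        outlierFlags = "logical", distortionPval = "numeric",
                        rawEstimate = "MREstimate",
                        correctedEstimate = "MREstimate",
                        nSim = "integer"))

#' LDSCResult: LD score regression estimates
#'
#' SNP heritability for one or two traits, regression intercepts, and the
#' cross-trait genetic correlation with block-jackknife uncertainty.
#'
#' @slot h2_1,h2_1_se,h2_2,h2_2_se heritability estimates and jackknife SEs
#'   (trait-2 fields NA for univariate fits).
#' @slot intercept1,intercept2,interceptCross regression intercepts.
#' @slot rg,rgSe,rgPval genetic correlation (clamped to [-1, 1]), its
#'   jackknife SE and normal-theory p-value.
#' @slot rgClamped TRUE when the raw ratio fell outside [-1, 1].
#' @slot degenerate TRUE when rg is undefined (non-positive h2).
#' @slot nBlocks jackknife block count actually used.
#'
#' @aliases LDSCResult-class
#' @exportClass LDSCResult
setClass("LDSCResult",
         representation(h2_1 = "numeric", h2_1_se = "numeric",
                        h2_2 = "numeric", h2_2_se = "numeric",
                        intercept1 = "numeric", intercept2 = "numeric",
                        interceptCross = "numeric",
                        rg = "numeric", rgSe = "numeric", rgPval = "numeric",
                        rgClamped = "logical", degenerate = "logical",
                        nBlocks = "integer"),
         prototype(h2_1 = NA_real_, h2_1_se = NA_real_,
                   h2_2 = NA_real_, h2_2_se = NA_real_,
                   intercept1 = NA_real_, intercept2 = NA_real_,
                   interceptCross = NA_real_,
                   rg = NA_real_, rgSe = NA_real_, rgPval = NA_real_,
                   rgClamped = FALSE, degenerate = FALSE,
                   nBlocks = NA_integer_))

#' MRSimConfig: synthetic MR summary-statistics generator settings
#'
#' @slot nSnp number of instruments to plant.
#' @slot causalBeta true causal effect of exposure on outcome (log-odds
#'   scale for a binary outcome).
#' @slot nExposure,nOutcome GWAS sample sizes.
#' @slot mafRange interval within (0, 0.5] minor allele frequencies are
#'   drawn from.
#' @slot exposureR2Total total exposure variance explained by the planted
#'   instruments.
#' @slot propInvalid fraction of instruments carrying pleiotropic effects.
#' @slot pleiotropyMode one of `none`, `balanced`, `directional`,
#'   `correlated` (the last violates InSIDE).
#' @slot pleiotropySd,pleiotropyMean pleiotropic-effect scale and mean.
#' @slot outcomeBinary logical; binary outcomes use the case-fraction se
#'   scaling.
#' @slot outcomeCaseFraction case fraction K of the outcome GWAS.
#' @slot seed integer seed; generators are pure functions of (config, seed).
#'
#' @aliases MRSimConfig-class
#' @exportClass MRSimConfig
setClass("MRSimConfig",
         representation(nSnp = "integer", causalBeta = "numeric",
                        nExposure = "numeric", nOutcome = "numeric",
                        mafRange = "numeric", exposureR2Total = "numeric",
                        propInvalid = "numeric", pleiotropyMode = "character",
                        pleiotropySd = "numeric", pleiotropyMean = "numeric",
                        outcomeBinary = "logical",
                        outcomeCaseFraction = "numeric",
                        seed = "integer"))

setValidity("MRSimConfig", function(object) {
    msgs <- character()
    if (object@nSnp < 1) msgs <- c(msgs, "nSnp must be >= 1")
    if (object@propInvalid < 0 || object@propInvalid >= 1)
        msgs <- c(msgs, "propInvalid must lie in [0, 1)")
    if (object@exposureR2Total <= 0 || object@exposureR2Total >= 1)
        msgs <- c(msgs, "exposureR2Total must lie in (0, 1)")
    if (object@pleiotropySd < 0) msgs <- c(msgs, "pleiotropySd must be >= 0")
    if (!object@pleiotropyMode %in%
        c("none", "balanced", "directional", "correlated"))
        msgs <- c(msgs, "unknown pleiotropyMode")
    if (length(object@mafRange) != 2 || object@mafRange[1] <= 0 ||
        object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
        msgs <- c(msgs, "mafRange must be an interval within (0, 0.5]")
    if (object@outcomeCaseFraction <= 0 || object@outcomeCaseFraction >= 1)
        msgs <- c(msgs, "outcomeCaseFraction must lie in (0, 1)")
    if (length(msgs)) msgs else TRUE
})

#' LDSCSimConfig: synthetic LDSC z-score generator settings
#'
#' @slot mVariants variant count m.
#' @slot h2Trait1,h2Trait2 SNP heritabilities in [0, 1].
#' @slot rgTrue genetic correlation in [-1, 1].
#' @slot n1,n2 GWAS sample sizes; `nOverlap` individuals shared.
#' @slot ldScoreShape,ldScoreScale gamma parameters for drawing per-variant
#'   LD scores (shifted by +1 so every score is >= 1).
#' @slot seed integer seed.
#'
#' @aliases LDSCSimConfig-class
#' @exportClass LDSCSimConfig
setClass("LDSCSimConfig",
         representation(mVariants = "integer", h2Trait1 = "numeric",
                        h2Trait2 = "numeric", rgTrue = "numeric",
                        n1 = "numeric", n2 = "numeric", nOverlap = "numeric",
                        ldScoreShape = "numeric", ldScoreScale = "numeric",
                        seed = "integer"))

setValidity("LDSCSimConfig", function(object) {
    msgs <- character()
    if (abs(object@rgTrue) > 1) msgs <- c(msgs, "|rgTrue| must be <= 1")
    if (object@h2Trait1 < 0 || object@h2Trait1 > 1 ||
        object@h2Trait2 < 0 || object@h2Trait2 > 1)
        msgs <- c(msgs, "h2 values must lie in [0, 1]")
    if (object@nOverlap < 0 || object@nOverlap > min(object@n1, object@n2))
        msgs <- c(msgs, "nOverlap must lie in [0, min(n1, n2)]")
    if (length(msgs)) msgs else TRUE
})
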