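Package: gwasMR
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: reading and munging summary statistics, genetic
    instrument selection (genome-wide significance, LD clumping, F-statistic
    and Steiger filters, proxy lookup), exposure/outcome allele
    harmonization, causal-effect estimation (Wald ratio, fixed- and
    multiplicative-random-effects inverse-variance weighting, MR-Egger,
    weighted median, weighted and simple mode), a sensitivity suite
    (Cochran's Q and I-squared, Egger intercept, MR-PRESSO
    global/outlier/distortion tests, leave-one-out, funnel tables),
    multivariable MR, LD score regression for SNP heritability and
    cross-trait genetic correlation with block-jackknife uncertainty, and
    non-centrality-based power calculation for binary outcomes.  Includes
    generators for synthetic two-trait GWAS summary statistics with
    block-diagonal LD, configurable horizontal pleiotropy and known ground
    truth, used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), knitr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'sumstats-io.R'
    'harmonization.R'
    'methods-accessors.R'
    'instruments.R'
    'ld-io.R'
    'ldsc.R'
    'mr-estimators.R'
    'mvmr.R'
    'power.R'
    'sensitivity.R'
    'pipeline.R'
    'synthetic-gwas.R'
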