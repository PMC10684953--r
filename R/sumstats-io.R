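#' @include AllClasses.R
NULL

.PALINDROMIC <- c(A = "T", T = "A", C = "G", G = "C")

.isPalindromic <- function(ea, oa) {
    ok <- ea %in% names(.PALINDROMIC)
    ok & .PALINDROMIC[ifelse(ok, ea, "A")] == oa
}

#' Construct a SummaryStats object from a variant table
#'
#' Low-level constructor; most users will call [readSumstats()].  Alleles
#' are normalised to uppercase, p-values of exactly 0 are clamped to the
#' smallest positive double (with a warning) so downstream quantile and log
#' operations stay finite.
#'
#' @param variants data.frame with the canonical columns (`snp_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n`); missing `eaf`/`n`/`chrom`/`pos` columns are filled with
#'   NA.
#' @param traitName trait label.
#' @param isBinary TRUE for case/control traits (effects on the log-odds
#'   scale).
#' @param nCase,nControl case/control counts, required when `isBinary`.
#' @param sampleN overall GWAS sample size; defaults to `nCase + nControl`
#'   for binary traits, else the median per-variant `n`.
#' @return a [SummaryStats-class].
#' @export
SummaryStats <- function(variants, traitName = "trait", isBinary = FALSE,
                         nCase = NA_real_, nControl = NA_real_,
                         sampleN = NA_real_) {
    for (col in .SUMSTATS_COLS)
        if (is.null(variants[[col]])) variants[[col]] <- NA
    variants <- variants[.SUMSTATS_COLS]
    variants$snp_id <- as.character(variants$snp_id)
    variants$chrom <- as.character(variants$chrom)
    variants$pos <- as.integer(variants$pos)
    variants$effect_allele <- toupper(as.character(variants$effect_allele))
    variants$other_allele <- toupper(as.character(variants$other_allele))
    for (col in c("eaf", "beta", "se", "pval", "n"))
        variants[[col]] <- as.numeric(variants[[col]])
    zero_p <- !is.na(variants$pval) & variants$pval == 0
    if (any(zero_p)) {
        warning(sum(zero_p), " p-value(s) of exactly 0 clamped to ",
                ".Machine$double.xmin")
        variants$pval[zero_p] <- .Machine$double.xmin
    }
    if (isBinary && is.na(sampleN) && !is.na(nCase) && !is.na(nControl))
        sampleN <- nCase + nControl
    if (!isBinary && is.na(sampleN) && any(!is.na(variants$n)))
        sampleN <- stats::median(variants$n, na.rm = TRUE)
    rownames(variants) <- NULL
    new("SummaryStats", variants = variants, traitName = traitName,
        isBinary = isBinary, nCase = as.numeric(nCase),
        nControl = as.numeric(nControl), sampleN = as.numeric(sampleN))
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file (gzip transparently supported) with
#' a header row, mapping file columns to variant-record roles via
#' `columnMap`.  Rows whose mandatory numeric fields (`beta`, `se`, `pval`)
#' fail to parse, or whose `se` is non-positive, are dropped and counted in
#' the audit log stored in `metadata(x)$audit`.
#'
#' @param path file path (plain or `.gz`).
#' @param columnMap named character vector mapping roles to file column
#'   names; must cover `snp_id`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `pval`.  Optional roles: `chrom`, `pos`, `eaf`, `n`.
#' @param traitName,isBinary,nCase,nControl,sampleN trait metadata, passed
#'   to [SummaryStats()].
#' @param defaultN per-variant sample size used when the file has no `n`
#'   column.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return a [SummaryStats-class]; `x@metadata$audit` is a named integer
#'   vector of per-reason removal counts.
#' @export
readSumstats <- function(path, columnMap, traitName = "trait",
                         isBinary = FALSE, nCase = NA_real_,
                         nControl = NA_real_, sampleN = NA_real_,
                         defaultN = NA_real_, sep = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se",
                   "pval")
    miss <- setdiff(mandatory, names(columnMap))
    if (length(miss))
        stop("columnMap lacks mandatory role(s): ",
             paste(miss, collapse = ", "))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    header <- readLines(con, n = 1L)
    if (!length(header) || !nzchar(header)) stop("empty input file: ", path)
    if (is.null(sep))
        sep <- if (grepl("\t", header)) "\t" else ","
    raw <- utils::read.table(con, header = FALSE, sep = sep,
                             col.names = strsplit(header, sep, fixed = TRUE)[[1]],
                             colClasses = "character", quote = "",
                             comment.char = "", check.names = FALSE)
    absent <- setdiff(unname(columnMap), names(raw))
    if (length(absent))
        stop("mapped column(s) not in file: ", paste(absent, collapse = ", "))
    get <- function(role) {
        if (role %in% names(columnMap)) raw[[columnMap[[role]]]] else NULL
    }
    n_in <- nrow(raw)
    num <- function(x) suppressWarnings(as.numeric(x))
    tab <- data.frame(
        snp_id = get("snp_id"),
        chrom = if (is.null(get("chrom"))) NA_character_ else get("chrom"),
        pos = if (is.null(get("pos"))) NA_integer_
              else suppressWarnings(as.integer(get("pos"))),
        effect_allele = get("effect_allele"),
        other_allele = get("other_allele"),
        eaf = if (is.null(get("eaf"))) NA_real_ else num(get("eaf")),
        beta = num(get("beta")),
        se = num(get("se")),
        pval = num(get("pval")),
        n = if (is.null(get("n"))) defaultN else num(get("n")),
        stringsAsFactors = FALSE)
    bad <- is.na(tab$beta) | is.na(tab$se) | is.na(tab$pval) |
        tab$se <= 0 | tab$pval < 0 | tab$pval > 1 | is.na(tab$snp_id) |
        !nzchar(tab$snp_id)
    audit <- c(unparseable = sum(bad))
    tab <- tab[!bad, , drop = FALSE]
    ss <- SummaryStats(tab, traitName = traitName, isBinary = isBinary,
                       nCase = nCase, nControl = nControl, sampleN = sampleN)
    ss@metadata$audit <- audit
    ss@metadata$n_input_rows <- n_in
    ss
}

#' Write summary statistics to delimited text
#'
#' Writes the canonical column order (`snp_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) as
#' tab-delimited text; a `.gz` suffix triggers gzip compression.
#'
#' @param stats a [SummaryStats-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(stats, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    on.exit(close(con))
    utils::write.table(stats@variants[.SUMSTATS_COLS], con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Munge summary statistics
#'
#' Quality filter applied before LD score regression (and, in a relaxed
#' form, before MR): removes (a) indels — variants where either allele has
#' more than one base, (b) strand-ambiguous palindromic variants (A/T and
#' C/G pairs), and (c) every copy of any duplicated snp_id.  For the MR arm
#' palindromic variants are retained (`dropPalindromic = FALSE`) because
#' harmonization resolves or drops them with its own frequency-based
#' policy.
#'
#' @param stats a [SummaryStats-class].
#' @param dropPalindromic remove A/T and C/G variants (default TRUE, the
#'   LDSC munge behaviour).
#' @return filtered [SummaryStats-class]; `metadata(x)$munge_removals` is a
#'   named integer vector with counts for `indel`, `palindromic`,
#'   `duplicate`.
#' @export
mungeSumstats <- function(stats, dropPalindromic = TRUE) {
    v <- stats@variants
    if (!nrow(v)) stop("empty SummaryStats")
    valid_base <- c("A", "C", "G", "T")
    is_indel <- nchar(v$effect_allele) > 1L | nchar(v$other_allele) > 1L |
        !(v$effect_allele %in% valid_base) | !(v$other_allele %in% valid_base)
    is_pal <- !is_indel & .isPalindromic(v$effect_allele, v$other_allele)
    if (!dropPalindromic) is_pal <- rep(FALSE, nrow(v))
    dup_ids <- unique(v$snp_id[duplicated(v$snp_id)])
    is_dup <- v$snp_id %in% dup_ids
    # precedence for counting: indel, then palindrome, then duplicate
    removals <- c(indel = sum(is_indel),
                  palindromic = sum(is_pal & !is_indel),
                  duplicate = sum(is_dup & !is_indel & !is_pal))
    keep <- !(is_indel | is_pal | is_dup)
    if (!any(keep)) warning("munging removed every variant")
    out <- stats
    out@variants <- v[keep, , drop = FALSE]
    rownames(out@variants) <- NULL
    out@metadata$munge_removals <- removals
    validObject(out)
    out
}
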