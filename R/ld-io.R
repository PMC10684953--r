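#' @include AllClasses.R
NULL

#' Read / write an LD reference
#'
#' On-disk layout: a variant index file (`snp_id`, `chrom`, `pos`,
#' `ld_score`, optionally `maf`) plus a sparse pairwise file of triples
#' (`snp_a`, `snp_b`, `r2`), both tab-delimited with a header; `.gz`
#' supported transparently.
#'
#' @param indexPath,pairsPath the two file paths.
#' @param ld an [LDReference-class] (for writing).
#' @return `readLDReference` returns an [LDReference-class];
#'   `writeLDReference` returns the paths invisibly.
#' @export
readLDReference <- function(indexPath, pairsPath) {
    idx <- utils::read.table(indexPath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c(snp_id = "character",
                                            chrom = "character"))
    prs <- utils::read.table(pairsPath, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c(snp_a = "character",
                                            snp_b = "character"))
    new("LDReference", variants = idx, r2pairs = prs)
}

#' @rdname readLDReference
#' @export
writeLDReference <- function(ld, indexPath, pairsPath) {
    utils::write.table(ld@variants, indexPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(ld@r2pairs, pairsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(indexPath, pairsPath))
}
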