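#' @include AllClasses.R
NULL

#' Accessors for gwasMR objects
#'
#' Small accessor generics used across the package: `variants()` returns the
#' per-variant table of a [SummaryStats-class] or [LDReference-class];
#' `traitName()`, `sampleN()`, `isBinary()` return trait metadata;
#' `nSnp()` the number of variants/instruments; `harmonizedData()` and
#' `exclusions()` the aligned table and exclusion audit of a
#' [HarmonizedSet-class]; `ldScores()` the per-variant LD scores.
#'
#' @param x a gwasMR object.
#' @return the corresponding slot content (data.frame, character, numeric or
#'   logical scalar).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' @rdname accessors
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @rdname accessors
#' @export
setGeneric("sampleN", function(x) standardGeneric("sampleN"))

#' @rdname accessors
#' @export
setGeneric("isBinary", function(x) standardGeneric("isBinary"))

#' @rdname accessors
#' @export
setGeneric("nSnp", function(x) standardGeneric("nSnp"))

#' @rdname accessors
#' @export
setGeneric("harmonizedData", function(x) standardGeneric("harmonizedData"))

#' @rdname accessors
#' @export
setGeneric("exclusions", function(x) standardGeneric("exclusions"))

#' @rdname accessors
#' @export
setGeneric("ldScores", function(x) standardGeneric("ldScores"))

#' Pairwise squared correlation lookup
#'
#' Vectorised lookup of pairwise r-squared values in an
#' [LDReference-class].  Unlisted pairs return 0; `r2(a, a)` returns 1.
#' Variants absent from the index return NA.
#'
#' @param ld an [LDReference-class].
#' @param a,b character vectors of snp_ids (recycled to common length).
#' @return numeric vector of r-squared values.
#' @export
setGeneric("ldR2", function(ld, a, b) standardGeneric("ldR2"))
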