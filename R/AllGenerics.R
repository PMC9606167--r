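#' @include AllClasses.R
NULL

#' Record identifiers of a collection
#' @param x A \code{\linkS4class{MarkerSet}}.
#' @return Character vector of record ids, in collection order.
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' Taxon (species) labels of a collection
#' @param x A \code{\linkS4class{MarkerSet}}.
#' @return Character vector of taxon labels (\code{NA} where unknown).
#' @export
setGeneric("taxonLabels", function(x) standardGeneric("taxonLabels"))

#' Replace taxon labels
#' @param x A \code{\linkS4class{MarkerSet}}.
#' @param value Character vector, recycled to \code{length(x)}.
#' @return The modified object.
#' @export
setGeneric("taxonLabels<-", function(x, value) standardGeneric("taxonLabels<-"))

#' Is a collection aligned?
#' @param x A \code{\linkS4class{MarkerSet}}.
#' @return Logical scalar.
#' @export
setGeneric("isAligned", function(x) standardGeneric("isAligned"))

#' Underlying sequences
#' @param x A \code{\linkS4class{MarkerSet}}.
#' @return The \code{\link[Biostrings]{DNAStringSet}} of sequences.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Extract an alignment sub-region by column coordinates
#'
#' @param x An aligned \code{\linkS4class{MarkerSet}}.
#' @param start,end 1-based inclusive alignment columns.
#' @return A \code{\linkS4class{MarkerSet}} of the trimmed records.
#' @export
setGeneric("extractRegion", function(x, start, end) standardGeneric("extractRegion"))

#' Number of distinguishable units
#' @param x A \code{\linkS4class{ResolutionResult}}.
#' @return Integer count of amplified units.
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' Unit membership partition
#' @param x A \code{\linkS4class{ResolutionResult}}.
#' @return Named list of character vectors of strain ids.
#' @export
setGeneric("unitMembers", function(x) standardGeneric("unitMembers"))
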