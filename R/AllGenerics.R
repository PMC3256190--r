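#' @describeIn BarcodeAlignment-class Locus name.
#' @param x,object A \code{BarcodeAlignment} (or subclass).
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))

#' @describeIn BarcodeAlignment-class Character matrix of aligned sequences.
#' @export
setGeneric("seqMatrix", function(x) standardGeneric("seqMatrix"))

#' @describeIn BarcodeAlignment-class Taxon metadata \code{data.frame}.
#' @export
setGeneric("taxonInfo", function(x) standardGeneric("taxonInfo"))

#' @describeIn BarcodeAlignment-class Number of alignment columns.
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))

#' @describeIn BarcodeAlignment-class Sequence ids (row names).
#' @export
setGeneric("seqIDs", function(x) standardGeneric("seqIDs"))

#' @describeIn Supermatrix-class Partition table (locus, start, end).
#' @param x A \code{Supermatrix}.
#' @export
setGeneric("partitionTable", function(x) standardGeneric("partitionTable"))

#' @describeIn GapReport-class Within-group distances.
#' @param x A \code{GapReport}.
#' @export
setGeneric("intraDistances", function(x) standardGeneric("intraDistances"))

#' @describeIn GapReport-class Between-group distances.
#' @export
setGeneric("interDistances", function(x) standardGeneric("interDistances"))

#' @describeIn GapReport-class Barcoding-gap statistic
#'   \code{min(inter) - max(intra)} (\code{NA} if either set is empty).
#' @export
setGeneric("gapStat", function(x) standardGeneric("gapStat"))

#' @describeIn GapReport-class Fraction of intra-group distances at or above
#'   the smallest between-group distance.
#' @export
setGeneric("overlapFraction", function(x) standardGeneric("overlapFraction"))

#' @describeIn CATable-class Attribute table \code{data.frame}.
#' @param x A \code{CATable}.
#' @export
setGeneric("caAttributes", function(x) standardGeneric("caAttributes"))

#' @describeIn CATable-class Per-clade CA counts with the "/length"
#'   denominator convention.
#' @export
setGeneric("caCounts", function(x) standardGeneric("caCounts"))
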