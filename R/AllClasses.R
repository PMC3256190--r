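#' @import methods
NULL

#' BarcodeAlignment: an aligned set of barcode sequences with taxon metadata
#'
#' The central container of the package: a per-locus multiple sequence
#' alignment stored as a character matrix (rows = sequences, columns =
#' alignment positions) together with a taxon metadata table.
#'
#' Sequences are uppercase over the IUPAC nucleotide alphabet plus \code{-}
#' (alignment gap) and \code{?} (missing data). The metadata table carries
#' one row per sequence with columns \code{id}, \code{species}, \code{genus},
#' \code{family} and \code{site}; \code{genus} must equal the first token of
#' \code{species} whenever a species name is present.
#'
#' @slot locus Character scalar naming the locus (e.g. \code{"rbcL"}).
#' @slot seqs Character matrix of single characters; rownames are sequence
#'   ids, unique within the alignment.
#' @slot meta \code{data.frame} with columns id/species/genus/family/site,
#'   one row per sequence, in row order of \code{seqs}.
#'
#' @seealso [readFastaAlignment()], [buildSupermatrix()]
#' @export
setClass("BarcodeAlignment",
  representation(locus = "character", seqs = "matrix", meta = "data.frame")
)

setValidity("BarcodeAlignment", function(object) {
  msg <- character()
  if (length(object@locus) != 1L) msg <- c(msg, "locus must be a single string")
  m <- object@seqs
  if (!is.character(m)) msg <- c(msg, "seqs must be a character matrix")
  if (ncol(m) < 1L) msg <- c(msg, "alignment must have at least one column")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "sequence ids (rownames) must be present and unique")
  if (is.character(m) && length(m)) {
    bad <- !m %in% .ALPHABET
    if (any(bad)) {
      i <- which(bad)[1]
      msg <- c(msg, sprintf("illegal character '%s' (row %d, column %d)",
                            m[i], (i - 1) %% nrow(m) + 1, (i - 1) %/% nrow(m) + 1))
    }
  }
  need <- c("id", "species", "genus", "family", "site")
  if (!all(need %in% names(object@meta))) {
    msg <- c(msg, paste("meta must have columns", paste(need, collapse = "/")))
  } else {
    if (nrow(object@meta) != nrow(m) ||
        !identical(as.character(object@meta$id), rownames(m)))
      msg <- c(msg, "meta rows must match seqs rows (same ids, same order)")
    sp <- object@meta$species
    gn <- object@meta$genus
    has <- !is.na(sp) & nzchar(sp)
    tok <- sub("\\s.*$", "", sp[has])
    if (any(tok != gn[has]))
      msg <- c(msg, "genus must equal the first token of species")
  }
  if (length(msg)) msg else TRUE
})

#' Supermatrix: column-wise concatenation of per-locus alignments
#'
#' Extends [BarcodeAlignment-class] with a partition table. Rows are
#' operational taxa (by default one row per sequence id shared across loci);
#' a taxon absent from a locus has that partition filled with \code{?}.
#'
#' @slot partitions \code{data.frame} with columns \code{locus},
#'   \code{start}, \code{end}: 1-based inclusive column spans, contiguous,
#'   non-overlapping, covering all columns in order.
#' @export
setClass("Supermatrix",
  contains = "BarcodeAlignment",
  representation(partitions = "data.frame")
)

setValidity("Supermatrix", function(object) {
  p <- object@partitions
  msg <- character()
  if (!all(c("locus", "start", "end") %in% names(p)))
    return("partitions must have columns locus/start/end")
  if (nrow(p) < 1L) return("at least one partition required")
  if (p$start[1] != 1L) msg <- c(msg, "first partition must start at column 1")
  if (nrow(p) > 1L && any(p$start[-1] != p$end[-nrow(p)] + 1L))
    msg <- c(msg, "partitions must be contiguous and non-overlapping")
  if (p$end[nrow(p)] != ncol(object@seqs))
    msg <- c(msg, "partitions must cover all columns")
  if (any(p$end < p$start)) msg <- c(msg, "partition end before start")
  if (length(msg)) msg else TRUE
})

#' GapReport: intra- vs inter-group p-distance partition
#'
#' Holds the two distance multisets underlying a barcoding-gap analysis,
#' produced by [partitionDistances()]. The gap statistic is
#' \code{min(inter) - max(intra)}; the overlap fraction is the share of
#' intra-group distances at or above \code{min(inter)}.
#'
#' @slot rank Grouping rank used (\code{"species"} or \code{"genus"}).
#' @slot intra,inter Numeric vectors of within-/between-group p-distances.
#' @slot nUndefined Number of sequence pairs with no comparable site
#'   (excluded from both sets).
#' @export
setClass("GapReport",
  representation(rank = "character", intra = "numeric", inter = "numeric",
                 nUndefined = "integer")
)

setValidity("GapReport", function(object) {
  if (any(c(object@intra, object@inter) < 0, na.rm = TRUE) ||
      any(c(object@intra, object@inter) > 1, na.rm = TRUE))
    return("distances must lie in [0, 1]")
  TRUE
})

#' CATable: diagnostic characteristic attributes per clade
#'
#' Character-based barcode produced by [findPureCAs()]: for each group, the
#' alignment columns at which one state is fixed within the group and absent
#' outside it ("pure, simple" characteristic attributes).
#'
#' @slot groupingSource How groups were formed (metadata rank or guide tree).
#' @slot attributes \code{data.frame} with columns \code{clade},
#'   \code{position} (1-based alignment column), \code{state},
#'   \code{insideCount} (group members carrying the state) and
#'   \code{outsideCount} (non-members carrying it; 0 for pure CAs).
#' @slot alignmentLength Denominator for the conventional "n/length" counts.
#' @slot groups Named list of character vectors: member ids per group.
#' @export
setClass("CATable",
  representation(groupingSource = "character", attributes = "data.frame",
                 alignmentLength = "integer", groups = "list")
)

setValidity("CATable", function(object) {
  a <- object@attributes
  need <- c("clade", "position", "state", "insideCount", "outsideCount")
  if (!all(need %in% names(a)))
    return(paste("attributes must have columns", paste(need, collapse = "/")))
  if (nrow(a) && (any(a$position < 1) || any(a$position > object@alignmentLength)))
    return("CA positions must lie within the alignment")
  TRUE
})
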