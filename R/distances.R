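# Uncorrected p-distances with pairwise deletion, and the barcoding-gap
# partition into intra- vs inter-group distance sets.

#' Uncorrected p-distance between two aligned rows
#'
#' Pairwise deletion: a site is comparable only when both characters are
#' unambiguous bases (A/C/G/T); gaps, \code{?} and ambiguity codes are
#' skipped. Returns \code{NA} when no site is comparable.
#'
#' @param a,b Character vectors (single characters) or strings of equal
#'   length.
#' @return Proportion of differing comparable sites, or \code{NA}.
#' @examples
#' pDistance("AC-T", "ACGT")  # 0 over 3 comparable sites
#' @export
pDistance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- .seqChars(a)
  if (is.character(b) && length(b) == 1L) b <- .seqChars(b)
  if (length(a) != length(b))
    stop("shape error: sequences have different lengths (",
         length(a), " vs ", length(b), ")")
  comp <- .isBase(a) & .isBase(b)
  n <- sum(comp)
  if (n == 0L) return(NA_real_)
  sum(a[comp] != b[comp]) / n
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param aln A [BarcodeAlignment-class] with at least 2 sequences.
#' @return Symmetric numeric matrix with zero diagonal; entries are
#'   [pDistance()] values (\code{NA} for pairs with no comparable site).
#' @export
distanceMatrix <- function(aln) {
  m <- seqMatrix(aln)
  if (nrow(m) < 2L) stop("at least 2 sequences required")
  n <- nrow(m)
  # base-only indicator once per row keeps the double loop cheap
  isb <- matrix(.isBase(m), nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- isb[i, ] & isb[j, ]
    nc <- sum(comp)
    d[i, j] <- d[j, i] <-
      if (nc == 0L) NA_real_ else sum(m[i, comp] != m[j, comp]) / nc
  }
  d
}

#' Partition pairwise distances into intra- and inter-group sets
#'
#' The quantitative substrate of the barcoding gap: every defined pair is
#' assigned to the within-group or between-group multiset at the chosen
#' taxonomic rank. Genus is the conservative default when species-level
#' sampling is thin.
#'
#' @param d Distance matrix from [distanceMatrix()].
#' @param metadata \code{data.frame} with \code{id} plus rank columns
#'   (\code{species}, \code{genus}); every matrix label must be mapped.
#' @param rank \code{"genus"} (default) or \code{"species"}.
#' @return A [GapReport-class].
#' @export
partitionDistances <- function(d, metadata, rank = c("genus", "species")) {
  rank <- match.arg(rank)
  labels <- rownames(d)
  idx <- match(labels, metadata$id)
  if (anyNA(idx))
    stop("metadata error: unmapped label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  grp <- metadata[[rank]][idx]
  if (any(!nzchar(grp)))
    stop("metadata error: empty ", rank, " for ",
         paste(labels[!nzchar(grp)], collapse = ", "))
  n <- nrow(d)
  intra <- numeric(); inter <- numeric(); undef <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- d[i, j]
    if (is.na(v)) { undef <- undef + 1L; next }
    if (grp[i] == grp[j]) intra <- c(intra, v) else inter <- c(inter, v)
  }
  new("GapReport", rank = rank, intra = intra, inter = inter,
      nUndefined = undef)
}

#' Histogram of intra- and inter-group distances
#'
#' Half-open bins \code{[k*w, (k+1)*w)} from zero to the largest observed
#' value; bin counts sum to the set sizes.
#'
#' @param report A [GapReport-class].
#' @param binWidth Bin width as a proportion (default 0.005, i.e. 0.5\%).
#' @param relative Also report relative frequencies.
#' @return \code{data.frame} with \code{binStart}, \code{binEnd},
#'   \code{intra}, \code{inter} (counts) and, when \code{relative},
#'   \code{intraFreq}/\code{interFreq}.
#' @export
gapHistogram <- function(report, binWidth = 0.005, relative = TRUE) {
  if (!is.numeric(binWidth) || binWidth <= 0)
    stop("parameter error: binWidth must be positive")
  vals <- c(intraDistances(report), interDistances(report))
  if (!length(vals))
    return(data.frame(binStart = numeric(), binEnd = numeric(),
                      intra = integer(), inter = integer()))
  nbin <- max(1L, floor(max(vals) / binWidth) + 1L)
  edges <- (0:nbin) * binWidth
  binOf <- function(v) pmin(floor(v / binWidth) + 1L, nbin)
  cnt <- function(v) tabulate(binOf(v), nbins = nbin)
  out <- data.frame(binStart = edges[-length(edges)], binEnd = edges[-1],
                    intra = cnt(intraDistances(report)),
                    inter = cnt(interDistances(report)))
  if (relative) {
    out$intraFreq <- if (length(intraDistances(report)))
      out$intra / length(intraDistances(report)) else NA_real_
    out$interFreq <- if (length(interDistances(report)))
      out$inter / length(interDistances(report)) else NA_real_
  }
  out
}

#' Share of distances below a threshold
#'
#' Convenience query, e.g. the share of intra-generic distances under 0.5\%.
#'
#' @param report A [GapReport-class].
#' @param threshold Distance threshold (proportion).
#' @param set \code{"intra"} or \code{"inter"}.
#' @return Fraction in \code{[0, 1]} (\code{NA} if the set is empty).
#' @export
fractionBelow <- function(report, threshold, set = c("intra", "inter")) {
  set <- match.arg(set)
  v <- if (set == "intra") intraDistances(report) else interDistances(report)
  if (!length(v)) return(NA_real_)
  mean(v < threshold)
}
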