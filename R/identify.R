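# In-silico PCR with degenerate primers and rank-level identification of
# queries against a local reference library (a reproducible, local
# stand-in for remote BLAST identification: scored local alignment plus
# hit-taxonomy logic, no E-value statistics).

#' Bundled barcoding primer pairs
#'
#' The six primer pairs used for the seagrass barcoding markers (rbcL,
#' matK, rps16-trnQ, ITS and the trnH-psbA spacer), shipped as a TSV in
#' \code{inst/extdata/primers.tsv}.
#'
#' @return \code{data.frame} with columns \code{name}, \code{locus},
#'   \code{forward}, \code{reverse} (both 5'\eqn{\to}3').
#' @export
barcodingPrimers <- function() {
  path <- system.file("extdata", "primers.tsv", package = "barcodeval")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# per-window IUPAC mismatch count helper (oracle-grade, used for reported
# mismatch counts)
.windowMismatches <- function(tmpl, primer) {
  sum(!vapply(seq_along(primer),
              function(i) .iupacCovers(primer[i], tmpl[i]), TRUE))
}

#' Match a degenerate primer against a template
#'
#' A binding site is a window where every primer position's IUPAC set
#' contains the template base, allowing up to \code{maxMismatches}
#' violations. Both the template and its reverse complement are scanned;
#' minus-strand bindings are reported in plus-strand coordinates.
#'
#' @param template DNA string (unambiguous bases).
#' @param primer IUPAC primer string, 5'\eqn{\to}3'.
#' @param maxMismatches Allowed violations per binding (default 0).
#' @return \code{data.frame} with \code{start}, \code{end}, \code{strand}
#'   (\code{"+"}/\code{"-"}), \code{mismatches}. Zero rows when the primer
#'   does not bind (a primer longer than the template binds nowhere).
#' @export
matchPrimer <- function(template, primer, maxMismatches = 0) {
  tch <- .seqChars(template, "template")
  pch <- .seqChars(primer, "primer")
  n <- length(tch); k <- length(pch)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (k > n) return(empty)
  scan <- function(tmpl, strand) {
    hits <- lapply(seq_len(n - k + 1L), function(s) {
      mm <- .windowMismatches(tmpl[s:(s + k - 1L)], pch)
      if (mm <= maxMismatches)
        data.frame(start = s, end = s + k - 1L, strand = strand,
                   mismatches = mm, stringsAsFactors = FALSE)
    })
    do.call(rbind, hits)
  }
  plus <- scan(tch, "+")
  rcch <- rev(unname(.COMPLEMENT[tch]))
  minus <- scan(rcch, "-")
  if (!is.null(minus) && nrow(minus)) {
    # map from reverse-complement coordinates back to plus strand
    s <- n - minus$end + 1L
    minus$end <- n - minus$start + 1L
    minus$start <- s
  }
  out <- rbind(plus, minus)
  if (is.null(out)) empty else out[order(out$start, out$strand), , drop = FALSE]
}

#' Predict PCR products from a primer pair
#'
#' Enumerates all convergent forward/reverse binding combinations within
#' the product-size cap. Product length is inclusive of both primers. Both
#' template orientations are considered.
#'
#' @param template DNA string.
#' @param forward,reverse Primer strings, each 5'\eqn{\to}3' on its own
#'   strand (standard PCR convention).
#' @param maxMismatches Allowed mismatches per primer binding.
#' @param maxProduct Maximum product length (default 5000).
#' @return \code{data.frame} with binding coordinates, \code{strand} of
#'   the forward primer, \code{productLength} and mismatch counts; zero
#'   rows when no product is predicted.
#' @export
insilicoPCR <- function(template, forward, reverse, maxMismatches = 0,
                        maxProduct = 5000) {
  fwd <- matchPrimer(template, forward, maxMismatches)
  rev_ <- matchPrimer(template, reverse, maxMismatches)
  combos <- list()
  orient <- function(f, r, strand) {
    # f binds strand `strand`, r must bind the opposite strand downstream
    if (!nrow(f) || !nrow(r)) return(NULL)
    rows <- list()
    for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
      a <- f[i, ]; b <- r[j, ]
      if (strand == "+" && a$strand == "+" && b$strand == "-" &&
          b$start > a$end) {
        len <- b$end - a$start + 1L
        if (len <= maxProduct)
          rows[[length(rows) + 1L]] <- data.frame(
            forwardStart = a$start, forwardEnd = a$end,
            reverseStart = b$start, reverseEnd = b$end,
            strand = "+", productLength = len,
            forwardMismatches = a$mismatches,
            reverseMismatches = b$mismatches, stringsAsFactors = FALSE)
      }
      if (strand == "-" && a$strand == "-" && b$strand == "+" &&
          a$start > b$end) {
        len <- a$end - b$start + 1L
        if (len <= maxProduct)
          rows[[length(rows) + 1L]] <- data.frame(
            forwardStart = a$start, forwardEnd = a$end,
            reverseStart = b$start, reverseEnd = b$end,
            strand = "-", productLength = len,
            forwardMismatches = a$mismatches,
            reverseMismatches = b$mismatches, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows)
  }
  out <- rbind(orient(fwd, rev_, "+"), orient(fwd, rev_, "-"))
  if (is.null(out))
    out <- data.frame(forwardStart = integer(), forwardEnd = integer(),
                      reverseStart = integer(), reverseEnd = integer(),
                      strand = character(), productLength = integer(),
                      forwardMismatches = integer(),
                      reverseMismatches = integer(), stringsAsFactors = FALSE)
  out
}

#' Percent identity and coverage of a query against a reference
#'
#' Local alignment with affine gaps (match +1, mismatch -1, gap open 2,
#' gap extend 0.5 by default, via \pkg{Biostrings}). Identity is matches
#' over alignment columns; coverage is the aligned query span over the
#' query length.
#'
#' @param query,reference Ungapped DNA strings.
#' @return Named numeric vector: \code{identity} and \code{coverage}, both
#'   in percent.
#' @export
alignIdentity <- function(query, reference) {
  if (!nzchar(query) || !nzchar(reference))
    stop("input error: empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(reference),
    type = "local", substitutionMatrix = mat,
    gapOpening = 2, gapExtension = 0.5)
  cols <- Biostrings::nchar(aln)
  ident <- 100 * Biostrings::nmatch(aln) / cols
  span <- Biostrings::width(Biostrings::pattern(aln))
  c(identity = ident, coverage = 100 * span / nchar(query))
}

#' Identify a query against a local reference library
#'
#' Scores the query against every reference by local-alignment identity,
#' takes the top \code{k} hits, and assigns a taxonomic level: species (S)
#' when all hits in the top identity band agree on one species at or above
#' the species threshold; else genus (G), family (F), order (O, only when
#' the metadata carries an \code{order} column), else unassigned. The
#' default thresholds are configuration, not doctrine, and are echoed in
#' the result.
#'
#' @param query DNA string.
#' @param referenceSeqs Named character vector of reference sequences.
#' @param metadata \code{data.frame} with \code{id}, \code{species},
#'   \code{genus}, \code{family} (optionally \code{order}).
#' @param k Number of top hits considered (default 5).
#' @param thresholds Named numeric: \code{species}, \code{genus},
#'   \code{family}, \code{floor} (percent identity).
#' @param band Identity band (points below the top hit) within which hits
#'   must agree taxonomically (default 0.5).
#' @return List with \code{hits} (top-k table), \code{level} in
#'   \{S, G, F, O, unassigned\}, \code{name}, \code{thresholds}.
#' @export
identifyQuery <- function(query, referenceSeqs, metadata, k = 5,
                          thresholds = c(species = 99, genus = 95,
                                         family = 90, floor = 80),
                          band = 0.5) {
  if (!length(referenceSeqs)) stop("input error: empty reference library")
  ids <- names(referenceSeqs)
  idx <- match(ids, metadata$id)
  if (anyNA(idx))
    stop("metadata error: reference id(s) unmapped: ",
         paste(ids[is.na(idx)], collapse = ", "))
  sc <- t(vapply(referenceSeqs, function(r) alignIdentity(query, r),
                 c(identity = 0, coverage = 0)))
  hits <- data.frame(id = ids, identity = sc[, "identity"],
                     coverage = sc[, "coverage"],
                     species = metadata$species[idx],
                     genus = metadata$genus[idx],
                     family = metadata$family[idx],
                     stringsAsFactors = FALSE)
  if ("order" %in% names(metadata)) hits$order <- metadata$order[idx]
  hits <- hits[order(-hits$identity, -hits$coverage), , drop = FALSE]
  hits <- utils::head(hits, k)
  rownames(hits) <- NULL
  top <- hits$identity[1]
  inBand <- hits[hits$identity >= top - band, , drop = FALSE]
  unanimous <- function(col) length(unique(inBand[[col]])) == 1L
  level <- "unassigned"; name <- NA_character_
  if (top >= thresholds[["species"]] && unanimous("species")) {
    level <- "S"; name <- inBand$species[1]
  } else if (top >= thresholds[["genus"]] && unanimous("genus")) {
    level <- "G"; name <- inBand$genus[1]
  } else if (top >= thresholds[["family"]] && unanimous("family")) {
    level <- "F"; name <- inBand$family[1]
  } else if (top >= thresholds[["floor"]] && "order" %in% names(inBand) &&
             unanimous("order")) {
    level <- "O"; name <- inBand$order[1]
  }
  list(hits = hits, level = level, name = name, thresholds = thresholds)
}
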