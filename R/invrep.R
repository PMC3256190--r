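# Inverted-repeat detection by local alignment of a sequence against its
# own reverse complement (the EINVERTED scoring scheme: match +3,
# mismatch -4, gap 12, with the short-spacer threshold of 40).
#
# DP state H[u, v]: best score of an arm alignment whose innermost pair so
# far joins left-arm position u with right-arm position rpos = n + 1 - v.
# The left arm extends rightwards (u grows) while the right arm extends
# leftwards (rpos shrinks), so an alignment's outermost pair joins the
# left-arm start with the right-arm end, as in a hairpin stem. Restricting
# cells to u + v <= n keeps left.end < right.start (loop >= 0).

.isComplementPair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Score an inverted-repeat arm alignment
#'
#' Columns pair a left-arm character with a right-arm character
#' (antiparallel); a column is a gap column when either side is \code{-}.
#'
#' @param left,right Equal-length character vectors; \code{left[i]} pairs
#'   with \code{right[i]}.
#' @param match,mismatch Per-column scores for complementary /
#'   non-complementary base pairs (defaults +3 / -4).
#' @param gapPenalty Per-gap-column penalty (default 12, subtracted).
#' @return Integer score.
#' @examples
#' scoreArmAlignment(rep("A", 14), rep("T", 14))  # 42
#' @export
scoreArmAlignment <- function(left, right, match = 3, mismatch = -4,
                              gapPenalty = 12) {
  stopifnot(length(left) == length(right))
  gap <- left == "-" | right == "-"
  comp <- .isComplementPair(left, right) & !gap
  sum(comp) * match + sum(!comp & !gap) * mismatch - sum(gap) * gapPenalty
}

# one DP pass over the ungapped character vector x; banned positions score
# as dead cells. Returns list(H, ptr) with 1-based (u, v) in [1, n].
.irDP <- function(x, match, mismatch, gapPenalty, banned) {
  n <- length(x)
  H <- matrix(0, n + 1L, n + 1L)
  ptr <- matrix(0L, n + 1L, n + 1L)  # 0 stop, 1 diag, 2 up (gap right), 3 left (gap left)
  for (u in seq_len(n)) {
    if (banned[u]) next
    vmax <- n - u  # ensure u + v <= n
    if (vmax < 1L) break
    xu <- x[u]
    for (v in seq_len(vmax)) {
      rpos <- n + 1L - v
      if (banned[rpos]) next
      s <- if (.isComplementPair(xu, x[rpos])) match else mismatch
      diag <- H[u, v] + s
      up <- H[u, v + 1L] - gapPenalty
      left <- H[u + 1L, v] - gapPenalty
      best <- max(0, diag, up, left)
      H[u + 1L, v + 1L] <- best
      ptr[u + 1L, v + 1L] <-
        if (best == 0) 0L else if (best == diag) 1L
        else if (best == up) 2L else 3L
    }
  }
  list(H = H, ptr = ptr)
}

# traceback from cell (u, v); returns the hit description
.irTraceback <- function(x, dp, u, v) {
  n <- length(x)
  leftAln <- character(); rightAln <- character()
  uu <- u; vv <- v
  while (uu >= 1L && vv >= 1L) {
    p <- dp$ptr[uu + 1L, vv + 1L]
    if (p == 0L) break
    if (p == 1L) {
      leftAln <- c(x[uu], leftAln); rightAln <- c(x[n + 1L - vv], rightAln)
      uu <- uu - 1L; vv <- vv - 1L
    } else if (p == 2L) {
      leftAln <- c(x[uu], leftAln); rightAln <- c("-", rightAln)
      uu <- uu - 1L
    } else {
      leftAln <- c("-", leftAln); rightAln <- c(x[n + 1L - vv], rightAln)
      vv <- vv - 1L
    }
  }
  # presented outermost-first: left arm 5'->3', right arm paired 3'->5'
  list(leftStart = uu + 1L, leftEnd = u,
       rightStart = n + 1L - v, rightEnd = n - vv,
       loopLength = (n + 1L - v) - u - 1L,
       score = dp$H[u + 1L, v + 1L],
       leftAln = rev(leftAln), rightAln = rev(rightAln))
}

#' Find inverted repeats in a DNA sequence
#'
#' Dynamic-programming local alignment of the sequence against its reverse
#' complement. Gaps (\code{-}) and \code{?} in the input are stripped
#' before scanning and reported coordinates refer to the ungapped sequence
#' (use [irConservation()] to project back onto alignment columns).
#' Maximal-scoring, mutually non-overlapping hits at or above the
#' threshold are reported greedily by descending score (ties by leftmost
#' start); after each accepted hit its full span is masked and the scan
#' repeats.
#'
#' @param seq Character string (IUPAC; gaps allowed and ignored).
#' @param threshold Minimum arm-alignment score (the spacer-tuned default
#'   is 40).
#' @param match,mismatch,gapPenalty Scoring parameters, defaults +3/-4/12.
#' @param maxLoop Maximum loop length (default 2000).
#' @param maxArm Maximum arm-alignment length in columns (default
#'   unbounded).
#' @return List of hits, each with 1-based \code{leftStart}/\code{leftEnd}/
#'   \code{rightStart}/\code{rightEnd}, \code{loopLength}, \code{score} and
#'   the paired arm alignment (\code{leftAln}, \code{rightAln});
#'   [scoreArmAlignment()] on the arm alignment reproduces \code{score}.
#' @export
findInvertedRepeats <- function(seq, threshold = 40, match = 3,
                                mismatch = -4, gapPenalty = 12,
                                maxLoop = 2000, maxArm = Inf) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("parameter error: threshold must be positive")
  x <- .seqChars(seq)
  x <- x[!x %in% c("-", "?")]
  n <- length(x)
  if (n < 2L) stop("sequence too short")
  banned <- rep(FALSE, n)
  hits <- list()
  repeat {
    dp <- .irDP(x, match, mismatch, gapPenalty, banned)
    # walk candidate end cells by descending score; a hit is accepted only
    # when its whole span (arms plus loop) avoids previously accepted
    # spans, so nested/enclosing repeats are never double-reported
    hit <- NULL
    scores <- sort(unique(dp$H[dp$H >= threshold]), decreasing = TRUE)
    for (sc in scores) {
      cand <- which(dp$H == sc, arr.ind = TRUE)
      cands <- lapply(seq_len(nrow(cand)), function(i) {
        u <- as.integer(cand[i, 1]) - 1L
        v <- as.integer(cand[i, 2]) - 1L
        .irTraceback(x, dp, u, v)
      })
      ok <- vapply(cands, function(h)
        h$loopLength <= maxLoop && length(h$leftAln) <= maxArm &&
          !any(banned[h$leftStart:h$rightEnd]), TRUE)
      cands <- cands[ok]
      if (!length(cands)) next
      ord <- order(vapply(cands, `[[`, 0L, "leftStart"),
                   vapply(cands, `[[`, 0L, "rightStart"))
      hit <- cands[[ord[1]]]
      break
    }
    if (is.null(hit)) break
    hits[[length(hits) + 1L]] <- hit
    banned[hit$leftStart:hit$rightEnd] <- TRUE
  }
  hits
}

#' Scan every row of an alignment for inverted repeats
#'
#' @param aln A [BarcodeAlignment-class].
#' @param ... Passed to [findInvertedRepeats()].
#' @return Named list (by sequence id) of hit lists in ungapped row
#'   coordinates.
#' @export
scanAlignmentIRs <- function(aln, ...) {
  m <- seqMatrix(aln)
  out <- lapply(seq_len(nrow(m)), function(i)
    findInvertedRepeats(paste(m[i, ], collapse = ""), ...))
  names(out) <- rownames(m)
  out
}

#' Inverted-repeat conservation across an alignment
#'
#' Maps each row's IR footprint (union of the two arm intervals, ungapped
#' coordinates) into alignment columns, then quantifies footprint overlap
#' between rows as Jaccard indices -- the quantitative form of shading
#' conserved IRs on an alignment.
#'
#' @param aln A [BarcodeAlignment-class] providing the common coordinate
#'   frame.
#' @param hitsPerRow As returned by [scanAlignmentIRs()] (named by
#'   sequence id; ungapped coordinates).
#' @param groups Optional named list of sequence-id vectors; when given,
#'   mean within-group and between-group Jaccard values are reported per
#'   group.
#' @return List with \code{occupancy} (logical rows x columns matrix),
#'   \code{jaccard} (rows x rows), and \code{groupSummary} when groups are
#'   supplied.
#' @export
irConservation <- function(aln, hitsPerRow, groups = NULL) {
  m <- seqMatrix(aln)
  ids <- rownames(m)
  miss <- setdiff(names(hitsPerRow), ids)
  if (length(miss))
    stop("input error: hit row(s) not in alignment: ",
         paste(miss, collapse = ", "))
  occ <- matrix(FALSE, nrow(m), ncol(m), dimnames = list(ids, NULL))
  for (id in names(hitsPerRow)) {
    colsOfUngapped <- which(!m[id, ] %in% c("-", "?"))
    for (h in hitsPerRow[[id]]) {
      span <- c(h$leftStart:h$leftEnd, h$rightStart:h$rightEnd)
      occ[id, colsOfUngapped[span]] <- TRUE
    }
  }
  n <- length(ids)
  jac <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    un <- sum(occ[i, ] | occ[j, ])
    jac[i, j] <- if (un == 0) NA_real_ else sum(occ[i, ] & occ[j, ]) / un
  }
  out <- list(occupancy = occ, jaccard = jac)
  if (!is.null(groups)) {
    rows <- lapply(names(groups), function(g) {
      within <- jac[groups[[g]], groups[[g]], drop = FALSE]
      within <- within[upper.tri(within)]
      othr <- setdiff(ids, groups[[g]])
      between <- jac[groups[[g]], othr, drop = FALSE]
      data.frame(group = g,
                 withinJaccard = mean(within, na.rm = TRUE),
                 betweenJaccard = if (length(othr))
                   mean(between, na.rm = TRUE) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    out$groupSummary <- do.call(rbind, rows)
  }
  out
}
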