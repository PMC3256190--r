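# Character-based barcoding: pure, simple characteristic attributes (CAs)
# per clade/taxon, and query classification by CA matching.
#
# A pure simple CA for group X at column c with state s means: every group
# member with a determinate character at c carries s, and s occurs in no
# non-member at c. Missing data (gap/'?'/ambiguity) inside the group does
# not break fixation; missing data outside never counts as a violation.

# determinate states at a column; gaps count only when gapAsState
.detStates <- function(chars, gapAsState) {
  keep <- chars %in% .BASES | (gapAsState & chars == "-")
  chars[keep]
}

#' Find pure characteristic attributes
#'
#' Exhaustive column scan over all groups of a grouping. Columns where the
#' whole group is missing are skipped.
#'
#' @param aln A [BarcodeAlignment-class].
#' @param grouping Named list of character vectors: member sequence ids per
#'   group. Every group must be non-empty; groups may overlap (e.g. nested
#'   tree clades).
#' @param gapAsState Allow \code{-} as a diagnostic state (indel-borne
#'   diagnostics; default \code{FALSE}). \code{?} and ambiguity codes are
#'   never diagnostic.
#' @param groupingSource Free-text provenance label stored in the result.
#' @return A [CATable-class].
#' @export
findPureCAs <- function(aln, grouping, gapAsState = FALSE,
                        groupingSource = "metadata") {
  m <- seqMatrix(aln)
  ids <- rownames(m)
  for (g in names(grouping)) {
    if (!length(grouping[[g]]))
      stop("grouping error: group '", g, "' has zero members")
    miss <- setdiff(grouping[[g]], ids)
    if (length(miss))
      stop("grouping error: unknown id(s) in group '", g, "': ",
           paste(miss, collapse = ", "))
  }
  rows <- list()
  for (g in names(grouping)) {
    inside <- ids %in% grouping[[g]]
    if (all(inside)) next  # no outside: nothing can be diagnostic
    for (col in seq_len(ncol(m))) {
      ins <- .detStates(m[inside, col], gapAsState)
      if (!length(ins)) next
      s <- ins[1]
      if (any(ins != s)) next
      out <- .detStates(m[!inside, col], gapAsState)
      if (s %in% out) next
      rows[[length(rows) + 1L]] <- data.frame(
        clade = g, position = col, state = unname(s),
        insideCount = length(ins), outsideCount = 0L,
        stringsAsFactors = FALSE)
    }
  }
  attrs <- if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  } else
    data.frame(clade = character(), position = integer(),
               state = character(), insideCount = integer(),
               outsideCount = integer(), stringsAsFactors = FALSE)
  new("CATable", groupingSource = groupingSource, attributes = attrs,
      alignmentLength = ncol(m), groups = grouping)
}

#' Classify an aligned query by CA matching
#'
#' Scores each clade as the fraction of its CAs matched by the query; the
#' assignment is the unique top scorer at or above the floor. Clades with
#' no CAs score \code{NA} and never win; ties or sub-floor top scores leave
#' the query unassigned.
#'
#' @param query Character vector (or string) aligned to the same column
#'   space as the CA table's alignment.
#' @param caTable A [CATable-class].
#' @param floor Minimum score for an assignment (default 0.8).
#' @return List with \code{scores} (named, sorted decreasing),
#'   \code{assigned} (clade label or \code{NA}).
#' @export
classifyByCAs <- function(query, caTable, floor = 0.8) {
  if (is.character(query) && length(query) == 1L) query <- .seqChars(query)
  if (length(query) != caTable@alignmentLength)
    stop("shape error: query length ", length(query),
         " != alignment length ", caTable@alignmentLength)
  a <- caAttributes(caTable)
  scores <- vapply(names(caTable@groups), function(g) {
    rows <- a[a$clade == g, , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    mean(query[rows$position] == rows$state)
  }, 0)
  ord <- order(-scores, na.last = TRUE)
  scores <- scores[ord]
  defined <- scores[!is.na(scores)]
  assigned <- NA_character_
  if (length(defined) && defined[1] >= floor &&
      sum(defined == defined[1]) == 1L)
    assigned <- names(defined)[1]
  list(scores = scores, assigned = assigned)
}

#' Derive a grouping from a guide tree
#'
#' One group per internal node with at least \code{minSize} leaves (node
#' label or a synthesized \code{node<N>} label); with \code{minSize = 1}
#' every leaf additionally becomes its own group, giving taxon-level CAs.
#'
#' @param tree \code{ape::phylo}; its tip set must equal the alignment's
#'   sequence ids when used with [findPureCAs()].
#' @param minSize Minimum leaf count for an internal-node group.
#' @param includeRoot Keep the root group (all leaves; default
#'   \code{FALSE} since it can never be diagnostic).
#' @return Named list of leaf-id vectors.
#' @export
groupsFromTree <- function(tree, minSize = 2, includeRoot = FALSE) {
  ntip <- length(tree$tip.label)
  groups <- list()
  rootNode <- ntip + 1L
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    if (!includeRoot && node == rootNode) next
    tips <- tree$tip.label[.descendantTips(tree, node)]
    if (length(tips) < minSize) next
    lab <- if (!is.null(tree$node.label) &&
               nzchar(tree$node.label[node - ntip]))
      tree$node.label[node - ntip] else paste0("node", node)
    groups[[lab]] <- tips
  }
  if (minSize <= 1)
    for (tp in tree$tip.label) groups[[tp]] <- tp
  groups
}

# tip indices descending from an internal node
.descendantTips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  todo <- node
  tips <- integer()
  while (length(todo)) {
    cur <- todo[1]; todo <- todo[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    tips <- c(tips, kids[kids <= ntip])
    todo <- c(todo, kids[kids > ntip])
  }
  sort(tips)
}
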