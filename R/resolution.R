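# Species-resolution and branch-support aggregation.
#
# Operational definition (printed in every report): a species is resolved
# when its sequences form an exclusive clade (monophyletic) whose most
# recent common ancestor carries bootstrap/consensus support at or above
# the threshold. Singleton species are excluded from the denominator by
# default; average branch support is taken over well-resolved internal
# nodes only (support >= threshold).

# numeric supports per internal node of a tree (NA where absent/blank)
.nodeSupports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Assess monophyly of groups on a tree
#'
#' A group is monophyletic when the most recent common ancestor (MRCA) of
#' its leaves contains no other leaves. Monophyly is read on the tree's
#' rooted representation; root or midpoint-root the tree first if its
#' orientation is arbitrary. Singleton groups are monophyletic by
#' convention, with the support of their parent edge.
#'
#' @param tree \code{ape::phylo}, optionally with supports in
#'   \code{node.label}.
#' @param metadata \code{data.frame} with \code{id} plus the grouping
#'   column; every leaf must be mapped.
#' @param rank Name of the grouping column (e.g. \code{"species"}).
#' @return \code{data.frame} with one row per group: \code{group},
#'   \code{nLeaves}, \code{monophyletic}, \code{support} (MRCA support; 0
#'   when the label is absent or blank).
#' @export
assessMonophyly <- function(tree, metadata, rank = "species") {
  idx <- match(tree$tip.label, metadata$id)
  if (anyNA(idx))
    stop("metadata error: unmapped leaf/leaves: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  grp <- metadata[[rank]][idx]
  sup <- .nodeSupports(tree)
  ntip <- length(tree$tip.label)
  out <- lapply(unique(grp), function(g) {
    tips <- tree$tip.label[grp == g]
    if (length(tips) == 1L) {
      tip <- match(tips, tree$tip.label)
      parent <- tree$edge[tree$edge[, 2] == tip, 1]
      s <- sup[parent - ntip]
      return(data.frame(group = g, nLeaves = 1L, monophyletic = TRUE,
                        support = ifelse(is.na(s), 0, s),
                        stringsAsFactors = FALSE))
    }
    mono <- ape::is.monophyletic(tree, tips)
    mrca <- ape::getMRCA(tree, tips)
    s <- sup[mrca - ntip]
    data.frame(group = g, nLeaves = length(tips), monophyletic = mono,
               support = ifelse(is.na(s), 0, s), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Species-resolution report for one tree
#'
#' A species with two or more sequences is resolved when it is
#' monophyletic and its MRCA support reaches the threshold. Singleton
#' species follow the chosen policy.
#'
#' @param tree Tree with supports (e.g. from [bootstrapSupport()]), rooted
#'   sensibly (midpoint rooting is applied when the tree is unrooted).
#' @param metadata \code{data.frame} with \code{id} and the rank column.
#' @param threshold Support threshold in percent (default 50).
#' @param rank Grouping column, default \code{"species"}.
#' @param singletonPolicy \code{"exclude"} (default) drops single-sequence
#'   species from the denominator; \code{"count_if_supported"} counts one
#'   as resolved when its parent-edge support reaches the threshold.
#' @param method,lociCombo Optional labels carried into the report.
#' @return List of class \code{resolutionReport}: per-species table,
#'   \code{resolutionPct}, \code{meanSupport} (mean over internal nodes
#'   with support >= threshold), \code{threshold}, labels.
#' @export
speciesResolution <- function(tree, metadata, threshold = 50,
                              rank = "species",
                              singletonPolicy = c("exclude",
                                                  "count_if_supported"),
                              method = "", lociCombo = "") {
  singletonPolicy <- match.arg(singletonPolicy)
  if (!ape::is.rooted(tree)) {
    # parsimony trees may come without branch lengths; midpoint rooting
    # then falls back to unit lengths (topological balance point)
    if (is.null(tree$edge.length))
      tree$edge.length <- rep(1, nrow(tree$edge))
    tree <- phangorn::midpoint(tree)
  }
  tab <- assessMonophyly(tree, metadata, rank)
  multi <- tab$nLeaves >= 2L
  tab$evaluable <- multi | singletonPolicy == "count_if_supported"
  tab$resolved <- tab$evaluable & tab$monophyletic & tab$support >= threshold
  if (!any(tab$evaluable))
    stop("degenerate input: no evaluable species ",
         "(all singletons under policy 'exclude')")
  sup <- .nodeSupports(tree)
  well <- sup[!is.na(sup) & sup >= threshold]
  structure(list(
    perSpecies = tab,
    resolutionPct = 100 * sum(tab$resolved) / sum(tab$evaluable),
    meanSupport = if (length(well)) mean(well) else NA_real_,
    threshold = threshold, rank = rank, method = method,
    lociCombo = lociCombo,
    definition = paste("resolved = exclusive clade with MRCA support >=",
                       threshold, "; singletons:", singletonPolicy)),
    class = "resolutionReport")
}

#' @export
print.resolutionReport <- function(x, ...) {
  cat(sprintf("Resolution report%s%s\n",
              if (nzchar(x$lociCombo)) paste0(" [", x$lociCombo, "]") else "",
              if (nzchar(x$method)) paste0(" (", x$method, ")") else ""))
  cat(" ", x$definition, "\n")
  cat(sprintf("  resolution: %.1f%%  mean support (nodes >= %g): %s\n",
              x$resolutionPct, x$threshold,
              ifelse(is.na(x$meanSupport), "NA",
                     sprintf("%.1f", x$meanSupport))))
  invisible(x)
}

#' Aggregate resolution reports across methods
#'
#' Unweighted mean and standard error over methods, per locus combination
#' (the shape of a combo-by-method support/resolution figure). When a combo
#' has a single method its SE is reported as 0 and flagged.
#'
#' @param reports List of [speciesResolution()] reports.
#' @param composition Optional [compositionTable()] to join PIC\% by combo
#'   name.
#' @return \code{data.frame}: one row per combo with
#'   \code{meanResolution}, \code{seResolution}, \code{meanSupport},
#'   \code{seSupport}, \code{nMethods}, \code{singleMethod} flag, and
#'   \code{pctPIC} when joined.
#' @export
aggregateMethods <- function(reports, composition = NULL) {
  stopifnot(length(reports) >= 1L)
  combos <- vapply(reports, function(r) r$lociCombo, "")
  se <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
  out <- lapply(unique(combos), function(cb) {
    rs <- reports[combos == cb]
    res <- vapply(rs, function(r) r$resolutionPct, 0)
    sup <- vapply(rs, function(r) r$meanSupport, 0)
    data.frame(lociCombo = cb,
               methods = paste(vapply(rs, function(r) r$method, ""),
                               collapse = "+"),
               nMethods = length(rs),
               meanResolution = mean(res), seResolution = se(res),
               meanSupport = mean(sup, na.rm = TRUE),
               seSupport = se(sup[!is.na(sup)]),
               singleMethod = length(rs) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(composition))
    out$pctPIC <- composition$pctPIC[match(out$lociCombo, composition$name)]
  out
}
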