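# Site-composition statistics: conserved / variable / singleton /
# parsimony-informative classification of alignment columns.

#' Classify one alignment column
#'
#' Only unambiguous bases (A/C/G/T) are comparable; gaps, \code{?} and IUPAC
#' ambiguity codes are excluded. A column with fewer than two comparable
#' bases is indeterminate. A variable column is parsimony-informative (PIC)
#' when at least two states each occur at least twice; otherwise it is a
#' singleton site.
#'
#' @param column Character vector, one character per sequence.
#' @return List with \code{nComparable}, \code{states} (named base counts),
#'   \code{label} in \{conserved, variable, indeterminate\} and
#'   \code{sublabel} in \{singleton, parsimony_informative, NA\}.
#' @examples
#' classifySite(c("A", "A", "T", "T"))$sublabel
#' @export
classifySite <- function(column) {
  bases <- column[.isBase(column)]
  counts <- table(factor(bases, levels = .BASES))
  counts <- counts[counts > 0]
  n <- length(bases)
  if (n < 2L)
    return(list(nComparable = n, states = counts,
                label = "indeterminate", sublabel = NA_character_))
  if (length(counts) < 2L)
    return(list(nComparable = n, states = counts,
                label = "conserved", sublabel = NA_character_))
  pic <- sum(counts >= 2L) >= 2L
  list(nComparable = n, states = counts, label = "variable",
       sublabel = if (pic) "parsimony_informative" else "singleton")
}

# vectorised column labels for a character matrix; returns factor vector in
# {conserved, singleton, pic, indeterminate}
.siteLabels <- function(m) {
  apply(m, 2, function(col) {
    cl <- classifySite(col)
    if (cl$label == "indeterminate") "indeterminate"
    else if (cl$label == "conserved") "conserved"
    else if (cl$sublabel == "parsimony_informative") "pic" else "singleton"
  })
}

#' Site composition of an alignment
#'
#' Aggregates [classifySite()] over all columns. Percentages use the number
#' of non-indeterminate columns as denominator, so
#' conserved + variable = 100 and singleton + PIC = variable.
#'
#' @param aln A [BarcodeAlignment-class] (or [Supermatrix-class]).
#' @return List with \code{name}, integer counts (\code{conserved},
#'   \code{singleton}, \code{pic}, \code{variable}, \code{indeterminate},
#'   \code{denominator}) and percentages (\code{pctConserved},
#'   \code{pctVariable}, \code{pctSingleton}, \code{pctPIC}).
#' @export
siteComposition <- function(aln) {
  m <- seqMatrix(aln)
  if (nrow(m) < 2L)
    stop("degenerate input: site composition needs at least 2 sequences")
  lab <- .siteLabels(m)
  n <- c(conserved = sum(lab == "conserved"),
         singleton = sum(lab == "singleton"),
         pic = sum(lab == "pic"),
         indeterminate = sum(lab == "indeterminate"))
  den <- ncol(m) - n[["indeterminate"]]
  pct <- function(k) if (den > 0) 100 * k / den else NA_real_
  list(name = locusName(aln),
       conserved = n[["conserved"]], singleton = n[["singleton"]],
       pic = n[["pic"]], variable = n[["singleton"]] + n[["pic"]],
       indeterminate = n[["indeterminate"]], denominator = den,
       pctConserved = pct(n[["conserved"]]),
       pctVariable = pct(n[["singleton"]] + n[["pic"]]),
       pctSingleton = pct(n[["singleton"]]),
       pctPIC = pct(n[["pic"]]))
}

#' Tabulate site composition across loci and combinations
#'
#' @param reports List of [siteComposition()] results.
#' @param sortByPIC Sort rows by PIC percentage, descending; ties keep input
#'   order.
#' @return \code{data.frame}, one row per locus/combination, percentages to
#'   one decimal place in the \code{pct*} columns.
#' @export
compositionTable <- function(reports, sortByPIC = FALSE) {
  stopifnot(length(reports) >= 1L)
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(name = r$name, columns = r$denominator + r$indeterminate,
               denominator = r$denominator,
               pctConserved = round(r$pctConserved, 1),
               pctVariable = round(r$pctVariable, 1),
               pctSingleton = round(r$pctSingleton, 1),
               pctPIC = round(r$pctPIC, 1),
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  if (sortByPIC)
    tab <- tab[order(-tab$pctPIC, seq_len(nrow(tab))), , drop = FALSE]
  tab
}
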