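#' @rdname BarcodeAlignment-class
#' @export
setMethod("locusName", "BarcodeAlignment", function(x) x@locus)

#' @rdname BarcodeAlignment-class
#' @export
setMethod("seqMatrix", "BarcodeAlignment", function(x) x@seqs)

#' @rdname BarcodeAlignment-class
#' @export
setMethod("taxonInfo", "BarcodeAlignment", function(x) x@meta)

#' @rdname BarcodeAlignment-class
#' @export
setMethod("alignmentLength", "BarcodeAlignment", function(x) ncol(x@seqs))

#' @rdname BarcodeAlignment-class
#' @export
setMethod("seqIDs", "BarcodeAlignment", function(x) rownames(x@seqs))

#' @rdname BarcodeAlignment-class
#' @export
setMethod("length", "BarcodeAlignment", function(x) nrow(x@seqs))

setMethod("show", "BarcodeAlignment", function(object) {
  cat(sprintf("BarcodeAlignment '%s': %d sequences x %d columns\n",
              object@locus, nrow(object@seqs), ncol(object@seqs)))
  sp <- unique(object@meta$species)
  sp <- sp[!is.na(sp) & nzchar(sp)]
  if (length(sp))
    cat(sprintf("  %d species, %d genera, %d families\n", length(sp),
                length(unique(object@meta$genus[nzchar(object@meta$genus)])),
                length(unique(object@meta$family[nzchar(object@meta$family)]))))
})

#' @rdname Supermatrix-class
#' @export
setMethod("partitionTable", "Supermatrix", function(x) x@partitions)

setMethod("show", "Supermatrix", function(object) {
  cat(sprintf("Supermatrix: %d taxa x %d columns, %d partitions\n",
              nrow(object@seqs), ncol(object@seqs), nrow(object@partitions)))
  for (i in seq_len(nrow(object@partitions)))
    cat(sprintf("  %-12s %d-%d\n", object@partitions$locus[i],
                object@partitions$start[i], object@partitions$end[i]))
})

#' @rdname GapReport-class
#' @export
setMethod("intraDistances", "GapReport", function(x) x@intra)

#' @rdname GapReport-class
#' @export
setMethod("interDistances", "GapReport", function(x) x@inter)

#' @rdname GapReport-class
#' @export
setMethod("gapStat", "GapReport", function(x) {
  if (!length(x@intra) || !length(x@inter)) return(NA_real_)
  min(x@inter) - max(x@intra)
})

#' @rdname GapReport-class
#' @export
setMethod("overlapFraction", "GapReport", function(x) {
  if (!length(x@intra) || !length(x@inter)) return(NA_real_)
  mean(x@intra >= min(x@inter))
})

setMethod("show", "GapReport", function(object) {
  cat(sprintf("GapReport at rank '%s'\n", object@rank))
  fmt <- function(v) if (length(v))
    sprintf("n=%d mean=%.4f min=%.4f max=%.4f", length(v), mean(v), min(v), max(v))
  else "empty"
  cat("  intra: ", fmt(object@intra), "\n", sep = "")
  cat("  inter: ", fmt(object@inter), "\n", sep = "")
  if (object@nUndefined > 0)
    cat("  undefined pairs excluded:", object@nUndefined, "\n")
  g <- gapStat(object)
  cat(sprintf("  gap statistic: %s, overlap fraction: %s\n",
              ifelse(is.na(g), "undefined", sprintf("%.4f", g)),
              ifelse(is.na(g), "undefined",
                     sprintf("%.3f", overlapFraction(object)))))
})

#' @rdname CATable-class
#' @export
setMethod("caAttributes", "CATable", function(x) x@attributes)

#' @rdname CATable-class
#' @export
setMethod("caCounts", "CATable", function(x) {
  n <- vapply(names(x@groups), function(g) sum(x@attributes$clade == g), 0L)
  data.frame(clade = names(x@groups), nCA = unname(n),
             denominator = x@alignmentLength,
             label = sprintf("%d/%d", unname(n), x@alignmentLength),
             stringsAsFactors = FALSE)
})

setMethod("show", "CATable", function(object) {
  cat(sprintf("CATable (%s): %d pure CAs over %d groups, alignment length %d\n",
              object@groupingSource, nrow(object@attributes),
              length(object@groups), object@alignmentLength))
  tab <- caCounts(object)
  for (i in seq_len(min(nrow(tab), 12)))
    cat(sprintf("  %-24s %s\n", tab$clade[i], tab$label[i]))
  if (nrow(tab) > 12) cat("  ...\n")
})
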