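# Shared alphabet conventions.
#
# One missing-data rule is used across the whole package: only unambiguous
# bases A/C/G/T are "determinate"; '-' is an alignment gap, '?' missing data,
# and IUPAC ambiguity codes are treated as missing for statistics (they are
# never expanded into candidate bases).

.BASES <- c("A", "C", "G", "T")
.AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
.ALPHABET <- c(.BASES, .AMBIG, "-", "?")

.COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N",
  "-" = "-", "?" = "?"
)

# IUPAC code -> set of bases it denotes
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' Complements IUPAC ambiguity codes and preserves gap/missing characters.
#'
#' @param x Character scalar over the IUPAC alphabet (plus \code{-}/\code{?}).
#' @return Character scalar, the reverse complement.
#' @examples
#' reverseComplement("ACGTR")
#' @export
reverseComplement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- toupper(strsplit(x, "", fixed = TRUE)[[1]])
  bad <- which(!ch %in% names(.COMPLEMENT))
  if (length(bad))
    stop("illegal character '", ch[bad[1]], "' at position ", bad[1])
  paste(rev(unname(.COMPLEMENT[ch])), collapse = "")
}

# split a sequence string into an uppercase character vector, validating
# against the package alphabet; `what` names the sequence in error messages
.seqChars <- function(x, what = "sequence") {
  ch <- toupper(strsplit(x, "", fixed = TRUE)[[1]])
  ch[ch == "U"] <- "T"
  bad <- which(!ch %in% .ALPHABET)
  if (length(bad))
    stop(what, ": illegal character '", ch[bad[1]], "' at position ", bad[1])
  ch
}

.isBase <- function(ch) ch %in% .BASES

# does IUPAC primer character p cover template base b?
.iupacCovers <- function(p, b) {
  set <- .IUPAC_SETS[[p]]
  !is.null(set) && b %in% set
}
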