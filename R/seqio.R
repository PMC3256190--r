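# Readers/writers and constructors for the core containers.

.emptyMeta <- function(ids) {
  data.frame(id = ids, species = "", genus = "", family = "", site = "",
             stringsAsFactors = FALSE)
}

# build a BarcodeAlignment from a named character vector of sequence strings
.alignmentFromStrings <- function(strings, locus, meta = NULL) {
  ids <- names(strings)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequence ids must be present and unique")
  rows <- lapply(seq_along(strings), function(i)
    .seqChars(strings[[i]], what = paste0("sequence '", ids[i], "'")))
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("alignment shape error: row lengths differ (",
         paste(unique(lens), collapse = ", "), ")")
  m <- matrix(unlist(rows), nrow = length(rows), byrow = TRUE,
              dimnames = list(ids, NULL))
  if (is.null(meta)) meta <- .emptyMeta(ids)
  rownames(meta) <- NULL
  new("BarcodeAlignment", locus = locus, seqs = m, meta = meta)
}

#' Construct a BarcodeAlignment from sequence strings
#'
#' @param strings Named character vector of equal-length aligned sequences.
#' @param locus Locus name.
#' @param meta Optional metadata \code{data.frame} (columns
#'   id/species/genus/family/site, one row per sequence in order). Missing
#'   metadata is filled with empty strings.
#' @return A [BarcodeAlignment-class].
#' @examples
#' barcodeAlignment(c(s1 = "ACGT", s2 = "ACGA"), "rbcL")
#' @export
barcodeAlignment <- function(strings, locus, meta = NULL)
  .alignmentFromStrings(strings, locus, meta)

#' Read an aligned FASTA file into a BarcodeAlignment
#'
#' Headers may carry metadata in a pipe-delimited dialect:
#' \code{>id|species|genus|family|site} (trailing fields optional). Lowercase
#' is normalised to uppercase and \code{U} to \code{T}. All rows must have
#' equal length (the file is an alignment, not raw reads).
#'
#' @param path Path to a FASTA file, or a character vector of FASTA text
#'   lines.
#' @param locus Locus name to record.
#' @return A [BarcodeAlignment-class].
#' @export
readFastaAlignment <- function(path, locus) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path))
    readLines(path) else unlist(strsplit(path, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records found")
  starts <- hdr + 1L
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (starts[i] > ends[i]) "" else
      paste(trimws(lines[starts[i]:ends[i]]), collapse = "")
  }, "")
  fields <- strsplit(sub("^>", "", trimws(lines[hdr])), "|", fixed = TRUE)
  ids <- vapply(fields, `[[`, "", 1L)
  pick <- function(f, i) if (length(f) >= i) trimws(f[[i]]) else ""
  species <- vapply(fields, pick, "", 2L)
  genus <- vapply(fields, pick, "", 3L)
  family <- vapply(fields, pick, "", 4L)
  site <- vapply(fields, pick, "", 5L)
  genus <- ifelse(!nzchar(genus) & nzchar(species),
                  sub("\\s.*$", "", species), genus)
  meta <- data.frame(id = ids, species = species, genus = genus,
                     family = family, site = site, stringsAsFactors = FALSE)
  names(seqs) <- ids
  .alignmentFromStrings(seqs, locus, meta)
}

#' Write a BarcodeAlignment to aligned FASTA
#'
#' Metadata rides in the header using the same pipe-delimited dialect
#' accepted by [readFastaAlignment()].
#'
#' @param aln A [BarcodeAlignment-class].
#' @param path Output path; if \code{NULL} the FASTA text is returned
#'   invisibly as a character vector.
#' @param withMeta Include species/genus/family/site in headers.
#' @export
writeFastaAlignment <- function(aln, path = NULL, withMeta = TRUE) {
  m <- seqMatrix(aln)
  meta <- taxonInfo(aln)
  hdr <- if (withMeta)
    paste0(">", meta$id, "|", meta$species, "|", meta$genus, "|",
           meta$family, "|", meta$site)
  else paste0(">", meta$id)
  txt <- as.vector(rbind(hdr, apply(m, 1, paste, collapse = "")))
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(txt)
}

#' Read a taxon metadata table
#'
#' TSV with header columns \code{id}, \code{species}, \code{genus},
#' \code{family}, \code{site}. Genus is derived from the species binomial
#' when the genus column is empty.
#'
#' @param path Path to the TSV file.
#' @return \code{data.frame} keyed by \code{id} (ids unique).
#' @export
readTaxonTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "species", "genus", "family", "site")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("taxon table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicate id in taxon table: ",
         tab$id[duplicated(tab$id)][1])
  blank <- !nzchar(tab$genus) & nzchar(tab$species)
  tab$genus[blank] <- sub("\\s.*$", "", tab$species[blank])
  tab[need]
}

#' Attach a taxon table to an alignment
#'
#' The side table is authoritative: on conflict with FASTA-header metadata
#' the table wins. In strict mode an alignment id absent from the table is
#' an error; in lenient mode it keeps its header metadata (or placeholders).
#'
#' @param aln A [BarcodeAlignment-class].
#' @param table Metadata \code{data.frame} as from [readTaxonTable()].
#' @param strict Error on ids missing from the table (default \code{TRUE}).
#' @return The alignment with updated metadata.
#' @export
attachTaxonTable <- function(aln, table, strict = TRUE) {
  meta <- taxonInfo(aln)
  idx <- match(meta$id, table$id)
  if (strict && anyNA(idx))
    stop("alignment id(s) absent from taxon table: ",
         paste(meta$id[is.na(idx)], collapse = ", "))
  hit <- !is.na(idx)
  for (col in c("species", "genus", "family", "site"))
    meta[[col]][hit] <- table[[col]][idx[hit]]
  initialize(aln, meta = meta)
}

#' Read / write Newick trees
#'
#' Thin wrappers around \pkg{ape}'s Newick parser kept so every pipeline
#' stage speaks through one interface. Internal node labels are used to
#' carry percent support values.
#'
#' @param text Newick string (or path for \code{readNewick} when the string
#'   names an existing file).
#' @return An \code{ape::phylo} tree.
#' @export
readNewick <- function(text) {
  tr <- suppressWarnings(
    if (length(text) == 1L && !grepl("[(;]", text) && file.exists(text))
      ape::read.tree(file = text) else ape::read.tree(text = text))
  if (is.null(tr)) stop("Newick parse error")
  tr
}

#' @rdname readNewick
#' @param tree An \code{ape::phylo} tree.
#' @param path Optional output file.
#' @export
writeNewick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Concatenate per-locus alignments into a supermatrix
#'
#' Rows are the union of taxa across loci (by \code{taxonKey}); partitions
#' are laid out in input order; a taxon absent from a locus has that
#' partition filled with \code{?}. A taxon occurring twice within one locus
#' is an ambiguity error, never a silent overwrite.
#'
#' @param alignments List of [BarcodeAlignment-class] objects.
#' @param taxonKey Function mapping a metadata row (1-row data.frame) to the
#'   taxon row label; the default uses the sequence id, which the simulator
#'   and most curated datasets share across loci.
#' @return A [Supermatrix-class].
#' @export
buildSupermatrix <- function(alignments,
                             taxonKey = function(meta) meta$id) {
  stopifnot(length(alignments) >= 1L)
  keyOf <- function(aln) {
    meta <- taxonInfo(aln)
    vapply(seq_len(nrow(meta)), function(i) taxonKey(meta[i, , drop = FALSE]), "")
  }
  keys <- lapply(alignments, keyOf)
  for (i in seq_along(alignments)) {
    d <- keys[[i]][duplicated(keys[[i]])]
    if (length(d))
      stop("ambiguity error: taxon '", d[1], "' occurs more than once in locus '",
           locusName(alignments[[i]]), "'")
  }
  taxa <- unique(unlist(keys))
  lens <- vapply(alignments, alignmentLength, 0L)
  total <- sum(lens)
  m <- matrix("?", nrow = length(taxa), ncol = total,
              dimnames = list(taxa, NULL))
  start <- cumsum(c(1L, lens[-length(lens)]))
  for (i in seq_along(alignments)) {
    cols <- start[i]:(start[i] + lens[i] - 1L)
    m[keys[[i]], cols] <- seqMatrix(alignments[[i]])
  }
  parts <- data.frame(
    locus = vapply(alignments, locusName, ""),
    start = as.integer(start), end = as.integer(start + lens - 1L),
    stringsAsFactors = FALSE)
  # taxon-level metadata: first metadata row seen per taxon
  allMeta <- do.call(rbind, lapply(alignments, taxonInfo))
  allKeys <- unlist(keys)
  meta <- allMeta[match(taxa, allKeys), , drop = FALSE]
  meta$id <- taxa
  rownames(meta) <- NULL
  new("Supermatrix", locus = paste(parts$locus, collapse = "+"),
      seqs = m, meta = meta, partitions = parts)
}

#' Export an alignment or supermatrix as NEXUS
#'
#' Writes a DATA block (ape's NEXUS writer) plus, for supermatrices, a SETS
#' block with one charset per locus partition.
#'
#' @param aln A [BarcodeAlignment-class] or [Supermatrix-class].
#' @param path Output file.
#' @export
writeNexus <- function(aln, path) {
  m <- seqMatrix(aln)
  rows <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  ape::write.nexus.data(as.list(rows), file = path, interleaved = FALSE)
  if (is(aln, "Supermatrix")) {
    p <- partitionTable(aln)
    sets <- c("begin sets;",
              sprintf("  charset %s = %d-%d;", gsub("[^A-Za-z0-9_]", "_", p$locus),
                      p$start, p$end),
              "end;")
    cat(sets, file = path, sep = "\n", append = TRUE)
  }
  invisible(path)
}
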