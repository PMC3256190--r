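# Shared fixture builders; everything is generated in code.

# alignment from a character vector of strings with auto ids s1, s2, ...
aln <- function(..., locus = "test", ids = NULL, meta = NULL) {
  strings <- c(...)
  if (is.null(ids)) ids <- paste0("s", seq_along(strings))
  names(strings) <- ids
  barcodeAlignment(strings, locus, meta = meta)
}

# metadata table for ids following the Genus_spN_iN convention of the
# simulator, or built explicitly
metaTable <- function(ids, species, genus = sub("\\s.*$", "", species),
                      family = "Fam", site = "") {
  data.frame(id = ids, species = species, genus = genus,
             family = rep_len(family, length(ids)),
             site = rep_len(site, length(ids)), stringsAsFactors = FALSE)
}

# random ungapped alignment matrix (rows x cols) over ACGT, optional
# missing-data characters sprinkled in
randomAlignment <- function(nrow, ncol, pMissing = 0, locus = "rand") {
  chars <- sample(c("A", "C", "G", "T"), nrow * ncol, replace = TRUE)
  if (pMissing > 0) {
    k <- rbinom(1, nrow * ncol, pMissing)
    if (k > 0)
      chars[sample(nrow * ncol, k)] <-
        sample(c("-", "?", "N", "R"), k, replace = TRUE)
  }
  strings <- apply(matrix(chars, nrow = nrow), 1, paste, collapse = "")
  names(strings) <- paste0("s", seq_len(nrow))
  barcodeAlignment(strings, locus)
}

# independent site classifier straight from the definitions (oracle)
oracleClassify <- function(column) {
  bases <- column[column %in% c("A", "C", "G", "T")]
  if (length(bases) < 2) return("indeterminate")
  tab <- table(bases)
  if (length(tab) < 2) return("conserved")
  if (sum(tab >= 2) >= 2) return("pic") else return("singleton")
}

# independent p-distance (oracle): per-site double loop
oraclePDist <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  nc <- 0L; mm <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% c("A", "C", "G", "T") && b[i] %in% c("A", "C", "G", "T")) {
      nc <- nc + 1L
      if (a[i] != b[i]) mm <- mm + 1L
    }
  }
  if (nc == 0L) NA_real_ else mm / nc
}

# expose the internal split enumeration for consensus checks
.splitKeysForTest <- function(tree) barcodeval:::.splitKeys(tree)

# a tiny simulation config that keeps tests fast: 2 families x 2 genera x
# 2 species x 2 individuals, two short loci with contrasting rates
tinyConfig <- function(seed = 1, ...) {
  simulationConfig(
    nFamilies = 2, generaPerFamily = 2, speciesPerGenus = 2,
    individualsPerSpecies = 2,
    loci = list(locusSpec("slow", 300, multiplier = 1),
                locusSpec("fast", 300, multiplier = 8)),
    seed = seed, ...)
}
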