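# End-to-end orchestration: simulate (or load) a multi-locus dataset, then
# for every locus combination run site composition, barcoding-gap
# analysis, tree inference with bootstrap for each method, species
# resolution, CA discovery on the guide tree, and the IR scan on spacer
# loci; collect everything into one report bundle.

#' Pipeline configuration
#'
#' @param loci Locus names to analyse (default: all in the dataset).
#' @param combos List of character vectors of locus names; default all
#'   singles, all pairs and the full combination.
#' @param methods Subset of \code{c("nj", "mp", "ml")}. Aggregates are
#'   labelled with the method set used (a Bayesian method is deliberately
#'   not implemented, so "all methods" here means this set).
#' @param bootstrapReps Bootstrap replicates per method (study convention
#'   1000; simulation work is stable from a few hundred).
#' @param supportThreshold Percent support defining a well-resolved clade.
#' @param gapRank Rank for the distance partition (default genus).
#' @param spacerLoci Loci scanned for inverted repeats (default: loci with
#'   \code{indelRate > 0} when simulating, else none).
#' @param irThreshold Inverted-repeat score threshold.
#' @param caMinSize Minimum clade size for tree-derived CA groups.
#' @param seed Integer seed for every stochastic stage.
#' @return Config list for [runPipeline()].
#' @export
pipelineConfig <- function(loci = NULL, combos = NULL,
                           methods = c("nj", "mp"), bootstrapReps = 100,
                           supportThreshold = 50, gapRank = "genus",
                           spacerLoci = NULL, irThreshold = 40,
                           caMinSize = 2, seed = 1) {
  stopifnot(bootstrapReps >= 1,
            all(methods %in% c("nj", "mp", "ml")))
  list(loci = loci, combos = combos, methods = methods,
       bootstrapReps = bootstrapReps, supportThreshold = supportThreshold,
       gapRank = gapRank, spacerLoci = spacerLoci,
       irThreshold = irThreshold, caMinSize = caMinSize, seed = seed)
}

.comboName <- function(loci) paste(loci, collapse = "/")

.allCombos <- function(loci) {
  singles <- as.list(loci)
  pairs <- if (length(loci) >= 2)
    utils::combn(loci, 2, simplify = FALSE) else list()
  full <- if (length(loci) >= 3) list(loci) else list()
  c(singles, pairs, full)
}

#' Run the full barcode evaluation pipeline
#'
#' @param dataset A [simulateDataset()] result, or a list with elements
#'   \code{alignments} (named list of [BarcodeAlignment-class]) and
#'   \code{metadata}.
#' @param config From [pipelineConfig()].
#' @return Report bundle (list): \code{composition} (per-combo site
#'   stats), \code{gap} (per-locus [GapReport-class] + summaries),
#'   \code{trees} (per combo x method, with supports),
#'   \code{resolution} (reports + cross-method aggregate), \code{ca}
#'   (per-locus [CATable-class]), \code{ir} (per-spacer hits and
#'   conservation), \code{config}.
#' @export
runPipeline <- function(dataset, config = pipelineConfig()) {
  alns <- dataset$alignments
  meta <- dataset$metadata
  loci <- config$loci
  if (is.null(loci)) loci <- names(alns)
  combos <- config$combos
  if (is.null(combos)) combos <- .allCombos(loci)
  comboAln <- function(cb) {
    if (length(cb) == 1L) alns[[cb]]
    else buildSupermatrix(alns[cb])
  }
  # --- site composition per combo
  composition <- lapply(combos, function(cb) {
    a <- comboAln(cb)
    r <- siteComposition(a)
    r$name <- .comboName(cb)
    r
  })
  compTable <- compositionTable(composition)
  # --- distances / barcoding gap per single locus
  gap <- lapply(loci, function(lc) {
    d <- distanceMatrix(alns[[lc]])
    partitionDistances(d, meta, rank = config$gapRank)
  })
  names(gap) <- loci
  gapSummary <- do.call(rbind, lapply(loci, function(lc) {
    g <- gap[[lc]]
    data.frame(locus = lc,
               meanIntra = if (length(intraDistances(g)))
                 mean(intraDistances(g)) else NA_real_,
               meanInter = if (length(interDistances(g)))
                 mean(interDistances(g)) else NA_real_,
               gapStat = gapStat(g), overlap = overlapFraction(g),
               intraBelow0.5pct = fractionBelow(g, 0.005),
               stringsAsFactors = FALSE)
  }))
  # --- trees with bootstrap per combo x method, then resolution
  trees <- list(); resReports <- list()
  for (cb in combos) {
    a <- comboAln(cb)
    for (mth in config$methods) {
      tr <- bootstrapSupport(a, method = mth,
                             reps = config$bootstrapReps,
                             seed = config$seed)
      key <- paste(.comboName(cb), mth, sep = "|")
      attr(tr, "bootTrees") <- NULL
      trees[[key]] <- tr
      resReports[[key]] <- speciesResolution(
        tr, meta, threshold = config$supportThreshold,
        method = mth, lociCombo = .comboName(cb))
    }
  }
  aggregate <- aggregateMethods(resReports, composition = compTable)
  # --- CAs per single locus, grouped by the guide (NJ) tree clades
  ca <- lapply(loci, function(lc) {
    guide <- trees[[paste(lc, config$methods[1], sep = "|")]]
    grouping <- groupsFromTree(guide, minSize = config$caMinSize)
    findPureCAs(alns[[lc]], grouping,
                groupingSource = paste0("guide tree (",
                                        config$methods[1], ")"))
  })
  names(ca) <- loci
  # --- IR scan on spacer loci
  spacers <- config$spacerLoci
  if (is.null(spacers)) {
    specs <- dataset$config$loci
    spacers <- if (!is.null(specs))
      vapply(specs, function(s) s$name, "")[
        vapply(specs, function(s) s$indelRate > 0, TRUE)]
    else character()
  }
  ir <- lapply(spacers, function(lc) {
    hits <- scanAlignmentIRs(alns[[lc]], threshold = config$irThreshold)
    fams <- split(meta$id, meta$family)
    list(hits = hits,
         conservation = irConservation(alns[[lc]], hits, groups = fams))
  })
  names(ir) <- spacers
  list(composition = composition, compositionTable = compTable,
       gap = gap, gapSummary = gapSummary, trees = trees,
       resolution = resReports, aggregate = aggregate, ca = ca, ir = ir,
       config = config)
}

#' Render a report bundle into flat tables and tree files
#'
#' Emits (a) the combo-by-method support/resolution table with standard
#' errors, (b) the PIC-versus-resolution table, (c) intra/inter distance
#' histograms, (d) the CA count table with "/length" denominators, and
#' (e) Newick trees with supports. Missing stages are noted, not fatal.
#'
#' @param bundle From [runPipeline()].
#' @param outDir Optional output directory for TSV/Newick/JSON files.
#' @return List of the rendered tables (invisibly when writing files).
#' @export
renderReport <- function(bundle, outDir = NULL) {
  methodNote <- paste("methods:",
                      paste(bundle$config$methods, collapse = "+"))
  supportTable <- bundle$aggregate
  picTable <- bundle$compositionTable
  hist <- lapply(bundle$gap, gapHistogram)
  caTable <- if (length(bundle$ca)) do.call(rbind, lapply(
    names(bundle$ca), function(lc) {
      tab <- caCounts(bundle$ca[[lc]])
      tab$locus <- lc
      tab
    })) else data.frame(note = "no CA stage output")
  newick <- vapply(bundle$trees, writeNewick, "")
  out <- list(supportTable = supportTable, picTable = picTable,
              gapHistograms = hist, caTable = caTable, trees = newick,
              note = methodNote)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(outDir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(supportTable, "support_resolution.tsv")
    wt(picTable, "site_composition.tsv")
    for (lc in names(hist))
      wt(hist[[lc]], paste0("gap_hist_", gsub("[^A-Za-z0-9]", "_", lc),
                            ".tsv"))
    wt(caTable, "ca_counts.tsv")
    writeLines(paste0(names(newick), "\t", newick),
               file.path(outDir, "trees.tsv"))
    jsonlite::write_json(
      list(note = methodNote, gapSummary = bundle$gapSummary,
           aggregate = supportTable),
      file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
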