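# Multi-locus barcode dataset simulator with known truth.
#
# Emulates the design of a plastid barcoding study: a rank-structured
# ultrametric taxonomy tree (family > genus > species > individual), three
# loci with strongly unequal substitution rates (a slow rbcL-like coding
# locus, an intermediate matK-like one, and a fast trnH-psbA-like spacer
# with indels), optional planted inverted repeats and planted diagnostic
# columns. Because the simulator knows every indel placement it emits TRUE
# alignments, so no alignment software is needed downstream.

#' Per-locus simulation specification
#'
#' @param name Locus name.
#' @param length Ungapped root-sequence length.
#' @param multiplier Substitution-rate multiplier relative to the tree's
#'   time scale (branch lengths are expected substitutions/site at
#'   multiplier 1).
#' @param indelRate Expected indel events per unit branch length over the
#'   whole locus (0 for coding loci).
#' @param indelMeanLength Mean indel length (geometric).
#' @param irPlant \code{NULL} or \code{list(clade =, armLength =,
#'   loopLength =)}: plant a shared inverted repeat in every member of the
#'   named clade (a family, genus or species present in the metadata).
#' @param caPlant \code{NULL} or \code{list(clade =, nColumns =)}: fix
#'   diagnostic states in the clade at that many columns, with a different
#'   fixed state outside.
#' @return Locus spec list.
#' @export
locusSpec <- function(name, length, multiplier = 1, indelRate = 0,
                      indelMeanLength = 6, irPlant = NULL, caPlant = NULL) {
  stopifnot(length >= 1, multiplier >= 0, indelRate >= 0)
  if (!is.null(irPlant) &&
      2 * irPlant$armLength + irPlant$loopLength > length)
    stop("parameter error: planted IR longer than locus")
  list(name = name, length = as.integer(length), multiplier = multiplier,
       indelRate = indelRate, indelMeanLength = indelMeanLength,
       irPlant = irPlant, caPlant = caPlant)
}

#' Simulation configuration with seagrass-like defaults
#'
#' Defaults encode the study design the package is validated against:
#' 4 families, 2 genera per family, 14 species (two monotypic genera),
#' 2 individuals per species; ultrametric crown heights (in expected
#' substitutions/site at rate multiplier 1) chosen so that intrageneric
#' divergence is low and intergeneric divergence high; loci
#' rbcL:matK:spacer at rate multipliers 1:3:8, the spacer with indels and
#' a planted inverted repeat.
#'
#' @param nFamilies,generaPerFamily,speciesPerGenus,individualsPerSpecies
#'   Taxonomy counts; \code{speciesPerGenus} and
#'   \code{individualsPerSpecies} are recycled over genera / species.
#' @param rootDepth Height (expected substitutions/site at multiplier 1)
#'   at which the families coalesce (the tree root).
#' @param familyDepth Height at which genera within a family coalesce.
#' @param genusDepth Height at which species within a genus coalesce.
#' @param intraspecificDivergence Expected substitutions/site between
#'   conspecific individuals (at multiplier 1); they coalesce at half
#'   this height.
#' @param loci List of [locusSpec()] objects.
#' @param model Substitution model from [substitutionModel()] (JC69 or
#'   HKY85).
#' @param seed Integer seed fixing the whole output bit-for-bit.
#' @return Config list for [simulateDataset()].
#' @export
simulationConfig <- function(nFamilies = 4, generaPerFamily = 2,
                             speciesPerGenus = c(2, 2, 2, 2, 2, 2, 1, 1),
                             individualsPerSpecies = 2,
                             rootDepth = 0.035, familyDepth = 0.015,
                             genusDepth = 0.004,
                             intraspecificDivergence = 0.001,
                             loci = list(
                               locusSpec("rbcL", 599, multiplier = 1),
                               locusSpec("matK", 845, multiplier = 3,
                                         caPlant = list(clade = "GenusA",
                                                        nColumns = 5)),
                               locusSpec("trnH-psbA", 420, multiplier = 8,
                                         indelRate = 8, indelMeanLength = 6,
                                         irPlant = list(clade = "Family1",
                                                        armLength = 14,
                                                        loopLength = 20))),
                             model = substitutionModel("JC69"),
                             seed = 1) {
  if (nFamilies < 1 || sum(rep_len(speciesPerGenus,
                                   nFamilies * generaPerFamily)) < 1)
    stop("parameter error: at least one species required")
  stopifnot(rootDepth > familyDepth, familyDepth > genusDepth,
            genusDepth > intraspecificDivergence / 2)
  list(nFamilies = nFamilies, generaPerFamily = generaPerFamily,
       speciesPerGenus = speciesPerGenus,
       individualsPerSpecies = individualsPerSpecies,
       rootDepth = rootDepth, familyDepth = familyDepth,
       genusDepth = genusDepth,
       intraspecificDivergence = intraspecificDivergence,
       loci = loci, model = model, seed = seed)
}

#' Build the rank-structured taxonomy tree and metadata
#'
#' Deterministic given the configuration: families, genera and species are
#' laid out as balanced clades with ultrametric heights from the config,
#' so genus and family clades are monophyletic by construction and branch
#' lengths shrink with rank (family stems longest, individual tips
#' shortest).
#'
#' @param config From [simulationConfig()].
#' @return List with \code{tree} (\code{ape::phylo}, branch lengths in
#'   expected substitutions/site at multiplier 1) and \code{metadata}
#'   (id/species/genus/family/site).
#' @export
sampleTaxonomyTree <- function(config) {
  # clades are (newick-without-stem, height) pairs; stems are added by the
  # parent so nested monotypic ranks keep correct total depths
  stem <- function(clade, parentHeight)
    sprintf("%s:%.6f", clade$str, parentHeight - clade$h)
  join <- function(clades, height) {
    if (length(clades) == 1L) return(clades[[1]])
    list(str = sprintf("(%s)", paste(vapply(clades, stem, "", height),
                                     collapse = ",")), h = height)
  }
  gIdx <- 0L; sIdx <- 0L
  meta <- list()
  famClades <- list()
  nGenera <- config$nFamilies * config$generaPerFamily
  spPerGenus <- rep_len(config$speciesPerGenus, nGenera)
  for (f in seq_len(config$nFamilies)) {
    fam <- paste0("Family", f)
    genClades <- list()
    for (g in seq_len(config$generaPerFamily)) {
      gIdx <- gIdx + 1L
      gen <- paste0("Genus", LETTERS[gIdx])
      spClades <- list()
      for (s in seq_len(spPerGenus[gIdx])) {
        sIdx <- sIdx + 1L
        sp <- paste(gen, paste0("sp", s))
        nInd <- rep_len(config$individualsPerSpecies, sIdx)[sIdx]
        ids <- paste0(gen, "_sp", s, "_i", seq_len(nInd))
        for (i in seq_len(nInd))
          meta[[length(meta) + 1L]] <- data.frame(
            id = ids[i], species = sp, genus = gen, family = fam,
            site = paste0("Site", ifelse(i %% 2 == 1, "A", "B")),
            stringsAsFactors = FALSE)
        tipClades <- lapply(ids, function(x) list(str = x, h = 0))
        spClades[[s]] <- join(tipClades,
                              config$intraspecificDivergence / 2)
      }
      genClades[[g]] <- join(spClades, config$genusDepth)
    }
    famClades[[f]] <- join(genClades, config$familyDepth)
  }
  root <- join(famClades, config$rootDepth)
  tree <- ape::read.tree(text = paste0(root$str, ";"))
  metadata <- do.call(rbind, meta)
  list(tree = tree, metadata = metadata)
}

# draw child bases from parent bases over branch of effective length t
.evolveBases <- function(bases, model, t) {
  if (t <= 0 || !length(bases)) return(bases)
  P <- .transitionP(model, t)
  out <- bases
  for (b in seq_along(.BASES)) {
    sel <- which(bases == .BASES[b])
    if (length(sel))
      out[sel] <- .BASES[sample.int(4L, length(sel), replace = TRUE,
                                    prob = P[b, ])]
  }
  out
}

#' Evolve one locus along a tree
#'
#' Root sequence from the model's base frequencies; per-branch
#' substitutions from the model's transition probabilities at branch
#' length times the locus rate multiplier; indels as Poisson events with
#' geometric lengths. Insertion placement is tracked with fractional
#' column keys so the emitted alignment is exact (the true alignment).
#'
#' @param tree \code{ape::phylo} from [sampleTaxonomyTree()].
#' @param spec A [locusSpec()].
#' @param model From [substitutionModel()] (JC69 or HKY85; no gamma).
#' @param seed Integer seed.
#' @param metadata Metadata table for the resulting alignment.
#' @return List with \code{alignment} (a [BarcodeAlignment-class]; planted
#'   features applied) and \code{planted} (registry of planted IR/CA
#'   positions, alignment-column coordinates).
#' @export
evolveLocus <- function(tree, spec, model = substitutionModel("JC69"),
                        seed = 1, metadata = NULL) {
  set.seed(seed)
  L <- spec$length
  rootKeys <- as.numeric(seq_len(L))
  rootBases <- .BASES[sample.int(4L, L, replace = TRUE,
                                 prob = model$baseFreqs)]
  allKeys <- new.env()
  assign("keys", rootKeys, envir = allKeys)
  ntip <- length(tree$tip.label)
  tipStates <- vector("list", ntip)
  recurse <- function(node, keys, bases) {
    kids <- which(tree$edge[, 1] == node)
    if (!length(kids)) return()
    for (ei in kids) {
      child <- tree$edge[ei, 2]
      t <- tree$edge.length[ei]
      b2 <- .evolveBases(bases, model, t * spec$multiplier)
      k2 <- keys
      if (spec$indelRate > 0 && t > 0) {
        nEv <- stats::rpois(1, spec$indelRate * t)
        for (e in seq_len(nEv)) {
          len <- stats::rgeom(1, 1 / spec$indelMeanLength) + 1L
          if (stats::runif(1) < 0.5 && length(k2) > len) {
            # deletion
            at <- sample.int(length(k2) - len + 1L, 1L)
            drop <- at:(at + len - 1L)
            k2 <- k2[-drop]; b2 <- b2[-drop]
          } else {
            # insertion after a random position (0 = before first column)
            at <- sample.int(length(k2) + 1L, 1L) - 1L
            lo <- if (at == 0L) k2[1] - 1 else k2[at]
            hi <- if (at == length(k2)) k2[length(k2)] + 1 else k2[at + 1L]
            newKeys <- lo + (hi - lo) * seq_len(len) / (len + 1)
            newBases <- .BASES[sample.int(4L, len, replace = TRUE,
                                          prob = model$baseFreqs)]
            k2 <- append(k2, newKeys, after = at)
            b2 <- append(b2, newBases, after = at)
            assign("keys", c(get("keys", envir = allKeys), newKeys),
                   envir = allKeys)
          }
        }
      }
      if (child <= ntip) tipStates[[child]] <<- list(keys = k2, bases = b2)
      else recurse(child, k2, b2)
    }
  }
  root <- ntip + 1L
  recurse(root, rootKeys, rootBases)
  cols <- sort(unique(get("keys", envir = allKeys)))
  m <- matrix("-", ntip, length(cols),
              dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(ntip)) {
    st <- tipStates[[i]]
    m[i, match(st$keys, cols)] <- st$bases
  }
  if (is.null(metadata)) metadata <- .emptyMeta(tree$tip.label)
  metadata <- metadata[match(tree$tip.label, metadata$id), , drop = FALSE]
  rownames(metadata) <- NULL
  planted <- list()
  cladeMembers <- function(clade) {
    hit <- metadata$family == clade | metadata$genus == clade |
      metadata$species == clade
    metadata$id[hit]
  }
  if (!is.null(spec$irPlant)) {
    p <- spec$irPlant
    members <- cladeMembers(p$clade)
    if (!length(members)) stop("IR plant clade not found: ", p$clade)
    w <- 2L * p$armLength + p$loopLength
    ok <- which(vapply(seq_len(ncol(m) - w + 1L), function(s)
      all(m[members, s:(s + w - 1L)] != "-"), TRUE))
    if (!length(ok)) stop("no gap-free window for planted IR")
    start <- ok[ceiling(length(ok) / 2)]
    arm <- .BASES[sample.int(4L, p$armLength, replace = TRUE)]
    loop <- .BASES[sample.int(4L, p$loopLength, replace = TRUE)]
    block <- c(arm, loop, rev(unname(.COMPLEMENT[arm])))
    for (id in members) m[id, start:(start + w - 1L)] <- block
    planted$ir <- list(clade = p$clade, members = members,
                       columns = start:(start + w - 1L),
                       armLength = p$armLength, loopLength = p$loopLength)
  }
  if (!is.null(spec$caPlant)) {
    p <- spec$caPlant
    members <- cladeMembers(p$clade)
    if (!length(members)) stop("CA plant clade not found: ", p$clade)
    outs <- setdiff(rownames(m), members)
    gapFree <- which(apply(m != "-", 2, all))
    gapFree <- setdiff(gapFree, planted$ir$columns)
    pos <- sort(sample(gapFree, p$nColumns))
    states <- character(p$nColumns)
    for (j in seq_along(pos)) {
      sIn <- .BASES[sample.int(4L, 1L)]
      sOut <- sample(setdiff(.BASES, sIn), 1L)
      m[members, pos[j]] <- sIn
      m[outs, pos[j]] <- sOut
      states[j] <- sIn
    }
    planted$ca <- list(clade = p$clade, members = members,
                       positions = pos, states = states)
  }
  aln <- new("BarcodeAlignment", locus = spec$name, seqs = m,
             meta = metadata)
  list(alignment = aln, planted = planted)
}

#' Simulate a complete multi-locus barcode dataset
#'
#' One shared taxonomy tree; every locus evolved on it with its own rate
#' multiplier and indel process; planted features recorded in a truth
#' registry. Fully reproducible from \code{config$seed}.
#'
#' @param config From [simulationConfig()].
#' @param outDir Optional directory: writes per-locus FASTA, the metadata
#'   TSV, the true tree (Newick) and the truth registry (JSON).
#' @return List with \code{tree}, \code{metadata}, \code{alignments}
#'   (named list of [BarcodeAlignment-class]), \code{planted} (per-locus
#'   registry) and \code{config}.
#' @export
simulateDataset <- function(config = simulationConfig(), outDir = NULL) {
  tax <- sampleTaxonomyTree(config)
  alignments <- list(); planted <- list()
  for (i in seq_along(config$loci)) {
    spec <- config$loci[[i]]
    res <- evolveLocus(tax$tree, spec, config$model,
                       seed = (config$seed * 131L + i) %% .Machine$integer.max,
                       metadata = tax$metadata)
    alignments[[spec$name]] <- res$alignment
    planted[[spec$name]] <- res$planted
  }
  out <- list(tree = tax$tree, metadata = tax$metadata,
              alignments = alignments, planted = planted, config = config)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(alignments))
      writeFastaAlignment(alignments[[nm]],
                          file.path(outDir, paste0(gsub("[^A-Za-z0-9]", "_",
                                                        nm), ".fasta")))
    utils::write.table(tax$metadata, file.path(outDir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeNewick(tax$tree, file.path(outDir, "true_tree.nwk"))
    jsonlite::write_json(planted, file.path(outDir, "truth_registry.json"),
                         auto_unbox = TRUE)
  }
  out
}
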