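# Tree inference and support: neighbour-joining, maximum parsimony and
# maximum likelihood with nonparametric bootstrap, majority-rule consensus
# and bipartition-level topology comparison. Inference engines are ape and
# phangorn; this module contributes the consistent missing-data convention,
# the bootstrap orchestration and the split bookkeeping.

# alignment -> phangorn phyDat with the package's missing-data rule:
# ambiguity codes are masked to '?' (never expanded), '-'/'?' stay missing
.alnToPhyDat <- function(aln) {
  m <- if (is(aln, "BarcodeAlignment")) seqMatrix(aln) else aln
  m[!m %in% c(.BASES, "-", "?")] <- "?"
  phangorn::phyDat(m, type = "DNA")
}

# fast p-distance matrix (same definition as distanceMatrix) used inside
# bootstrap loops; x is a character matrix
.pdistMatrix <- function(m) {
  n <- nrow(m)
  isb <- matrix(m %in% .BASES, nrow = n)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    bi <- isb[i, ]; ri <- m[i, ]
    for (j in (i + 1L):n) {
      comp <- bi & isb[j, ]
      nc <- sum(comp)
      d[i, j] <- d[j, i] <-
        if (nc == 0L) NA_real_ else sum(ri[comp] != m[j, comp]) / nc
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Canonical NJ agglomeration (via \pkg{ape}); negative branch lengths are
#' clamped to zero with the clamped deficit recorded in attribute
#' \code{"clampedDeficit"}.
#'
#' @param d Symmetric numeric distance matrix (no \code{NA} entries), e.g.
#'   from [distanceMatrix()].
#' @return Unrooted \code{ape::phylo} tree.
#' @export
njTree <- function(d) {
  if (anyNA(d))
    stop("input error: distance matrix has undefined entries; ",
         "NJ needs pairwise-complete input")
  if (nrow(d) < 3L) stop("at least 3 taxa required")
  tr <- ape::nj(d)
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clampedDeficit") <- deficit
  tr
}

#' Fitch parsimony score of a tree on an alignment
#'
#' Sum over columns of the minimum number of state changes; gaps, \code{?}
#' and ambiguity codes are missing data.
#'
#' @param tree \code{ape::phylo}; its tips must all carry sequences.
#' @param aln A [BarcodeAlignment-class] or character matrix.
#' @return Integer parsimony score.
#' @export
fitchScore <- function(tree, aln) {
  dat <- .alnToPhyDat(aln)
  miss <- setdiff(tree$tip.label, names(dat))
  if (length(miss))
    stop("label error: tree leaf without sequence: ", paste(miss, collapse = ", "))
  as.integer(phangorn::fitch(tree, dat[tree$tip.label]))
}

#' Maximum-parsimony search
#'
#' NNI hill climbing from a neighbour-joining start plus optional
#' random-addition starts; returns all co-optimal topologies found.
#'
#' @param aln A [BarcodeAlignment-class].
#' @param nStarts Total number of starts (1 = NJ start only).
#' @param seed Integer seed; the search is reproducible.
#' @return List with \code{trees} (class \code{multiPhylo}) and
#'   \code{score}.
#' @export
mpSearch <- function(aln, nStarts = 1, seed = 1) {
  dat <- .alnToPhyDat(aln)
  set.seed(seed)
  starts <- list(njTree(.pdistMatrix(seqMatrix(aln))))
  if (nStarts > 1)
    starts <- c(starts, lapply(seq_len(nStarts - 1),
                               function(i) phangorn::random.addition(dat)))
  fits <- lapply(starts, function(s)
    phangorn::optim.parsimony(s, dat, method = "fitch",
                              rearrangements = "NNI", trace = 0))
  scores <- vapply(fits, function(t) phangorn::fitch(t, dat), 0)
  best <- min(scores)
  top <- fits[scores == best]
  top <- top[!duplicated(vapply(top, function(t)
    paste(sort(.splitKeys(t)), collapse = ";"), ""))]
  class(top) <- "multiPhylo"
  list(trees = top, score = as.integer(best))
}

#' Substitution model specification
#'
#' @param name One of \code{"JC69"}, \code{"K2P"}, \code{"HKY85"},
#'   \code{"GTR"}.
#' @param baseFreqs Base frequencies (A, C, G, T), summing to 1. Forced to
#'   uniform for JC69/K2P.
#' @param kappa Transition/transversion rate ratio (K2P, HKY85).
#' @param rates Six GTR exchangeabilities in the order AC, AG, AT, CG, CT,
#'   GT.
#' @param alpha Gamma shape for among-site rate variation (\code{NULL} for
#'   rate homogeneity); discretised into \code{ncat} categories.
#' @param ncat Number of discrete gamma categories (default 4).
#' @param pinv Proportion of invariant sites in \code{[0, 1)}.
#' @return A model list consumed by [treeLogLik()], [mlSearch()] and the
#'   simulator.
#' @export
substitutionModel <- function(name = c("JC69", "K2P", "HKY85", "GTR"),
                              baseFreqs = rep(0.25, 4), kappa = 2,
                              rates = rep(1, 6), alpha = NULL, ncat = 4L,
                              pinv = 0) {
  name <- match.arg(name)
  if (name %in% c("JC69", "K2P")) baseFreqs <- rep(0.25, 4)
  if (abs(sum(baseFreqs) - 1) > 1e-9 || any(baseFreqs <= 0))
    stop("base frequencies must be positive and sum to 1")
  if (pinv < 0 || pinv >= 1) stop("pinv must be in [0, 1)")
  Q6 <- switch(name,
    JC69 = rep(1, 6),
    K2P = c(1, kappa, 1, 1, kappa, 1),
    HKY85 = c(1, kappa, 1, 1, kappa, 1),
    GTR = rates)
  list(name = name, baseFreqs = baseFreqs, Q = Q6, alpha = alpha,
       ncat = if (is.null(alpha)) 1L else as.integer(ncat), pinv = pinv)
}

# 4x4 rate matrix scaled to mean rate 1 (rows sum to 0)
.rateMatrix <- function(model) {
  f <- model$baseFreqs; r <- model$Q
  Q <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- idx[k, 1]; j <- idx[k, 2]
    Q[i, j] <- r[k] * f[j]; Q[j, i] <- r[k] * f[i]
  }
  diag(Q) <- -rowSums(Q)
  Q / sum(-f * diag(Q))
}

# transition probability matrix P(t) via eigendecomposition
.transitionP <- function(model, t) {
  if (t <= 0) return(diag(4))
  Q <- .rateMatrix(model)
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(.BASES, .BASES)
  P
}

# direct pruning likelihood for trees too small for phangorn (2-3 tips):
# all tips hang off the single internal (root) node, so the site
# likelihood is sum_x pi_x prod_tips (P(t_tip) L_tip)_x, averaged over
# gamma categories with an optional invariant class
.smallTreeLogLik <- function(tree, m, model) {
  cats <- if (model$ncat > 1L)
    phangorn::discrete.gamma(model$alpha, model$ncat) else 1
  if (model$pinv > 0) cats <- cats / (1 - model$pinv)  # keep mean rate 1
  f <- model$baseFreqs
  tips <- tree$tip.label
  tipPartial <- function(ch) {
    out <- matrix(1, 4, length(ch), dimnames = list(.BASES, NULL))
    det <- ch %in% .BASES
    out[, det] <- 0
    out[cbind(match(ch[det], .BASES), which(det))] <- 1
    out
  }
  edgeLen <- function(tip) {
    tree$edge.length[which(tree$edge[, 2] == match(tip, tips))]
  }
  siteL <- rep(0, ncol(m))
  for (k in seq_along(cats)) {
    partials <- lapply(tips, function(tp) {
      P <- .transitionP(model, edgeLen(tp) * cats[k])
      P %*% tipPartial(m[tp, ])
    })
    rootL <- Reduce(`*`, partials)
    siteL <- siteL + (1 / length(cats)) * as.vector(f %*% rootL)
  }
  if (model$pinv > 0) {
    rootL0 <- Reduce(`*`, lapply(tips, function(tp) tipPartial(m[tp, ])))
    siteL <- (1 - model$pinv) * siteL +
      model$pinv * as.vector(f %*% rootL0)
  }
  sum(log(siteL))
}

# build a phangorn pml fit for a model spec
.pmlFit <- function(tree, dat, model) {
  phangorn::pml(tree, dat, bf = model$baseFreqs, Q = model$Q,
                k = model$ncat,
                shape = if (is.null(model$alpha)) 1 else model$alpha,
                inv = model$pinv)
}

#' Log-likelihood of a tree under a substitution model
#'
#' Felsenstein pruning over discrete-gamma rate categories (plus an
#' invariant class when \code{pinv > 0}); missing data marginalises to 1 at
#' the leaf, so an all-missing sequence does not change the likelihood.
#'
#' @param tree \code{ape::phylo} with branch lengths.
#' @param aln A [BarcodeAlignment-class] or character matrix.
#' @param model From [substitutionModel()].
#' @return Log-likelihood (numeric scalar).
#' @export
treeLogLik <- function(tree, aln, model = substitutionModel("JC69")) {
  m <- if (is(aln, "BarcodeAlignment")) seqMatrix(aln) else aln
  miss <- setdiff(tree$tip.label, rownames(m))
  if (length(miss))
    stop("input error: tree leaf without sequence: ",
         paste(miss, collapse = ", "))
  if (length(tree$tip.label) < 4L) {
    mm <- m
    mm[!mm %in% .BASES] <- "?"
    return(.smallTreeLogLik(tree, mm, model))
  }
  dat <- .alnToPhyDat(m)
  as.numeric(stats::logLik(.pmlFit(tree, dat[tree$tip.label], model)))
}

#' Maximum-likelihood tree search
#'
#' Starts from a neighbour-joining tree, then alternates branch-length
#' optimisation and nearest-neighbour-interchange moves until the
#' log-likelihood improves by less than the tolerance.
#'
#' @param aln A [BarcodeAlignment-class].
#' @param model From [substitutionModel()]; free parameters (GTR
#'   exchangeabilities, gamma shape, invariant proportion) are optimised
#'   when \code{estimate = TRUE}.
#' @param seed Integer seed (the search itself is deterministic; the seed
#'   pins any stochastic tie handling in the optimiser).
#' @param estimate Optimise model parameters alongside the topology.
#' @return List with \code{tree} (branch lengths optimised),
#'   \code{logLik} and the \code{pml} fit.
#' @export
mlSearch <- function(aln, model = substitutionModel("GTR", alpha = 1),
                     seed = 1, estimate = TRUE) {
  set.seed(seed)
  dat <- .alnToPhyDat(aln)
  start <- njTree(.pdistMatrix(seqMatrix(aln)))
  start$edge.length[start$edge.length <= 0] <- 1e-8
  fit <- .pmlFit(start, dat, model)
  fit <- phangorn::optim.pml(
    fit, optNni = TRUE, optEdge = TRUE,
    optBf = estimate && model$name %in% c("HKY85", "GTR"),
    optQ = estimate && model$name == "GTR",
    optGamma = estimate && model$ncat > 1L,
    optInv = estimate && model$pinv > 0,
    control = phangorn::pml.control(trace = 0, epsilon = 1e-6))
  list(tree = fit$tree, logLik = as.numeric(stats::logLik(fit)), fit = fit)
}

# one inference step used by bootstrapSupport; m is a character matrix
.inferTree <- function(m, method, model = NULL, quick = TRUE) {
  switch(method,
    nj = njTree(.pdistMatrix(m)),
    mp = {
      dat <- .alnToPhyDat(m)
      start <- njTree(.pdistMatrix(m))
      phangorn::optim.parsimony(start, dat, method = "fitch",
                                rearrangements = "NNI", trace = 0)
    },
    ml = {
      if (is.null(model)) model <- substitutionModel("GTR", alpha = 1)
      dat <- .alnToPhyDat(m)
      start <- njTree(.pdistMatrix(m))
      start$edge.length[start$edge.length <= 0] <- 1e-8
      fit <- .pmlFit(start, dat, model)
      fit <- phangorn::optim.pml(
        fit, optNni = TRUE, optEdge = TRUE,
        control = phangorn::pml.control(trace = 0,
                                        epsilon = if (quick) 1e-4 else 1e-6))
      fit$tree
    },
    stop("unknown method: ", method))
}

#' Nonparametric bootstrap support for a tree
#'
#' Resamples alignment columns with replacement (whole-supermatrix columns,
#' partitions ignored by default), re-infers a tree per replicate with the
#' chosen method, and maps bipartition frequencies (percent) onto the
#' point-estimate tree's internal nodes as \code{node.label}.
#'
#' @param aln A [BarcodeAlignment-class] or [Supermatrix-class].
#' @param method \code{"nj"}, \code{"mp"} or \code{"ml"}.
#' @param reps Number of bootstrap replicates (the study convention is
#'   1000; smaller values are adequate for simulation work).
#' @param seed Integer seed.
#' @param model Substitution model for \code{method = "ml"}.
#' @param byPartition Resample within each locus partition instead of over
#'   the whole matrix.
#' @return The point-estimate tree with percent supports in
#'   \code{node.label}; replicate trees in attribute \code{"bootTrees"}.
#' @export
bootstrapSupport <- function(aln, method = c("nj", "mp", "ml"), reps = 1000,
                             seed = 1, model = NULL, byPartition = FALSE) {
  method <- match.arg(method)
  stopifnot(reps >= 1)
  m <- seqMatrix(aln)
  point <- .inferTree(m, method, model, quick = FALSE)
  set.seed(seed)
  spans <- if (byPartition && is(aln, "Supermatrix")) {
    p <- partitionTable(aln)
    lapply(seq_len(nrow(p)), function(i) p$start[i]:p$end[i])
  } else list(seq_len(ncol(m)))
  boot <- vector("list", reps)
  for (r in seq_len(reps)) {
    cols <- unlist(lapply(spans, function(s) sample(s, length(s), replace = TRUE)))
    boot[[r]] <- .inferTree(m[, cols, drop = FALSE], method, model)
  }
  class(boot) <- "multiPhylo"
  cnt <- ape::prop.clades(point, boot, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  point$node.label <- as.character(round(100 * cnt / reps))
  # the root "clade" of an unrooted tree is not a real bipartition
  point$node.label[1] <- ""
  attr(point, "bootTrees") <- boot
  point
}

#' Majority-rule consensus of trees
#'
#' Retains bipartitions occurring in more than \code{threshold} of the
#' input trees (\code{threshold = 1} gives the strict consensus) and labels
#' them with their percent frequency.
#'
#' @param trees List or \code{multiPhylo} of trees on one leaf set.
#' @param threshold Retention frequency threshold in \code{[0.5, 1]}.
#' @return Consensus \code{ape::phylo} with percent frequencies as
#'   \code{node.label}.
#' @export
majorityConsensus <- function(trees, threshold = 0.5) {
  if (!inherits(trees, "multiPhylo")) {
    trees <- unname(trees); class(trees) <- "multiPhylo"
  }
  labs <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(labs, paste, "", collapse = ";"))) != 1L)
    stop("input error: trees must share one leaf set")
  pEff <- if (threshold >= 1) 1 else min(1, threshold + 1e-9)
  cons <- ape::consensus(trees, p = pEff, check.labels = TRUE)
  cnt <- ape::prop.clades(cons, trees, rooted = FALSE)
  cnt[is.na(cnt)] <- length(trees)
  cons$node.label <- as.character(round(100 * cnt / length(trees)))
  cons$node.label[1] <- ""
  cons
}

# canonical keys for the non-trivial bipartitions of a tree: each split is
# written as the sorted tip set on the side not containing the reference
# (alphabetically first) tip
.splitKeys <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- vapply(parts, function(idx) {
    clade <- labs[idx]
    side <- if (ref %in% clade) setdiff(tips, clade) else clade
    paste(sort(side), collapse = ",")
  }, "")
  sizes <- vapply(strsplit(keys, ",", fixed = TRUE), length, 0L)
  unique(keys[sizes >= 2L & sizes <= length(tips) - 2L])
}

#' Compare two tree topologies
#'
#' Bipartition-level comparison on a shared leaf set: shared splits, splits
#' private to each tree, and the Robinson-Foulds (symmetric-difference)
#' distance.
#'
#' @param t1,t2 \code{ape::phylo} trees with identical tip labels.
#' @return List with \code{shared}, \code{onlyFirst}, \code{onlySecond}
#'   (character vectors of comma-joined tip sets) and \code{rf}.
#' @export
compareTopologies <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("input error: trees must share one leaf set")
  s1 <- .splitKeys(t1); s2 <- .splitKeys(t2)
  list(shared = intersect(s1, s2),
       onlyFirst = setdiff(s1, s2),
       onlySecond = setdiff(s2, s1),
       rf = length(setdiff(s1, s2)) + length(setdiff(s2, s1)))
}
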