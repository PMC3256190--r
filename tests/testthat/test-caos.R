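test_that("findPureCAs emits only fixed-inside, absent-outside states", {
  # group X fixed G at column 5; everyone else A there
  a <- aln("AAAAGAAA", "AAAAGAAA", "AAAAAAAA", "AAAAAAAA",
           ids = c("x1", "x2", "y1", "y2"))
  grouping <- list(X = c("x1", "x2"), Y = c("y1", "y2"))
  ca <- findPureCAs(a, grouping)
  tab <- caAttributes(ca)
  expect_true(any(tab$clade == "X" & tab$position == 5 & tab$state == "G"))
  # the complementary CA for Y at the same column
  expect_true(any(tab$clade == "Y" & tab$position == 5 & tab$state == "A"))

  # not fixed inside -> no CA at that column
  b <- aln("AAAAGAAA", "AAAAAAAA", "AAAACAAA", "AAAACAAA",
           ids = c("x1", "x2", "y1", "y2"))
  cb <- caAttributes(findPureCAs(b, grouping))
  expect_false(any(cb$clade == "X" & cb$position == 5))

  # identical groups -> zero CAs for both
  c2 <- aln("ACGTACGT", "ACGTACGT", "ACGTACGT", "ACGTACGT",
            ids = c("x1", "x2", "y1", "y2"))
  expect_equal(nrow(caAttributes(findPureCAs(c2, grouping))), 0L)

  expect_error(findPureCAs(a, list(X = character(), Y = "y1")),
               "zero members")
})

test_that("findPureCAs matches a hand-scan oracle on a 3-group alignment", {
  set.seed(41)
  rows <- c(x1 = "ACGTACGTACGT", x2 = "ACGTACGTACGT",
            y1 = "ACGAACGTACCT", y2 = "ACGAACGTACCT", y3 = "ACGAACGTACCT",
            z1 = "ACGCTCGTAAGT", z2 = "ACGCTCGTAAGT", z3 = "ACGCTCGTACGT")
  a <- barcodeAlignment(rows, "toy")
  grouping <- list(X = c("x1", "x2"), Y = c("y1", "y2", "y3"),
                   Z = c("z1", "z2", "z3"))
  got <- caAttributes(findPureCAs(a, grouping))
  # independent oracle: brute scan over groups x columns
  m <- do.call(rbind, strsplit(rows, ""))
  expected <- list()
  for (g in names(grouping)) {
    ins <- rownames(m) %in% grouping[[g]]
    for (col in seq_len(ncol(m))) {
      s <- unique(m[ins, col])
      if (length(s) == 1 && s %in% c("A", "C", "G", "T") &&
          !s %in% m[!ins, col])
        expected[[length(expected) + 1]] <-
          paste(g, col, s, sep = ":")
    }
  }
  expect_setequal(paste(got$clade, got$position, got$state, sep = ":"),
                  unlist(expected))
})

test_that("CA discovery ignores missing data per the permissive rule", {
  a <- aln("GGGG", "G?G-", "AAAA", "A-N?", ids = c("x1", "x2", "y1", "y2"))
  ca <- caAttributes(findPureCAs(a, list(X = c("x1", "x2"),
                                         Y = c("y1", "y2"))))
  # every column diagnostic for both groups despite holes
  expect_equal(sum(ca$clade == "X"), 4L)
  expect_equal(sum(ca$clade == "Y"), 4L)
  # gap as state only behind the flag
  b <- aln("A-A", "A-A", "AAA", "AAA", ids = c("x1", "x2", "y1", "y2"))
  noGap <- findPureCAs(b, list(X = c("x1", "x2"), Y = c("y1", "y2")))
  expect_false(any(caAttributes(noGap)$state == "-"))
  withGap <- findPureCAs(b, list(X = c("x1", "x2"), Y = c("y1", "y2")),
                         gapAsState = TRUE)
  expect_true(any(caAttributes(withGap)$state == "-" &
                  caAttributes(withGap)$position == 2))
})

test_that("CA discovery is idempotent and row-order invariant", {
  set.seed(42)
  a <- randomAlignment(8, 30, pMissing = 0.1)
  grouping <- list(G1 = paste0("s", 1:3), G2 = paste0("s", 4:8))
  c1 <- findPureCAs(a, grouping)
  c2 <- findPureCAs(a, grouping)
  expect_identical(caAttributes(c1), caAttributes(c2))
  perm <- sample(8)
  ap <- initialize(a, seqs = seqMatrix(a)[perm, , drop = FALSE],
                   meta = taxonInfo(a)[perm, , drop = FALSE])
  c3 <- findPureCAs(ap, grouping)
  expect_identical(caAttributes(c1), caAttributes(c3))
})

test_that("classifyByCAs scores, assigns and refuses cleanly", {
  a <- aln("GGGGGGGGGG", "GGGGGGGGGG", "AAAAAAAAAA", "AAAAAAAAAA",
           ids = c("x1", "x2", "y1", "y2"))
  ca <- findPureCAs(a, list(X = c("x1", "x2"), Y = c("y1", "y2")))
  # held-out member of X classifies back at 1.0
  hit <- classifyByCAs(strrep("G", 10), ca)
  expect_equal(hit$assigned, "X")
  expect_equal(unname(hit$scores["X"]), 1.0)
  # half the CAs mutated -> score 0.5, below the 0.8 floor
  half <- classifyByCAs(paste0(strrep("G", 5), strrep("C", 5)), ca)
  expect_equal(unname(half$scores["X"]), 0.5)
  expect_true(is.na(half$assigned))
  # all-missing query matches nothing
  blank <- classifyByCAs(strrep("?", 10), ca)
  expect_true(is.na(blank$assigned))
  expect_error(classifyByCAs("GG", ca), "shape")
})

test_that("groupsFromTree enumerates internal-node clades", {
  tr <- readNewick("((a,b),(c,d));")
  g2 <- groupsFromTree(tr, minSize = 2)
  expect_equal(sort(unname(vapply(g2, paste, "", collapse = ""))),
               sort(c("ab", "cd")))
  g1 <- groupsFromTree(tr, minSize = 1)
  expect_true(all(c("a", "b", "c", "d") %in% names(g1)))

  cat5 <- readNewick("(((((a,b),c),d),e),f);")
  gc <- groupsFromTree(cat5, minSize = 2)
  sizes <- sort(unname(lengths(gc)))
  expect_equal(sizes, c(2, 3, 4, 5))
  # nested chain: each group contains the previous
  ord <- order(lengths(gc))
  for (i in seq_along(ord)[-1])
    expect_true(all(gc[[ord[i - 1]]] %in% gc[[ord[i]]]))
})

test_that("planted diagnostic columns round trip through discovery", {
  cfg <- simulationConfig(seed = 17)
  sim <- simulateDataset(cfg)
  plant <- sim$planted$matK$ca
  grouping <- split(sim$metadata$id, sim$metadata$genus)
  ca <- findPureCAs(sim$alignments$matK, grouping)
  tab <- caAttributes(ca)
  mine <- tab[tab$clade == plant$clade, ]
  for (j in seq_along(plant$positions)) {
    expect_true(any(mine$position == plant$positions[j] &
                    mine$state == plant$states[j]))
  }
  # held-out member classifies back to its clade with full score
  member <- plant$members[1]
  q <- seqMatrix(sim$alignments$matK)[member, ]
  res <- classifyByCAs(q, ca)
  expect_equal(res$assigned, plant$clade)
  expect_equal(unname(res$scores[plant$clade]), 1.0)
})
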