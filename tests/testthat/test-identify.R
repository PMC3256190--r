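test_that("matchPrimer expands IUPAC codes and scans both strands", {
  hits <- matchPrimer("TTACATTTACGTT", "ACR")
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$start, c(3, 9))  # ACA and ACG (R = A/G)
  expect_true(all(plus$mismatches == 0))

  mm <- matchPrimer("AAACCCAAA", "CCG", maxMismatches = 1)
  expect_true(any(mm$strand == "+" & mm$mismatches == 1))

  none <- matchPrimer("AAAAAAAA", "CGCG")
  expect_equal(nrow(none), 0L)
  # primer longer than template binds nowhere
  expect_equal(nrow(matchPrimer("ACG", "ACGTACGT")), 0L)
})

test_that("matchPrimer agrees with the Biostrings IUPAC oracle", {
  set.seed(61)
  for (k in 1:5) {
    tmpl <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
    primer <- paste(sample(c("A", "C", "G", "T", "R", "Y", "N"), 8,
                           replace = TRUE, prob = c(rep(0.2, 4), rep(0.4/3, 3))),
                    collapse = "")
    mine <- matchPrimer(tmpl, primer)
    plus <- mine[mine$strand == "+", ]
    oracle <- Biostrings::matchPattern(
      Biostrings::DNAString(primer), Biostrings::DNAString(tmpl),
      fixed = "subject")
    expect_setequal(plus$start, Biostrings::start(oracle))
    minus <- mine[mine$strand == "-", ]
    oracleM <- Biostrings::matchPattern(
      Biostrings::DNAString(primer),
      Biostrings::reverseComplement(Biostrings::DNAString(tmpl)),
      fixed = "subject")
    expect_setequal(minus$start,
                    300 - Biostrings::end(oracleM) + 1)
  }
})

test_that("insilicoPCR predicts the constructed 599-bp rbcL amplicon", {
  primers <- barcodingPrimers()
  rbcl <- primers[primers$locus == "rbcL", ]
  expect_equal(nchar(rbcl$forward), 20L)
  expect_equal(nchar(rbcl$reverse), 26L)
  set.seed(62)
  insert <- paste(sample(c("A", "C", "G", "T"), 553, replace = TRUE),
                  collapse = "")
  fwdSite <- gsub("R", "A", rbcl$forward)  # one concrete degenerate choice
  template <- paste0(fwdSite, insert, reverseComplement(rbcl$reverse))
  prod <- insilicoPCR(template, rbcl$forward, rbcl$reverse)
  expect_equal(nrow(prod), 1L)
  expect_equal(prod$productLength, 599L)
  expect_equal(prod$forwardStart, 1L)
  expect_equal(prod$reverseEnd, 599L)

  # fixed point: the product re-amplifies to the same length
  amplicon <- substr(template, prod$forwardStart, prod$reverseEnd)
  prod2 <- insilicoPCR(amplicon, rbcl$forward, rbcl$reverse)
  expect_equal(prod2$productLength, 599L)

  # reverse-site-only template yields nothing
  lonely <- paste0(insert, reverseComplement(rbcl$reverse))
  expect_equal(nrow(insilicoPCR(lonely, rbcl$forward, rbcl$reverse)), 0L)

  # two forward sites upstream of one reverse site -> two products
  double <- paste0(fwdSite, strrep("A", 30), template)
  prodD <- insilicoPCR(double, rbcl$forward, rbcl$reverse)
  expect_equal(nrow(prodD), 2L)
  expect_setequal(prodD$productLength, c(599L, 599L + 30L + 20L))
})

test_that("alignIdentity reports local identity and query coverage", {
  s <- strrep("ACGT", 25)
  expect_equal(unname(alignIdentity(s, s)),
               c(100, 100))
  mut <- paste0(substr(s, 1, 49), "T", substr(s, 51, 100))
  expect_equal(unname(alignIdentity(s, mut)["identity"]), 99.0)
  # query a clean substring: full coverage, full identity
  half <- substr(s, 26, 75)
  res <- alignIdentity(half, s)
  expect_equal(unname(res["identity"]), 100)
  expect_equal(unname(res["coverage"]), 100)
  expect_error(alignIdentity("", s), "empty")
})

test_that("identifyQuery assigns ranks by hit agreement and thresholds", {
  set.seed(63)
  base <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  mutate <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(length(ch), n)
    ch[at] <- vapply(ch[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(ch, collapse = "")
  }
  refs <- c(zm = base,
            zn = mutate(base, 12),     # congener, ~97% identity
            ho = mutate(base, 80))     # different family, ~80%
  md <- metaTable(c("zm", "zn", "ho"),
                  c("Zostera marina", "Zostera noltii", "Halophila ovalis"),
                  family = c("Zosteraceae", "Zosteraceae",
                             "Hydrocharitaceae"))
  hit <- identifyQuery(base, refs, md)
  expect_equal(hit$level, "S")
  expect_equal(hit$name, "Zostera marina")

  # equidistant between two congeners -> genus level
  refs2 <- c(zm = mutate(base, 4), zn2 = mutate(base, 4), ho = refs[["ho"]])
  md2 <- metaTable(c("zm", "zn2", "ho"),
                   c("Zostera marina", "Zostera noltii",
                     "Halophila ovalis"),
                   family = c("Zosteraceae", "Zosteraceae",
                              "Hydrocharitaceae"))
  hit2 <- identifyQuery(base, refs2, md2)
  expect_equal(hit2$level, "G")
  expect_equal(hit2$name, "Zostera")

  # nothing close -> unassigned
  far <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  hit3 <- identifyQuery(far, refs["ho"], md[md$id == "ho", ])
  expect_equal(hit3$level, "unassigned")
})

test_that("every library member identifies to itself at species level", {
  sim <- simulateDataset(tinyConfig(seed = 23))
  m <- seqMatrix(sim$alignments$fast)
  refs <- apply(m, 1, function(ch)
    paste(ch[ch %in% c("A", "C", "G", "T")], collapse = ""))
  for (id in names(refs)) {
    hit <- identifyQuery(refs[[id]], refs, sim$metadata)
    expect_equal(hit$level, "S", info = id)
    expect_equal(hit$name,
                 sim$metadata$species[sim$metadata$id == id], info = id)
  }
})

test_that("leave-one-out identification falls back to congeners", {
  sim <- simulateDataset(tinyConfig(seed = 24))
  m <- seqMatrix(sim$alignments$fast)
  refs <- apply(m, 1, function(ch)
    paste(ch[ch %in% c("A", "C", "G", "T")], collapse = ""))
  md <- sim$metadata
  # drop all sequences of one species with a sampled congener remaining
  target <- md$id[md$species == "GenusA sp1"]
  keep <- setdiff(names(refs), target)
  hit <- identifyQuery(refs[[target[1]]], refs[keep],
                       md[md$id %in% keep, ],
                       thresholds = c(species = 99.5, genus = 90,
                                      family = 85, floor = 80))
  expect_true(hit$level %in% c("G", "F"))
  if (hit$level == "G") expect_equal(hit$name, "GenusA")
})
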