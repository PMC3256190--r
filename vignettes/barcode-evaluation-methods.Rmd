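---
title: "Evaluating multi-locus DNA barcodes: models and methods"
author: "barcodeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-locus DNA barcodes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

# The problem

A DNA barcoding system identifies species from short, PCR-amplifiable
marker sequences. For plants — and for seagrasses in particular, where
phenotypic plasticity makes morphological determination unreliable — no
single plastid locus is sufficient: the slowly evolving coding gene
*rbcL* aligns trivially but discriminates poorly, the faster *matK*
discriminates better, and the *trnH-psbA* intergenic spacer is the most
variable but is indel-rich, hard to align and structurally complicated
by inverted repeats. `barcodeval` implements the complete quantitative
toolkit a locus-evaluation study needs, exercisable end-to-end on
simulated multi-locus data with known truth:

* site-composition statistics (conserved / variable / singleton /
  parsimony-informative characters),
* uncorrected *p*-distance analysis with intra-/inter-genus
  partitioning — the "barcoding gap",
* tree-based evaluation (NJ, MP, ML with nonparametric bootstrap,
  majority-rule consensus, topology comparison) and species-resolution
  statistics,
* character-based barcoding via diagnostic characteristic attributes
  (CAs),
* inverted-repeat (IR) detection in spacer sequences,
* in-silico PCR with degenerate primers and rank-level identification
  against a local reference library.

# Data model and missing-data convention

The central containers are S4 classes: `BarcodeAlignment` (a per-locus
alignment as a character matrix plus a taxon metadata table) and
`Supermatrix` (the column-wise concatenation of loci over the taxon
union, with a partition table; absent loci are padded with `?`).

One convention is used everywhere: only the unambiguous bases A/C/G/T
are *determinate*. `-` is an alignment gap, `?` missing data, and IUPAC
ambiguity codes are treated as missing rather than expanded into
candidate bases. This makes every statistic deterministic and keeps
site classification, distances, parsimony, likelihood and CA discovery
mutually consistent. The two missing characters are preserved
distinctly on output because they mean different things (indel versus
unsequenced), but both are "non-base" for every statistic.

# Site composition

A column is *indeterminate* when fewer than two determinate bases are
present; it is excluded from the percentage denominator (the
alternative — counting it as conserved — would flatter gap-rich
spacers). Among the remaining columns, a column is *conserved* when one
state is present, *variable* otherwise; a variable column is
*parsimony-informative* (PIC) when at least two states each occur at
least twice, else a *singleton*. Percentages are reported to one
decimal place. Gapped columns participate via their determinate bases
only; a `gapAsState` sensitivity flag exists in the CA module but site
statistics always treat gaps as missing.

# Distances and the barcoding gap

`pDistance` is the uncorrected proportion of differing sites over the
sites where *both* sequences are determinate (pairwise deletion). Pairs
with no comparable site are *undefined* and are excluded from the gap
analysis and counted separately — silently scoring them 0 or 1 would
bias the gap. Distances are partitioned at a chosen rank (genus by
default, matching sampling designs too thin for species-level
statistics) into intra- and inter-group multisets. The report carries

* `gapStat` = min(inter) − max(intra) (positive iff the distributions
  separate),
* `overlapFraction` = share of intra values at or above min(inter),
* histograms over half-open bins `[kw, (k+1)w)` with default width
  0.5%, in both absolute and relative frequencies (the binning of such
  figures is rarely stated, so both are emitted).

# Trees, bootstrap and resolution

Tree inference goes through the field's standard engines — `ape` for
neighbour joining and consensus, `phangorn` for Fitch parsimony, NNI
searches and pruning-algorithm likelihoods (JC69/K2P/HKY85/GTR, with
discrete-gamma rate variation and an invariant class). The package
contributes the orchestration and the consistent missing-data masking:
bootstrap resampling is column-wise over the whole (super)matrix by
default (per-partition resampling is a flag), every replicate re-runs
the full inference, and bipartition frequencies are mapped back onto
the point-estimate tree as percent supports. For trees of fewer than
four tips the likelihood is computed by a direct pruning evaluation, so
closed-form two-taxon identities hold to numerical precision.
Tie-breaking inside the search engines follows those libraries;
everything is seeded and reproducible.

Because "species resolution" is rarely defined operationally, the
package fixes a definition and prints it in every report: *a species
with two or more sequences is resolved when its sequences form an
exclusive clade whose MRCA support meets the threshold (default 50%).*
Singleton species are excluded from the denominator by default (a
`count_if_supported` policy exists); average branch support is the mean
over internal nodes at or above the threshold — i.e. over well-resolved
clades only. Monophyly is read on a rooted representation; unrooted
trees are midpoint-rooted first (with unit branch lengths substituted
when an inference method returns none). Cross-method aggregation uses
the unweighted mean and standard error over methods; aggregates are
always labelled with the method set, which here is {NJ, MP, ML} —
Bayesian MCMC inference is deliberately out of scope, so "all methods"
never silently implies it.

# Character-based barcoding

Only *pure, simple* characteristic attributes are discovered: state *s*
at column *c* is a CA for group *X* when every member of *X* with a
determinate character at *c* carries *s* and no non-member carries *s*.
Missing data outside the group is ignored rather than treated as
violating absence (the permissive reading); `-` can be admitted as a
diagnostic state behind a flag for indel-borne spacer diagnostics, but
`?` and ambiguity codes never are. Compound (multi-position) attributes
are not implemented: single-nucleotide diagnostics are what CA tables
report in practice, and compound logic would multiply complexity
without an evaluation surface. Classification scores a query per clade
as the fraction of that clade's CAs matched; assignment requires a
unique top scorer at or above a floor (default 0.8). CA counts are
always reported against the package's own alignment length ("n/845"
style), never an external denominator.

# Inverted repeats

IRs are found by local alignment of a sequence against its own reverse
complement, with the classical scoring of the EMBOSS inverted-repeat
tool: +3 per complementary pair, −4 per mismatch, −12 per gap column,
and a score threshold of 40 tuned for short spacer fragments. The
dynamic programme restricts end cells to left-arm end < right-arm
start, so reported arms never overlap and the loop is non-negative.
Hits are reported greedily by descending score (ties by leftmost
start); after each accepted hit its whole span — arms plus loop — is
masked and the scan repeats, so reported hits are mutually
non-overlapping and nested repeats are not double-reported. Scans run
on ungapped sequences; `irConservation` projects the footprints back
into alignment columns and quantifies cross-taxon conservation as
Jaccard overlaps, with within-/between-clade summaries.

# In-silico PCR and identification

Degenerate primers are matched by IUPAC set containment on both
strands, with an allowance for mismatches; products are enumerated for
all convergent binding combinations under a size cap, lengths inclusive
of both primers. The six bundled primer pairs cover *rbcL*, two *matK*
fragments, *rps16-trnQ*, ITS and *trnH-psbA*; the *rbcL* pair (20 and
26 nt) brackets a 599 bp product in the canonical construction.

Identification is a deliberately local, reproducible stand-in for a
remote BLAST search: scored local alignment (match +1, mismatch −1, gap
open 2, extend 0.5) against a reference FASTA with taxonomy, no
E-values. The top five hits are considered; the query is assigned to
species level (S) when all hits within 0.5 identity points of the top
agree on one species at ≥ 99% identity, else genus (G, ≥ 95%), family
(F, ≥ 90%), order (O, only when order metadata exists), else
unassigned. These thresholds are configuration, echoed in every result,
not doctrine.

# The simulator: what it emulates, and what it does not

`simulateDataset` generates the study conditions end to end. The
default configuration encodes a seagrass-like design chosen once:

* taxonomy 4 families × 2 genera × 1–2 species × 2 individuals
  (14 species, 28 sequences), as a deterministic ultrametric
  rank-structured tree — families coalesce at 0.035 expected
  substitutions/site (at rate multiplier 1), genera at 0.015, species
  within a genus at 0.004, conspecific individuals at 0.0005. These
  heights put congeneric divergence near the low single percents and
  intergeneric divergence an order of magnitude higher on the fast
  locus, the regime in which a barcoding gap exists to be detected.
* loci `rbcL` (599 nt), `matK` (845 nt) and `trnH-psbA` (420 nt) at
  rate multipliers 1 : 3 : 8 — the qualitative slow/intermediate/fast
  contrast of the three plastid markers. The spacer also receives
  Poisson indels (rate 8 events per unit branch length, geometric mean
  length 6), a 14 bp-arm/20 nt-loop inverted repeat planted in one
  family, and five diagnostic columns planted in one genus of *matK*.
* substitution model JC69 by default (HKY85 available); sequences
  evolve by exact transition probabilities per branch.

Because the simulator records every indel placement (insertions get
fractional column keys between their neighbours), it emits the *true*
alignment — no alignment software enters the pipeline, and alignment
error is explicitly outside what the tests exercise. Other features of
real data the simulator does not attempt: rate variation across sites,
base-composition bias, hybridisation/chloroplast capture, alignment
ambiguity at the spacer 3′ end, and sequencing error. Passing tests
therefore demonstrate the correctness and calibration of the
*statistics*, not robustness to alignment or assembly artefacts.

# Numerical choices

* NJ branch lengths are clamped at zero with the clamped deficit
  recorded; ML branch optimisation converges at 1e-6 log-likelihood.
* Bootstrap supports are rounded to whole percent; the root "split" of
  an unrooted tree is never labelled.
* Consensus retention is strictly greater-than the threshold, except
  threshold 1.0 which means unanimity (strict consensus).
* Histogram bins are half-open on the right; boundary values fall into
  the upper bin.
* All randomness flows from a single integer seed; per-locus simulator
  seeds are derived arithmetically and stay within 32-bit range.

# Problem sizes used in validation

The shipped tests and the acceptance script run the default 28-sequence
three-locus design with 100 bootstrap replicates per method (the
field's convention of 1000 replicates is a configuration away; support
values are stable to a few percent already at 100 on these data), ten
simulation seeds for the qualitative locus-comparison checks, and 50
replicates for the Monte-Carlo check of simulated *p*-distances against
the JC69 closed form. Exhaustive small-case oracles cover all 256
four-row columns (site classifier), all 105 six-taxon topologies
(parsimony), random additive matrices up to ten taxa (NJ) and gapless
inverted-repeat enumerations up to 60 nt.

# Known limitations

* Bayesian inference is not implemented; cross-method aggregates are
  over {NJ, MP, ML} and say so.
* Substitution-model *selection* is out of scope; models are supplied
  or estimated within the chosen family (GTR-class defaults).
* The identification module is not a BLAST re-implementation: no
  E-values, no database statistics — identity/coverage plus taxonomy
  logic only.
* `findInvertedRepeats` is quadratic per sequence; it is meant for
  spacer-length (hundreds of nt) inputs, not genomes.

# A worked example

```{r example, eval = FALSE}
sim <- simulateDataset(simulationConfig(seed = 1))
bundle <- runPipeline(sim, pipelineConfig(methods = c("nj", "mp"),
                                          bootstrapReps = 100, seed = 1))
bundle$compositionTable      # PIC% per locus and combination
bundle$gapSummary            # intra/inter means, gap statistic per locus
bundle$aggregate             # resolution and support, mean +/- SE over methods
renderReport(bundle, outDir = "report")
```
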