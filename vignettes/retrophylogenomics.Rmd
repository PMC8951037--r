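---
title: "Retrophylogenomics with SINE presence/absence matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrophylogenomics with SINE presence/absence matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The data and the model

Short interspersed elements (SINEs) insert into a genome essentially
irreversibly: precise excision and independent insertion at the same
orthologous site are both rare enough to neglect. A fixed insertion shared
by several species is therefore a nearly homoplasy-free binary character —
present (`1`) in every descendant of the lineage in which it inserted,
absent (`0`) elsewhere. `sinephylo` analyses matrices of such characters:
taxa as rows, insertion loci as columns, states in `{0, 1, ?}`.

Three evolutionary signals are disentangled:

1. **Species phylogeny.** Most insertions arose on a branch of the species
   tree and mark a clade.
2. **Incomplete lineage sorting (ILS).** An insertion segregating through
   several rapid speciations can fix in a non-clade set of species. Under
   the multispecies coalescent, for any four taxa the two presence
   patterns that conflict with the species tree are *exchangeable*: ILS
   alone inflates both equally.
3. **Introgression.** Gene flow between two lineages inflates exactly one
   of the two conflicting patterns. The asymmetry between the two minority
   patterns is therefore a test for introgression that is robust to ILS.

## Pipeline stages

### From MELT calls to the 01 matrix

`read_melt_vcf()` parses MELT-style VCFs from both discovery modes. In
Split mode the ALT allele *is* the insertion; in Deletion mode the ALT
allele is the deletion of a reference insertion, so genotype polarity is
inverted. A heterozygous genotype counts as presence: a segregating
insertion is still evidence the element inserted in that lineage.
`filter_melt_calls()` retains PASS calls, requiring `ASSESS >= 2`
(i.e. > 1) for Split-mode calls; Deletion mode has no ASSESS score.
`filter_complete()` drops loci not genotyped in every species, and
`filter_informative()` keeps parsimony-informative columns.

The informativeness default is `min_present = 2, min_absent = 2`, the
standard binary parsimony-informative rule. Under Dollo parsimony a
pattern present in all but one taxon is tree-dependent (it may cost a
loss), so `min_absent = 1` is available as an explicit relaxation
(`--dollo-informative` on the command line). We default to the stricter
rule because it is reproducible without reference to any tree.

When the same (species, locus) pair is genotyped by both MELT modes with
conflicting genotypes, the Deletion-mode call wins (with a warning): it
genotypes the reference insertion allele directly rather than inferring it
from split reads.

### Dollo parsimony

The Dollo model allows one 0→1 gain per character (placed at the most
recent common ancestor of the carriers) and any number of 1→0 losses,
with ancestral absence. Although insertions themselves only ever gain,
scoring uses the classic Dollo transition count — gain plus losses — since
a non-clade presence pattern must be explained by losses once a single
gain is imposed; this is the quantity the PHYLIP `dollop` program reports
as state transitions. `dollo_character_score()` is verified in the test
suite against exhaustive enumeration of all internal-state assignments on
every rooted topology of up to six taxa.

Dollo scoring needs a root; the search (`dollo_search()`) therefore fixes
a user-designated outgroup as one of the root's two children and explores
rooted topologies. The heuristic is stepwise addition (once per jumbled
taxon order, default `n_jumbles = 7`) followed by
nearest-neighbor-interchange hill-climbing. Equal-score NNI moves are
accepted up to a bounded plateau budget (25 moves, visited topologies
tracked): binary-character landscapes contain large plateaus of equally
parsimonious trees, and a purely greedy climb demonstrably stalls on
them. NNI rather than SPR keeps an 11-taxon, 10^4-column bootstrap
analysis interactive; the search scores collapsed unique column patterns
with multiplicities, which is what makes bootstrap replicates cheap.
Exhaustive search is available to 9 taxa and is the oracle against which
the heuristic is tested.

`bootstrap_replicates()` resamples columns with replacement;
`majority_consensus()` keeps clades in strictly more than the threshold
fraction of trees (a clade at exactly 50% is excluded, matching PHYLIP's
majority rule with the extended option off) and annotates each with its
frequency. `nj_tree()` provides the distance-based view: Saitou–Nei
neighbor joining on normalized Hamming distances, negative branch
lengths clamped to zero.

### Discordance and its attribution

A locus needing two or more transitions on the species tree is
*discordant*: its carriers are not a clade. Each discordant locus is
attributed to the most recent common ancestor of its carriers — the
ancestral population in which the underlying ILS or introgression event
must have occurred. `discordance_report()` tabulates per-locus
transitions, per-node attribution counts (all nodes reported, including
zeros), and the ranked table of discordant presence patterns (ties broken
lexicographically so output is deterministic).

### Bipartition gene trees and quartet support

Each informative column, read as a bipartition of the taxa, is an
incompletely resolved gene tree with exactly one internal edge —
the input unit of quartet-based species-tree methods (ASTRAL).
`bp_gene_trees()` writes them as newick; `branch_quartet_support()`
computes, for every internal branch of a species tree, the fraction of
resolved quartets (one taxon from each of the four clusters around the
branch) supporting the branch's arrangement versus the two alternatives,
using exact closed-form products of cluster intersection counts rather
than sampling. The closed form is verified against brute-force quartet
enumeration in the tests. `quartet_score()` ranks whole candidate
topologies by total quartet agreement; full ASTRAL-style search is out of
scope — the package emits ASTRAL's inputs instead.

### The quartet asymmetry test

For each of the C(n, 4) quartets (330 for 11 taxa):

* Restrict every column to the four taxa; columns with exactly two
  carriers among them vote for the split uniting those two. Other
  restricted patterns are uninformative.
* The *accepted* split is the one induced by the supplied species tree —
  always, even if an alternate has more votes (a warning is emitted);
  quartets spanning a polytomy are untestable and excluded.
* Under ILS the two non-accepted splits have equal expected counts
  `(n_alt1 + n_alt2) / 2`. A Pearson χ² with 1 df (no continuity
  correction) tests the asymmetry; quartets with `n_alt1 + n_alt2 < 10`
  are flagged `low_count` but still tested, preserving auditability.
* Holm–Bonferroni correction is applied across all testable quartets.
* For significant quartets, both taxon pairs united by the
  overrepresented split are recorded; `implicated_pairs()` tallies them
  across quartets. The truly introgressing pair accumulates support from
  many quartets while the incidental partners scatter, so the tally —
  rather than an arbitrary per-quartet choice — identifies the pair.
  Mapping pair tallies onto named ancestral pathways remains an
  interpretive step for the user, done on the tree.

The identity linking this test to parsimony scores: on the quartet tree
for a split, a supporting informative character costs 1 step and a
non-supporting one costs 2, so with N informative characters and tree
length L the support is `N - (L - N) = 2N - L`.
`parsimony_crosscheck()` computes support that way (vectorised Fitch on
the quartet topology) and the tests require exact agreement with the
direct pattern counts on every random instance.

## The simulator: what it emulates and what it does not

`sim_model()` + `simulate_matrix()` generate homoplasy-free insertion
matrices under the multispecies coalescent. One haploid lineage is
sampled per species (matching the one-individual-per-species design of
insertion presence/absence studies); time is in coalescent units (2N
generations), so population sizes are absorbed into branch lengths.
Lineages coalesce within populations at rate 1 per pair; at a speciation
time the child populations merge (backward in time). Introgression
pulses are instantaneous admixture events: tracing backward, a lineage
in the recipient population at the pulse time switches to the donor with
the stated probability. A single insertion per locus is placed on a
genealogy branch chosen proportionally to its duration; carriers are the
tips below it. With `condition_on_informative = TRUE` loci are
rejection-sampled until informative, mirroring the informativeness filter
applied to real matrices.

The simulator's correctness is pinned to coalescent closed forms in the
tests: pairwise TMRCA means (τ + 1), the (2/3)e^(−T) triplet discordance
law (within Monte-Carlo error at 10^4 genealogies), equifrequent triplets
at T = 0, exchangeability of the two minority quartet patterns without
pulses, and the calibration of the χ² test's type-I error at the nominal
5% over 500 simulated matrices.

It deliberately does **not** emulate: genotyping error or missing data
(MELT false calls), insertion-rate variation across branches, precise
excision or parallel insertion (assumed absent, as for real SINEs),
diploid genotypes and heterozygosity, or continuous migration (pulses
are discrete). Passing tests on simulated data therefore validate the
inference machinery under the model's assumptions, not the robustness of
MELT genotyping on real reads.

The core loop is implemented in C++ (driven by R's RNG, so `set.seed()`
gives bit-reproducible runs); calibration experiments draw millions of
genealogies.

## Numerical and design choices

* Matrices are integer matrices with `NA` for `?`; all scoring is
  vectorised over columns via a single node-by-taxon incidence product.
* Ties among equally parsimonious trees: all are retained;
  consensus-facing output is ordered by lexicographic canonical newick so
  snapshots are stable.
* Consensus threshold is strict (`> 0.5` by default, configurable in
  `[0.5, 1)`); frequencies are attached as node labels.
* Quartet split order is canonical — for sorted taxa `(a, b, c, d)`:
  `ab|cd`, `ac|bd`, `ad|bc` — and all outputs are sorted, so results are
  invariant to taxon and column order (tested).
* The χ² p-value is the upper tail of χ²(1); `p.adjust(method = "holm")`
  performs the step-down correction.
* Degenerate inputs: empty matrices score 0; all-absent characters have 0
  transitions; a zero-alternate quartet is untestable rather than χ² = 0;
  heterozygosity with no genotyped calls is `NA` with a warning.

## Scales used in the shipped analyses

The test suite and the acceptance script run at desk scale, chosen to
keep full runs in minutes while leaving Monte-Carlo error well inside
the tested tolerances: 11-taxon matrices of 10^4 conditioned loci for
pipeline runs, 500 replicate 4-taxon matrices of 2000 loci for χ²
calibration, 100 replicate pulse matrices for power, 10^4 genealogies
per point for closed-form checks, and 100 bootstrap replicates for
consensus recovery. The 6-taxon power configuration (pulse of
probability 0.3 at time 0.5 between non-sister taxa) and the 4-taxon
calibration tree (internal branches of 0.5 coalescent units) are fixed
study conditions, not tuning knobs.

## Limitations

* Dollo search is heuristic beyond 9 taxa; the plateau-tolerant NNI climb
  matches exhaustive optima on all tested instances up to 7 taxa, but no
  optimality guarantee exists for larger trees (as for parsimony search
  generally).
* Attribution of a discordant locus to the carriers' MRCA is a
  bookkeeping convention: it cannot distinguish ILS from introgression
  for an individual locus.
* The accepted quartet split always follows the supplied species tree;
  in anomaly-zone-like regions the test can then be conservative (the
  warning about inverted support flags this).
* The quartet test assumes independent loci; tightly linked insertions
  violate this and would inflate significance.
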