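# sinephylo

Phylogenomics from SINE insertion presence/absence data.

Retrotransposon insertions are nearly perfect binary phylogenetic
characters: a SINE inserts once, is inherited by every descendant, and is
essentially never precisely excised or independently inserted at the same
orthologous site. A matrix of such characters (taxa × loci, states
`0/1/?`) lets one both *infer* a species tree and *quantify* the two
processes that make individual loci disagree with it — incomplete lineage
sorting (ILS) and introgression. `sinephylo` implements that whole
pipeline for researchers working on rapid radiations (the motivating
setting is genus-level bat phylogenomics, but nothing is taxon-specific):

* **matrix building** — parse MELT-style VCFs (Split + Deletion mode),
  quality-filter calls (`PASS`, `ASSESS > 1`), map genotypes to binary
  states (heterozygous = presence), require complete genotyping, keep
  parsimony-informative loci; read/write NEXUS `01`, relaxed PHYLIP and
  TSV matrices; per-species heterozygosity.
* **Dollo parsimony** — scoring under the "one gain (at the carriers'
  MRCA), any losses" model; outgroup-rooted heuristic tree search
  (jumbled stepwise addition + plateau-tolerant NNI) with an exhaustive
  mode to 9 taxa; column bootstrap; strict majority-rule consensus with
  clade frequencies; NJ tree from normalized Hamming distances.
* **discordance** — loci needing ≥ 2 state transitions on a tree are
  discordant; each is attributed to the MRCA of its carriers (the
  ancestral population where the ILS/introgression event occurred), with
  per-node counts and a ranked table of discordant presence patterns.
* **bipartition gene trees & quartet support** — one-split gene trees for
  ASTRAL, and exact per-branch quartet support fractions (q1/q2/q3) for
  any species tree.
* **quartet asymmetry test** — for every 4-taxon subset, the characters
  conflicting with the species-tree split divide equally between the two
  alternate splits under ILS alone; a χ²(1) test with Holm–Bonferroni
  correction flags asymmetric quartets, and the taxon pairs united by
  overrepresented splits are tallied to localize introgression. The
  parsimony identity `support = 2N − L` ties the counts to quartet tree
  lengths.
* **coalescent simulator** — multispecies-coalescent generator of
  homoplasy-free insertion matrices (C++ core, seed-reproducible), with
  instantaneous introgression pulses and optional conditioning on
  informativeness, so every stage is testable end-to-end against known
  truth and closed forms.

## Worked example

Simulate an ILS-heavy 11-taxon radiation (internal branches of 0.5
coalescent units) with one introgression pulse (probability 0.3, between
the non-sister taxa `t06` and `t09`), then run the full pipeline:

```r
library(sinephylo)

tree   <- demo_species_tree()
pulses <- data.frame(time = 0.5, donor = "t06", recipient = "t09", prob = 0.3)
model  <- sim_model(tree, pulses = pulses, n_loci = 10000)
m      <- simulate_matrix(model, seed = 1)

boots <- dollo_bootstrap(m, outgroup = "out", n_reps = 100, seed = 2)
cons  <- majority_consensus(boots)
discordance_report(m, cons)
#> Discordance report: 3809 / 10000 loci discordant (38.1%)
#> Attributed loci per ancestral node:
#>   node 13 (t01,t02,t03,t04,t05,t06,t07,t08,t09,t10): 1388 (36.4%)
#>   node 14 (t01,t02,t03,t04,t05,t06,t09,t10): 983 (25.8%)
#>   node 19 (t06,t09,t10): 539 (14.2%)
#>   node 15 (t01,t02,t03,t04,t05): 505 (13.3%)
#>   node 16 (t01,t02,t03): 246 (6.5%)
#>   node 12 (out,t01,t02,t03,t04,t05,t06,t07,t08,t09,t10): 148 (3.9%)
```

38% of loci conflict with the inferred tree, concentrated at the short
internal branches — and the consensus itself has been distorted by the
pulse (it groups `t06` with the recipient's cherry). The quartet
asymmetry test, run against the generating species tree, localizes the
cause:

```r
qt <- quartet_asymmetry_test(m, tree)
#> Quartet asymmetry: 52 / 330 testable quartets significant
head(implicated_pairs(qt), 3)
#>      pair n_quartets
#> 1 t06-t09         25
#> 2 out-t10          8
#> 3 out-t07          6
```

The donor–recipient pair tops the tally by a wide margin: 25 significant
quartets implicate `t06–t09`, while incidental pairs scatter. On real
data the same calls consume a matrix built from MELT VCFs
(`read_melt_vcf()` → `filter_melt_calls()` → `build_matrix()` →
`filter_complete()` → `filter_informative()`), and `bp_gene_trees()`
exports ASTRAL-ready inputs.

A command-line wrapper covering each stage is installed at
`system.file("exec", "sinephylo", package = "sinephylo")`
(subcommands `matrix`, `dollo`, `nj`, `discordance`, `bp`, `quartets`,
`simulate`).

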