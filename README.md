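# ribolandscape

Fitness-landscape and ancestral-activity analysis for self-cleaving
ribozyme mutational libraries.

## What this package is for

The mammalian CPEB3 ribozyme is an HDV-like self-cleaving RNA whose 67-nt
sequence is extraordinarily conserved. To ask whether its *activity* — not
just its sequence — has been conserved, one can build a combinatorial
"doped" library over the handful of positions that vary across mammals,
transcribe it in vitro, and sequence the co-transcriptional cleavage
products: a molecule that cleaved has lost the 9-nt leader
(5'-GGACCAUUC-3') upstream of the cleavage site, while an uncleaved
molecule retains it. Counting reads in each state gives every genotype a
relative activity,

    f_cleaved = n_cleaved / (n_cleaved + n_uncleaved),

and mapping those activities onto a species tree — with ancestral
sequences reconstructed by parsimony and maximum likelihood — turns the
library into a fitness landscape over which mutational pathways, genotype
networks and epistasis can be analyzed.

`ribolandscape` implements this entire computational pipeline for R users
working with such assays (and, via its simulation module, for anyone who
wants to study the method itself without sequencing data):

* **Variant schemes and genotype arithmetic** — `variant_scheme()`,
  `default_scheme()` (10 biallelic + 3 triallelic positions,
  2^10 x 3^3 = 27,648 genotypes), `enumerate_genotypes()`,
  `hamming_distance()`, `neighbors()`, `genotype_to_sequence()` /
  `sequence_to_genotype()`, `mutations_from()`.
* **Synthetic data** — `generate_truth_landscape()` (multiplicative
  per-position penalties with the assay's qualitative structure: G1
  mutations kill activity, L4-loop mutations are nearly neutral),
  `simulate_reads()` (Bernoulli cleavage, 9/12/15/18-nt phasing pads,
  leader, 3' primer site, substitution errors, replicate streams),
  `simulate_tree_sequences()` (sequence evolution with recorded internal
  truth).
* **Read processing** — `classify_read()` (anchor on the primer-binding
  site, call cleaved/uncleaved from the leader, extract the genotype),
  `count_reads()`, `fraction_cleaved()`, `aggregate_replicates()`.
* **Ancestral reconstruction** — `fitch_parsimony()` (Hartigan
  generalization, full MPR sets, multifurcation-safe),
  `ml_marginal_reconstruction()` (marginal posteriors under JC69 or
  Tamura–Nei via the pruning recursion), `compare_reconstructions()`,
  `assign_node_activity()` (measured values, then the G1 rule, then the
  L4 rule, then flagged as external).
* **Landscape analysis** — `build_network()` (igraph genotype network of
  genotypes above an activity threshold), `count_viable_pathways()`
  (ordered distinct-position pathways; 37,200 length-4 pathways per start
  in the default scheme), `neighborhood_rings()`,
  `distance_activity_profile()`, `count_below()`, `group_summary()`.
* **Epistasis** — `enumerate_squares()` (117 mutation-pair squares per
  reference), `classify_square()` (none / magnitude / sign /
  reciprocal sign), `epistasis_summary()`,
  `epistasis_dataset_summary()`.

The packaged `default_scheme()` is a documented synthetic stand-in that
honors the structural constraints of the real library (G1 with alleles
G/A, C9U, G30A, U36C, four L4-loop positions); supply your own scheme as
TSV for real data.

## Worked example

Simulate the assay for the ancestral genotype and three of its single
mutants, then recover their activities end to end:

```r
library(ribolandscape)
scheme    <- default_scheme()
anc       <- ancestral_genotype(scheme)
landscape <- generate_truth_landscape(scheme)   # ancestral p = 0.92
focus     <- c(anc, neighbors(scheme, anc)[1:3])
reads     <- simulate_reads(landscape, scheme, reads_per_genotype = 1000,
                            n_replicates = 3, error_rate = 0.001, seed = 42,
                            genotypes = focus)
activity  <- aggregate_replicates(count_reads(reads, scheme))
```

The recovered activities match the simulation truth (0.92 ancestral, 0.03
for the G1A mutant, near-neutral C9U, strongly deleterious A5G), and the
three replicates correlate at r > 0.999:

```
      genotype mean_fraction total_reads mutations
 AACCGGUCAUAGC        0.0324        2960       G1A
 GACCGGUCAUAGC        0.9109        2975
 GAUCGGUCAUAGC        0.8991        2973       C9U
 GGCCGGUCAUAGC        0.3194        2955       A5G
```

Landscape summaries on the full 27,648-genotype truth landscape:

```r
distance_activity_profile(landscape, scheme)   # mean activity per distance
#   distance    n mean_activity
# 1        0    1        0.9200
# 2        1   16        0.5447
# 3        2  117        0.3136
# 4        3  518        0.1754
# 5        4 1550        0.0951

count_viable_pathways(landscape, scheme, anc)
# Pathway report from GACCGGUCAUAGC
#   4 steps, activity threshold 0.5
#   37200 enumerated, 600 viable (1.6%)

epistasis_summary(landscape, scheme, anc)
# 117 squares, 117 evaluable; 100% magnitude, 0% sign, 0% reciprocal_sign
```

The mean activity decays with mutational distance from the ancestral
genotype; every length-4 ordered pathway over distinct positions is
enumerated (37,200 of them) and only those whose every intermediate stays
above activity 0.5 count as viable; and the noise-free multiplicative
landscape shows no sign or reciprocal-sign epistasis, the expected
negative control for a landscape in which activity is a monotone function
of a per-position score.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/ribolandscape-cli.R` (subcommands `simulate`, `count`,
`reconstruct`, `network`, `pathways`, `profile`, `epistasis`).

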