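---
title: "Models and methods behind ribolandscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribolandscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribolandscape)
```

This vignette is the package's own account of the models, conventions and
numerical choices it implements. It states no empirical result beyond what
the test suite and the acceptance script themselves compute.

## The assay model

A self-cleaving ribozyme library is transcribed in vitro; each molecule
either cleaves during transcription or does not. Cleavage removes the 9-nt
leader (`GGACCAUUC`) 5' of the cleavage site, so after 5'-RACE reverse
transcription — which appends a constant primer-binding region to the 3'
end of every cDNA and a variable-length phasing pad (9, 12, 15 or 18 nt)
to the 5' end — the two reaction outcomes are distinguishable from the
read sequence alone:

```
uncleaved:  [pad] [leader] [67-nt ribozyme] [primer site]
cleaved:    [pad]          [67-nt ribozyme] [primer site]
```

The per-genotype activity measure is the fraction of classified reads in
the cleaved state, `f = n_cleaved / (n_cleaved + n_uncleaved)`. This is a
relative, end-point measure of self-cleavage during transcription, not a
rate constant; it saturates near 1 for fast ribozymes and is bounded below
by the misclassification floor.

## The variant scheme

A `variant_scheme` fixes a 67-nt backbone (the ancestral sense strand,
RNA alphabet), the variable positions with their allowed alleles, the
leader and the primer site. Coordinates are 1-based with position 1 (the
"G1" nucleotide) immediately 3' of the cleavage site; the leader is
indexed separately, so position names like `G1` or `U36` match the
field's mutation nomenclature (`G1A`, `C9U`, ...). The default scheme has
ten biallelic and three triallelic positions, hence
`2^10 * 3^3 = 27,648` genotypes. Its backbone sequence and exact position
identities are a **synthetic stand-in**: they honor the structural facts
the pipeline depends on — G1 admits G/A, C9U and G30A exist and are
near-neutral, U36 pairs with G1, four positions sit in the peripheral L4
loop — but they are not the biological CPEB3 sequence, whose full library
definition is not republished here. All analyses accept a user scheme via
`read_scheme_tsv()`.

Genotypes are strings over the variable positions, enumerated in
lexicographic order so that indices are stable across runs.

## The synthetic truth landscape

`generate_truth_landscape()` assigns every genotype a true cleavage
probability under a multiplicative-penalty model:

* the ancestral genotype gets `p0 = 0.92`, the ancestral fraction cleaved
  measured by the assay this package models;
* any genotype with a non-reference base at G1 is scaled so that the pure
  single G1 mutant lands at `p_g1 = 0.03`, the measured activity of the
  rat ribozyme, whose only change from the ancestral sequence is G1A;
* each additional mutated position multiplies activity by a per-position
  penalty: 0.98 at L4 positions (near-neutral), 0.97 at C9/G30 (mildly
  deleterious), 0.15 at U36 (breaks the G1:U36 wobble pair), 0.35
  elsewhere.

Only the two anchor values (0.92, 0.03) are empirical; the remaining
penalties are package choices made once to reproduce the qualitative
structure of the measured landscape: a strongly bimodal activity
distribution (the large majority of random mutation combinations
essentially inactive, a distinct high mode around the ancestral
neighborhood of L4/C9/G30 variation) and a mean activity that decays
monotonically with mutational distance from the ancestral genotype. A
multiplicative model is the simplest one with these properties, and it
doubles as a negative control for the epistasis classifier: with no noise,
activity is a monotone function of a per-position additive score on the
log scale, so no mutation pair can show sign or reciprocal-sign epistasis.

Optional Gaussian noise is applied on the logit scale (`noise_sd`,
default 0). The default is noise-free so that the anchor genotypes carry
exactly their nominal probabilities; binomial sampling in the read
simulator is then the only stochastic layer, which is what the estimator
actually has to overcome. Optional pairwise multipliers
(`rules$epistasis`) let users engineer epistatic landscapes.

### What the generator emulates, and what it does not

`simulate_reads()` reproduces: Bernoulli cleavage at the genotype's true
probability, leader presence/absence, one of four fixed phasing pads
(uniformly chosen; their common 9-nt 3' end is deliberately dissimilar
from the leader so a pad suffix can never be mistaken for it), the
constant primer site, i.i.d. substitution errors, and per-replicate
pseudo-random streams derived from one master seed (same seed, identical
FASTQ bytes). It does **not** model: indels, quality-score profiles,
PCR-amplification or reverse-transcription bias, cDNA orientation
bookkeeping, or misfolding effects of upstream sequence context. Passing
tests therefore certify the analysis logic under substitution-only noise
with honest binomial counting statistics — not robustness to the full
error structure of a real sequencing run. Defaults of 100 reads per
genotype per replicate, three replicates and a 0.001 substitution rate
are package choices (the modeled assay does not publish its depth or
error profile).

## Read classification

`classify_read()` follows the anchor logic of the assay's analysis
scripts: find the rightmost occurrence of the primer site (allowing
`max_mismatch` substitutions, default 1), index the 67-mer immediately 5'
of it, and call the state from the 9 nt immediately 5' of the ribozyme —
leader present (same tolerance) means uncleaved; otherwise the read is
cleaved provided its remaining 5' prefix fits within the longest phasing
pad (18 nt). Alleles are then read off at the scheme's variable offsets.
Policy choices, each exposed as configuration because the original
analysis does not state its values:

* anchor tolerance 1 mismatch — tolerant enough to keep reads with one
  sequencing error in a 20-nt anchor, strict enough that spurious anchors
  are vanishingly unlikely;
* reads with a disallowed base at a variable position are **rejected,
  never corrected** — a genotype miscall contaminates a neighbor's
  counts, which is worse than losing depth;
* indel-bearing reads fail the positional checks and fall out as
  unassigned; there is no alignment step, matching the exact-position
  design of the assay;
* `min_reads = 20` classified reads per genotype-replicate for inclusion
  in the activity table; the headline activity is the unweighted mean of
  per-replicate fractions (a pooled-counts alternative is available via
  `pooled = TRUE`).

Reads that cannot be assigned a genotype at all are tallied per replicate
so that counts always conserve the input total.

## Ancestral reconstruction

Two reconstructions are implemented on rooted (possibly multifurcating)
trees with leaf sequences:

* **Parsimony** (`fitch_parsimony()`) uses Hartigan's generalization of
  the Fitch algorithm, which is exact for nodes of any degree: the
  downpass keeps, per node and site, the state set attaining the minimum
  number of changes below that node (plus the "runner-up" set needed for
  the uppass), and the uppass produces the full most-parsimonious
  reconstruction (MPR) set per node and site. The reported single
  sequence takes the alphabetically first member of each MPR set and
  flags every multi-state site as ambiguous — ambiguity is surfaced,
  never hidden.
* **Marginal ML** (`ml_marginal_reconstruction()`) computes per-site
  posterior distributions at every internal node under JC69 or TN93 with
  uniform rates across sites (no Gamma, no invariant-site class), via the
  pruning recursion plus an outside pass, which is algebraically the
  re-rooting construction. Transition matrices come from the symmetrized
  eigendecomposition of the reversible rate matrix, normalized to one
  expected substitution per unit branch length; per-node column scaling
  guards against underflow. TN93 defaults: empirical base frequencies
  from the leaves (with a pseudocount) and both transition/transversion
  ratios fixed at 2 — the conventional neighborhood when no estimate is
  supplied, since the upstream tree software this emulates does not
  publish its fitted values.

`compare_reconstructions()` reports site-by-site agreement of the chosen
sequences. One structural caveat matters for interpreting agreement: on a
tree whose root has exactly two children, neither method can orient an
event that falls on the root split — parsimony returns a two-state MPR
set there (resolved alphabetically) and a reversible-model ML posterior
is near-tied (resolved by branch-length asymmetry) — so the two resolved
sequences can legitimately differ at such sites while both reconstructions
are correct as sets. This is the classic outgroup-free rooting limit. The
recovery tests therefore use trees with a basal trifurcation, where a
majority vote among the three root subtrees orients every single event;
on such low-divergence trees (total length 0.05 substitutions/site, 67
sites, 6–8 leaves) parsimony and ML agree exactly in ≥ 95% of replicates
and recover ≥ 99% of true internal sites.

`assign_node_activity()` puts an activity on every node by strict
precedence: (1) *measured* — the node's sequence maps into the library
and has a measured mean fraction; (2) *rule_G1* — any non-reference base
at G1 predicts very low activity, numeric stand-in 0.05 (the value used
for low-activity extant sequences in the modeled study's distributions);
(3) *rule_L4* — differences confined to L4 positions predict
ancestral-like activity (the ancestral genotype's measured value);
(4) *external* — anything else (e.g. length-variant, gel-assayed
sequences) is flagged with `NA` for a user-supplied value, never guessed.

## Genotype networks, pathways and epistasis

The genotype network keeps genotypes with activity **strictly greater**
than the threshold (default 0.5) and connects Hamming-distance-1 pairs.
Strict inequality mirrors the rule that pathways *end* upon reaching
activity < 0.5. One documented discrepancy in the modeled study — a
figure caption citing 0.05 where the methods text says 0.5 — is handled
by making the threshold a parameter everywhere, with 0.5 the default.

Pathway enumeration is over **ordered sequences of single-position
substitutions at pairwise-distinct positions** (no reversions), each to
any allowed non-current allele. For the default scheme at four steps this
gives the closed form

$$P(4) \;=\; 4!\sum_{k=0}^{3}\binom{3}{k}\binom{10}{4-k}2^{k} \;=\; 37{,}200,$$

which is the total the pipeline must reproduce; permitting reversions
would give $16^4 = 65{,}536$ and contradicts it, which fixes the
interpretation. A pathway is viable when the genotype after every step
stays strictly above the threshold (the start itself is not filtered);
truncation by that rule is what makes realized pathways "up to" four
steps, so shorter viable pathways are prefixes, not separately counted.
`neighborhood_rings()` uses the matching reachability notion: ring *d*
holds genotypes at distance *d* reachable from the start by a viable
pathway whose distance increases by one at every step.

Pairwise epistasis is classified per square (reference, two single
mutants at distinct positions, double mutant) from the interaction
`e = w11 - w10 - w01 + w00`. With `|e|` at or below the tolerance δ the
square is *none*; otherwise each mutation's effect is compared across the
two backgrounds, a mutation *flips* when the two effects have strictly
opposite signs and both exceed δ in magnitude (effects within δ of zero
never flip); both flip → *reciprocal sign*, one → *sign*, neither →
*magnitude*. δ defaults to 0 and a 10⁻⁹ internal guard absorbs
floating-point cancellation so that exactly additive squares classify as
*none*; the exact conventions of the external epistasis server used by
the modeled study are not published, so this contract is fixed here and
symmetric under swapping the mutations. Squares with any missing or
QC-failing corner are skipped and counted, not imputed.

## Numerical and degenerate-input conventions

* `fraction_cleaved(0, 0)` is `NA` (no data), never 0.
* Activity tables with no qualifying genotype are returned empty with a
  warning; empty networks are valid igraph objects.
* ML on zero-length branches uses the exact identity transition matrix;
  negative branch lengths are an error.
* Posterior columns are renormalized to sum to 1 (checked in tests to
  10⁻⁹); argmax ties break alphabetically in both reconstructions.
* FASTA/FASTQ readers accept `T` and normalize to `U`; writers emit RNA.
* All generators are deterministic given their seed; replicate streams
  use sub-seeds drawn once from the master seed.

## Problem sizes used by the test suite

The suite favors exhaustive oracles at small size over sampled checks at
large size: brute-force labeling enumeration for parsimony and ML on
4–6-leaf trees (5 sites), exact combinatorial identities on the full
27,648-genotype library, binomial-bound estimator checks at 10,000 reads
per genotype on toy schemes, and 20-replicate recovery runs on simulated
trees. These sizes were chosen as the smallest at which each property is
non-trivially exercised.

## Known limitations

* The default scheme is a stand-in; conclusions about the biological
  library require the real scheme TSV.
* No indel handling anywhere in read processing; reads from length-variant
  ribozymes are unassigned by design.
* No topology inference or divergence dating: trees are inputs.
* `epistasis_dataset_summary()` over all 27,648 references evaluates
  ~3.2 million squares; it is vectorized over square templates and takes
  a few seconds on the full default library.
* The outgroup-free root-orientation limit described above applies to any
  binary-rooted input tree; the deepest split should be interpreted as a
  set of equally parsimonious orientations.
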