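---
title: "Methods and design notes for panarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for panarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panarch)
```

panarch is a comparative-genomics toolkit aimed at collections of small,
streamlined prokaryotic genomes — the regime typified by nanosized,
mostly host-associated archaea, where genome reduction dominates
evolution, core genomes vanish after a handful of genomes, and lateral
transfer supplies much of the remaining flexibility.  This vignette
explains the models each module implements, the tunable parameters and
their defaults, the synthetic-data generator that stands in for real
genome collections, and the numerical and design choices that were
genuinely open.

## Pan- and core-genome models

Given a binary gene-family presence/absence matrix, `permutation_curves()`
accumulates, for each random genome ordering, the union (pan) and
intersection (core) sizes after each added genome.  Random orderings —
300 by default — remove the bias of any particular addition sequence; an
exhaustive mode enumerates all `n!` orderings for small collections and
is what the tests compare against a brute-force oracle.

The mean pan curve is fitted with the Heaps-law power model
`Ps(n) = kappa * n^gamma` and the mean core curve with the exponential
decay `Fc(n) = kappa_c * exp(-rate * n)`.  Both models are exactly
linearizable, so `fit_power_law()` and `fit_exponential()` use ordinary
least squares on the log scale: the fit is deterministic, reproducible,
and recovers generating parameters to machine precision on noiseless
model data.  Means rather than medians are fitted by default (medians are
available via `stat = "median"`); means are smooth at small `n`, where
medians jump in integer steps.  The zero tail of the core curve is
truncated before fitting, since a vanished core carries no further
information about the decay rate.

Openness follows the exponent: `gamma` in (0, 1) means every added genome
still contributes new families — an open pan-genome, the more open the
closer `gamma` is to 1 — while `gamma <= 0` means the collection has
stopped growing.  The boundary `gamma = 0` (a perfectly flat curve) is
classified closed, because a constant pan-genome adds nothing.
`gamma >= 1` is labelled open with a warning; super-linear growth is
outside the regime the rule was formulated for.  `core_extinction_point()`
returns the smallest `n` at which the fitted core drops below a single
family.

`cluster_families()` provides the upstream step when only proteomes are
available: greedy centroid clustering in length order, joining a sequence
to the first centroid reaching the identity cutoff (30% by default, the
conventional permissive threshold for gene families in diverged
collections).  Identity is matches over global-alignment columns under
unit scores (match +1, mismatch −1, gap −2); clustering engines differ in
their identity definitions, so the convention is documented and
configurable rather than claimed to be bit-compatible with any of them.

## Dollo parsimony gain/loss reconstruction

`dollo_reconstruct()` reconstructs ancestral gene content under the Dollo
assumption: each family originates exactly once and may only be lost
thereafter.  The gain is placed at the most recent common ancestor of the
family's carriers; one loss goes on the stem of each maximal subtree
below that node from which the family is entirely absent.  This is the
minimum-loss assignment under the single-gain constraint, and the test
suite checks it against exhaustive enumeration of all internal-state
assignments on every rooted topology with up to six leaves.

Two bookkeeping decisions matter when reading the outputs:

* The root stem is treated as a branch, so the ancestral gene complement
  appears as gains on the stem.  `branch_event_counts()` therefore
  reports both `gains` (including the stem) and `novel_gains` (excluding
  it).  Published gain-versus-loss headlines display ancestral content on
  the node and mark only lineage events on branches, so `novel_gains` is
  the comparable quantity.
* Genome incompleteness is not modelled: absence is taken as true
  absence.  For real draft genomes this overcounts losses; it is a
  documented caveat, not a correction the package attempts.

Recovery against simulation truth distinguishes the *true* gain node from
the *observable* gain node (the MRCA of surviving carriers).  When losses
excise an entire basal subclade of the original gain, no method working
from leaf data can recover the original placement; the generator records
both nodes, and `gainloss_recovery_report()` scores agreement with the
observable node (which parsimony should achieve exactly) alongside exact
agreement with the true node on the subset where the two coincide.  The
same logic applies to losses: a loss whose parent retains no surviving
carriers elsewhere is masked and excluded from the recovery score.

## Composition-vector phylogeny

`composition_vector()` implements alignment-free genome comparison by
k-mer composition with a Markov background correction.  For pooled k-mer
frequencies `f`, the background predicted by the (k−2)-order Markov model
is `q(a1..ak) = f(a1..ak-1) * f(a2..ak) / f(a2..ak-1)`, and the stored
component is `(f − q)/q` wherever `q > 0`.  The support therefore
includes k-mers that were *not* observed but whose prefix and suffix
were: their component is −1, and this absence signal is part of the
vector (a detail that matters — dropping it weakens the distances
noticeably).  Dissimilarity is `D = (1 − C)/2` with `C` the cosine
correlation over the union of stored k-mers, giving values in [0, 1].

`k = 4` is the default, and amino-acid vectors over concatenated
proteomes are the default alphabet, which is the convention of
composition-vector phylogenetics; a nucleotide mode is available
(`alphabet = "nt"`, counting the given strand only).  Whole-genome
nucleotide mode at small `k` carries little lineage signal on synthetic
genomes built by deterministic back-translation, which is itself a reason
the proteome convention is the default here.

Trees are built by neighbor joining (`neighbor_joining()`, a thin wrapper
with negative branch-length estimates clamped to zero), rooted on a
user-specified outgroup (`root_on_outgroup()`).  `mrca_node()` and
`select_closest_reference()` implement the reference-genome rule used for
pairwise comparisons: walk from the query leaf rootwards to the first
ancestor whose clade contains a reference; among several references in
that clade, take the one attaching most basally (fewest edges from the
ancestor), breaking remaining ties lexicographically.

## ANI, POCP and taxonomic novelty

`compute_ani()` follows the classical fragment convention: the query
genome is cut into consecutive 1,020-bp fragments, each locally aligned
to the subject; fragments are retained when identity is at least 30% over
an alignment covering at least 70% of the fragment, and ANI is the mean
identity of retained fragments (averaged over both directions).  When
nothing survives the filter the result is undefined (`NA`), never 0 —
unrelated genomes have no meaningful ANI.

`compute_pocp()` counts a protein as conserved when it has a hit in the
other proteome with E-value < 1e−5, identity ≥ 40% and an aligned region
covering ≥ 50% of the query, and reports
`((C1/T1) + (C2/T2))/2 × 100`.

`classify_novelty()` applies the conventional thresholds: POCP < 50
indicates a genome from an unrepresented family; POCP > 50 with ANI < 95
(or undefined) an unrepresented species within a represented family;
POCP > 50 with ANI > 95 a represented species.  The published rules are
strict inequalities on both sides, so exact boundary values are assigned
to the less-novel class with a warning rather than silently.

Alignments use Smith–Waterman (local) or Needleman–Wunsch (global)
dynamic programming via Biostrings, with E-values from the
Karlin–Altschul form `K·m·n·exp(−lambda·S)` over the explicit search
space `m·n`.  Protein mode uses BLOSUM62 with the published gapped
constants (lambda = 0.267, K = 0.041); nucleotide mode uses unit scores
with the exact ungapped lambda = ln 3 for +1/−1 under uniform base
composition and K = 0.34.  The E-values are monotone and correctly
scaled, which is what the thresholds need; bit-level parity with any
particular search engine is a non-goal.

## Lateral-transfer calling

`call_ltg()` implements best-hit taxonomy screening: for each gene,
self-genome hits are removed and the ranked hit list is compared with the
recipient's lineage at a configurable rank (phylum by default — the rank
is a parameter because published descriptions of the rule name several
ranks without fixing one).  The default, conjunctive, reading requires
(i) the best hit to lie outside the lineage and (ii) every within-lineage
hit to score below 90% of the best bit score; this matches the clause
"but with lower-scoring hits or no hits within the lineage" and is the
stricter, more defensible default.  The disjunctive reading — any outside
hit within the 90% band of the best, with the best within-lineage hit
strictly below the best overall — is available as `rule = "or"`.  A tie
at the top spanning inside and outside the lineage yields no call;
unknown-lineage hits are excluded from the evaluation.  Donors are
summarized by domain and phylum (`donor_summary()`), including the
cross-domain fraction, and calls can be profiled by COG category.

## Similarity networks

`build_ssn()` keeps an undirected edge when E ≤ 1e−5 and identity ≥ 35%,
merging reciprocal duplicates onto the better E-value; every input
sequence remains a node, so singletons survive.  `collapse_metanodes()`
consolidates sequences sharing more than 90% identity — strictly greater
than, following the usual wording — into metanodes by transitive closure
(union–find).  Transitive closure means single-linkage chaining: a 95%
and a 92% edge merge three sequences even if the outer pair is below the
threshold; this is the representative-node convention of the standard SSN
tools and is stated here because it is occasionally surprising.
Inter-metanode edges inherit the best underlying edge.  `graph_stats()`
reports components, degrees and maximal-degree hub nodes; interpreting a
hub cluster as ancestral is an interpretive claim the package does not
automate.

## Primer mismatch screening

`scan_primer()` slides a degenerate primer without indels along both
strands of a target, counting a mismatch at each position whose IUPAC
code shares no base with the target's code (so R over A matches, and
degenerate target codes are compatible when the expansion sets
intersect).  The minimum-mismatch placement is reported, ties broken
leftmost with the plus strand first.  Ungapped counting is the
conventional model of primer–template annealing; gapped alignment would
trade that convention for alignment-engine details without changing the
question being asked.  `mismatch_matrix()` tabulates the minima for a
primer panel against a set of 16S-like sequences and is validated both
against planted fixtures and against an independent naive scanner.

## The synthetic-data generator

Real genome collections of this kind cannot be bundled or downloaded at
test time, so `simulate_dataset()` builds collections with known ground
truth:

* `simulate_tree()` draws a rooted binary tree with exponential branch
  lengths (mean 0.1), leaves `G1...Gn`.
* `evolve_gene_content()` starts from `root_family_count` families and,
  on every branch, loses each inherited family with probability
  `loss_prob` and gains Poisson(`gain_rate`) novel single-origin
  families.  Single origin means the histories are Dollo-compatible by
  construction, which gives the reconstruction stage a clean, exactly
  recoverable target.  The defaults (200 root families, loss 0.25/branch,
  gains 0.5/branch) describe a loss-dominant regime, the qualitative
  signature of streamlined symbiont genomes.
* `emit_sequences()` evolves one prototype protein per family down the
  tree, substituting each site on a branch of length `t` with probability
  `1 − exp(−(mutation_rate/0.1)·t)` — i.e. `mutation_rate` (default
  0.05) is the expected per-site substitution probability on a branch of
  mean length.  Genome nucleotide sequences are deterministic
  back-translations (one fixed codon per residue) joined by 50 nt of
  random spacer.
* `inject_lgt()` copies donor genes verbatim into recipient proteomes
  and records the donor lineages; `generate_primer_fixture()` plants
  primer-binding sites with known mismatch counts (0–5), including
  degenerate positions and one reverse-complement case, and certifies
  every planted count as the global two-strand minimum with an
  independent naive scan before returning.

Everything is seeded; a fixed seed fixes every output byte, which the
tests assert.

What the generator does **not** emulate — and hence what green tests do
not show about real data: genome incompleteness and contamination (every
absence is a true absence), realistic codon usage and GC structure
(back-translation is deterministic), rate heterogeneity across sites and
genes, paralogy and convergent family re-gain, and database-scale
taxonomic breadth for the LGT search.  Results on real collections
inherit all the corresponding caveats.

## Problem sizes, numerics and known limitations

The suite runs at desk scale by choice: topology-recovery experiments use
8 leaves with 500 root families (~75k residues of proteome per genome,
matching the problem size of the gain/loss recovery simulations),
gain/loss recovery uses 10 leaves and 500 families, exhaustive oracles
cover all rooted topologies with ≤ 6 leaves, and alignment-based stages
(POCP, ANI, hit emulation) use proteomes of a few dozen genes and genomes
of a few kilobases, since all-vs-all dynamic programming is quadratic.
The pipeline wrapper exposes `hit_genes_per_genome` and `ani_max_bases`
as explicit desk-scale guards.

Numerical conventions: tie-breaks are lexicographic everywhere;
floating-point comparisons use a 1e−12 tolerance; negative NJ branch
estimates are clamped to zero; matrices are validated strictly (0/1
entries, no all-zero family columns, unique ids); boundary inputs
(POCP = 50, ANI = 95, `gamma` = 0 or ≥ 1) are resolved as described
above, with warnings where the published rules are silent.

One limitation is worth stating plainly: with exponential branch lengths
of mean 0.1, a sizeable minority of random 8-leaf trees contain an
internal branch shorter than ~0.01 — under the default mutation scaling,
fewer than ~0.5% expected substitutions per site.  Composition-vector
cosine distances at desk-scale proteome sizes cannot reliably resolve
such branches, so neighbor joining occasionally misplaces exactly one
split.  The acceptance suite measures this recovery rate honestly rather
than hiding hard replicates; on exactly additive distance matrices (the
regime where NJ carries a consistency guarantee) recovery is exact in
every tested case.

## Interface notes

The package is a library: the exported functions, `run_pipeline()` (which
executes the full synthetic demonstration and writes a checksummed
manifest), and `validate_config()` (which returns precondition violations
as data) are the interface, and this vignette plus the README are the
usage documentation.  Genome ids are recovered from gene ids by a
configurable delimiter rule (substring before the first `|` by default),
because BLAST-style tabular hits carry no genome column.  Lineage strings
accept GTDB-style `x__` prefixes or bare positional names, with explicit
gaps; all coordinates in reports are 1-based inclusive.
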