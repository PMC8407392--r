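# panarch

Comparative-genomics toolkit for collections of small, streamlined
prokaryotic genomes — the regime of nanosized, mostly host-associated
archaea, where gene loss dominates evolution, the shared core genome
collapses after a handful of genomes, and lateral gene transfer supplies
much of the remaining metabolic flexibility.

It is written for researchers who have a set of genomes (or metagenome-
assembled genomes) with predicted proteomes and want the standard
battery of desk-scale comparative analyses under one roof, with every
stage testable against simulated ground truth:

* **Pan/core-genome openness.** Permutation-based accumulation curves
  (default 300 random genome orderings) fitted with the Heaps-law power
  model `Ps(n) = κ·n^γ` and the exponential core decay
  `Fc(n) = κc·e^(−r·n)`. A pan-genome is *open* when `γ ∈ (0, 1)` — the
  closer to 1, the more open — and *closed* when `γ ≤ 0`;
  `core_extinction_point()` reports the `n` at which the fitted core
  drops below one family.
* **Dollo-parsimony gain/loss reconstruction.** Each gene family
  originates once (at the MRCA of its carriers) and may only be lost
  afterwards; losses land on the minimal branch set excising every
  absence subtree. Per-branch event counts, ancestral content sizes and
  COG-category profiles of gains and losses.
* **Alignment-free phylogeny.** Composition vectors at `k = 4`:
  k-mer frequencies with the (k−2)-order Markov background subtracted,
  component `(f − q)/q`, cosine dissimilarity `D = (1 − C)/2`,
  neighbor-joining trees, outgroup rooting, MRCA queries and the
  closest-reference-by-MRCA selection rule.
* **ANI / POCP / taxonomic novelty.** Fragment-based average nucleotide
  identity, percentage of conserved proteins
  `((C1/T1)+(C2/T2))/2×100`, and the conventional novelty rules
  (POCP < 50 → unrepresented family; POCP > 50 with ANI < 95 →
  unrepresented species; both high → represented species).
* **Lateral-transfer calling.** Best-hit taxonomy: a gene is called when
  its best hit lies outside the recipient's lineage at a chosen rank and
  every within-lineage hit scores below 90% of the best bit score, with
  donor and cross-domain summaries.
* **Sequence similarity networks.** Edge thresholds E ≤ 1e−5 and
  identity ≥ 35%, with >90%-identity transitive metanode collapsing and
  component/degree/hub statistics.
* **Degenerate-primer screening.** Ungapped two-strand scanning of IUPAC
  primers over 16S-like sequences, reporting minimal mismatch counts.
* **A seeded simulator** that evolves gene-family content and protein
  sequences on known trees, injects lateral transfers with known donors,
  and plants primer-binding sites with certified mismatch counts — the
  ground truth every downstream stage is validated against.

## Worked example

Simulate an open collection, fit the pan/core models, and reconstruct
gain/loss events on the known tree:

```r
library(panarch)

cfg     <- sim_config(n_leaves = 8, seed = 7, root_family_count = 100,
                      gain_rate = 5, loss_prob = 0.2)
tree    <- simulate_tree(cfg)
content <- evolve_gene_content(tree, cfg)

curves <- permutation_curves(content$matrix, n_permutations = 300, seed = 7)
fit    <- fit_power_law(curves)
sprintf("kappa = %.3f, gamma = %.3f -> %s pan-genome",
        fit$kappa, fit$gamma, classify_openness(fit))
#> "kappa = 66.914, gamma = 0.483 -> open pan-genome"

core_fit <- fit_exponential(curves)
sprintf("core: kappa_c = %.1f, rate = %.3f, extinct at n = %d",
        core_fit$kappa_c, core_fit$rate, core_extinction_point(core_fit))
#> "core: kappa_c = 64.2, rate = 0.373, extinct at n = 12"

recon <- dollo_reconstruct(tree, content$matrix)
attr(branch_event_counts(recon), "totals")[c("novel_gains", "losses")]
#> novel_gains      losses
#>         114         135

gainloss_recovery_report(recon, content$truth)$gain_observable_match
#> [1] 1
```

Read: with five novel families gained per branch and 20% loss per
branch, each added genome still contributes new families (`γ ≈ 0.48`,
open), the core decays at rate 0.37 per genome and would vanish after
about a dozen genomes, and the Dollo reconstruction places every
family's gain exactly at the most recent common ancestor of its
surviving carriers (100% agreement with the simulation truth).

`run_pipeline(pipeline_config(), out_dir)` chains all stages —
simulation, clustering/curves, composition-vector NJ tree, gain/loss,
ANI/POCP, LGT calls, SSN, primer screen — and writes every stage's
outputs plus a checksummed `manifest.tsv`; rerunning with the same seed
reproduces every byte.

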