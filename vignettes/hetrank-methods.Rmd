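---
title: "Network-informed gene ranking for heterogeneous monogenic disease: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-informed gene ranking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetrank)
```

## The problem

Exome-sequencing studies of rare monogenic disease usually look for a gene in
which several unrelated affected individuals carry a plausible variant
("intersection filtering"). Under genetic (locus) heterogeneity — different
genes causing the same disease in different patients — the overlap that this
strategy relies on disappears. The premise of this package is that genes
causing the same disease are frequently direct neighbors in protein
interaction networks, so evidence observed in *different* genes of the same
network neighborhood, in *different* patients, can be pooled. The ranking
proceeds in four phases per study of $N$ affected individuals.

## The model

**Phase 1 — variant scoring.** Within each exome, every variant is ranked on
each of $m$ user-declared criteria (allele frequencies, effect class,
optionally any deleteriousness score), with average ranks for ties and
reference tables for ordered categorical criteria. A rank $r$ is mapped to a
score by a scaled reciprocal,

$$\mathrm{score}(r) = \min\!\Big(1,\; \frac{\max(r_\mathrm{top},\, r_F/2)}{r}\Big),$$

where $r_\mathrm{top}$ is the (average) rank of the joint best tier and $r_F$
is the *phantom rank* of the criterion's filter-equivalent value — the rank a
hypothetical variant carrying exactly the hard-filter threshold would
receive if inserted into the exome (it is discarded afterwards and never
perturbs real ranks). This form has the three properties the transform must
have: reciprocal decay (so weak evidence is not over-weighted), every member
of the joint top tier scores exactly 1, and every variant ranking at or
better than the filter-equivalent value scores at least 0.5. When no
filter-equivalent value is declared the scale is simply $r_\mathrm{top}$.
The transform is isolated in `rank_to_score()` so alternative profiles can
be swapped in. Note one consequence of the three constraints jointly: when
$r_F < 2\,r_\mathrm{top}$ the top-tier rule dominates and scores can stay at
or above 0.5 slightly beyond $r_F$; the "at least 0.5 above the threshold"
guarantee is one-directional by construction.

A variant's total is the sum of its $m$ per-criterion scores. Gene scores
then depend on the assumed inheritance: **AD** takes the best heterozygous
variant total (homozygotes are ignored); **AR** takes the larger of the best
homozygous total and half the sum of the top two heterozygous totals
(compound heterozygosity; a lone heterozygous variant contributes half its
total); **neutral** takes the best total regardless of zygosity. Every gene
score lies in $[0, m]$, with absence of variants meaning score 0.

**Phase 2 — control penalty.** Long and variant-tolerating genes score well
in everyone. With $K$ = the number of control exomes in which gene $g$
scores at least as well as in the case ($\ge$, ties counting), the score is
deflated to $S'_g = S_g/(1+K)$. Scores are compared after rounding to 12
decimal places so tie counting is platform-stable. With no controls the
phase is the identity.

**Phase 3 — network sharing.** For gene $g$, the $d$-neighborhood
$N_d(g)$ is everything within $d$ interactions (including $g$). Let $S'_h$
be the best phase-2 score in $N_d(g)$. The neighborhood may propose
$S_g(d) = S'_h/(1+d)$ — penalized because the evidence is indirect — but
only if that score is unlikely to be matched by chance: with $t$ genes in
the network at score $\ge S'_h$ out of $n$ network genes, the probability
that $|N_d(g)|$ randomly chosen network genes contain one is the
hypergeometric tail

$$p = 1 - \binom{n-t}{|N_d(g)|}\Big/\binom{n}{|N_d(g)|},$$

computed exactly in log space (`chance_probability()`). If $p \ge 0.1$
(configurable) nothing is proposed, which is what protects against hub
genes: a hub's huge neighborhood makes good neighbors likely by chance, so
its gate rarely opens. The final score is
$S''_g = \max(S'_g,\, S_g(1),\, S_g(2))$; $d$ is capped at 2 (configurable
down to 0, which disables the phase). The score pool is taken per exome over
all network genes, with non-mutated network genes at 0; genes outside the
network keep $S'_g$ unchanged, so the method still ranks genes the network
does not cover.

**Phase 4 — aggregation.** $S''_g$ is summed over the $N$ cases; final
scores lie in $[0, m \times N]$ and genes are ranked by descending score
with average ties.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `neighborhood_p_threshold` | 0.1 | chance-probability gate for phase 3; smaller = more conservative sharing |
| `max_d` | 2 | how far scores travel in the network (0 disables phase 3) |
| `control_count_threshold` | 5 | baseline ranker: genes with post-filter variants in this many controls are excluded |
| `default_rank` | 10,000 | rank assigned to genes absent from a ranking |
| `filter_equivalent` (per criterion) | 0.001 for allele frequencies, protein-altering for effect | hard-filter threshold reused as the score-0.5 anchor |
| `missing_policy` (per criterion) | `"worst"` | missing annotations tie at the bottom, so absent evidence never looks like strong evidence |

## The intersection-filtering baseline

The comparator ranker drops variants failing any filter-equivalent
threshold, applies the zygosity rule of the mode (AD: no homozygotes; AR: a
gene needs one homozygote or two heterozygotes), excludes genes with
post-filter variants in five or more control exomes, and ranks genes by the
number of case gene lists containing them (average ties), everything else
at rank 10,000. Control gene lists use the variant-level filters only; the
AR two-variant gene rule is applied to case lists. The exclusion step is
monotone in the control threshold, which the tests assert.

## Disease-subnetwork permutation analysis

To motivate the network assumption on a user's own disease-gene table, the
package counts *disease subnetworks*: connected sets of $\ge 2$ genes, all
causal for the same generalized disease term, in the interaction network.
Disease terms are generalized by a table-driven tokenizer (drop "type"/
"group" and the following token, drop purely numeric or roman-numeral
tokens); the stop-token list is configurable because curated nomenclature
conventions vary. Counts per size class (2 / 3 / 4 / 5+) are compared
against permuted networks. Two nulls are provided, and the output labels
which was used:

* `node_label` — uniformly random relabeling; preserves topology exactly.
* `degree_constrained` — labels shuffled only within degree bins on a log2
  grid, so each disease gene lands on a node of comparable degree. This
  conditions on the number *and degree distribution* of disease genes,
  countering the bias of curated networks toward well-studied genes. Bins
  holding a single node keep their label fixed (logged).
* `rewire` — an alternative null that randomizes edges by degree-preserving
  double-edge swaps rather than moving labels.

The one-sided p-value uses the +1 correction,
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(1 + B)$, so with
$B = 10{,}000$ the smallest representable value is $10^{-4}$. The
permutation statistic is discrete, so the reported p-value is conservative
under ties; the calibration test therefore checks uniformity of the
*randomized* p-value, which is the standard way to remove that discreteness.

## The study simulator

The spike-in simulator emulates a benchmark of simulated exome studies
without any patient data. What it reproduces:

* **Background exomes** from a fixed synthetic gene universe (default 4,000
  genes over 22 autosomes — sex chromosomes are excluded since the modeled
  modes are autosomal). Per gene, variant counts are Poisson with a
  gene-specific intensity whose heavy tail (2% of genes at 10× intensity)
  models long/variant-tolerating genes, giving the control penalty real
  signal. Variants draw a frequency class (novel 5% — frequency exactly 0 —
  rare 12%, common 83%), two allele-frequency criteria correlated through a
  shared base frequency with log-normal noise, an effect class (2%
  truncating/splicing, 48% protein-altering, 50% synonymous), and a
  zygosity (homozygous with probability 0.30 for common, 0.05 for rare
  variants). These constants live in `background_model()`, not in code
  paths. They were chosen once so that a typical exome carries a few
  hundred rare protein-altering variants and roughly ten genes pass the
  recessive baseline filter — the regime in which recessive-mode analyses
  are easier than dominant ones because plausible recessive candidates are
  scarce.
* **Recombination**: study exomes are novel chromosome-wise recombinations
  of a larger pool (each chromosome block drawn without replacement across
  outputs), and cases and controls are disjoint recombinants — no sequence
  data is shared.
* **Spiking**: each case receives a disease-causing mutation. The gene is
  drawn from a planted disease subnetwork with probability $1-u$ (captured
  heterogeneity; balanced, or unbalanced with probabilities $3(1-u)/4,
  (1-u)/4$ for two genes, $(1-u)/2, (1-u)/4, (1-u)/4$ for three, and
  $(1-u)/2, (1-u)/6, (1-u)/6, (1-u)/6$ for four), or uniformly from the
  rest of the exome with probability $u$ (uncaptured heterogeneity). In AR
  mode the spike is, with probability 0.9, equally likely a homozygous
  variant or a compound heterozygote (two heterozygous variants in the same
  gene), otherwise a single heterozygous variant; AD mode switches the 0.9
  and 0.1. The pathogenic annotation templates are synthetic: frequency 0
  with probability 0.8 (otherwise below 0.001) and truncating or
  protein-altering effect with equal probability.
* **Coverage mismatch**: disease subnetworks can be drawn from a denser
  network than the one used for ranking (`drop_edges()` thins the ranking
  network), emulating low network coverage of the true interactions.

What it does **not** emulate: read-level sequencing error, linkage
disequilibrium and realistic site-frequency spectra, population structure,
annotation pipeline artifacts, or the empirical annotation distributions of
real patient exomes. Passing benchmark tests therefore demonstrates the
*mechanism* — that network sharing of variant evidence recovers
heterogeneous disease genes that per-gene overlap misses — not performance
figures transferable to any particular cohort.

## Numerical choices and degenerate inputs

* All rankings use average-tie ranks; descending for scores, ascending for
  variant keys. Score comparisons that count ties (phases 2 and 3) round to
  12 decimals first.
* The hypergeometric tail is computed via `lchoose` differences in log
  space; `t = 0` returns exactly 0 and `k > n - t` exactly 1.
* Ties for a neighborhood's best score do not matter for the adjustment
  (only the score is used); the audit trail records the lexicographically
  smallest holder for reproducibility.
* Empty exomes, empty networks, zero controls, and genes absent from the
  network all reduce to well-defined identities (no variants = no
  evidence = score 0; empty network or `max_d = 0` = phases 1–2 only;
  zero controls = phase 2 identity), and the tests pin these down.
* Every stochastic entry point takes a seed; equal seeds give byte-identical
  outputs.

## Desk-scale test sizes

The shipped tests and the reproduction script run the benchmark at reduced
scale — 50 replicates of 20 cases / 60 controls over a 4,000-gene universe
with a 600-node scale-free ranking network, and permutation analyses with
500–1,000 permutations — sizes chosen so the whole suite runs on a laptop
in minutes while leaving the qualitative contrasts (network vs no network
vs hard filtering; planted vs random disease genes) clearly resolved.

## Known limitations

* The generalized-term tokenizer is heuristic; nomenclatures that encode
  subtypes differently (suffix letters, Greek letters) need a custom
  stop-token list.
* Hemizygosity is not modeled: X/Y zygosity is taken at face value, and the
  simulator is autosomal.
* The method assumes heterogeneity is at least partly explained by direct
  or distance-2 interactions; if it is not, phase 3 adds nothing (by
  design, it can never *lower* a gene's score below $S'_g$).
* Identifier mapping is out of scope: gene symbols are matched exactly
  (after whitespace trimming), so the variant tables and the network must
  share a symbol convention.
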