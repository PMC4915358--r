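---
title: "Locating and comparing gene duplications by reconciliation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating and comparing gene duplications by reconciliation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genedup)
```

# The problem

When a complex trait evolves independently in two related lineages — the
motivating case is the two origins of C4 photosynthesis among the grasses,
one in the Andropogoneae (maize, sorghum) and one in the Paniceae (foxtail
and switchgrass millets) — a natural question is whether the *same* genes
were duplicated and retained in parallel in both lineages.  `genedup`
answers it in four steps:

1. map every duplication in a set of gene trees onto a branch of the
   species tree (reconciliation);
2. keep only duplications with credible, persistent signal (retention
   filters);
3. compare the duplications on the two focal branches, at orthogroup and
   at single-ortholog ("same gene") resolution, with a hypergeometric
   overlap test;
4. relate duplicate cohorts to cell-type expression: bundle-sheath (BS)
   versus mesophyll (M) preference, expression-dominance concordance
   across species, and ontology-term enrichment.

A birth–death gene-family simulator with fully labelled ground truth makes
every step testable end to end.

# Reconciliation model

Input gene trees are rooted and binary; each leaf maps to a species through
an explicit two-column table (no identifier-prefix guessing).  The
reconciliation is classical duplication–loss parsimony: each gene-tree node
`v` receives the species-tree node

$$M(v) = \mathrm{LCA}_S\bigl(M(\mathrm{left}(v)),\,M(\mathrm{right}(v))\bigr),$$

computed in a single post-order pass, and `v` is a **duplication** iff
`M(v)` equals the mapping of at least one child.  The event is assigned to
the species-tree branch whose lower node is `M(v)`; a branch is identified
throughout by the sorted, comma-joined set of species below it
(`"Sbicolor,Zmays"`).  Implied losses on the gene-tree edge from `v` to a
child `c` number `d − 1` for a speciation and `d` for a duplication, where
`d` counts species-tree edges from `M(v)` down to `M(c)`.

Two remarks on fidelity.  First, joint likelihood methods that co-estimate
gene trees and reconciliations can resolve discordant nodes differently
from parsimony applied to fixed trees; parsimony is used here because it is
deterministic, cheap, and exactly testable against brute-force oracles.
This is the main caveat when comparing event counts with analyses built on
probabilistic reconciliation.  Second, species LCA queries are answered by
a parent-pointer walk rather than constant-time preprocessing: with a
handful of species the tree height is tiny and correctness, not asymptotic
complexity, is the contract.

For unrooted input trees, `root_by_cost()` scores every edge as a root
position by `w_dup · duplications + w_loss · losses` (default weights 1, 1)
and returns the minimum.  Ties are broken by smaller duplication count,
then by the lexicographically smallest leaf label of the root clade not
containing the overall smallest leaf, then by input edge order — a fully
deterministic convention, chosen because any rule serves as long as it is
reproducible.

# Retention filters

Two criteria, applied per event:

* **Criterion 1 (evidence).** At least `min_evidence_species` (default 2)
  species must each retain a gene in *both* paralog clades.  A species
  witnesses a duplication only through both copies; under this reading
  every terminal-branch (species-specific) event fails, which is exactly
  the behaviour reported for the published genome-wide screen this package
  operationalizes.  The threshold is configurable so the alternative
  single-witness reading stays testable.
* **Criterion 2 (full retention).** Every species descending from the
  event's branch must retain at least one gene in each clade — the
  duplication survived fractionation in all descendant genomes.

On internal branches criterion 2 implies criterion 1 whenever the branch
has at least two descendant species; the filter chain
`retained ⊆ criterion‑1 ⊆ all` is asserted property-style on simulated
catalogs.  Events mapped to the species-tree root are reported and
flagged: "species that diverged after the duplication" is then every
species, and the root is not a branch proper.

# Parallel duplications and the overlap test

Given two focal branches (neither ancestral to the other), the orthogroups
carrying at least one retained event on each branch are counted as `K` and
`n`, their intersection as `k`.  Under the null that the two sets fall
independently across the `N`-orthogroup universe, `k` is hypergeometric
with expectation `nK/N`; the reported p-value is the upper tail
`P(X ≥ k)`, evaluated in log space (`stats::phyper(log.p = TRUE)`) so that
tails at the `1e-21` scale are exact.

The universe `N` defaults to the orthogroups in which a duplication on both
branches is observable — those containing at least one gene from at least
one species of each focal clade — plus, unconditionally, every orthogroup
that does carry a focal-branch event (post-duplication losses can empty the
other clade).  `universe = "all"` switches to all orthogroups; with the
published counts (225 and 381 orthogroups in a universe of 13,773) the
expectation is 6.2 either way, and the choice is logged with the result.

Orthogroup-level overlap is necessary but not sufficient for "the same
gene duplicated twice": the two duplications may sit in paralogous
subtrees created by an older duplication.  `same_gene_parallel()` declares
two duplication nodes parallel duplications of one ortholog iff every
internal node strictly between them on the gene-tree path — their LCA
included, the endpoints excluded — is a speciation, and `FALSE` when one
node is ancestral to the other.  Qualifying pairs are deduplicated per
ancestral lineage (the pair's gene-tree LCA), so several duplications on
one branch within one orthologous lineage count once at gene level,
matching the convention under which two parallel events in one orthogroup
comprise four duplications.

# Expression statistics

**Cell preference.** The published screen derived BS/M calls from a
negative-binomial count model on raw reads; this package consumes TPM
tables and uses Welch's t on `log2(TPM + 1)` (3 BS vs 3 M replicates in
the simulated conditions), BH-corrected, with a fold-change ≥ 2 gate and
α = 0.05 — all configurable, and precomputed calls can be supplied
instead.  Genes below 1 TPM in both conditions are not tested.  Two
degenerate conventions matter: zero-variance groups with differing means
get p = 0 (the noiseless limit, which makes σ = 0 simulations recover
planted calls exactly), and with equal means p = 1.

**Cohort enrichment.** Whether duplicate cohorts are enriched for BS- or
M-preferential genes is tested against the background proportion among all
classified genes with a two-sided exact binomial p (doubling of the
smaller tail, clipped at 1); a degenerate background proportion of 0 or 1
collapses the p-value to 0/1 and is flagged in the output.  The exact test
on a discrete statistic is conservative, which the calibration tests
confirm.

**Dominance concordance.** For retained duplications on a branch ancestral
to two species with whole-leaf expression data, each paralog clade is
represented per species by its most highly expressed member gene
(mean TPM over `"leaf"` samples).  An event is assessed only when the
higher representative exceeds 10 TPM in *each* species — the published
inclusion rule, kept separate from the 1 TPM classification floor.  The
wording of that rule is ambiguous between per-representative and per-gene
thresholds; the per-representative reading is implemented and flagged
here.  Exact representative ties are excluded rather than split
(determinism; measure zero under continuous noise).  The concordance
percentage is `100 · n_concordant / n_assessed`.

**Term enrichment.** Standard hypergeometric over-representation of
annotation terms in an orthogroup set against a universe, BH-corrected at
FDR 0.05.

# The simulator and what it does (not) emulate

`simulate_forest()` runs a top-down duplication–loss birth–death process:
one ancestral gene enters at the root, each extant copy duplicates at rate
λ and dies at rate μ per unit branch length (exponential waiting times),
and copies bifurcate at speciations.  Only surviving lineages are emitted;
the truth table records every duplication with surviving descendants on
both sides, keyed by branch and descendant clades.  Defaults are the study
conditions: the seven-taxon monocot tree (six named grasses plus *Musa
acuminata* as a documented placeholder outgroup — the published species
list names only six of its seven monocots), unit branch lengths, and
λ = 1/16 so that, over the tree's total length of 16, about one event
survives per orthogroup; μ = 0.02 adds modest fractionation.  With μ = 0,
LCA reconciliation recovers the planted events *exactly* (count, branch,
clades) — the identifiability property the oracle tests exploit; with
losses, parsimony and truth may legitimately differ, so tests compare
against oracles, not truth.

Planted structure is injected by construction, not rejection sampling:
same-gene parallels force one duplication at the top of each focal branch
within a single ancestral lineage; orthogroup-level-only parallels first
force an ancestral duplication at the root and then one focal event inside
each root copy, so the two events are paralogous by construction; a
planted ancestral cohort forces one event on a chosen branch.  Planted
orthogroups run with the background process off (λ = μ = 0 within them) so
planted truth counts are exact.

Expression is simulated at TPM level: per-gene log-normal baselines
(meanlog `log 20`, sdlog 1), an exact-count fraction `f = 0.3` of genes
made BS-preferential by multiplying the BS mean 16-fold, multiplicative
log-normal replicate noise σ = 0.25, and, for every true event on the
dominance branch (default: the pre-Poaceae branch, assessed in the
*O. sativa*/*Z. mays* pair), clade dominance planted concordantly with
probability c = 0.74 at 200 vs 20 TPM — the published 893/1210 regime.
The σ default is backed by a noncentral-t power computation: for 3-vs-3
Welch with df ≈ 4, a 16-fold effect and σ = 0.25 give > 99.9 % power at
BH-scale thresholds, so parameter-recovery checks measure bookkeeping
rather than test power (at σ = 0.4 the same computation gives ~89 % power,
which would confound recovery with classifier misses).

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: sequence evolution and gene-tree estimation
error (trees are emitted true), whole-genome-duplication block structure
and rate heterogeneity across families, count-level expression noise
(TPM-level log-normal only), correlated expression between paralogs, and
any biological linkage between duplication and expression status.

# Numerical and design choices

* p-values are computed and reported in log10 alongside the linear scale;
  no truncation at machine epsilon.
* BH adjustment is the standard step-up (`stats::p.adjust`); its output is
  rank-monotone and capped but — contrary to a tempting intuition — *not*
  idempotent, so no such property is asserted.
* Fold change is the plain ratio of mean TPM (10 for BS 100 vs M 10);
  division by a zero mean yields `Inf`, which orders correctly in the
  gate.
* Polytomous gene trees are rejected by default; silent resolution changes
  duplication counts.  An explicit `"resolve"` policy applies
  deterministic left-to-right resolution and records the affected
  orthogroups.
* All randomness flows from a single integer seed; identical seeds give
  byte-identical forests, expression tables, and pipeline outputs.

Problem sizes used by the validation suite — chosen as comfortable
desk-scale analogues of the published scales — are: 500 random
reconciliations (≤ 32 leaves) and 200 exhaustive rooting enumerations
(≤ 12 leaves) against brute-force oracles; 200 loss-free forests of 10
orthogroups for exact truth recovery; complete hypergeometric enumeration
to N = 12 plus the published-scale tail; 500 null and 200 powered overlap
replicates; preference-fraction recovery pooled over ~5,700 genes and
concordance recovery at the published n = 1,210; 10,000 random vectors for
the BH oracle.

# Known limitations

Parsimony reconciliation on fixed gene trees is the main fidelity caveat
versus joint probabilistic inference.  The package does not infer
orthogroups, alignments or gene trees, does not model transfers or
incomplete lineage sorting, and analyzes exactly one focal branch pair per
run.  Published headline counts from the motivating genome-wide screen
depend on proteome versions and a likelihood reconciler and are not
reproducible at desk scale; the validation strategy is therefore
property-based (oracles, planted truth, calibration) plus the published
arithmetic identities, which the acceptance script recomputes.
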