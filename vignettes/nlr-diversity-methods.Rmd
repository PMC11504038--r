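---
title: "Methods: NLR gene-family diversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NLR gene-family diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlrdiversity)
```

## The problem

Plant genomes carry large, fast-evolving families of NLR
(nucleotide-binding leucine-rich repeat) resistance genes. Questions
about such a family — how its members partition into the canonical TNL,
CNL, RNL and NL architectures, and how duplication, horizontal transfer
and recombination generated the copy-number differences seen between
related genomes — are usually answered with a chain of ad hoc scripts
around HMMER, BLAST, tree builders, RDP and PAML. This package makes
that chain a tested pipeline. Heavy external tools are deliberately
*upstream*: their tabular outputs (domain tables, BLAST hits, gene
trees, per-method p-values, codeml log-likelihoods and BEB sites) are
the package's inputs.

## Classification

An NLR is gated on the NB-ARC nucleotide-binding domain; the N-terminal
domain then decides the class:

* TIR present → **TNL**
* else RPW8 present → **RNL**
* else Rx_N present → **CNL** (Rx_N is the four-helix bundle annotated
  where older studies annotated a coiled-coil motif, so Rx_N–NBS–LRR is
  the CNL architecture)
* else → **NL** (NBS-only and NBS–LRR proteins alike; LRR presence is
  recorded but never changes the class)
* no NB-ARC → **NOT_NLR**

Proteins carrying more than one N-terminal domain are rare and not
covered by the published rule, so the package fixes the precedence
TIR > RPW8 > Rx_N — this keeps the classification a total, deterministic
partition — and flags such proteins (`dual_domain`) so they can be
inspected. `classify_architecture()` is verified in the test suite
against an exhaustive 32-case truth table.

## The phylogenetic screen

The published screen keeps an NB-ARC candidate when it forms a
monophyletic group with plant R proteins and discards it when it groups
with non-plant homologs. "Forms a monophyletic group with" needs an
operational definition; `filter_by_phylogeny()` uses the smallest
enclosing reference clade: walk from the candidate toward the root until
the clade contains at least one reference leaf (`plant_R` or
`non_plant`); retain the candidate iff that clade contains no
`non_plant` reference. This is the strictest reading — a mixed nearest
context excludes. A permissive mode (retain if *any* enclosing clade is
purely candidates + plant R with at least one reference) is available
behind a flag for sensitivity analysis. Outgroup leaves (e.g. MalT and
SWACOS domain proteins) carry the label `outgroup` and are neutral in
both modes.

## Event calling from species-labeled gene trees

Both callers operate on *maximal single-species clades*: clades whose
leaves all belong to one species and whose parent clade does not.

**Duplication.** Genes of one species forming a monophyletic group are
duplication-derived. Published tallies rarely state whether a clade of
*n* genes counts as one event or *n − 1*; the package reports both
granularities, with `node_count` (each bifurcation inside the clade is
one duplication) as the default and `per_clade` available. On simulated
families without loss or transfer, the `node_count` tally equals, per
species, the number of true duplications that occurred on terminal
species branches — the test suite asserts this exactly over 100
replicates.

**Horizontal transfer.** "The genetic diversity of one species falls
within that of another" is read as nesting: for a maximal single-species
clade (putative recipient A), walk `context_depth` consecutive enclosing
clades; if each step adds genes of one and the same other species B, an
event B → A is called. The default `context_depth = 2` demands
two-sided nesting — sisterhood alone (depth 1) would also fire on plain
species-tree-concordant cherries, which is why the default is 2.
Direction follows the topology: the enclosing, rendered-paraphyletic
species donates; the nested clade receives. Raising `context_depth`
never adds events (monotone specificity, property-tested). Node-support
filtering (`min_support`) is off by default since the published rule
states none; a `min_recipient_size` flag can require the transferred
gene to have duplicated in the recipient. A duplication clade inside an
HGT recipient clade is counted by both callers — transfer followed by
duplication — since the two tallies are independent.

Trees must arrive rooted; unrooted inputs should be rooted by the user
(e.g. midpoint) before calling, and `read_newick_tree()` never re-roots
silently.

## Recombination

**MaxChi.** `maxchi_test()` implements a pairwise maximum chi-square
scan. The scan is restricted to the polymorphic columns of the
alignment (the classical variable-site restriction); columns where
either member of the tested pair has a gap or `N` are dropped pairwise,
not alignment-wide. Each remaining site is a match or a mismatch for
the pair; at each partition point a 2×2 chi-square (no continuity
correction) contrasts match/mismatch counts in the `half_window` sites
on either side, and the maximum over partition points is the statistic.
Under the no-recombination null the site order is exchangeable, so the
p-value is estimated by site-order permutation with the add-one
estimator `p = (1 + #{perm ≥ obs}) / (B + 1)` — its smallest attainable
value is `1/(B+1)`, and the same seed always reproduces the same
p-value. Defaults: `half_window = 25` sites (windows much narrower than
typical between-breakpoint distances but wide enough for a stable 2×2
table), `B = 1000`.

Two consequences of the variable-site restriction are worth noting.
First, a two-sequence alignment is degenerate — every polymorphic
column is then a mismatch — so a pair must be tested inside the
alignment that provides its comparison context (parents plus candidate
recombinant); the function returns `p = 1` rather than an error when
fewer than `2 × half_window` usable sites remain. Second, breakpoint
accuracy is naturally measured in polymorphic sites: on planted
recombinants (30% parent divergence, 1000 bp, central breakpoint) the
argmax partition point recovers the junction to within a few polymorphic
sites and the permutation p-value reaches its floor.

Calibration is checked empirically in the acceptance tests: over 1000
null alignments (two independent 30%-divergent descendants of a common
ancestor, 300 columns, 500 permutations each) the empirical type-I
error at nominal 0.05 must fall within the binomial band [0.03, 0.07].

**Consensus.** Detection in practice runs seven methods (RDP, GENECONV,
Chimaera, MaxChi, BootScan, SiScan, 3Seq); `consensus_call()` applies
the rule that an event is significant only when at least `min_methods`
(default 4) methods report p strictly below `alpha` (default 1e-6).
Strict inequality is deliberate — the rule is stated as "p < 10⁻⁶" — so
a p-value exactly at the threshold does not count, and missing method
columns count as non-supporting. The rule is verified against brute
force over all 2⁷ support patterns and is monotone: lowering any
p-value never loses significance.

## Positive selection

`lrt_m7m8()` computes the M7-vs-M8 likelihood-ratio statistic
`max(0, 2(lnL₈ − lnL₇))` and refers it to χ² with 2 degrees of freedom
(the standard df for this comparison: M8 adds one proportion and one ω
parameter), whose survival function has the closed form `exp(−stat/2)`;
the tests require agreement with numerical integration to 1e-10 across
[0, 50]. Negative statistics are optimiser noise under a nested model
and clamp to 0. `classify_selection_groups()` calls a group positive
when the LRT p-value is below `alpha` (default 0.05) **and** at least
one BEB site reaches `min_posterior` (default 0.95) — both conventional
values, exposed as parameters because the upstream study prints
neither — and reports the "k/n" positive-group tally.

## The simulator

`simulate_gene_family()` is a birth–death–transfer process along a
species tree: each gene lineage duplicates at rate λ, dies at rate μ,
and at rate τ sends a copy to a uniformly chosen contemporaneous branch
of another part of the species tree (no phylogenetic-distance bias —
no transfer mechanism is assumed); at each speciation every lineage
copies into both daughters. The returned gene tree is pruned to
lineages with extant descendants, and the event log records every
duplication, loss and transfer with its branch, time, terminal-branch
flag and (for transfers) donor, recipient and surviving descendant
genes — the ground truth against which the event callers are scored.

Defaults define the reference study conditions: a 10-leaf ultrametric
ladder species tree of unit depth (ten related genomes of one genus),
λ = 0.3, μ = 0, τ = 0 (each per gene per unit branch length), one root
gene. With all rates zero the gene tree reproduces the species tree
exactly; with λ only, the expected number of extant copies per species
is e^{λ·depth}, which the acceptance tests verify to within 10% over
500 replicates at λ = 0.5, depth 2.

`evolve_domain_states()` adds domain ground truth: TIR, RPW8, Rx_N and
LRR each evolve as an independent two-state Markov chain along the
gene-tree branches, from an NL root state (NB-ARC + LRR, no N-terminal
domain) — encoding the inference that TNL/RNL/CNL receptors arose from
NL ancestors by domain acquisition. Default rates (gain 0.1, loss 0.3
per unit length for the three N-terminal domains; gain 0.5, loss 0.1
for LRR) make N-terminal acquisitions occasional and reversible while
keeping LRR mostly present, so simulated families are NL-dominated with
a minority of TNL/RNL/CNL — the qualitative shape of real NLR families.
NB-ARC is always present, since losing it removes a gene from the
family by definition.

`simulate_recombinant_alignment()` plants a single known breakpoint:
parent A is i.i.d. over ACGT, parent B (and optional extra background
sequences) differ from A independently per site with probability
`divergence`, and the recombinant C switches from A to B at
`round(breakpoint_frac × length)`. There is no substitution model
beyond this i.i.d. generator — rate heterogeneity, indels and shared
ancestry among background sequences are not emulated, so MaxChi power
estimates here are upper bounds for messy real alignments.

**Recovery scoring.** `hgt_recovery()` matches a called event to a true
transfer when the called recipient species occurs among the species of
the transfer's surviving descendant genes and at least 50% of the
called recipient clade descends from the transferred copy. Under the
reference transfer regime (λ = 0.3, μ = 0, τ = 0.1, 200 replicates)
called-event precision must reach 0.8; recall is deliberately not
bounded — transfers whose donor lineage speciated afterwards leave a
mixed context and are invisible to a clade heuristic, which is a known
limitation of the method, not of the implementation.

## Numerical and design choices

* All E-value cutoffs compare inclusively (≤); the consensus and
  selection thresholds compare strictly (<) as their rules are stated.
* Isoform reduction keeps the longest protein per locus, ties broken by
  lexicographically smallest id, making results order-independent.
* Correlations (`correlate_counts_events()`) default to Pearson with
  the two-sided t-transform p-value (df = n−2); Spearman applies the
  same transform to ranks, appropriate at n ≈ 10 species. Perfect
  correlations report the smallest positive double rather than 0.
* Every stochastic routine takes an explicit integer seed; identical
  seeds give byte-identical outputs (property-tested).
* Validation problem sizes — 100 replicates for caller soundness, 200
  for transfer recovery, 500 for the birth-process expectation, 1000
  null pairs × 500 permutations for MaxChi calibration — were chosen to
  put Monte-Carlo error well inside each test's acceptance band while
  keeping the default suite fast.

## What passing tests do and do not show

The simulator provides clean, fully observed families: no annotation
error, no alignment error, no incomplete lineage sorting, no
hybridisation or introgression (both of which can mimic the HGT nesting
signature among closely related cultivars), and no gene conversion.
Passing recovery tests therefore demonstrate that the callers implement
their stated rules correctly and recover events under the assumed
generative process — not that the rules are immune to those confounders
on real data. Full duplication–transfer–loss reconciliation against a
species tree, parental-triplet identification for recombinants, and
codon-model fitting are out of scope; the package consumes the outputs
of tools that do those jobs.
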