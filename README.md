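# nlrdiversity

Analysis of the diversity and evolution of plant **NLR**
(nucleotide-binding leucine-rich repeat) resistance gene families, for
comparative genomicists working on a clade of related genomes. The
package takes the *tabular outputs* of the usual upstream tools —
hmmscan domain tables, BLAST tabular hits, gene trees in newick,
per-method recombination p-values, codeml log-likelihoods and BEB
sites — and turns them into tested, reproducible answers:

* **Classification** — gate on the NB-ARC domain, then classify by the
  N-terminal domain: TIR → TNL, RPW8 → RNL, Rx_N (the coiled-coil
  stand-in) → CNL, none → NL; precedence TIR > RPW8 > Rx_N for
  dual-domain proteins.
* **Phylogenetic screen** — keep NB-ARC candidates whose smallest
  reference-containing clade holds plant R proteins only.
* **Event calling** — duplications as maximal same-species
  monophyletic groups (per-bifurcation or per-clade tallies); directed
  HGT when one species' gene diversity nests inside another's
  (donor-pure context over `context_depth` consecutive enclosing
  clades), plus the donor × recipient event matrix.
* **Recombination** — a pairwise MaxChi test: maximum sliding-window
  2×2 chi-square over the alignment's polymorphic sites with a
  site-order permutation p-value, and the seven-method consensus rule
  (significant iff ≥ 4 methods at p < 10⁻⁶).
* **Selection** — the M7-vs-M8 likelihood-ratio test
  (`stat = max(0, 2(lnL₈ − lnL₇))`, p = `exp(−stat/2)`, χ² df = 2) with
  BEB-site-gated positive/negative group calls.
* **Summaries** — per-species TNL/CNL/RNL/NL count tables and
  count-versus-event-frequency correlations (Pearson/Spearman).
* **Simulator** — a birth–death–transfer gene-family generator along a
  species tree with domain gain/loss and planted recombinants,
  providing the ground truth behind every validation test.

## Worked example

Simulate a family on the default 10-species ladder tree (duplication
rate 0.3, transfer rate 0.1 per gene per unit branch length), evolve
domain states, and call events:

```r
library(nlrdiversity)

fam <- simulate_gene_family(sim_config(dup_rate = 0.3, transfer_rate = 0.1,
                                       seed = 4))
fam <- evolve_domain_states(fam)
fam
#> Simulated gene family: 20 extant genes in 10 species; 5 logged events

call_duplications(fam$gene_tree, fam$species_map)[, 1:3]
#>   species_id size n_events
#> 1        sp1    2        1

call_hgt(fam$gene_tree, fam$species_map)[, 1:3]
#>   donor_species recipient_species context_depth
#> 1           sp4               sp9             2
```

One maximal same-species clade of two `sp1` genes gives one duplication
event; one `sp9` gene nested in a donor-pure `sp4` context gives one
directed transfer call, which matches the simulator's truth log
(`hgt_recovery(...)` reports precision 1). Recombination on a planted
recombinant (C = first half of parent A, second half of parent B, 30%
divergence):

```r
sim <- simulate_recombinant_alignment(length = 1000, divergence = 0.3, seed = 8)
maxchi_test(sim$alignment, c("C", "A"), seed = 9)
#> MaxChi pair (C, A): max chi-square = 50.000, p = 0.000999 (1000 permutations)
#>   breakpoint after comparison site 152 (alignment column 500) of 315 sites
```

The permutation p-value is at its floor `1/(B+1)` and the estimated
breakpoint (alignment column 500) hits the planted junction. The
consensus rule and the selection summary work on plain data frames:

```r
lik <- data.frame(group_id = c("g1", "g2"),
                  lnl_m7 = c(-2301.4, -1887.2),
                  lnl_m8 = c(-2292.1, -1886.8))
beb <- data.frame(group_id = c("g1", "g1"),
                  site_index = c(45L, 101L), posterior = c(0.99, 0.96))
calls <- classify_selection_groups(lik, beb)
calls
#>   group_id lrt_stat      p_value n_beb_sites  verdict
#> 1       g1     18.6 9.142423e-05           2 positive
#> 2       g2      0.8 6.703200e-01           0 negative
attr(calls, "summary")
#> [1] "1/2"
```

Correlating per-species gene counts with duplication-event counts:

```r
counts <- c(56, 70, 94, 107, 111, 130, 178, 208, 216, 405)
dups   <- c(6, 10, 12, 14, 20, 22, 35, 48, 10, 116)
correlate_counts_events(counts, dups)
#>    x_name   y_name         r      p_value  n  method
#> 1 n_genes n_events 0.9126582 0.0002288783 10 pearson
```

A significant positive correlation (r = 0.91, p ≈ 2e-4) of this shape
is the signature of duplication-driven family expansion.

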