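# phyloconflict

Genome-wide gene-tree/species-tree discordance analysis for three-lineage
radiations under the multispecies coalescent.

Rapid radiations — the motivating case is the three genera of
nematode-trapping fungi (*Arthrobotrys*, *Dactylellina*, *Drechslerella*)
plus a non-trapping outgroup — leave genomes full of gene trees that
conflict with the species tree. `phyloconflict` answers, with one
reproducible pipeline, the questions such a data set raises:

* **How much conflict?** Gene concordance factors (gCF) per species-tree
  branch, pairwise Robinson–Foulds (RF) distances, and a classical MDS
  embedding of the tree cloud.
* **Is it incomplete lineage sorting (ILS)?** Gene trees are filtered for
  cross-strategy consistency and bootstrap support, classified against the
  backbone ((L1,L2),L3) as TREE1/TREE2/TREE3/UNCLASSIFIED, and every
  four-taxon set (outgroup fixed) is tested against the multispecies
  coalescent (MSC) null. Under the MSC the two discordant quartet
  topologies are equally likely — each with probability (1/3)e^(−t) for an
  internal branch of t coalescent units — so with minor counts m₁, m₂ the
  statistic X² = (m₁ − m₂)²/(m₁ + m₂) is χ²₁ under ILS alone.
* **Is there gene flow?** The ABBA-BABA test:
  D = (ΣABBA − ΣBABA)/(ΣABBA + ΣBABA) over outgroup-polarized biallelic
  sites, with a delete-one block-jackknife Z score.
* **Does branch length corroborate ILS?** Welch t-tests on the
  node1→node2 divergence segment and cumulative tree length across
  topology classes.

A built-in coalescent simulator (gene trees with an optional introgression
pulse of weight γ; single-mutation biallelic site patterns) generates data
with known truth, so every stage is validated against closed forms and
brute-force oracles.

## Worked example

```r
library(phyloconflict)

fix <- make_fixture("mini-ntf", dir = "fixture", seed = 42)
report <- run_conflict_pipeline(c(fix, list(outdir = "results")))
report
#> Phylogenetic conflict report
#>   genes: 200 input, 10 inconsistent, 19 low support, 171 retained
#>   classes: TREE1 92 (53.8%), TREE2 38 (22.2%), TREE3 33 (19.3%), UNCLASSIFIED 8 (4.7%)
#>   quartets: ILS_consistent 67.9%, rejected 32.1%, undetermined 0.0%
#>   D = -0.1047, Z = -1.662 (20000 informative sites)
```

Reading the output: of 200 simulated genes, 10 were dropped because the two
inference strategies disagreed and 19 for mean bootstrap support below 80;
of the 171 retained trees 53.8% match the species backbone (the fixture's
internal branch is 0.5 coalescent units, so substantial ILS is expected),
and the two minor classes are nearly symmetric — the ILS signature. The
fixture has no gene flow (γ = 0), and accordingly |Z| < 3: the D statistic
is not significant. Per-stage tables (gene records, gCF, MDS coordinates,
per-quartet tests, D-statistic, branch-length comparisons) are written to
`results/`, byte-identical across reruns with the same seed.

Individual stages are plain functions on tibbles and trees:

```r
sim <- simulate_gene_trees(10000, t_internal = 1, seed = 1)
cnt <- quartet_counts(sim$trees, c("L1_1", "L2_1", "L3_1"), "OUT")
cnt
#> # A tibble: 1 × 6
#>      n1    n2    n3 n_total n_unresolved n_skipped
#>   <int> <int> <int>   <int>        <int>     <int>
#> 1  7544  1226  1230   10000            0         0
msc_test(cnt$n1, cnt$n2, cnt$n3)
#> # A tibble: 1 × 3
#>   statistic p_value verdict
#>       <dbl>   <dbl> <chr>
#> 1   0.00651   0.936 ILS_consistent
```

7544/10000 ≈ 0.754 matches the closed form 1 − (2/3)e^(−1) ≈ 0.7547, and
the near-equal minor counts (1226 vs 1230) are exactly what the MSC
predicts. `plot_mds()`, `plot_quartet_simplex()` and
`plot_branch_lengths()` provide the standard figures; `tidy()`/`glance()`
methods cover the result objects. A thin CLI wrapper with `simulate`,
`validate`, per-stage and `all` subcommands is installed at
`inst/scripts/phyloconflict`.

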