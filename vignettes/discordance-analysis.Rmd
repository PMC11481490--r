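---
title: "Quantifying and explaining gene-tree/species-tree discordance"
author: "phyloconflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and explaining gene-tree/species-tree discordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloconflict)
```

## The problem

Rapid radiations leave a characteristic genomic signature: individual gene
trees disagree with the species tree, and with each other, far more often
than inference error alone can explain. The canonical example this package
is built around is a radiation of three lineages plus an outgroup — in the
motivating system, the three genera of nematode-trapping fungi
(*Arthrobotrys* with 3D adhesive networks, *Dactylellina* with 2D adhesive
traps, *Drechslerella* with constricting rings), rooted with a non-trapping
relative. The analysis questions are always the same:

1. How much conflict is there? (gene concordance factors, RF distances, MDS)
2. Is the conflict explained by incomplete lineage sorting (ILS) under the
   multispecies coalescent (MSC)? (quartet topology-count tests)
3. Is there gene flow on top of ILS? (ABBA-BABA D-statistic)
4. Do the discordant trees carry the branch-length signature of ILS?
   (divergence-segment and cumulative-length comparisons)

`phyloconflict` implements this chain end to end, together with a coalescent
simulator that generates data with known truth, so every stage is testable.

## The model

Label the ingroup lineages L1, L2, L3 with species-tree backbone
((L1,L2),L3) and an outgroup. Time is measured in coalescent units
(2N generations). The species tree is parametrized by three times:
`t_split` (tips to the L1/L2 population merger), `t_internal`
(the branch between the (L1,L2) ancestor and the ingroup root) and `t_root`
(ingroup root to the outgroup join). Under the MSC with one sampled lineage
per species, a gene tree matches the backbone with probability

$$P(\text{TREE1}) = 1 - \tfrac{2}{3}e^{-t},$$

where `t = t_internal`, and each discordant resolution —
((L1,L3),L2) ("TREE2") and ((L2,L3),L1) ("TREE3") — occurs with probability
$\tfrac{1}{3}e^{-t}$. Two consequences drive the whole analysis:

* **Minor-class symmetry.** ILS alone cannot prefer TREE2 over TREE3. The
  quartet test exploits exactly this: with observed minor counts $m_1, m_2$,
  $X^2 = (m_1 - m_2)^2/(m_1 + m_2)$ is $\chi^2_1$ under the null. An exact
  binomial variant (`mode = "exact"`) is provided for small counts. This is
  the testable core of the MSC null; variants that additionally use branch
  lengths exist, but topology counts are what the count data identify.
* **Invertibility.** The discordant fraction $d = \tfrac{2}{3}e^{-t}$ gives
  the estimator $\hat t = -\log(1.5\,d)$, which the test suite uses to check
  that the simulator and the theory agree (within 10% relative error at
  10,000 genes for $t \in [0.5, 2]$).

The ABBA-BABA test polarizes biallelic sites by the outgroup and compares
the two discordance-supporting patterns: with derived-allele frequencies
$p_1, p_2, p_3$,

$$\mathrm{ABBA} = (1-p_1)\,p_2\,p_3, \qquad \mathrm{BABA} = p_1\,(1-p_2)\,p_3,
\qquad D = \frac{\sum \mathrm{ABBA} - \sum \mathrm{BABA}}
                {\sum \mathrm{ABBA} + \sum \mathrm{BABA}}.$$

ILS alone makes ABBA and BABA equally frequent; introgression between P3 and
P2 (or P1) skews them. Significance uses a delete-one block jackknife over
contiguous site blocks (default 50 blocks), $Z = D/\mathrm{SE}$, with the
conventional $|Z| \ge 3$ significance label.

## The pipeline and its filters

`run_conflict_pipeline()` mirrors the field's standard accounting chain:

1. **Consistency filter** — a gene is kept only if the trees inferred under
   two alignment/trimming strategies have identical unrooted topologies
   (RF = 0). Trees that disagree are treated as likely analytical error.
2. **Support filter** — trees whose support statistic falls below 80 are
   removed. The statistic is the *mean* over internal-node bootstrap values
   by default; published descriptions of this filter rarely say whether
   mean, median or minimum was used, so the choice is explicit and
   configurable (`support_statistic`), with the boundary kept (≥ 80).
3. **Classification** — each retained tree is re-rooted on the outgroup
   (classification must respect rooting even though RF ignores it), each
   lineage is checked for monophyly, and the tree is assigned TREE1/2/3 by
   which two lineage MRCAs are siblings, or UNCLASSIFIED when a lineage is
   non-monophyletic or the backbone is a polytomy.
4. **Concordance** — gene concordance factors per species-tree branch with
   a decisive-tree denominator (a gene tree restricted to a branch must
   keep ≥ 2 taxa on both sides to count), highlighted strictly above 60%;
   the RF matrix and its classical MDS embedding.
5. **Quartet MSC tests** — all ingroup triples with the outgroup fixed; by
   default only the trees discordant with the species tree feed the counts
   (`quartet_trees = "discordant"`, mirroring the standard design), at
   α = 0.0001 without multiple-testing correction (per-quartet verdicts at
   fixed α; Bonferroni/Holm are available but off by default).
6. **D-statistic** — when an alignment and population map are configured.
7. **Branch-length comparisons** — two-sided Welch t-tests between classes
   on the node1→node2 divergence segment (the path from the ingroup MRCA to
   the sister-pair MRCA, which generalizes to one branch in the binary
   case) and on cumulative tree length. Welch is used because no
   equal-variance assumption is warranted; results are reported without
   asserting a direction, since the expected sign of the divergence-segment
   difference depends on how gene trees are estimated and reported values
   in the literature are not internally consistent on this point.

Every stage writes its table before the next begins, and a rerun with the
same config and seed is byte-identical.

## The simulator: what it emulates and what it does not

`simulate_gene_trees()` implements the standard structured coalescent on the
species tree: within each branch, `k` lineages coalesce at rate
`choose(k, 2)`; survivors pass rootward; the process above the root always
completes. Trees are ultrametric in coalescent units. The one-taxon-per-
lineage case is additionally implemented as a vectorized four-lineage
labelled-history sampler (the same epoch structure, batch-drawn), which the
test suite cross-checks against both the general engine and the closed form.

Introgression is a per-gene *pulse*: with probability γ the recipient
lineage's ancestry moves into the donor population at `t_mig` (default
halfway up the lineage branches, `t_split / 2`). This matches the
hybrid-edge abstraction used by network methods and keeps closed-form
expectations available; it is not a continuous-migration model.

`simulate_site_patterns()` draws one four-tip genealogy per site and places
exactly one mutation uniformly on the total branch length, emitting a
biallelic column. This is the minimal generative model that the D-statistic
is sensitive to. Deliberately **not** modelled: realistic substitution
processes (multiple hits, rate variation), linkage between sites,
recombination within loci, and gene-tree estimation error. Consequently,
passing calibration tests shows the statistics behave correctly on clean
coalescent signal — not that they are robust to alignment error or
substitution saturation in real genomes.

Simulated bootstrap supports follow a logistic-beta model: the expected
support rises logistically with the subtending branch length (midpoint 0.2
coalescent units, scale 0.1, beta concentration 30), so short internal
branches get diffuse, often sub-80 supports. This exists purely to exercise
the support filter with known truth; it is not a model of real bootstrap
behaviour. Strategy-B tree sets are produced by copying strategy A and
applying one random NNI to a configured fraction of genes, exercising the
consistency filter with a known planted rate.

The fixture presets reflect the study conditions the package targets:
`mini-ntf` (200 genes, 3+3+2 ingroup taxa, deep within-lineage time
`t_split = 4` so lineages are usually monophyletic, `t_internal = 0.5`, 5%
planted inconsistencies), `null-ils` (γ = 0) and `introgression` (γ = 0.3
from L3 into L2) — both with `t_internal = 0.5`, a value that yields roughly
40–60% backbone concordance, the regime in which these analyses are
actually run.

## Numerical and design choices

* **Bipartitions** are canonicalized as the side not containing the
  alphabetically first taxon; RF is the symmetric difference of these sets
  on the unrooted topology. Polytomies simply contribute fewer splits.
* **Branch lengths** serialize with 10 significant digits so parse/write
  round-trips are exact at working precision.
* **Supports** are read from internal-node labels (the IQ-TREE convention),
  with an optional split rule for composite labels such as `"aLRT/ufboot"`.
* **MDS** is metric classical (Torgerson) scaling via double-centred squared
  distances — the variant almost universally meant by "MDS of an RF matrix";
  a non-metric alternative would be a reasonable substitute but is not
  implemented. RF matrices are not Euclidean, so negative eigenvalues occur:
  those axes are dropped and reported. Axes are deterministically reflected
  (largest-magnitude loading positive) so runs are comparable.
* **Quartet test ties** for the major topology are resolved toward the null
  (the largest p-value over admissible major choices); zero minor counts
  give p = 1 (such counts cannot reject equal minors).
* **D-statistic sites** with a polymorphic, missing or ambiguous outgroup
  are discarded (polarization must be unambiguous); within P1–P3, missing
  sequences are dropped from that site's frequency, and a site where a
  whole population is missing is discarded. With fewer informative sites
  than blocks, the block count is reduced with a warning; an SE of zero
  flags Z as undefined rather than inventing a value.
* **Evolutionary rate** is total tree length divided by the number of
  leaves (`method = "total"` gives the raw sum): toolkits differ in their
  exact definition, so ours is recorded and configurable.
* **Gene identity across strategy files** is taken from an
  `id<TAB>newick` prefix when present; bare files fall back to line order
  with a message.

## Problem sizes used in validation

The test suite validates the closed-form MSC frequencies at 10,000 genes for
t ∈ {0.25, 1, 2}; quartet-test type-I error on 500 pure-ILS quartet sets of
300 trees at α = 0.05 (expected 5% ± 2%) and power > 95% at minor
proportions (0.15, 0), n = 300, α = 10⁻⁴; D-statistic null calibration on
200 replicates of 20,000 sites (|Z| < 3 at least 95% of the time) and power
on 200 replicates of 50,000 sites at γ = 0.3 (D > 0 and Z > 3 at least 95%);
and exact agreement of RF and gCF with brute-force oracles. These sizes give
comfortably narrow Monte-Carlo error while keeping a full run fast on a
single core; `scripts/acceptance.R` recomputes the same quantities from
scratch.

## A worked example

```{r example, eval = FALSE}
fix <- make_fixture("mini-ntf", dir = tempfile(), seed = 42)
report <- run_conflict_pipeline(c(fix, list(outdir = tempfile())))
report
#> Phylogenetic conflict report
#>   genes: 200 input, 10 inconsistent, 19 low support, 171 retained
#>   classes: TREE1 92 (53.8%), TREE2 38 (22.2%), TREE3 33 (19.3%), UNCLASSIFIED 8 (4.7%)
#>   quartets: ILS_consistent 67.9%, rejected 32.1%, undetermined 0.0%
#>   D = -0.1047, Z = -1.662 (20000 informative sites)
```

The accounting identity (input = inconsistent + low-support + retained)
holds on every run, class proportions are over retained trees, and with
γ = 0 in the fixture the D-statistic is correctly non-significant.

## Known limitations

* Classification requires the outgroup to attach outside the ingroup after
  re-rooting; gene trees where the outgroup falls inside an ingroup clade
  are UNCLASSIFIED rather than errors.
* The quartet test uses topology counts only; with very few discordant
  trees per quartet it has little power, and the `undetermined` verdict is
  reserved for quartets with no counts at all.
* The D-statistic operates on a single alignment (no VCF input, no sliding
  windows, no f4-ratio admixture fractions).
* gCF here is the gene concordance factor only; site concordance factors
  are out of scope.
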