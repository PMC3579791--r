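---
title: "Distinguishing incomplete lineage sorting from mitochondrial introgression in kangaroos"
author: "macroils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing incomplete lineage sorting from mitochondrial introgression in kangaroos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(macroils)
```

## The question

Mitochondrial and nuclear gene trees for kangaroos and wallabies disagree on
two placements. The mitochondrial genome puts the swamp wallaby (*Wallabia
bicolor*) outside a monophyletic *Macropus*, while concatenated nuclear genes
nest it next to the *M. (Notamacropus)* wallabies; and the mitochondrial
genome of the black-gloved wallaby (*M. irma*) groups with the wallaroos
(*M. (Osphranter)*) although every other line of evidence places the species
with *Notamacropus*. Two population processes can produce such conflicts:
incomplete lineage sorting (ILS) — ancestral polymorphism persisting through
a burst of speciations — and introgression, the wholesale transfer of a
mitochondrial genome between species by hybridization.

The two hypotheses make quantitatively different predictions. ILS becomes
plausible when the internodes separating speciations are short relative to
the coalescent timescale (2·N~e~ generations for an autosomal locus, N~e~/4
for the maternally inherited mitochondrion). This package simulates gene
genealogies under the multispecies coalescent (MSC) on dated species trees,
evolves sequences on them, re-estimates gene trees by maximum likelihood,
and asks: *at what effective population size, if any, does ILS reproduce the
observed pattern of gene-tree conflict?*

## The model

Gene lineages (one per species) coalesce within the branches of an
ultrametric species tree. Within a branch, each lineage pair coalesces at
rate $1/(2N_e)$ per generation for nuclear loci. The mitochondrial effective
size is one quarter of the nuclear reference (haploid and maternally
inherited), so its pairwise rate is $1/(N_e/4)$; equivalently, the
population mutation parameter is $\theta = 4N_e\mu$ for nuclear loci and
$\theta = 2(N_e/4)\mu$ for mtDNA, with $\theta = 2\,\mathrm{E}[T_2]\,\mu$ in
both cases. Node ages in Ma convert to generations at $10^6/g$ per Ma with
generation time $g = 7$ years, the macropodid average. Lineages that fail to
coalesce enter the parent branch; the process is exact (no time
discretization).

Sequences then evolve site-independently along the genealogy under GTR-family
models with discrete-gamma rate heterogeneity (4 equal-probability
categories represented by their means, one category per site across the
whole tree, root state drawn from the stationary frequencies, no indels).
Gene trees are re-estimated by maximum likelihood and clade recovery is
tallied: *a gene supports a clade when the clade appears in that gene's ML
point-estimate tree* — bootstrap thresholds are reserved for the
gene-number power scan.

## Study conditions

Two 16-taxon dated guide trees drive all simulations (`study_guide_trees()`):

* **combined** — *Wallabia* sister to a monophyletic *Macropus*; root
  20.0 Ma, Potoroidae 17.0, Macropodidae 14.4, Dendrolagini/Macropodini 7.6,
  *Lagorchestes* split 6.6, *Macropus*/*Wallabia* 5.3, *Macropus* crown 4.8,
  *M. (Macropus)*/*M. (Osphranter)* 4.4, core-*Notamacropus* crown 3.4 Ma.
* **nuclear-only** — *Wallabia* sister to *Notamacropus*; 20.0, 16.4, 17.7,
  10.7, 8.8, 7.3, 6.8, 6.7, 5.8 Ma.

Ages not reported for within-subgenus splits are interpolated evenly between
the nearest dated crown and the tips (an unaged node at maximal chain depth
*k* below its parent gets *parent age · k/(k+1)*). *M. irma* is grafted
mid-stem onto the core-*Notamacropus* lineage (4.1 Ma on the combined tree,
6.25 Ma on the nuclear-only tree), reflecting its treatment as a suspected
introgressive hybrid whose own position cannot be co-estimated. Both trees
are scaled to a root height of 20 Ma.

The locus set mirrors the real data: one 5,593 bp mitochondrial locus
(GTR+Γ, strong transition bias, α = 0.4) and five nuclear loci totalling
5,988 bp (HKY+Γ, κ = 3, α = 0.8; individual lengths
1,198/1,198/1,198/1,197/1,197 — only the total is constrained). Mutation
rates are documented placeholders — mt 1.0 × 10⁻² and nuclear
1.5 × 10⁻³ substitutions/site/Myr, divided by the generation time to
per-generation units — because the tree-length-derived rates behind the
original study are unpublished. The nuclear N~e~ grid is
10³, 10⁴, 10⁵, 10⁶; mitochondrial runs use the same populations at
mitochondrial equivalency (N~mt~ = 250 to 250,000).

## The diagnostics

* `run_ils_scan()` — for each N~e~ and replicate, simulate each locus's
  genealogy and alignment, estimate its ML tree, and record which focal
  clades it contains. `support_profile()` summarizes the mean number of
  genes supporting each clade; `sum_of_squares()` scores each N~e~ against
  observed support counts.
* `placement_query()` / `placement_frequency()` — predicates over replicate
  trees, including the introgression diagnostic: the frequency with which
  the focal wallaby abandons its species-tree position and attaches, outside
  core-*Notamacropus*, to a group at least as shallow (on the guide tree) as
  the *M. (Osphranter)* crown.
* `power_scan()` — how many simulated 1 kb genes must be concatenated before
  ML bootstrap support for a clade reaches 95%, in increments of five.
* `parametric_homogeneity_test()` — likelihood gain of per-gene topologies
  over one shared topology, calibrated by simulating datasets on the shared
  ML topology with per-gene fitted branch lengths and models; Monte-Carlo
  p-values use the (1 + exceedances)/(n + 1) convention so p is never 0.
* `ild_test()` — the parsimony incongruence length difference test with
  random re-partitioning into the original gene sizes (sampling without
  replacement).
* `chi2_composition_test()` — taxa × base contingency χ² on
  (n − 1) · 3 degrees of freedom, with parsimony-uninformative and gapped
  sites excluded by default.
* `mdc_infer()` — species-tree inference by minimizing deep coalescences,
  after collapsing gene-tree branches below 50% bootstrap support.

## Inference engines

The pruning-likelihood engine in this package (per-category partial
likelihoods over compressed site patterns, per-node max-scaling against
underflow, coordinate-wise Brent branch-length optimization, NNI
hill-climbing from random-addition parsimony starts, first-found
tie-breaking at |ΔlnL| < 10⁻⁸) is the reference implementation: every
statistic that needs site likelihoods (RELL bootstrap, KH/SH tests, the
homogeneity test) reads them from it, and the test suite checks it against
closed forms and an independent enumeration oracle. Branch lengths and model
parameters alternate until the joint improvement falls below the tolerance;
per-partition models carry their own branch-length multipliers (first class
anchored at 1).

For the replicate scans — hundreds of 16-taxon trees per analysis — the
pipeline calls FastTree 2 (`engine = "fasttree"`, the default when the
binary is available), an established approximate-ML program whose
topology-level results at this scale match full ML searches. Bootstrap
support in the power scan defaults to RELL resampling over the NNI
neighborhood of the concatenated ML tree (each candidate's branch lengths
re-optimized locally around the rearranged edge): site log-likelihoods are
resampled rather than re-searched, which is orders of magnitude faster and,
near the 95% decision threshold, agrees with full bootstrap to within a few
points. `boot_mode = "full"` restores re-searching.

## What the generator does and does not emulate

The synthetic data reproduce the dimensional and process structure of the
study — taxon set, locus lengths, ploidy, dated species trees, coalescent
regime — with known truth retained for every replicate, which is what the
parameter-recovery and calibration tests need. They do not emulate
alignment error, indels and missing data, codon structure and selection,
among-lineage rate variation (no relaxed clock), or base-composition
drift. Passing tests therefore validate the machinery and the coalescent
reasoning, not the fidelity of any particular empirical alignment.

Three empirical anchors deserve caution when comparing simulated numbers to
the published ones. First, the nuclear-only guide tree here carries the
printed average nuclear divergence times, which compress the critical
internodes (0.1–0.5 Myr) around the *Wallabia* and subgenera splits; the
species tree actually used for the original mitochondrial simulations was
never printed with its node ages, and mitochondrial clade-recovery
percentages are very sensitive to those internodes. Cross-validation of the
simulator against an independent coalescent implementation (and against the
closed-form triplet concordance law 1 − (2/3)e^(−T)) shows the machinery is
exact, so residual disagreement with the published mitochondrial
percentages reflects these input ages, not the algorithm. Second, per-locus
mutation rates are placeholders (above); they control how much estimation
noise dilutes or inflates clade recovery in the weak-signal nuclear regime.
Third, the composition χ² test assumes independent sequences; shared
ancestry makes it conservative, which the test suite demonstrates and which
matches its standard usage as a screening tool.

## Numerical choices

* Branch lengths are bounded below at 10⁻⁹ substitutions/site; Brent
  tolerance tracks the lnL tolerance (two orders tighter, capped at 10⁻⁴).
* Likelihood scaling: per-node column maxima, accumulated in log space per
  site pattern; site likelihoods are floored at 10⁻³⁰⁰ inside edge
  optimization only.
* Discrete gamma uses category means over equal-probability bands computed
  from the incomplete-gamma identity, so the mean relative rate is exactly 1.
* SH tests center resampled log-likelihood sums at each tree's own mean and
  compare the per-replicate max deficit to the observed ΔlnL; the best tree
  reports p = 1. KH is the one-sided centered pairwise version.
* MDC scores soft polytomies as the minimum over refinements, computed by
  merging polytomy children that fall inside the species-tree cluster; the
  test suite verifies this equals brute-force enumeration over refinements.
  The cluster DP is exact over the full power set up to 12 taxa; beyond
  that the candidate set is gene-tree clusters, their pairwise unions and
  singletons, and optima are flagged when tied (ties broken in lexicographic
  mask order).
* Every pipeline function draws per-replicate substream seeds from a single
  seeded generator, so identical (configuration, seed) pairs give
  bit-identical outputs regardless of scheduling.

## Problem sizes

The shipped analyses use 200 replicates per N~e~ for the scans (100 in the
reduced test-suite versions), 100 bootstrap replicates in the power scan,
199 re-partitions for the ILD test and 99–199 simulated datasets for the
homogeneity test, with the congruence calibrations run on 4–8 taxon
fixtures. These sizes put every Monte-Carlo standard error well below the
effect sizes of interest while keeping each analysis in the minutes range
on a single core.

## Known limitations

* N~e~ is constant across all species-tree branches per run, as in the
  original design; no per-branch demography.
* One haploid sample per species per locus.
* The introgression hypothesis itself is never simulated — the logic is
  one-sided (ILS is either sufficient or insufficient to explain the
  observed placements), mirroring the study's argument.
* Exhaustive ML search is limited to 6 taxa and exhaustive MDC to 8; larger
  problems rely on NNI hill-climbing and the cluster DP respectively.
* The MDC cluster machinery is limited to 31 taxa (integer bitmasks).
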