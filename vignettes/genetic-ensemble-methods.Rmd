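---
title: "Detecting epistatic SNP interactions with a genetic ensemble"
author: "geneticEnsemble maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting epistatic SNP interactions with a genetic ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneticEnsemble)
```

## The problem

Complex diseases are rarely driven by single loci. Pairs (or larger sets)
of SNPs can act *epistatically*: jointly predictive of case/control status
while each locus alone shows little or no marginal association, so
single-marker statistics miss them, and exhaustively testing all
$\binom{n}{k}$ combinations is infeasible beyond small $n$. This package
treats the problem as combinatorial feature selection over a case-control
genotype matrix $D_{m \times n}$ (SNPs coded 0/1/2 for aa/Aa/AA, plus
categorical environment factors such as Sex or a discretised Age): a
genetic algorithm (GA) proposes factor subsets, and an ensemble of
classifiers scores how well each subset separates cases from controls.

## The fitness model

A candidate subset $s$ is evaluated by $M = 5$ base classifiers (a
gain-ratio decision tree, KStar, and k-nearest-neighbour with
$k \in \{1, 3, 5\}$) under stratified 5-fold cross-validation, and three
components are combined:

$$\mathrm{fitness}(s) = w_B\,\mathrm{fitness}_B(s) +
  w_V\,\mathrm{fitness}_V(s) + w_D\,\mathrm{fitness}_D(s)$$

* **Blocking** — the mean over classifiers of balanced accuracy
  $BC = (Se + Sp)/2$ on the *same* data split, which compares subsets under
  identical conditions and is robust to imbalanced case:control ratios.
* **Voting** — the balanced accuracy of the majority vote, requiring
  $k = M/2 + 1$ (even $M$) or $(M+1)/2$ (odd $M$) agreeing members.
* **Double-fault diversity** — one minus the mean fraction of samples
  misclassified by both members of a classifier pair, averaged over all
  $M(M-1)/2$ pairs; 1 when no pair coincides in error, 0 when every
  classifier errs on every sample.

The default weights are $w_B = w_V = 0.425$ and $w_D = 0.15$, the tuned
setting of the original tool. The raw blocking definition is a *sum* of
balanced-accuracy percentages, which is not commensurate with a single
balanced accuracy (voting) or a [0, 1] statistic (diversity); we therefore
normalise blocking to mean-$BC$/100 and voting to $BC$/100 so the weights
act on a common scale. Subsets tying exactly in combined fitness are
ordered by size (smaller preferred — complexity regularisation), then
lexicographically, making the search total-ordered and reproducible.

The evaluation protocol is a deliberate design choice: the original
description asks for "an independent test set" without defining one. We
use stratified 5-fold cross-validation with pooled out-of-fold
predictions, drawing the folds once per GA run and sharing them across
every subset evaluated in that run, so that subset comparisons are paired
and fitness differences reflect subsets rather than fold noise.

## The base classifiers

All five members treat genotypes as unordered categories:

* **Decision tree** (J48-like): greedy gain-ratio splits on categorical
  factors, multiway on observed values, unlimited depth by default, no
  pruning. A zero-gain split is still taken when the node is impure and
  attributes remain — this is what lets the tree cut through pure
  XOR-type interactions whose single loci carry no information. Attribute
  ties go to the lowest column index; label ties to control; prediction
  of an unseen category falls back to the node majority.
* **kNN** with overlap (Hamming) distance; distance ties are broken by
  training-row order and vote ties by the training class prior. The
  cover-tree variants of the original tool are an indexing accelerator
  with identical predictions, so plain exact kNN stands in for them.
* **KStar**, simplified to a categorical entropic transformation: a value
  survives transmission with probability $1 - b$ and is otherwise
  replaced uniformly among the attribute's $v$ observed values, giving
  per-attribute match probability $1 - b + b/v$. Training instances vote
  with the product of these probabilities (blend $b = 0.20$ fixed; the
  original names KStar without parameters).

Every tie-break above is fixed and documented because the GA consumes
millions of predictions; any hidden nondeterminism would make restarts
irreproducible.

## The search and ranking

Chromosomes are length-$d$ strings of factor ids with 0 marking an empty
position, so subsets of all sizes from 2 to $d$ evolve in one population.
Selection is by tournament (size $t$, drawn with replacement), crossover
is single-point with probability 0.7, and mutation is multi-point: a
first mutation fires with probability 0.1 and each further mutation
continues with probability 0.25 (a geometric chain that enables pair
mutations). Duplicate ids are collapsed to 0 (set semantics) and
chromosomes are repaired to hold at least two distinct factors. One elite
chromosome is carried over per generation — the original description is
silent on elitism, but it makes "the best chromosome of the final
generation" the best subset seen and the fitness trace monotone.

Defaults scale with the number of factors inside the published ranges:
20-factor data get $(d, p, g, t) = (15, 40, 8, 3)$ and 100-factor data
$(25, 340, 20, 7)$, interpolating linearly in between and clamping
outside.

The GA is restarted $n = 30$ times with seeds `masterSeed + i`. Every
pair/triplet (configurable $k$ range; pairs and triplets by default,
bounding the $\binom{d}{k}$ enumeration) contained in a best subset is
counted, and its *identification frequency score* is count/$n$ — a pair
present in 25 of 30 best subsets scores 0.833. Combinations are called
either by a frequency cutoff (strictly greater; 0.8 is a conservative
default with near-zero false discovery in simulation) or by a dense-rank
cutoff with boundary ties included. Ranks are assigned both within each
combination size and pooled; the calling helpers use the within-size
ranks by default, and both are reported.

## The simulator

`findPenetranceTable()` builds two-locus purely epistatic models: a 3 × 3
penetrance table $f_{ij}$ over the genotype pair with Hardy–Weinberg
genotype frequencies, prevalence $K = \sum_{ij} p_i p_j f_{ij}$, and
heritability on the penetrance scale
$h^2 = \sum_{ij} p_i p_j (f_{ij} - K)^2 / K(1-K)$ — the convention of the
penetrance-table simulation literature, since the study names
heritabilities without defining them. Rather than hill-climbing on the
nine table cells, the search samples a prevalence $K$ and a random
perturbation, projects the perturbation onto the subspace with zero
genotype-frequency-weighted row and column sums (weighted
double-centering), and scales it to hit the target $h^2$ in closed form;
the first candidate with all penetrances in [0, 1] is accepted. Marginal
effects are zero and the heritability exact by construction (both far
inside the 1e-3 acceptance tolerances), the search is deterministic given
its seed, and infeasible targets (e.g. $h^2 = 0.999$ at MAF 0.05) exhaust
`maxIter` and error.

`simulateDataset()` draws the functional genotype pair conditional on
status — $P(g_A, g_B \mid \mathrm{case}) \propto p_A p_B f$ and
$P(g_A, g_B \mid \mathrm{control}) \propto p_A p_B (1 - f)$ — by exact
inverse-CDF sampling over the nine cells, and noise SNPs independently of
the label under HWE. The functional loci sit at seeded-random column
positions so that nothing downstream can learn their location from the
layout, and samples are emitted in seeded-random row order so that no
classifier tie-break can read the phenotype off the row order (real
cohorts are not class-sorted). Defaults mirror the evaluation study:
functional MAF 0.2 (the only value the study prints), noise MAFs uniform
on [0.05, 0.5] (a realistic genotyping-panel spread), 200 samples
balanced 100:100 or imbalanced 67:133, 20 or 100 SNPs, heritability 0.2,
0.1 or 0.05, 100 replicates per condition (`simDesigns()`).

What the simulator does *not* emulate: linkage disequilibrium between
loci, genotyping error, population structure, missingness, and more than
one functional pair. Passing tests therefore certify the detector's
behaviour under clean two-locus epistasis, not under the full complexity
of real GWA data. The exact penetrance tables behind the original
evaluation datasets were never published, so published power values
(e.g. 99/80/45 on the balanced 20-SNP designs) are reproducible only in
trend, not cell by cell; our checks assert the high-heritability recovery
rate, the monotone decay of power with heritability, and the near-zero
FDR above the 0.8 frequency cutoff.

## Evaluation statistics

Power is the percentage of replicates whose true pair is top-ranked
among pairs (ties at rank 1 containing the true pair count as success —
the inclusive reading of "reported as the top rank"). FDR and TPR are
computed from the accepted size-2 calls at a rank or frequency cutoff,
with FDR defined as 0 when nothing is accepted (the 0/0 case). For
combining detectors, per-replicate success vectors (importable from a
plain TSV for external tools such as MDR and PIA) are cross-tabulated
into success/failure fault tables; the degree of complementarity is
$CD = SF/(DF + SF)$, undefined (reported `NA`) when both detectors are
perfect, and joint power counts replicates where at least one detector
succeeds. `faultTableFromMarginals()` reconstructs the 2 × 2 table from
published marginal and joint success counts by inclusion-exclusion, which
is how the package's acceptance script re-derives the published CD values.

## Numerical and scale choices

* Age is discretised around its mean with the *population* standard
  deviation (divisor $m$); the original does not say which estimator it
  used, so the choice is fixed here for reproducibility.
* The allelic chi-square filter uses the plain Pearson statistic without
  continuity correction (that is what "allelic chi-square statistic"
  names), keeping SNPs with $p < 0.05$ after excluding SNPs with more
  than 20% missing genotypes (strictly greater). Missing genotypes are
  then mode-imputed (ties to the smaller code) — the original does not
  state its post-filter handling.
* Category codes must lie below 32 (genotypes use 0–2; environment
  factors are small coded categories).
* The test-suite problem sizes are scaled to desk hardware: 20 replicates
  per heritability level for the power checks and a 200 × 10 dataset for
  the exhaustive-search comparison, against the study's 100 replicates
  per condition. The full 100-replicate protocol is a few hours of
  single-core compute via `makeReplicates()`/`estimatePower()`.

## Known limitations

* Only binary phenotypes; no quantitative traits.
* Only pairwise functional models are simulated (the detector itself
  ranks higher-order combinations).
* The two preprocessing filters are the only GWA-scale reduction steps
  provided; genome-wide runs need an upstream filtering strategy.
* KStar's original blend and missing-value handling are unstated
  upstream; our fixed blend of 0.20 is a documented substitute, and a
  config switch (`classifierSpec()`) admits any replacement member.
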