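---
title: "Deterministic microbial succession: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic microbial succession: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recolonizr)
```

# The experimental system and the analysis model

A recolonization experiment starts from germfree hosts (antibiotic-cleared
sea anemone polyps) and inert controls (silicone tubes shaped to imitate an
inactive polyp), each inoculated with one of three source communities taken
from different host life stages: larvae (`bL`), juveniles (`bJ`) and adult
polyps (`bA`). Communities are profiled by 16S amplicon sequencing at the
inoculum stage and at 2, 7, 14 and 28 days post recolonization (dpr), with
five replicates per substrate × inoculum × timepoint cell.

The package asks three questions of such data and implements one pipeline
per question.

## 1. Is host reassembly deterministic?

Beta-diversity statistics on the samples-by-taxa table: relative
abundances, a dissimilarity matrix (Bray–Curtis by default; quantitative
and binary Jaccard and the square-rooted base-2 Jensen–Shannon divergence
are available), classical PCoA, and one-way PERMANOVA / ANOSIM per factor
(inoculum; dpr). If the host drives assembly, dpr should explain far more
variance than the inoculum on polyps, while on tubes the two factors should
be comparable.

PERMANOVA partitions the total sum of squared dissimilarities
(`SS_total = Σ_{i<j} d²_ij / n`) into within- and between-group components
and forms `F = (SS_B/(k−1)) / (SS_W/(n−k))`; ANOSIM compares mean ranks of
between- versus within-group dissimilarities, `R = (r̄_B − r̄_W)/(M/2)`
with `M = n(n−1)/2` pairs and midranks for ties, the standard
normalization under which perfectly separated groups give `R = 1`.
Significance in both cases comes from whole-sample label permutation:
`p = (1 + #{F* ≥ F}) / (1 + n_perm)`. The default 999 permutations give the
conventional p-resolution floor of 0.001. Both tests accept an explicit
permutation matrix, which makes exhaustive enumeration on small designs
(and hence exact unit tests) possible.

Distances are computed on relative abundances without rarefaction;
richness comparisons use the bias-corrected Chao1 estimator
`S_obs + f₁(f₁−1)/(2(f₂+1))`.

## 2. Who colonizes early, who late?

The succession module reduces the table to a core set: an ASV is kept if
there is at least one recolonization timepoint at which it reaches the
detection floor (default 0.005% relative abundance) in *every* sample of
that timepoint — constant detection, not mere presence. Abundances are then
scaled to [0, 1] per ASV within each display block — the inocula plus one
block per recolonization treatment — so that each taxon's temporal
trajectory is preserved within a treatment while magnitudes become
comparable across taxa. Rows are ordered by average-linkage hierarchical
clustering with optimal leaf ordering (the dendrogram rotation minimizing
the summed distance between adjacent rows), which makes the heatmap order
deterministic. Finally each ASV is classified **early** if its mean scaled
abundance peaks at 2 or 7 dpr and **late** if it peaks at 14 or 28 dpr,
ties breaking toward the earlier timepoint. Published analyses of this
kind involve some visual judgment in that assignment; here the rule is
declared and deterministic, and a user-supplied class table can override
individual calls downstream.

## 3. Do metabolic capabilities track the stage?

Amplicon variants and genomes live at different resolutions, so both are
mapped to 97% identity clusters. Identity is Needleman–Wunsch global
alignment identity (match +1, mismatch −1, gap open −2, gap extend −1)
with the full alignment length — gap columns included — as denominator,
and `N` counting as a mismatch; this is the closest simple declared
semantics to cd-hit-est's global identity. Clustering is greedy and
incremental in cd-hit style: sequences sorted by length (ties
lexicographic by id) either join the first existing representative at ≥97%
identity or found a new cluster. Genome 16S genes are then attached to
*every* cluster whose representative they reach at the threshold; a genome
may match several clusters, and unmatched genomes are reported rather than
dropped.

The projection itself is the pipeline's central arithmetic: a cluster
carries a pathway when at least one assigned genome is predicted (by an
external reconstruction tool such as gapseq; its binary output is an input
here) to encode it, and the **relative cumulative pathway abundance** in a
sample is the summed relative abundance of all carrying clusters. Clusters
with no matched genome contribute to no pathway; the fraction of the
community they represent is reported as `1 − coverage` and never silently
renormalized, so pathway abundances remain fractions of the *whole*
community. A `--consensus`-style majority option exists for multi-genome
clusters; the union rule is the default because the quantity being summed
is "abundance of all bacteria predicted to possess the pathway".

Stage-associated pathways are found by shadow-feature random-forest
selection: samples at 2 and 7 dpr are labelled early, 14 and 28 dpr late;
every pathway gets a value-permuted shadow copy; a random forest with
z-score-scaled permutation importance is fitted; and a pathway scores a
hit whenever it out-ranks the *maximum* shadow importance. Hits accumulate
over iterations and two-sided binomial tests (hit probability ½) at level
α = 0.01, Bonferroni-adjusted across pathways, confirm or reject each
pathway. Two details matter for calibration and were chosen deliberately:

* the shadow pool keeps its full original width even after pathways are
  rejected (rejected pathways keep serving as noise probes), so the
  max-shadow bar does not drop as the candidate set shrinks;
* selection is repeated (default 10 times) with consecutive seeds and only
  pathways confirmed in **every** repeat enter the `consistent_set`.

The selected set is evaluated by stratified k-fold (default k = 5)
random-forest classification accuracy, pooled over folds. Per-pathway
importances are normalized to a per-repeat maximum of 1 and averaged, and
subsystem scores are the sums of these importances over confirmed pathways
(threshold 0.5 for display) — the normalization gives that threshold a
defined scale, since raw permutation importances are not comparable across
runs. Early/late enrichment is summarized as
`log2((mean_late + ε)/(mean_early + ε))`, so early-enriched pathways are
negative; the direction is recorded in the output.

# The synthetic experiment generator

Real recolonization data require deposited reads, assembled genomes and an
external pathway predictor, none of which a test suite should depend on.
The generator (`truth_spec()` + `simulate_recolonization()`) therefore
emulates the study design with known ground truth:

* **Design**: 3 inocula × 4 timepoints × 5 replicates × 2 substrates plus
  one sample per inoculum homogenate (123 samples), sequencing depth
  20,000.
* **Taxa**: 24 early + 24 late colonizers shared by all inocula, plus 4
  taxa unique to each inoculum. Early taxa peak at 2 or 7 dpr with a
  geometric decay of their share away from the peak; late taxa are their
  time-reflected mirrors. Class budgets on the host substrate are fixed at
  (0.72, 0.60, 0.36, 0.24) early versus (0.24, 0.36, 0.60, 0.72) late, so
  the early class holds 3× the late share at 2 dpr and vice versa at
  28 dpr; inoculum-specific taxa keep a constant 4%.
* **Host reset vs inoculum persistence**: polyp trajectories are identical
  across inocula (the host imposes the succession), while tube
  trajectories interpolate between the inoculum pool and the succession
  profile with mixing weights (0.45, 0.60, 0.75, 0.85) over 2/7/14/28 dpr.
  Those weights were set so the default experiment reproduces the
  qualitative structure expected of an inert substrate — inoculum and time
  explaining comparable variance (synthetic Bray–Curtis R² ≈ 0.36 vs
  0.37) — while the host shows time dominance (≈ 0.67 vs 0.09).
* **Counts**: Dirichlet-multinomial around the expected composition with
  concentration 200, emulating replicate-level overdispersion. No
  published dispersion estimate exists for this design; the value is a
  fixture choice giving visible but not overwhelming replicate noise.
* **Pathways**: 100 pathways, 10% planted as stage-associated (half early,
  half late; mapped to polysaccharide-degradation and nitrogen/sulfur
  subsystems respectively). Presence is Bernoulli with base probability
  0.3, pulled toward certainty for the matching class:
  `p = 0.3 + effect_size × 0.7` (effect size 0.6 by default). Because the
  late taxa mirror the early taxa, each neutral pathway is carried
  *pairwise* (a late taxon carries it exactly when its early partner
  does), which makes neutral pathways exactly stage-balanced in
  expectation. Without that coupling, any random carriage pattern across a
  deterministically shifting community is weak-but-real signal, and
  false-confirmation rates of the selection stage would be
  uninterpretable.
* **Sequences**: per-cluster families descend from ancestor sequences
  (members mutated at rate 1 − within-identity, ancestors from a root at
  1 − between-identity); ancestors double as synthetic genome 16S genes,
  so the planted ASV→cluster→genome chain is fully known.

What the generator deliberately does **not** emulate: sequencing error,
chimeras, compositional zero-inflation beyond the multinomial, phylogenetic
correlation between taxa, pathway correlation within genomes beyond class
structure, and inter-genome 16S copy-number variation. Passing tests on
synthetic data therefore demonstrate that the pipeline recovers planted
signal of realistic magnitude under replicate noise — not that any
particular real dataset will show the same effect sizes.

# Numerical choices and degenerate inputs

* Permutation p-values use the `(1 + hits)/(1 + n)` convention and a
  `1e-12` tie tolerance on statistic comparisons; both tests accept an
  explicit permutation matrix for exhaustive enumeration.
* PCoA retains eigenvalues above `max(|λ|)·1e-9`; an all-zero distance
  matrix returns all-zero coordinates; requesting more axes than positive
  eigenvalues truncates with a warning.
* Bray–Curtis is not a metric; only symmetry, range and a zero diagonal
  are asserted, never the triangle inequality.
* Identical-value inputs to the Kruskal–Wallis test return H = 0, p = 1
  (the tie-corrected statistic is undefined there).
* Block scaling leaves all-zero sub-rows at zero; the colonizer
  classification excludes (with a warning) ASVs absent from every
  recolonization sample.
* Greedy clustering sorts by length, then id, which makes the result
  invariant to input file order. Cluster memberships near the 97%
  boundary are still sensitive to the identity definition itself; the
  word-filter heuristics of cd-hit-est are not reproduced, so boundary
  assignments may differ from that tool's.
* `N` bases never count as matches, including `N`–`N` pairs.
* The alignment identity fast path computes matches and alignment length
  from alignment statistics; sequences containing `N` take the explicit
  aligned-string path. Both give identical results by construction and by
  test.
* Selection requires ≥4 samples per class; cross-validation requires every
  class to be at least as large as k.

# Problem sizes

Unit and acceptance tests run entirely on generated data: the default
123 × 60 experiment with 100 pathways, sequence families of 4–40 members
at lengths 250–1000 nt, exhaustive permutation checks at n ≤ 7, a
1000-replicate type-I-error simulation at n = 12, and 20 label-permutation
trials of the repeated selection at its default 10 repeats. These sizes
were chosen to exercise every code path at full statistical defaults while
keeping a complete run of the suite in the minutes range.

# Known limitations

* One-way PERMANOVA/ANOSIM only; the two experimental factors are tested
  in separate one-way runs, not jointly or stratified.
* UniFrac distances are out of scope (no phylogeny is built here).
* The early/late rule is a declared simplification of a partly manual
  published procedure; it is overridable but not "the" published
  assignment.
* gapseq (or any pathway predictor) is consumed, never executed; pathway
  presence quality is inherited from its input.
* The importance scale behind the subsystem threshold of 0.5 is the
  package's declared normalization (per-repeat max = 1); other Boruta
  implementations report different scales, so the threshold is meaningful
  only relative to this one.
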