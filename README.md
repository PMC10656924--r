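# recolonizr

Analysis toolkit for bacterial **recolonization time series**: experiments
in which germfree hosts (e.g. antibiotic-cleared *Nematostella vectensis*
polyps) and inert control substrates (silicone tubes) are recolonized with
source communities ("inocula") from different host life stages — larvae
(`bL`), juveniles (`bJ`) and adults (`bA`) — and sampled at 2, 7, 14 and 28
days post recolonization (dpr). The central questions the package
addresses:

* Is community reassembly on the host **deterministic** (time-driven,
  independent of the inoculum), while inert surfaces retain their inoculum's
  identity?
* Which taxa are **early** vs **late colonizers**?
* Do the **metabolic capabilities** of the community track colonization
  stage (e.g. polysaccharide/chitin degradation early; nitrite/sulfide
  oxidation late)?

## What it computes

| Stage | Functions | Method |
|---|---|---|
| IO / validation | `read_community_table`, `read_fasta`, `read_pathway_presence`, `validate_inputs` | TSV/FASTA with strict schema checks |
| Beta diversity | `distance_matrix`, `pcoa`, `permanova`, `pairwise_permanova`, `anosim`, `chao1`, `kruskal_wallis` | Bray–Curtis / Jaccard / binary Jaccard / Jensen–Shannon; classical PCoA; seeded permutation tests with BH correction |
| Succession | `filter_core_asvs`, `scale_blocks`, `order_rows`, `classify_colonizers` | core-ASV detection filter (0.005% floor), per-treatment 0–1 scaling, average-linkage clustering with optimal leaf ordering, peak-timepoint early/late rule |
| Genome matching | `global_identity`, `greedy_cluster`, `assign_genomes` | Needleman–Wunsch global identity; cd-hit-style greedy 97% clustering; genome 16S assignment |
| Pathway projection | `aggregate_to_clusters`, `project_pathways`, `pathway_timecourse` | relative cumulative pathway abundance: for each pathway, the summed relative abundance of all clusters whose matched genomes encode it, A(p, s) = Σ_{c ∋ p} x_c(s) |
| Feature selection | `label_stages`, `boruta_select`, `repeated_selection`, `cv_accuracy`, `subsystem_scores`, `early_late_lfc` | shadow-feature random-forest (Boruta-style) selection of stage-associated pathways, repeated-run consistency, stratified k-fold accuracy, subsystem importance sums |
| Synthetic data | `truth_spec`, `simulate_recolonization`, `generate_sequences` | Dirichlet–multinomial recolonization experiments with planted colonizer classes, pathway–stage associations and sequence clusters |
| Orchestration | `run_config`, `run_pipeline` | end-to-end run with JSON manifest (also `inst/scripts/pipeline.R`) |

## Worked example

```r
library(recolonizr)

spec <- truth_spec(seed = 1)            # 60 taxa, 100 pathways, planted truth
sim  <- simulate_recolonization(spec)   # 123 samples x 60 taxa
rel  <- relative_abundance(sim$community)
meta <- sim$community$meta

polyp <- !is.na(meta$substrate) & meta$substrate == "polyp" &
  meta$timepoint != "inoculum"
d <- distance_matrix(rel[polyp, ], "bray_curtis")
permanova(d, meta$timepoint[polyp], 999, seed = 1)
#> permanova: statistic = 37.83, R2 = 0.6696, p = 0.001 (999 permutations)
permanova(d, meta$inoculum[polyp], 999, seed = 1)
#> permanova: statistic = 2.81, R2 = 0.08975, p = 0.006 (999 permutations)

prof <- succession_analysis(sim$community, "polyp")
table(prof$class_of)
#> early  late
#>    24    24
```

Time explains ~67% of the variance on the host while the inoculum explains
~9% — the host "resets" whatever community it receives onto one
deterministic succession. On the tube substrate the two factors come out
comparable (~0.37 vs ~0.36). The succession profile recovers the planted
early/late colonizer classes.

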