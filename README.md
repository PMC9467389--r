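# viromeAF

Analysis toolkit for gut **virome signals in atrial fibrillation (AF)**.
Shotgun fecal metagenomes contain a viral fraction — mostly bacteriophages
plus vertebrate-infecting viruses — whose composition shifts with disease.
`viromeAF` implements the full analysis chain used to characterize such
shifts in a case-control AF cohort and to ask whether viral taxa predict
arrhythmia recurrence after catheter ablation:

1. **Abundance profiling.** Contig read counts are filtered (length
   > 1,000 bp), normalized to RPKM
   (`reads / (length/10³) / (total mapped/10⁶)`), averaged per virus, and
   column-normalized to relative abundances; host-class (vertebrate vs phage)
   and lysogenic-phage proportions are summarized from taxonomy/marker flags.
2. **Diversity.** Per-sample richness, Shannon `H = −Σ p ln p`, Simpson
   `D = 1 − Σ p²`, Pielou `J = H / ln S`, Chao1 `S + F₁²/(2F₂)`; sample
   accumulation curves; Bray–Curtis `Σ|x−y| / Σ(x+y)` with NMDS ordination
   (Kruskal stress-1); Wilcoxon rank-sum group contrasts and
   confounder-adjusted (age, sex, BMI, HTN, T2DM, TC, medication) linear
   models.
3. **Differential abundance.** A negative-binomial Wald test in the DESeq
   mould (median-of-ratios size factors, method-of-moments dispersion), with
   the strict effect filter `q < 0.05` and `|log₂FC| > 2`; an
   empirical-Bayes moderated t-test for log-scale functional profiles;
   Benjamini–Hochberg control throughout.
4. **Trans-kingdom networks.** Spearman co-occurrence among the top 100
   viruses and top 100 bacterial species per group, edges at `|ρ| ≥ 0.7` and
   `q < 0.05`; density, betweenness, virus–bacteria linkage counts,
   **natural connectivity** `ln((1/N) Σ e^{λᵢ})` over adjacency eigenvalues,
   **degree entropy** (Shannon entropy of the degree distribution), and
   random-node-removal robustness curves; Cytoscape-ready exports.
5. **Recurrence risk score.** Wilcoxon screening (q < 0.05) of viral taxa
   against recurrence, LASSO-penalized Cox selection with cross-validated λ
   (1-SE rule), a linear viral score, nearest-neighbour (Heagerty–Lumley–Pepe)
   time-dependent ROC with a Youden cutoff, Kaplan–Meier/log-rank
   stratification, multivariate Cox adjustment with HR and 95 % CI, and
   bootstrap optimism-corrected internal validation.

A synthetic cohort generator (`generate_cohort()`) emulates the study design
— 50 controls + 50 AF cases (30 paroxysmal, 12 persistent < 12 m,
8 persistent ≥ 12 m), 40 ablated patients with follow-up, heavy-tailed
Dirichlet-multinomial abundances at 3–5 × 10⁶ viral reads per sample, an AF
evenness increase, Gaussian-copula correlation blocks that are tight in
controls and attenuated in AF, and survival driven by a known linear
combination of viral taxa — so every stage is testable without sequencing
data.

## Worked example

```r
library(viromeAF)

ch <- generate_cohort(cohort_config(seed = 42))
ch
#> <synthetic_cohort> 100 samples (50 CTR / 50 AF), 500 viruses, 500 bacteria
#>   ablated: 40, recurrences: 16, planted pairs: 30

rel   <- to_relative(ch$virus_counts)
alpha <- alpha_diversity(rel, counts = ch$virus_counts)
af    <- ch$metadata$group != "CTR"
wilcoxon_rank_sum(alpha$shannon[!af], alpha$shannon[af])$p.value
#> 7.07e-18        # AF viral Shannon diversity is elevated (4.04 -> 5.19)

# control-group virus-bacteria co-occurrence network
ctr <- ch$metadata$sample[!af]
vv  <- abundance_matrix(unclass(rel)[, ctr], kind = "relative", kingdom = "virus")
bb  <- abundance_matrix(unclass(to_relative(ch$bacteria_counts))[, ctr],
                        kind = "relative", kingdom = "bacteria")
top <- select_top_taxa(vv, bb, k = 100)
sub <- rbind(unclass(vv)[top$taxon[top$kingdom == "virus"], ],
             unclass(bb)[top$taxon[top$kingdom == "bacteria"], ])
network_metrics(build_network(spearman_matrix(sub), top))
#> <network_metrics> 16 nodes, 56 edges, 30 linkages
#>   density 0.4667 | natural connectivity 4.9229 | degree entropy 0.0000
```

The 16 connected nodes are exactly the planted block taxa: all 30 planted
virus–bacteria pairs pass the `|ρ| ≥ 0.7`, `q < 0.05` edge cutoffs in
controls (in the AF samples, where the same blocks are attenuated to
ρ ≈ 0.3, none do).

Fitting the recurrence risk model on a 200-patient ablated cohort with three
causal taxa:

```r
chr <- generate_cohort(cohort_config(
  n_control = 5, n_paf = 200, n_psaf_short = 2, n_psaf_long = 2,
  n_ablated = 200, n_viruses = 200, n_bacteria = 25, seed = 42))
rel <- t(unclass(to_relative(chr$virus_counts))[, chr$survival$sample])
fit <- viral_risk(rel, chr$survival$time_months, chr$survival$event, seed = 42)
fit
#> <viral_risk> 3 taxa selected (lambda = 0.07084)
#>   12-month NNE AUC 0.908 | cutoff 0.0998 | high risk: 84 / 200
#>   log-rank p = 8.191e-25
coef(fit)
#> Virus_0001 Virus_0004 Virus_0007
#>  0.6902000 -0.7424688  0.5886884
```

The three selected taxa are the three planted causal viruses, with
coefficient signs matching the planted log-hazard weights (+1.2, −1.0, +0.9).

`run_pipeline(cohort, outdir)` chains all stages, writes every table as TSV
and finishes with a manifest recording the configuration, seeds and MD5
checksum of each output; identical input + config + seed reproduces the
manifest byte for byte.

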