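---
title: "Methods: gut virome profiling, trans-kingdom networks, and recurrence risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gut virome profiling, trans-kingdom networks, and recurrence risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromeAF)
```

`viromeAF` analyses the viral fraction of bulk fecal shotgun metagenomes in
an atrial fibrillation (AF) case-control design. This vignette documents the
models and estimators, the tunable parameters and their defaults, the
synthetic cohort the package is validated on, and the numerical and design
choices a maintainer should know about.

## Abundance model

The pipeline starts from contig-level mapped read counts. Contigs of at most
1,000 bp are discarded (`filter_contigs()`, strict inequality: a 1,000 bp
contig is dropped) because short contigs carry little signal for viral
sequence prediction. Coverage is expressed as RPKM,

$$\mathrm{RPKM}_{cs} = \frac{r_{cs}}{(L_c/10^3)\,(N_s/10^6)},$$

with $r_{cs}$ reads mapped to contig $c$ in sample $s$, $L_c$ the contig
length and $N_s$ the sample's total mapped reads. RPKM is invariant to
proportional scaling of reads and totals. A virus's abundance is the
*unweighted arithmetic mean* RPKM over its assigned contigs — length
weighting is already inside RPKM; the alternative (length-weighted mean)
would double-count contig length. Relative abundances are column
normalizations *within kingdom*; whether virus and bacteria should be
normalized jointly is a genuinely open choice, and within-kingdom is the
default because the two communities are profiled from different read pools.

A phage species is called temperate when **any** of its three
temperate-evidence marker flags (reference-genome, prophage-gene,
curated-protein) is set: each flag is an independent evidence source, so OR
rather than AND is the common-practice reading. The per-sample lysogenic
proportion divides temperate-phage abundance by *phage* abundance (not the
whole virome), since lysogeny is a property of the phage community; the
denominator is configurable.

## Diversity

Alpha indices are computed from relative abundances: Shannon in natural log
(hence Pielou $J = H/\ln S$ is dimensionless in $[0,1]$), Simpson as
$1-\sum p^2$, and Chao1 from the *count* matrix
($S + F_1^2/2F_2$, or $S + F_1(F_1-1)/2$ when no doubletons exist) because
singletons and doubletons are undefined on normalized data. Beta diversity
is Bray–Curtis, embedded by non-metric multidimensional scaling (Kruskal
stress-1, `vegan::metaMDS` engine) with the first configuration from
classical metric scaling and up to `n_restarts` (default 20) random
restarts; the seed fixes the restart stream, so ordinations are
reproducible. Group separation is tested per NMDS axis with the Wilcoxon
rank-sum test — mirroring a per-axis reporting style — rather than with
PERMANOVA, which is out of scope. Axis p-values are reported raw; whether to
BH-adjust the two axes is left to the reader since the axes are few and not
independent.

The Wilcoxon implementation uses the exact null distribution when the
combined sample size is at most 12 and there are no ties, and the normal
approximation with tie and continuity correction otherwise; two identical
groups return $p = 1$.

Confounder adjustment regresses each index on the AF indicator plus age,
sex, BMI, hypertension, diabetes, total cholesterol and medication by OLS;
the design matrix is checked for rank deficiency and the collinear columns
are named in the error, since silently dropping a confounder would change
the estimand.

Rarefaction follows repeated random sampling of the *patients* (default 100
draws, with replacement) and reports the mean number of distinct features
against the number of samples drawn; a without-replacement variant exists
for combinatorial checks.

## Differential abundance

`nb_wald_test()` is a deliberately simple negative-binomial Wald test:
median-of-ratios size factors (rescaled to geometric mean 1), a per-feature
method-of-moments dispersion $\hat\alpha = \max((s^2 - \bar\mu\overline{1/s_j})/\bar\mu^2, 10^{-8})$
pooled within groups, and a delta-method SE for the log2 fold change under
$\mathrm{Var}(K) = \mu + \alpha\mu^2$. There is **no dispersion shrinkage
trend**: the estimator does not claim DESeq2 parity, and its null behaviour
is therefore checked directly — under an NB null at $n = 25$ per group the
empirical type-I error at nominal 0.05 must stay within $[0.03, 0.08]$
(enforced in the test suite). The 0.5 pseudo-count enters only when a group
mean is exactly zero, where the fold change is otherwise undefined.
Features are tested independently at each taxonomic rank with BH control
within rank, and the effect filter is strict: $q < 0.05$ *and*
$|\log_2 FC| > 2$.

Functional profiles arrive on a log scale and are tested with a moderated
t: per-feature variances are shrunk toward a prior $(d_0, s_0^2)$ estimated
by moment-matching the log sample variances to a scaled log-F distribution
($\mathrm{var}(\log s^2) = \psi'(d_g/2) + \psi'(d_0/2)$, solved by
`uniroot` on the trigamma), with $\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0+d_g)$
and $d_0 + d_g$ degrees of freedom. When the observed spread of log
variances does not exceed the sampling spread, $d_0 = \infty$ and all
features share $s_0^2$. The suite cross-checks the prior and posterior
variances against `limma::squeezeVar`.

## Trans-kingdom co-occurrence networks

Per group, the top 100 viruses and top 100 bacterial species by mean
relative abundance are selected (boundary ties broken by lexicographic
taxon id, so selection is deterministic). All $\binom{200}{2}$ Spearman
correlations are computed with average ranks; p-values use the t
approximation with $n-2$ df, and BH adjustment treats **all pairs as one
family** — intra- and inter-kingdom together — the conservative reading of a
single multiple-testing correction. Edges require $|\rho| \ge 0.7$ and
$q < 0.05$; the magnitude cutoff is inclusive and the significance cutoff
exclusive, matching how such thresholds are printed. Isolated nodes are
dropped, so the node count reflects connected taxa (configurable).

Metrics: density $2E/(N(N-1))$; *linkages* are edges joining a virus to a
bacterium — distinct from the total edge count, which also includes
within-kingdom edges; betweenness by unweighted shortest-path counting
(igraph); **natural connectivity**
$\bar\lambda = \ln\!\big(\tfrac1N\sum_i e^{\lambda_i}\big)$ over the
adjacency eigenvalues (natural log, $1/N$ normalization, whole graph — the
standard spectral form; computed with a max-shift to avoid overflow), which
is non-negative by Jensen's inequality and 0 for an empty graph; and
**degree entropy**, the plug-in Shannon entropy (nats) of the empirical
node-degree distribution — zero iff all degrees are equal, at most the log
of the number of distinct degrees. Robustness curves remove a fraction of
nodes uniformly at random (without replacement, not targeted), recompute
natural connectivity on the induced subgraph and average over `n_reps`
(default 100) repetitions; the fraction-0 point is the intact value and the
seed fixes the removal stream.

## Recurrence risk model

`viral_risk()` is the package's model-fitting function (classed S3 object
with `print`, `coef`, `predict`, `summary`). Features are
$z$-scored $\log_{10}(\text{relative abundance} + 10^{-6})$ — the pseudo-count
sits below any observed non-zero relative abundance at the simulated
library sizes, and both it and the transform are configurable since the
scale fed to a penalized Cox fit is a genuine design choice. Candidates are
screened per taxon by Wilcoxon rank-sum between recurrence groups at
$q < 0.05$ (strict). The LASSO-penalized Cox path (glmnet; Breslow ties
inside coordinate descent, warm starts) is tuned by 10-fold
cross-validation on held-out partial-likelihood deviance with folds
stratified on the event indicator; the default λ is the **1-SE** choice
(the sparser model), with `lambda = "min"` available. A single surviving
candidate is fit by unpenalized univariate Cox — there is nothing to
select. The viral score is the exact linear combination
$\sum_j \hat\beta_j z_{ij}$.

The score is evaluated with the Heagerty–Lumley–Pepe nearest-neighbour
time-dependent ROC at a 12-month horizon (a blanking-period-aware,
clinically standard horizon; configurable): conditional survival
$S(t\mid X{=}x)$ is a Kaplan–Meier fit over a marker-percentile window of
half-width $0.25\,n^{-0.2}$, giving monotone TPR/FPR sweeps and a trapezoid
AUC. The cutoff maximizes the Youden index on that curve (ties resolved
toward the score median; a flat curve falls back to the median with a
warning). Strata are compared by Kaplan–Meier/log-rank, and the score's
independence from clinical covariates is assessed by multivariate Cox
(Efron ties) reporting $HR = e^\beta$ with CI $e^{\beta \pm 1.96\,SE}$ and
Harrell's C. Internal validation is Harrell's bootstrap optimism
correction — the *entire* pipeline (screen → LASSO → score) refit on each
resample, the optimism averaged and subtracted from the apparent AUC and
C-index; this is a documented substitute for study-specific internal
validation procedures that are not reproducible from the outside.

## The synthetic cohort

`generate_cohort()` draws the validation cohort. Defaults mirror the study
design: 50 controls, 30 paroxysmal AF, 12 persistent < 12 months,
8 persistent ≥ 12 months; 40 ablated patients; viral library sizes uniform
on $3{-}5\times10^6$ reads (bacterial $4{-}5\times10^7$); per-taxon base
log-abundances $N(0, 2^2)$ sorted so that taxon index equals abundance
rank; per-sample log fluctuations of SD 1; Dirichlet-multinomial sampling
with total concentration $10^4$; uniform administrative censoring on
$(0, 36]$ months (giving a mean follow-up near 16 months and roughly 40 %
events at the default baseline hazard 0.03 month⁻¹).

Three planted structures drive the recovery tests:

* **Evenness.** A positive `evenness_shift` (default 0.5) scales the AF
  Dirichlet concentration by $1+\text{shift}$ *and* tempers the AF
  log-abundance profile by $1/(1+\text{shift})$. Concentration alone only
  moves richness — the dominant taxa that control Shannon/Simpson/Pielou are
  sampled almost noiselessly at any concentration compatible with accurate
  correlation planting — whereas tempering genuinely flattens the heavy
  tail. Tempering is a per-taxon monotone transform, so it cannot disturb
  planted rank correlations.
* **Correlation blocks.** Block members load on a shared per-sample Gaussian
  factor with the Spearman target converted to a latent Pearson correlation
  by $r = 2\sin(\pi\rho_s/6)$; negative targets give bacteria members
  negative loadings. Because each kingdom's relative abundances share a
  fluctuating per-sample total, the closure term $\log S_s$ would otherwise
  attenuate trans-kingdom rank correlations by $\approx 1/(1+\sigma^2\,\Sigma p^2)$;
  the generator adds the realized kingdom log-total back onto block members
  before normalization, after which the achieved Spearman of planted pairs
  is within 0.02 of target at $n = 500$ per group (tested at tolerance
  0.05). Default blocks sit at abundance ranks 11–20 — well inside the
  top-100 selection, but off the very top ranks where residual closure
  distortion is largest. Controls get $\rho_s = 0.85$, AF 0.30.
* **Survival.** Recurrence times are exponential with rate
  $h_0 \exp(\sum_v \beta_v z_v)$, $z_v$ the standardized log relative
  abundance of causal virus $v$; defaults plant $\beta = (+1.2, -1.0, +0.9)$
  on abundance ranks 1, 4, 7.

What the generator does *not* emulate: real taxonomies and phylogeny,
sequencing error, batch effects, compositional bias between kingdoms beyond
the closure itself, non-exponential hazards, and informative censoring.
Passing recovery tests therefore shows the estimators are correct under the
assumed data-generating process, not that the biological findings replicate
on real cohorts.

At the study's own scale (40 ablated patients) single-taxon Wilcoxon
screening at $q<0.05$ retains nothing under realistic effect sizes, so the
pipeline treats an empty screen as a logged skip of the risk stage, and the
risk-recovery guarantees are stated — and tested — at $n = 200$ ablated
patients, where screening, LASSO selection (≥ 2 of 3 causal taxa in ≥ 80 %
of seeds) and discrimination (mean 12-month NNE AUC ≥ 0.75) are all
reliable.

## Numerical choices and degenerate inputs

* All randomness flows from a single seed; stage seeds are derived offsets,
  and RNG state is restored after every seeded call, so package functions
  never perturb the session stream. Identical input + config + seed gives a
  byte-identical pipeline manifest (MD5 per output file).
* Natural connectivity uses a max-eigenvalue shift before exponentiation;
  dispersion estimates are floored at $10^{-8}$; saturated Spearman
  correlations are pulled to $1-10^{-12}$ before the t transform;
  `cor.test` p-values are capped at 1.
* Empty samples yield missing diversity indices; all-zero relative columns
  stay zero with a warning; all-zero count features are excluded from
  testing and reported; constant features are excluded from correlation with
  a warning; two all-zero profiles get Bray–Curtis 0 with a warning.
* Fold sizes in cross-validation shrink (with a warning) when events are
  fewer than folds; bootstrap resamples without events are redrawn.
* Problem sizes used by the test suite and acceptance script — 2,000-feature
  null panels at 25 samples per group, 50-seed NNE null, 100 Cox coverage
  simulations, 20-seed risk recovery at 200 patients, and one full
  study-scale pipeline run — were chosen to keep Monte-Carlo error well
  inside each asserted tolerance.
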