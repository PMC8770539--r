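---
title: "Methods: epi-driver discovery and methylation-based tissue of origin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epi-driver discovery and methylation-based tissue of origin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`methorigin` integrates two omics layers measured on paired tumor/normal
cohorts spanning several cancer types: CpG methylation beta values
(HM450-style arrays, probes × samples, values in [0, 1]) and RNA-seq read
counts (genes × samples). Its two deliverables are

1. **epi-driver genes** — genes whose aberrant expression is plausibly
   driven by epigenetic alteration. A gene is called an epi-driver when it
   is (i) differentially expressed between tumor and matched normal
   tissue, (ii) a *key gene* in at least one directed biological network
   (metabolic or protein–protein interaction), and (iii) associated with
   at least one significantly methylation-correlated CpG in its promoter
   windows or gene body; and
2. **a tissue-of-origin classifier** — a small panel of tissue-specific
   CpGs selected from the epi-driver genes, used to train a one-vs-rest
   random-forest classifier whose intended application is tracing the
   primary site of carcinoma of unknown primary (CUP).

## Differential layers

Differential methylation is a per-probe two-sided Mann–Whitney U test of
tumor versus normal beta values; a probe is called when the BH-adjusted p
is below 0.05 **and** the tumor-minus-normal mean difference exceeds 0.2
in absolute value (so `hyper` means hypermethylated in tumor). The null is
enumerated exactly (via the Wilcoxon distribution) whenever there are no
ties and both groups have at most 25 samples; otherwise a tie-corrected
normal approximation with continuity correction is used. The switch point
is a numerical choice: exact enumeration at these sizes is cheap and
removes approximation error exactly where small cohorts make it matter.

Differential expression is a moderated two-sample t-test on
`log2(CPM + 1)`: per-gene pooled variances are shrunk halfway toward the
mean pooled variance across genes (weight 0.5), a deliberately simple
empirical-Bayes stabiliser that keeps the test self-contained and exactly
reproducible. Genes are called at BH q < 0.05 and |log2FC| > 2. Genes with
zero counts throughout are reported with `log2fc = 0, p = 1` rather than
erroring, so degenerate inputs cannot abort a pipeline run.

## Networks and the Score_A statistic

The cancer co-expression network is built from tumor samples only:
adjacency is `|Pearson r|` of `log2(CPM + 1)` with an edge when
`|r| >= tau` (default 0.6); modules are average-linkage clusters of the
distance `1 − |r|` cut at height 0.3, discarding modules below 10 genes. A
module is *tumor-specific* when the per-sample mean of its members'
z-scored expression differs between tumor and normal samples (rank-sum,
BH q < 0.05); any shift direction qualifies. The defaults give, on the
synthetic data, modules that recover planted co-expressed blocks exactly;
they are exposed because real data typically need a gentler threshold.

Two directed networks feed the importance score: the metabolic network
(gene A → gene B when a product metabolite of a reaction catalysed by A is
a substrate of a reaction catalysed by B) and the PPI network (undirected
edges with interaction weight ≥ 0.4, expanded to both directions so that
out-neighborhoods are defined uniformly). For each gene A with
out-neighbors,

```
Score_A = |AUC − 0.5| × log2( (C_in / C_all) / (N_in / N_all) )
```

where `C_all` is A's out-degree, `C_in` counts out-neighbors inside
tumor-specific modules, `N_all` is the number of genes in the
co-expression network and `N_in` the number in tumor-specific modules. The
AUC term is not fully pinned down by its originating description; this
package operationalises it as a rank statistic: the probability that a
uniformly random out-neighbor of A has higher `|r|` with A (tumor samples)
than a uniformly random non-neighbor, ties counted 1/2. That reading makes
the term exactly the degree to which A is more co-expressed with its
downstream genes than with the background, is testable against a
brute-force all-pairs oracle, and degenerates gracefully (AUC = 0.5, hence
Score_A = 0) when A's neighborhood is uninformative. Genes with
`C_in = 0` receive a `−Inf` sentinel and can never be key genes. Key genes
are the top 10% of finite scores (configurable); a quantile was preferred
over a permutation cutoff because it is deterministic and the downstream
call intersects with two other evidence layers anyway. The two networks
are combined by union (either network may nominate a key gene);
intersection is available as an option.

## Region windows and methylation–expression association

Probes are annotated to genes strand-awarely: `upstream_1500` spans
1–1500 bp 5′ of the TSS (the TSS base itself is excluded),
`downstream_1500` spans 0–1500 bp 3′ of the TSS (TSS included), and
`gene_body` is the remainder of the TSS–TES span. The windows are disjoint
within a gene; a probe may annotate to several genes; probes hitting no
window are intergenic (IGR). The boundary convention fixes the inherent
ambiguity of a "0–1500 bp" phrasing deterministically and is pinned by
unit tests.

For each (probe, gene, region) the association model is ordinary least
squares of `log2(CPM + 1)` on beta across tumor samples, either plain or
with the cancer type as a categorical covariate (`type_corrected`). The
slope's t statistic gives the p-value; BH runs within each
(region, model) family, matching the per-window reporting of the
gene-level counts. Cancer-type correction exists because class-level mean
shifts present in both omics (different tissues having both different
methylomes and transcriptomes) masquerade as within-tumor coupling in the
plain model; the synthetic generator plants exactly this artifact
(`confound_fraction`) and the corrected model removes it.

The permutation null uses the whole-window variant: per gene, the
methylation profile is the mean beta over the gene's assigned probes; each
of the shuffles permutes the sample-column assignment of that matrix while
expression and class labels stay fixed, and the type-corrected,
BH-adjusted count of significant genes is recorded. Implementation note:
both models reduce to within-group centring (Frisch–Waugh), so a shuffle
costs a handful of vectorised row operations rather than per-gene `lm()`
calls.

## Marker selection

Candidate probes are restricted to epi-driver genes. Stage one is a
one-vs-rest Welch t-test per (probe, class) over tumor samples with BH
within class, gated by the pooled standard deviation of the probe across
all tumor samples (> 0.2). "SD of what" is underdetermined in the
field's descriptions; the pooled reading was chosen because a probe that
separates one class from the rest necessarily has high pooled SD on the
beta scale, making 0.2 a meaningful gate, and the per-class variant is a
configuration switch. Welch rather than pooled-variance t because
one-vs-rest groups are strongly unbalanced. BH is the default adjustment
(Bonferroni available).

Stage two ranks passing probes by gradient-boosted Shapley attribution: a
multiclass xgboost ensemble (200 rounds, depth 3, learning rate 0.1,
fixed seed, single thread) with exact tree-Shapley contributions
(`predcontrib`); importance is the mean |attribution| over samples and
classes, ties broken by probe id. Panel size then comes from the plateau
rule: `cumulative_accuracy[k]` is the 10-fold cross-validated accuracy of
a random forest on the top-k probes (folds stratified and shared across k
so increments reflect the added probe), and `selected_k` is the smallest k
whose next `m = 2` increments each improve accuracy by less than
`eps = 0.005`; if the rule never fires the full length K is kept.

## Origin classifier

The cohort is split 7:3 per class with rounding toward training; matched
tumor/normal pairs are one unit and never straddle the split. Each class's
binary problem is balanced by under-sampling the rest classes evenly
(remainder slots by seeded draw). The forest is an in-package bagged CART
ensemble built on `rpart`, because the out-of-bag hyperparameter grid
spans both the Gini and the entropy (information) splitting criteria and
the established R forests expose only Gini. Design choices that matter:

* every tree sees a bootstrap sample of the rows and, by default, all
  panel probes (`mtry` remains available for wide inputs). With small
  panels a random feature subspace is actively harmful: trees blinded to
  a class's own marker see that class's positives as unmethylated
  everywhere and claim the shared all-low signature — the signature that
  genuinely belongs to marker-silent tumors of the heterogeneous class —
  for their own class, scattering exactly the samples that are hardest
  to call. Ensemble diversity comes from the bootstrap;
* trees grow to single-observation leaves (`minsplit = 2`,
  `minbucket = 1`, `cp = 0`): a class pattern carried by one in-bag
  example — a tumor recognisable only through its class's backup marker —
  must still be learnable, and any floor on leaf size structurally
  forbids exactly that split. Two guards keep the deep trees honest.
  Leaf probabilities are Laplace-smoothed,
  `(n_class + 1) / (n_leaf + K)`, so small or genuinely ambiguous leaves
  (marker-silent tumors of two classes share the unmethylated signature)
  contribute graded probabilities instead of hard 0/1 votes. And
  continuous split thresholds are re-centred on the midpoint of the
  node's empirical margin, ignoring one straggler per side: CART places
  a cut immediately next to a boundary observation, so a single aberrant
  value — typically an imputed cell sitting between the unmethylated and
  methylated levels — would otherwise drag the decision boundary to the
  imputation level and misroute every future value in the margin;
* the grid (trees 10–100, criterion gini/entropy) is scored by OOB
  accuracy, fitting the largest forest once per criterion and scoring
  nested tree subsets; ties prefer fewer trees, then gini.

Multi-class prediction renormalises the per-class binary positive
probabilities to sum to one; ties break toward the class with larger
training prevalence, then lexicographically. Evaluation reports per-class
one-vs-rest AUC (rank statistic), per-class OVR accuracy and overall
argmax accuracy, with 95% CIs as `estimate ± 1.96 × SE` where SE comes
from fold-level metrics (cross-validation) or 1,000 stratified bootstrap
resamples (held-out cohorts), clipped to [0, 1]. How the original CIs were
constructed is unreported upstream; both of these are labelled in the
output. Models serialise as versioned, uncompressed RDS so identical
training runs produce identical bytes.

# The synthetic-data generator

The generator (`sim_config()` / `simulate_bundle()`) emulates the study
design: paired tumor/normal samples across 5 classes (40 pairs each),
1,000 probes, 500 genes, and complete ground truth. Its defaults are the
package's reference conditions; the test-suite problem sizes below are
stated as the package's own choices.

* **Beta values** are logit-normal: a per-probe mean in [0.15, 0.85],
  noise of SD 0.05 on the beta scale applied via the delta method on the
  logit scale, clipped to [0.001, 0.999]. Roughly 2% of entries are
  missing at random plus a few probes above 50% missingness, to exercise
  the filter and imputation paths.
* **Counts** are negative binomial (dispersion 0.2) around per-gene log2
  means with a per-sample scale factor.
* **Epi-drivers**: 10 planted genes get a +3 log2 tumor shift and a
  shared per-sample latent factor that couples their expression to one
  promoter probe (negative sign, hypomethylated in tumor by the
  configured delta-beta) and one gene-body probe (positive sign,
  hypermethylated). Loadings are calibrated, with bounded retries, so the
  achieved tumor |correlation| reaches `coupling_r − 0.05`; an
  infeasible request errors instead of silently under-delivering. Each
  driver also drives a module of 12 co-expressed partner genes whose
  tumor shifts alternate up/down across modules — balanced directions
  keep the library composition near-neutral, so planted fold changes
  survive CPM normalisation (a one-sided design silently shrinks every
  planted log2FC by the library-size ratio).
* **Networks**: each desired directed edge is encoded through a dedicated
  shared metabolite, so the derived metabolic network equals the designed
  one; drivers point at all of their partners (plus a downstream chain),
  non-planted genes get three random out-edges, making drivers upstream
  hubs by construction. The PPI list mirrors the hub structure at weight
  0.8 with sub-threshold decoys below 0.4.
* **Confounding**: a fraction of genes receive aligned class-level mean
  shifts in both omics with no within-class coupling — exactly the
  artifact the type-corrected association model must remove.
* **Markers**: six planted tissue-specific CpGs hosted in driver genes —
  two for the first class, one for each other class, own-class tumor mean
  `0.5 + s` versus `0.5 − s` elsewhere with `s = 0.4`. The displacement
  is symmetric about 0.5 because a literal one-sided 0.4 gap with five
  balanced classes yields a pooled SD of ~0.17, below the 0.2 screening
  gate — i.e., such markers could never pass the package's own filter.
  Marker *penetrance* is deliberately partial: the first class's two
  markers are each present in 85% of its tumors — with silences disjoint,
  so each silent tumor is carried by the class's other marker — and the
  first single-marker class is modelled as a strongly heterogeneous
  carcinoma with 70% penetrance, whose silent tumors share the fully
  unmethylated signature. The heterogeneous class's sizeable silent
  population anchors the classifier's interpretation of the unmethylated
  signature; a thinner population (85% penetrance was evaluated) leaves
  that signature contested between classes and degrades both the
  panel-size analysis and held-out accuracy. Marker-silent tumors are a real feature
  of tissue-of-origin panels, and they are what makes a backup marker
  worth carrying: with fully penetrant one-hot markers, any single
  missing class is recoverable by elimination (all markers low), so a
  sixth marker could never improve a classifier and no plateau analysis
  would ever select it.

What the generator does **not** emulate: array chemistry and probe
cross-hybridisation structure, batch effects, tumor purity, copy number,
and library-size artifacts beyond a lognormal scale factor. Passing tests
therefore demonstrate that the algorithms recover planted structure at
realistic effect sizes and noise — not that the thresholds are optimal
for any particular real cohort.

# Numerical choices and degenerate inputs

* KNN imputation measures probe distances as Euclidean over
  pairwise-complete samples, scaled by the shared count; it is computed
  with three cross-products rather than a double loop. Ties in neighbor
  distance break by probe id; a cell with no eligible neighbor falls back
  to the probe mean. Observed cells are never altered. `k = 10` by
  default — the algorithm's originating description names only "KNN".
* Probe filtering attributes each removed probe to the first matching
  rule (XY > SNP > multimap > missingness) so report counts are
  deterministic; the missingness rule is strictly greater than 50%.
* Zero-variance probes are skipped (itemised) in association models;
  constant expression is excluded from correlation with a warning count;
  constant heatmap rows z-score to zero with a warning.
* Fisher overlap tests are one-sided enrichment tails computed from the
  hypergeometric distribution; pairwise class overlaps are BH-adjusted.
* All stochastic stages take explicit seeds; derived seeds are kept below
  2^31. Identical configuration implies bit-identical outputs, which the
  run manifest (MD5 per written file) makes checkable.

# Test-suite problem sizes

Unit tests run on bundles of roughly 150 probes × 48 samples. The
simulation sweep backing the headline checks uses the default conditions
(1,000 probes, 5 × 40 pairs) over 20 seeds; the association-recovery
analysis uses 3 classes × 20 pairs (60 tumors), 500 genes with 20 coupled
ones, and a 100-shuffle permutation null; the confounding analysis uses 2
classes × 40 pairs with 40% of genes confounded; the null-calibration
analysis uses 50 replicates of 1,000 null probes at 10 versus 10 samples.

# Known limitations

* The moderated DE test is a fixed-weight shrinkage, not a full
  empirical-Bayes fit; it is calibrated for the pipeline's gating use,
  not as a general DE method.
* The Score_A AUC construction is one consistent reading of an
  under-specified statistic and is intentionally configurable.
* Whether Table-style performance metrics should come from training CV or
  the held-out split is ambiguous upstream; both are computed and
  labelled (`folds` versus the held-out report).
* The classifier's CIs assume approximate normality of the resampled
  metric; near-perfect AUCs make them conservative after clipping.
* The paired design informs the cohort split only; tests are unpaired, as
  in the methods this package operationalises.
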