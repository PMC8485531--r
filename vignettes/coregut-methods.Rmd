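---
title: "Methods: core indices, indicator screening and stability for gut metastudies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core indices, indicator screening and stability for gut metastudies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coregut` implements a multi-stage analysis of soil invertebrate gut
microbiotas: harmonizing heterogeneous per-experiment 16S count tables,
identifying core taxa with an occupancy-abundance index, screening
pollution-indicator taxa with machine learning and meta-analysis,
quantifying community stability through cohesion, processing HT-qPCR
resistome chips, and scoring host locomotion. This vignette explains the
models and the choices behind them.

## Harmonizing multi-study count tables

Gut amplicon studies differ in primer region, depth and taxonomy
resolution, so cross-study claims are made at a coarse rank (class) on
depth-equalized samples. `rarefy_counts()` subsamples every sample
without replacement (hypergeometric) to a common depth, 2000 reads by
default; samples below the depth are dropped with a message rather than
pooled, the usual minimum-depth filter. `collapse_taxa()` sums counts at
the requested rank and pools taxa whose lineage is empty at that rank
into `unclassified_<parent>` — pooling, not dropping, so the abundance
terms of the core index keep every read. `merge_experiments()` takes the
union of taxa with zero fill; the merge is lossless and order-invariant.

Diversity utilities follow the field's conventions: Shannon on natural
logs, bias-corrected Chao1, Bray-Curtis on post-rarefaction relative
abundances, and a single-factor PERMANOVA (vegan's `adonis2`, 9999
permutations by default) with `p = (1 + #{F* >= F}) / (1 + n_perm)`.

## The core index

For each taxon, `taxon_stats()` computes occupancy `f` (fraction of all
samples with a nonzero count), the number of experiments `n` (out of
`N`) in which it is detected, and its aggregate read count `s` out of
the table total `S`. The core index multiplies the three ingredients:

$$\mathrm{CI} = f \cdot \frac{n}{N} \cdot \frac{s}{S}$$

CI is zero exactly for undetected taxa and strictly increasing in each
ingredient; it rewards taxa that are prevalent within studies,
ubiquitous across studies, and abundant overall. Published variants of
such indices differ in algebraic detail, so `core_index()` accepts a
user-supplied formula; the product form is the default because it is
the simplest monotone combination of the three named quantities.

`normalize_ci()` rescales by the maximum over detected taxa (NorCI), so
the top taxon scores 1 and thresholds live on a 0-1 scale;
sum-normalization is available as an alternative. `classify_taxa()`
applies the thresholds 0.83 and 0.3: core when NorCI >= 0.83, transient
when 0.3 <= NorCI < 0.83, rare otherwise. Both bounds are closed from
below — a taxon exactly at a threshold takes the higher category.
`shared_taxa()` separately reports the taxa detected in every
experiment, the "shared set" of the metastudy.

## The synthetic metastudy generator

All downstream stages are validated on data with known planted
structure. `simulate_metastudy()` draws Dirichlet-multinomial counts
(concentration 200 by default) around class-level expected compositions:
the standard overdispersed compositional model for 16S counts. The
default design emulates a ~400-sample metastudy: 17 experiments, 12
samples per group, 20 classes x 3 genera, library size 2500 rarefied
downstream to 2000.

Planted structure has three levers:

* **Presence is hierarchical.** A class is first present or absent in an
  entire experiment, then per sample. Core classes are ubiquitous
  (1, 1); transient classes occur in every experiment but only 80% of
  samples; rare classes appear in 40% of experiments and 85% of samples
  within those. The experiment-level lever is what keeps rare classes
  out of the shared set, mirroring how real independent studies simply
  fail to report many minor classes.
* **Shares are calibrated to the three-way split.** Nominal per-class
  shares (core 0.1689, transient 0.1114, rare 0.0301, normalized
  internally) were chosen once so the expected realized abundance of
  the three categories lands near 51 / 36 / 14 percent of reads, and so
  the NorCI values of the planted strata sit far from the 0.83 / 0.3
  thresholds (transient classes land near NorCI 0.4, rare near 0.02).
* **Batch effects.** Per-experiment, per-class log-normal multipliers
  (sd 0.15) create the inter-study heterogeneity the meta-analysis must
  absorb. The value is a compromise chosen at design time: large enough
  that experiments differ visibly, small enough that the three equal
  core shares stay within the 0.83 NorCI band of each other with high
  probability (the band requires realized core shares within 17% of one
  another; at sd 0.15 averaged over 12+ experiments the pairwise ratio
  sits about 3 standard deviations inside it).

Pollution enrichment multiplies the indicator class's genera by a fold
change (default 2.5) in Pollution samples before renormalization. One
consequence, deliberate and documented: enrichment moves the indicator
class's CI away from the other core classes, so the partition benchmark
is generated with fold change 1 — the planted partition is the truth of
the *unperturbed* community, and the enrichment is exactly the signal
the indicator screen is asked to find.

What the generator does not emulate: taxonomic misassignment, primer
bias differences between regions, depth gradients within an experiment,
and phylogenetic correlation between classes. Tests passing on this
generator therefore demonstrate correctness of the statistics, not
robustness to every artifact of real amplicon data.

## Indicator screening

`compare_classifiers()` evaluates random forest, SVM and logistic
regression on identical stratified cross-validation folds and ranks
them by out-of-fold AUC. `scan_taxonomic_levels()` collapses the table
to each rank and reports the random-forest out-of-bag error with
default hyperparameters (500 trees, sqrt(p) candidate features per
split) — the level with the lowest OOB error is where the indicator
model is built. `cv_importance()` runs tenfold cross-validation with
five repeats and averages the per-taxon permutation importance (mean
decrease in accuracy) over all 50 fits. `select_indicator()` combines
min-max-normalized importance with occupancy as a product — a
scale-free rule under which a moderately important but ubiquitous genus
can outrank a strong but rarely observed one — and reports each genus's
class so class-level claims are checkable. Ties break
lexicographically. `train_test_predict()` uses a stratified 70/30
split (the proportion is a package choice, exposed as a flag) and
reports per-class accuracies separately.

Features are relative abundances after rarefaction throughout; the
transform is a package choice where upstream practice varies.

`random_effects_meta()` computes a per-experiment Hedges' g for the
indicator taxon (chosen for robustness to per-study scale), pools with
the DerSimonian-Laird estimator, and reports leave-one-out pooled
effects as the sensitivity analysis. Zero-variance studies are floored
with a warning rather than dropped.

## Networks and cohesion

`cooccurrence_network()` builds the display network: pairwise Spearman
correlations with an edge when |r| > 0.6 and the two-sided p < 0.05.
`network_topology()` reports degree, closeness and betweenness;
closeness is computed within each connected component (isolates score
0).

`connectedness()` implements the cohesion framework. For each taxon
pair, the observed Pearson correlation of relative abundances is
corrected by subtracting the mean correlation under a taxa-shuffle
null (one taxon's abundances permuted across samples, 200 iterations
by default). A taxon's positive (negative) connectedness is the mean
of its positive (negative) corrected correlations. `cohesion()` then
weights each sample's relative abundances by connectedness:
`cohesion_pos(i) = sum_j a_ij conn_pos(j)`, likewise for the negative
part, and the group-level stability index is
`|mean cohesion_neg| / mean cohesion_pos` (means over samples; the
choice of mean over median is a package decision). A persistence
filter (occupancy >= 0.05) removes near-absent taxa whose correlations
are unstable. `subcommunity_cohesion()` restricts to a focal class
plus its significant co-occurrence neighbors before recomputing.

Two numerical caveats worth knowing. First, closed compositions force
negative covariance somewhere in every community (row sums are
constant), so an "all-positive" community cannot exist in relative
abundance space; the sign contract (cohesion_pos >= 0 >= cohesion_neg,
ratio 0 when no negative connectedness) is exercised directly on the
connectedness profile. Second, the negative:positive ratio is nearly
invariant to designs that strengthen positive and negative coupling
together — planted-structure tests therefore hold the positive
structure fixed and vary only the negatively coupled pairs. The ratio
is computed and reported; its ecological interpretation (stability vs
instability) is left to the caller.

## Resistome

`detect_genes()` applies the chip detection rule: a gene is detected
iff at least 3 biological replicates each have at least 3 technical
replicates amplified strictly below cycle 31. Strictness at the
boundary is a package choice exposed as a flag (`strict = FALSE`
admits wells at exactly 31); non-amplified wells are encoded as `NA`
and never count. `copy_number()` is the printed transform
`10^((31 - CT)/(10/3))`, exactly log-linear:
`log10(copy) = 0.3 (31 - CT)`. `gene_abundance()` reports both raw
copy numbers and the per-16S ratio (the chip convention when a 16S
reference is present; missing references yield `NA` with a warning).
`arg_taxon_correlation()` screens taxon classes against ARG abundance
with Spearman correlation and Benjamini-Hochberg q-values.

## Locomotion

`haa_index()` scores one timepoint of the five-ring locomotion map
(outer radii 5-30 cm): with weights `w_i = i` increasing outward,
`HAA = sum w_i c_i / (max(w) n)`, ranging from 0.2 (all individuals
innermost) to 1 (all outermost); the exact published weighting can be
registered via the `weights` argument. `motility_slope()` fits the OLS
slope K of HAA against minutes. `welch_t()` is the two-tailed Welch
test with Satterthwaite degrees of freedom used for group comparisons,
and `taxon_phenotype_regression()` reports OLS fits under the signed
r-squared convention (`sign(slope) * R^2`), which encodes negative
associations as negative values; the unsigned R^2 is also returned.

## Problem sizes and determinism

Every stochastic function takes a seed, and `run_pipeline()` derives
all stage seeds from one integer, so a full chain is byte-identical
across reruns. The packaged benchmarks use 12-experiment metastudies
(288 samples) for partition recovery, 6-experiment ones (144 samples)
for the indicator screen, 500 simulations for type-I calibration of
Welch and PERMANOVA (199 permutations each under the null), and
10-sample x 6-taxon toys for the exact cohesion oracle — sizes at
which each property is statistically decidable in minutes on one core.

## Known limitations

* The CI and HAA formulas are the package's default monotone forms;
  published variants can be registered but are not transcribed here.
* Cohesion inherits the compositional closure effects discussed above.
* No phylogeny is modeled, so UniFrac-type analyses are out of scope.
* The generator's pollution effect is a single multiplicative fold
  change on one class; real pollution responses are polygenic across
  taxa.
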