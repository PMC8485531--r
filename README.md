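# coregut

Multi-study analysis of soil invertebrate gut microbiotas: core-taxon
identification, pollution-indicator screening, community stability, and
the host-side assays that accompany them.

Soil invertebrates (springtails, earthworms, enchytraeids, mites, ants)
carry gut bacterial communities that respond to soil pollutants at
environmentally realistic concentrations — often before the host shows
any overt physiological effect. Working across many independent
sequencing studies raises recurring methodological problems: tables must
be harmonized to a common depth and rank; "core" taxa must be defined in
a way that survives between-study heterogeneity; candidate indicator
taxa must be screened with classifiers that are validated rather than
anecdotal; and claims about community stability need a quantitative
footing. `coregut` packages this entire workflow for R, together with a
seeded synthetic-metastudy generator so every stage is testable without
any external sequence data.

## The statistics at the core

**Core index.** For each taxon, with occupancy `f` (fraction of all
samples in which it is detected), detection in `n` of `N` experiments,
and `s` of `S` total reads:

    CI = f · (n/N) · (s/S)
    NorCI = CI / max(CI)

Taxa are partitioned by NorCI: **core** ≥ 0.83, **transient** in
[0.3, 0.83), **rare** below. The formula is pluggable
(`core_index(formula = ...)`).

**Indicator screen.** Random forest, SVM and logistic regression are
compared by cross-validated AUC on identical folds; the taxonomic level
is chosen by random-forest out-of-bag error; per-genus importance comes
from tenfold cross-validation with five repeats (mean decrease in
accuracy), and the indicator score is min-max-normalized importance ×
occupancy. A DerSimonian–Laird random-effects meta-analysis (Hedges' g
per experiment, leave-one-out sensitivity) checks the indicator's
cross-study trend.

**Stability.** Spearman co-occurrence networks (|r| > 0.6, p < 0.05)
with degree/closeness/betweenness topology, and cohesion: per-taxon
null-corrected connectedness (taxa-shuffle null) weighted by per-sample
relative abundances, summarized as the negative:positive cohesion
ratio.

**Resistome.** HT-qPCR chips are processed with the strict detection
rule (3 technical × 3 biological replicates below cycle 31) and the
relative copy-number transform `10^((31−CT)/(10/3))`.

**Locomotion.** The high-area-activity index
`HAA = Σ wᵢcᵢ / (max(w)·n)` on a five-ring test map, and its OLS slope
K over time.

## Worked example

```r
library(coregut)

# a 17-experiment synthetic metastudy (~408 samples, Control/Pollution),
# unperturbed so the planted core structure is the ground truth
cfg <- synth_config(pollution_fold_change = 1, seed = 1)
sim <- simulate_metastudy(cfg)
merged <- rarefy_counts(merge_experiments(sim$tables), depth = 2000, seed = 2)
classes <- collapse_taxa(merged, "class")

length(shared_taxa(classes)$shared)
#> [1] 7

part <- core_partition(classes)
round(part$category_abundance, 2)
#>      core transient      rare
#>     51.48     34.94     13.58
subset(part$stats, category == "core", c(taxon, f, n, NorCI))
#>   taxon f  n     NorCI
#> 1   C01 1 17 1.0000000
#> 2   C02 1 17 0.9305892
#> 3   C03 1 17 0.9670330
```

Seven classes are detected in every experiment; the three planted core
classes carry ~51% of reads and score NorCI ≥ 0.93, the four transient
classes ~35%, and the 13 rare classes ~14% — the structure the
generator plants.

With pollution enrichment switched on (`pollution_fold_change = 2.5`,
the default), the indicator screen recovers the enriched class:

```r
cfg2 <- synth_config(seed = 1)
merged2 <- rarefy_counts(merge_experiments(simulate_metastudy(cfg2)$tables),
                         depth = 2000, seed = 2)
genus <- collapse_taxa(merged2, "genus")
imp <- cv_importance(rel_abundance(genus), genus$sample_meta$group, seed = 3)
head(select_indicator(imp, taxon_stats(genus), genus$taxonomy), 3)
#>    taxon importance f     score class
#> 1 C01_g2 0.10665901 1 1.0000000   C01
#> 2 C01_g1 0.09144562 1 0.8574459   C01
#> 3 C01_g3 0.07572466 1 0.7101355   C01
```

All three genera of the enriched class C01 top the ranking. The same
run yields a held-out random-forest AUC of ~0.99 and a pooled Hedges'
g of ~4 with a 95% interval well above zero.

The whole chain — simulate → ingest → core-index → indicator →
stability → resistome → phenotype — runs as one call and writes every
stage's tables:

```r
run_pipeline("out_dir", config = synth_config(), seed = 1)
```

or from a shell via the thin driver
`Rscript inst/scripts/pipeline.R --out out_dir --seed 1`.

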