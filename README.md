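# sourveyor

Statistical toolkit for citizen-science sourdough survey campaigns: it
harmonises the three tables such a study produces — a registration survey, an
at-home experiment results survey (pH strips, bread density, check-all-that-
apply aroma ticks) and laboratory measurements (pH, titratable acidity) —
into one analysis-ready table, and then runs the analysis layer used to
characterise baking practice across Europe. A synthetic survey generator
with a planted-effect registry makes the whole pipeline testable end to end
without any external data.

**Who it is for:** food-microbiology and fermentation researchers analysing
multi-country survey + lab metadata, and anyone who needs a tested
implementation of fold-enrichment scoring over sample clusters, mixed-type
collinearity screening, or CATA sensory ordination.

## The statistics at the core

For samples partitioned into clusters (countries, sources, flour types),
fold-enrichment of a category level *k* in cluster *c* is

    score = (n_kc / n_c) / (N_k / N)

(the within-cluster share over the overall share), with a chi-square test on
the 2×2 collapse, Cramér's V as effect size, Benjamini–Hochberg FDR across
the partition's pairs, and PE/NE (over/under-represented) plus U/M
(uniquely/multiply enriched) flags. Numeric features score as

    score = (mean_c + ε) / (mean + ε),    ε = 1e-4

log₂-normalised, with Mann–Whitney cluster-vs-rest significance. Around
this sit: pairwise effect sizes (Cohen's d, rank-biserial, Cramér's V, with
a Shapiro–Wilk/Brown–Forsythe gate choosing the test), directional (signed)
Cramér's V profile clustering, a mixed-type association matrix
(|r|/V/epsilon-squared) with representative-variable selection, Jaccard →
PCoA → PERMANOVA/Mantel for the 56-descriptor CATA matrix, and PCA with 95%
group confidence ellipses. See `vignettes/sourveyor-methods.Rmd` for models,
assumptions and every numerical choice.

## Worked example

```r
library(sourveyor)

cfg   <- generator_config(n_participants = 600, seed = 42)
study <- generate_study(cfg)          # registration / results / lab + truth
tab   <- harmonize_study(study)       # 766 integrated samples

# lab pH is systematically below home strip pH (generator plants -0.73):
mean(tab$ph_lab - tab$ph_home, na.rm = TRUE)
#> -0.732

# household vs bakery practice differences, gated tests + BH-FDR:
sc <- source_contrast(tab)
pairwise_table(sc, c("backslop_frequency", "storage_temp_C", "tta"),
               "source", levels = c("bakery", "household"))
#>             variable                        method statistic   effect_kind effect_size        p        q stars   n
#> 1 backslop_frequency mann-whitney (normal approx.)  12574.00 rank_biserial       0.606 1.26e-22 3.77e-22   *** 733
#> 2     storage_temp_C                        t-test      7.72      cohens_d       0.875 3.23e-12 4.85e-12   *** 695
#> 3                tta                        t-test      2.12      cohens_d       0.308 3.76e-02 3.76e-02     * 427
```

Bakery starters are refreshed more often (rank-biserial 0.61: most
bakery/household pairs order that way), stored warmer (d = 0.88) and carry
slightly higher acidity — exactly the effects the generator's default
registry plants.

```r
# country enrichment of organic flour use inside the European bounding box:
reg  <- geo_filter(tab)
part <- cluster_partition("country",
          setNames(as.character(reg$country), reg$sample_code),
          min_cluster_size = 5)
enr <- category_enrichment(setNames(reg$organic_flour, reg$sample_code), part)
subset(enr, q < 0.05,
       c(feature, cluster, score, log2_score, q, effect_size, direction, multiplicity))
#>  feature     cluster score log2_score      q effect_size direction multiplicity
#>       no Switzerland  0.71     -0.495 0.0355       0.112        NE            U
#>      yes Switzerland  1.17      0.225 0.0355       0.115        PE            U
```

Swiss samples over-select organic flour (score 1.17: their organic share is
17% above the cohort-wide share; q = 0.035, uniquely enriched) — the planted
Switzerland-organic odds effect, recovered from scratch.

One command runs everything (generate → harmonize → collinearity → pairwise
→ enrichment → CATA → feature space) and writes plot-ready CSVs, a JSON-lines
log and a reproducible manifest:

```r
run_pipeline(pipeline_config(generator = cfg, outdir = "out", seed = 42))
```

or from a shell: `Rscript inst/scripts/sourveyor-cli.R analyze --seed 42
--outdir out`.

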