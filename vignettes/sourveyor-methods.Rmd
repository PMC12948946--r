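---
title: "Methods: statistical analysis of citizen-science sourdough surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical analysis of citizen-science sourdough surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sourveyor)
```

## The problem

Large citizen-science fermentation campaigns collect heterogeneous,
multi-table survey data: a registration questionnaire (who the baker is,
where they live, how the starter is fed), a results questionnaire from
standardised at-home experiments (pH strips, bread density, a
check-all-that-apply sensory evaluation), and laboratory measurements on the
mailed-in starter (pH by metre, total titratable acidity). The tables are
linked by 5-character sample codes and person identifiers, are incomplete in
different ways, and mix numeric, categorical and multi-select fields.

`sourveyor` implements the full analysis layer for such a study:
harmonisation into one integrated table, fold-enrichment scoring of features
across sample clusters, pairwise effect-size testing, mixed-type
collinearity screening, CATA sensory ordination, and PCA of the numeric
feature space — together with a synthetic survey generator that plants known
effects so every stage can be validated without access to the deposited
data.

## Harmonisation rules

* **Merge**: an outer merge anchored on registration; result-phase variables
  missing in the results table are back-filled from registration and flagged
  in a per-cell provenance map. Result rows without a registration match are
  quarantined (with a warning); laboratory orphans are reported in the QC
  block.
* **Dough yield**: $DY = (flour + water)/flour \times 100$; $DY = 200$ means
  equal masses. DY is scale-invariant in the ingredient masses and undefined
  for non-positive flour mass.
* **Flour decomposition**: composite labels ("wholemeal rye") split into
  grain base (wheat, spelt, rye, mixture) and milling grade (wholemeal,
  semi-wholemeal, endosperm, unspecified). Chi-square analyses use a grouped
  view in which semi-wholemeal is merged into wholemeal (it existed only for
  wheat and tracks wholemeal wheat closely); numeric and feature-space
  analyses keep the two distinct.
* **Rare-level binning**: category levels at $\le 1\%$ prevalence among
  non-missing entries (threshold inclusive) become `"Other"`.
* **Bread density**: values above 1 g/cm³ are physically impossible for
  bread and treated as reporting errors; they are blanked (the boundary 1.0
  is retained) and counted in the QC report.
* **Numeric categorisation**: half-open bins, lower limit included, upper
  excluded, with open-ended extreme bins.
* **Missing data** are excluded per variable, not per sample, everywhere;
  complete-case behaviour is an explicit opt-in of individual analyses
  (e.g. PCA).
* **Source contrast**: "bakery" aggregates all non-household origins; the
  single rare industrial label and unknown sources are excluded from
  household-versus-bakery contrasts.

## Enrichment scoring

For a partition of samples into clusters (countries, sources, flour types):

* **Categorical** (per category level $k$, cluster $c$):
  $\text{score} = \dfrac{n_{kc}/n_c}{N_k/N}$ — the within-cluster share of
  the level over its overall share. Significance comes from a chi-square
  test on the 2×2 collapse (level vs rest × cluster vs rest); Cramér's V is
  the effect size. Scores stay on the raw ratio scale; `log2_score` is
  carried for display (a zero count gives $-\infty$).
* **Numeric** (per cluster): $\text{score} =
  \dfrac{\bar{x}_c + \varepsilon}{\bar{x} + \varepsilon}$ with
  $\varepsilon = 10^{-4}$ guarding division by zero, log₂-normalised for
  scale-free comparison; significance from a Mann–Whitney U test of the
  cluster against all other clusters. The ratio assumes a non-negative
  variable; signed variables are shifted by their global minimum first, with
  a logged note.
* **FDR family**: Benjamini–Hochberg across all (feature, cluster) pairs of
  one partition analysis, not across partitions, matching per-figure
  correction.
* **Flags**: PE/NE for score above/below 1; U when a feature is significant
  (q < α) in exactly one cluster, M in two or more. We read "uniquely
  enriched" as exactly-one-cluster; the alternative (one partition variable)
  is noted as an open reading.
* **Geography**: enrichment over countries is restricted to the European
  bounding box, longitude $[-50, 70]$, latitude $[0, 70]$, boundaries
  inclusive (the source text does not specify open or closed bounds; the
  inclusive choice keeps corner coordinates).
* **Conservation**: with cluster weights $n_c/N$, the weighted mean of
  categorical scores equals 1 for every feature — an exact identity the test
  suite asserts at $10^{-9}$. (Weighting by the category's own cluster
  shares does not produce an invariant; the cluster-size weighting is the
  algebraically correct reading.)

Directional Cramér's V attaches the sign of the focal cell's
observed-minus-expected deviation to $|V|$; feature × cluster matrices of
signed V (zeroed where non-significant) are ordered by average-linkage
hierarchical clustering on Euclidean distances for bubble-plot style output.

## Pairwise testing

Two-group comparisons choose between the t-test (Cohen's d, pooled
$(n-1)$-denominator SD) and the Mann–Whitney U test (rank-biserial
correlation) with a data-driven gate: Shapiro–Wilk per group plus the
Brown–Forsythe variance test, both at α = 0.05, must pass for the t-test.
The gate procedure is our own choice (the choice criterion "normality and
homoscedasticity" is stated, the procedure is not) and every decision is
recorded on the result object.

The rank-biserial correlation is defined so that it equals the mean of
$\mathrm{sign}(x_i - y_j)$ over all pairs — positive when the first group is
stochastically larger. The U statistic reported alongside counts pairs with
$x < y$ (plus half-ties) so that $r = 1 - 2U/(n_1 n_2)$ holds literally.
Chi-square tests never apply a continuity correction, because the effect
size (V) is the quantity of interest and the correction would bias it.
BH-FDR is a hand-rolled step-up implementation verified against
`stats::p.adjust`; note that BH q-values are *not* idempotent under
re-adjustment (a sometimes-claimed property that is false; see the test
suite).

## Collinearity screening

The mixed-type association matrix stores, in $[0, 1]$: max of |Pearson|,
|Spearman| and centred cosine similarity for numeric pairs (centred cosine
is algebraically identical to Pearson, but all three are computed so the
contract is explicit); Cramér's V for categorical pairs; Kruskal–Wallis
epsilon-squared ($H/(n-1)$) for mixed pairs. How the published analysis
combined its three numeric measures is unstated; max-of-three is our choice
and is flagged. Representative selection runs average-linkage clustering on
$1 - A$ and cuts at height $1 - t$ (so $t$ is an *association* threshold,
default 0.7 — the only reading under which raising the threshold
monotonically keeps more variables), keeping per cluster the variable with
the highest mean association to its cluster mates (ties lexicographic).
Every exclusion is logged; the published variable lists cannot be
regenerated from the text alone, so the cut is configuration, not canon.

## CATA ordination

Jaccard distances over the full 56-descriptor spectrum; two all-empty
profiles are at distance 0 by convention (logged), an empty against a
non-empty profile at distance 1. PCoA uses Gower double-centring and
reports negative eigenvalues rather than correcting them; "variance
explained" uses the sum of positive eigenvalues as denominator, which keeps
the quantity well-defined for non-Euclidean input. PERMANOVA is one-way per
variable (matching the per-variable R² reporting), drops levels with fewer
than 3 samples (the ≥3 filter is read per level, flagged as an open
reading), and uses the add-one permutation rule so p is never 0. Mantel
tests (Pearson and Spearman) z-score the numeric predictor before forming
Euclidean predictor distances and drop samples missing that predictor from
both matrices ("dynamic exclusion"). Exact enumeration of all label
permutations is available for both tests at $n \le 8$ and is what the
oracle tests compare against. Top features are descriptors ranked by
$\max(|r_{PC1}|, |r_{PC2}|)$ of Pearson correlations with the first two
principal coordinates.

## Feature-space PCA

Variables that survived collinearity selection are z-scored; `prcomp` on the
correlation structure; a deterministic sign convention (largest-|loading|
entry positive per axis) makes runs reproducible. Two variants mirror the
published feature spaces: *geographic* (feeding parameters, home results,
TTA, latitude; substrate excluded — latitude only, per the figure caption)
and *substrate* (feeding, home results, TTA, flour proportions; geography
excluded). Group ellipses are *data* ellipses at the χ²₂ quantile of the
group score covariance (semi-axes $\sqrt{\lambda_i \chi^2_{2}(0.95)}$), not
standard-error-of-mean ellipses — this matches the visual spread
interpretation of the published plots; groups under 5 samples are dropped.

## The synthetic world

The generator emulates the deposited study's structure with values fixed
from its reported summaries wherever stated, and field-realistic choices
otherwise (documented here, then left alone):

* ~12.8% of samples of bakery origin (87.2% household), a 0.3% industrial
  and 0.5% unknown remainder; 1–5 samples per person with ~10% multi-sample
  owners; hub countries plus Germany and Austria with one non-European
  country so the bounding-box filter is exercised.
* Home pH on a 0.25-unit strip scale; laboratory pH continuous with a
  systematic −0.73 offset plus 0.08 SD noise (shipping acidification and
  strip-vs-metre bias); TTA in mL 0.1 M NaOH around 11 ± 3.
* Dough yields centred on 200 (SD 30, clipped to [105, 350]), i.e. the
  typical 150–250 band; ~2% of bread densities drawn above 1 g/cm³ as the
  QC filter's target.
* 56 CATA descriptors in 13 categories; base prevalence drawn per descriptor
  from [0.02, 0.45], with a handful pinned (fermented, grain, sour, yoghurt
  prevalent; ocean, animal, body odour rare).
* Multi-select motivations/benefits are independent Bernoulli per option (no
  dependence structure is reported to emulate); missingness is MCAR per
  field (the missingness mechanism of the real data is uncharacterised).
* The default flour profile is **shared across countries**: real
  country-level structure exists, but a registry-free configuration must be
  a clean statistical null for calibration testing, so country effects are
  planted explicitly through the effect registry. The default registry
  encodes the reported practice effects (rye → higher TTA, DY, density,
  lower pH; bakery → more frequent backslopping, warmer storage and
  fermentation, larger and older starters; rye ↔ sour and wheat ↔ chemical
  aromas; German-speaking wholemeal/organic preference).

Planted effects act on the natural scale: odds multipliers for categorical
levels (non-target levels rescaled proportionally so the realised odds ratio
is exact), SD-unit shifts for numeric features (dough-yield shifts act on
water mass so ingredient columns stay consistent), probability deltas for
aroma descriptors (clipped to [0, 1], clipping logged), and correlation
coefficients for numeric-numeric couplings.

What a green test does **not** establish: the generator draws samples
i.i.d. within persons' countries, models no within-person correlation of
practices, no multilingual free text, no non-MCAR missingness, and no
microbial dynamics. Effect-recovery results transfer to real data only to
the extent these simplifications are benign.

## Numerical and procedural choices

* Exact Mann–Whitney distribution when tie-free and $n_1 n_2 \le 10^4$;
  tie-corrected normal approximation otherwise; mid-ranks for ties.
* Permutation tests default to 999 permutations (199 in the pipeline's
  batch mode for runtime); the add-one rule bounds p away from 0.
* Master pipeline seed deterministically derives per-stage seeds by hashing
  stage names, so toggling one stage never shifts another stage's stream;
  the test suite asserts byte-identical output hashes.
* Degenerate inputs fail loudly and specifically: duplicate sample codes,
  non-positive flour masses, non-binary CATA entries, zero-margin
  contingency tables, constant PCA variables, zero-variance Mantel vectors.

## Known limitations

* One acceptance property (planted categorical effect is the top
  |log₂ score| record among significant records in ≥95% of replicates) sits
  at ~80% in this world: the composite flour label space contains several
  2–4% levels whose scores occasionally spike above the planted record's
  (~2.2) with q < 0.05, and the planted enrichment itself induces genuine
  negative enrichments of the same level in other countries. The planted
  pair itself is positively enriched and significant in ~100% of
  replicates. We report this honestly rather than coarsening the category
  space after the fact.
* The reproduction of the deposited study's headline numbers requires its
  Zenodo archive and network access; the harmonisation stage accepts the
  archive's table schema, but no downloaded data ships with or is fetched by
  this package.
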