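# morphospec

Morphotype detection and individual-specialization metrics for fish, from
landmark photographs and two-tissue stable-isotope data.

Coastal fish populations often contain morphotypes — within-species clusters
of body shape — whose members may also differ in how specialized their
resource use is. `morphospec` implements the full analysis chain used to ask
that question in a population of Greenland cod (*Gadus ogac*):

1. **Geometric morphometrics.** Read tpsDig-style landmark files
   (21 landmarks per fish), filter by photo/landmark quality ranks, apply the
   image scale, align shapes by generalized Procrustes analysis (GPA), run a
   shape PCA, and compute nine inter-landmark linear measurements
   (head length, head depth, snout length, eye width, maxilla length, body
   depths, caudal peduncle, post-pelvic fin length).
2. **Allometric size adjustment (Reist).** Each measurement *M<sub>i</sub>*
   is standardized to a common fork length *L<sub>m</sub>*:

   *Y<sub>i</sub>* = log₁₀ *M<sub>i</sub>* + *b* (log₁₀ *L<sub>m</sub>* − log₁₀ *L<sub>i</sub>*),

   with *b* the pooled OLS slope of log₁₀ *M* on log₁₀ *L*.
3. **Morphotyping.** PCA of the nine size-adjusted measurements
   (correlation matrix), silhouette-method choice of *k*, k-means clustering,
   then a one-way MANOVA (Pillai's trace) and Bonferroni-corrected Welch
   *t* tests per measurement, with Shapiro–Wilk and Levene diagnostics.
4. **Stable-isotope niche metrics.** δ¹³C and δ¹⁵N from slow-turnover red
   blood cells (RBC) and fast-turnover plasma are corrected with diet–tissue
   discrimination factors (δ¹³C: plasma 1.2‰, RBC 0.1‰; δ¹⁵N: plasma 0.9‰,
   RBC 1.1‰), contrasted per fish (RBC − plasma "switch" metrics), and
   decomposed per morphotype with the random-intercept mixed model

   *y<sub>it</sub>* = β₀ + β₁ FL*<sub>i</sub>* + β₂ tissue*<sub>t</sub>* + *u<sub>i</sub>* + ε*<sub>it</sub>*,  *u<sub>i</sub>* ~ N(0, σ²*<sub>B</sub>*),  ε ~ N(0, σ²*<sub>W</sub>*),

   fit by a native REML routine (1-D profiling over λ = σ²*<sub>B</sub>*/σ²*<sub>W</sub>*).
   The residual variance is the **within-individual component (WIC)**, the
   fish-level variance the **between-individual component (BIC)**, their sum
   the **total niche width (TNW)**, and **IS = WIC/TNW** the individual
   specialization index (near 0: a population of individual specialists;
   near 1: every individual as generalist as the population). Individual WIC
   values (absolute residuals of a plasma-on-RBC regression) feed a GLM on
   log₁₀ WIC against cluster, fork length and year, with ΔAIC-guarded
   pruning of interaction terms.
5. **Synthetic data with known truth.** `synthetic_truth()`,
   `simulate_landmarks()` and `simulate_isotopes()` generate landmark and
   paired-tissue isotope datasets with controllable shape separation,
   digitization noise, allometry, σ²*<sub>B</sub>*, σ²*<sub>W</sub>*, tissue
   offsets and dropout, so every stage is testable by parameter recovery —
   no downloads required.

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; fitted objects have `tidy()`/`glance()` methods
and `autoplot()` visualizations.

## Worked example

```r
library(morphospec)

truth <- synthetic_truth(n_fish = 45, seed = 7)   # study-scale defaults
landmarks <- simulate_landmarks(truth) |> apply_scale()

adjusted <- landmarks |>
  interlandmark_distances() |>
  reist_adjust()

pca <- measurement_pca(adjusted)
ks  <- select_k_silhouette(pca, k_range = 2:5, pcs = 2, seed = 7)
ks
#> <kselect> chosen k = 2
#> # A tibble: 4 × 3
#>       k mean_silhouette tot_withinss
#>   <int>           <dbl>        <dbl>
#> 1     2           0.603         88.3
#> 2     3           0.545         54.3
#> 3     4           0.425         39.8
#> 4     5           0.418         31.8

manova_pillai(adjusted, ks$clustering$assignments)
#> # A tibble: 1 × 8
#>   statistic value approx_f   df1   df2  p_value     n groups
#>   <chr>     <dbl>    <dbl> <dbl> <dbl>    <dbl> <int>  <int>
#> 1 Pillai    0.980     192.     9    35 4.37e-27    45      2

isotopes <- simulate_isotopes(truth) |>
  apply_discrimination() |>
  dplyr::mutate(cluster = ks$clustering$assignments[
    match(fish_id, landmarks$specimen_id)])

decompose_niche(isotopes)
#> # A tibble: 6 × 9
#>   isotope group        WIC   BIC   TNW    IS boundary n_fish n_obs
#>   <chr>   <chr>      <dbl> <dbl> <dbl> <dbl> <lgl>     <int> <int>
#> 1 d13C    cluster1   0.201 0.474 0.675 0.298 FALSE        20    34
#> 2 d13C    cluster2   0.215 0.588 0.803 0.268 FALSE        25    42
#> 3 d13C    population 0.204 0.531 0.734 0.277 FALSE        45    76
#> 4 d15N    cluster1   0.108 0.431 0.539 0.200 FALSE        20    34
#> 5 d15N    cluster2   0.299 0.514 0.813 0.368 FALSE        25    42
#> 6 d15N    population 0.217 0.450 0.667 0.326 FALSE        45    76
```

The silhouette table shows two morphotypes are the best-supported clustering
of the size-adjusted measurements; the MANOVA confirms the clusters differ
multivariately (Pillai's trace 0.98, F ≈ 192 here because the synthetic shape
separation is strong relative to digitization noise). In the decomposition
table each row is one isotope × group fit: `WIC` and `BIC` are in ‰², and
`IS` is the within-individual share of total niche width — at this sample
size (45 fish, 76 tissue observations) single-run IS estimates scatter
around the generator's truth of 0.40.

The whole chain (including the individual-WIC GLM) can also be run in one
call from a config:

```r
report <- run_pipeline(list(synthetic = list(n_fish = 45, seed = 7), seed = 7))
```

or from a shell via the thin wrapper `inst/scripts/morphospec-cli.R`
(`simulate` and `run-all` subcommands).

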