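---
title: "Methods: morphotypes and individual specialization from landmarks and stable isotopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphotypes and individual specialization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphospec)
```

# Overview

`morphospec` chains two analyses that are usually run separately: landmark
based geometric morphometrics, which asks whether a fish population contains
distinct body-shape clusters (morphotypes), and a two-tissue stable-isotope
variance decomposition, which asks how specialized individuals are in habitat
(δ¹³C) and trophic level (δ¹⁵N) use. The package's defaults describe a
coastal Greenland cod population: 45 fish, two morphotypes differing mainly
in head shape and body depth, fork lengths around 389 ± 58 mm, and blood
sampled as red blood cells (RBC, slow isotopic turnover) and plasma (fast
turnover).

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

# Geometric morphometrics

## Quality filtering

Each photograph and each of its 21 landmarks carries a rank from 1 (poor)
to 3 (excellent). `quality_filter()` retains a specimen when its photo rank
and all landmark ranks meet the thresholds (defaults: both 2). The original
field protocol reported only how many fish survived its screening, not the
thresholds themselves, so the thresholds are explicit arguments rather than
hard-coded guesses; specimens without ranks pass with a warning because
deposited datasets often omit them. The filter is a partition — every input
specimen appears exactly once in `retained` or `excluded`, with the failing
criterion named.

## Generalized Procrustes alignment

`gpa()` removes position, size and orientation: configurations are centered,
scaled to unit centroid size, and rotated onto the running mean shape, which
is recomputed and re-standardized each iteration (partial Procrustes — no
per-iteration rescaling beyond unit centroid size). Rotations are restricted
to determinant +1: all photographs are same-side lateral views, so
reflections can only be digitization errors. Convergence is declared when
the summed squared Procrustes distance changes by less than `tol` (default
1e-8, dimensionless squared shape units) within `max_iter` (default 100)
iterations; non-convergence flags the result rather than failing.
Orthogonal projection onto the tangent plane at the mean is on by default
(`tangent = TRUE`) so that shape PCA operates in a linear space; it perturbs
centroid sizes by O(d²) for shapes at Procrustes distance d from the mean,
which is why the unit-size invariant is tested with projection off.
Degenerate configurations (all landmarks coincident) are excluded with a log
entry.

## Measurements and Reist size adjustment

The nine linear measurements are Euclidean distances between landmark pairs.
The landmark identities of each measurement come from a figure in the
original protocol rather than a machine-readable table, so the pair map is a
required, documented configuration; `default_pair_map()` ships pairs
consistent with the measurement names on the package's 21-landmark template
(e.g. HL = snout tip to posterior operculum edge, fork length = snout tip to
posterior caudal peduncle).

Size adjustment follows the standard allometric standardization
Y = log₁₀ M + b (log₁₀ L_m − log₁₀ L), with the slope b estimated per
measurement by OLS pooled across all retained fish — pooling matches the
protocol's wording; a within-group common slope is deliberately not used.
L_m defaults to the mean fork length of the retained fish, with an override
(`l_m`) for reproducing analyses anchored to another alignment length
(e.g. 368.1 mm). Whether a published alignment length was the mean of the
retained or of all photographed fish is unknowable from summaries alone;
the default-plus-override design covers both readings. By construction the
adjusted values are orthogonal to log₁₀ fork length (slope 0 to 1e-10,
tested), and adjusted values are reported explicitly as log₁₀(mm) in all
output headers — their magnitudes (e.g. 3.37 for a ~2,300 mm² measurement
product) are easily misread as mm otherwise.

# Morphotyping

PCA of the nine adjusted measurements uses the correlation matrix
(standardized variables) by default — the measurements span an order of
magnitude, and covariance-matrix PCA would let the largest ones dominate;
`scale = FALSE` switches to covariance. Loadings follow a deterministic sign
convention (largest-magnitude loading positive) so runs are comparable.

Clustering operates on the first two PCs by default (`pcs` configurable up
to all nine). The choice was genuinely open — "PCA components" could mean
all of them — but the two-PC reading matches how such analyses are plotted
and interpreted (the leading axes carry the head/body-depth signal), and the
option covers the other reading. k-means uses Lloyd's algorithm with 50
seeded restarts (best within-cluster sum of squares kept; `stats::kmeans`
re-seeds empty clusters internally); k is chosen by maximizing the mean
silhouette width over `k_range` (default 2–8), ties toward the smaller k.

Group differences are tested with a one-way MANOVA using Pillai's trace,
computed from the between- and within-group cross-product matrices with the
standard F approximation (it reduces exactly to the one-way ANOVA F for a
single response — tested). Post hoc per-measurement tests default to
Welch's unequal-variance t with Welch–Satterthwaite df: fractional degrees
of freedom (44.7, 45.5, …) in the reference analysis are diagnostic of the
Welch form even where the label "Student" is used, and the pooled-variance
variant remains available (`welch = FALSE`). Both Bonferroni conventions are
reported — the adjusted level α/m (0.05/9 ≈ 0.00556) and adjusted p values
min(1, mp) — because "a Bonferroni correction" alone does not say which.
Shapiro–Wilk (per group) and Levene (deviations from the group mean)
diagnostics are reported but never gate the pipeline, matching how such
checks are used in practice.

# Isotope metrics

δ values are per mil deviations of the isotope ratio from the international
standard, (R_sample/R_standard − 1) × 1000. Raw tissue values are corrected
by *subtracting* the diet–tissue discrimination factor Δ (defaults, in ‰:
δ¹³C plasma 1.2, RBC 0.1; δ¹⁵N plasma 0.9, RBC 1.1, from a controlled study
of a comparable marine piscivore). The subtraction direction follows from
the definition Δ = δ_consumer − δ_food: subtracting maps each tissue onto a
common diet-referenced scale. The source protocol never states the sign, so
the convention is isolated in one function (`apply_discrimination()`) and
easily swapped; within tissue the correction is a rigid shift, so every
variance-based metric downstream (WIC, BIC, TNW, IS, group contrasts) is
invariant to the choice (tested to 1e-12).

Tissue-switch metrics are RBC − plasma differences of corrected values per
fish; fish missing either tissue are excluded with a logged count.

# The variance decomposition (WIC / BIC / TNW / IS)

The core statistic is the random-intercept mixed model

y_it = β₀ + β₁ FL_i + β₂ tissue_t + u_i + ε_it,
u_i ~ N(0, σ²_B), ε_it ~ N(0, σ²_W),

fit separately per isotope for each morphotype cluster and for the pooled
population. WIC = σ̂²_W (within-individual component), BIC = σ̂²_B
(between-individual), TNW = WIC + BIC, IS = WIC/TNW ∈ [0, 1].

The REML fit is implemented natively rather than delegated to a mixed-model
package, because the decomposition is the scientific deliverable and its
numerics should be fully auditable here. The marginal covariance is
σ²_W (I + λ Z Zᵀ) with λ = σ²_B/σ²_W; for fixed λ the GLS fixed effects and
the profiled σ²_W are closed-form (the fish-block structure makes every
solve O(n)), leaving a 1-D minimization of the profiled REML criterion
log|H| + log|XᵀH⁻¹X| + (n − p) log(rᵀH⁻¹r). The optimizer is a coarse
log-scale grid (multistart, including the λ = 0 boundary), Brent refinement,
and a short Newton polish on log λ; λ is constrained to [0, 1e8]. Boundary
solutions (BIC = 0, hence IS = 1) are expected in real data and are reported
with a `boundary` flag, not an error. The implementation is tested against a
dense-grid criterion oracle (1e-4), the method-of-moments ANOVA estimators
in the balanced intercept-only limit (1e-8), and `lme4::lmer` as an
independent cross-check; estimates are invariant to fish relabeling and row
order.

Interpreting per-group σ²_B needs one caveat the generator makes visible:
if fish with different *mean* isotope values are pooled (e.g. two
morphotypes with a group-mean gap, in the population-level fit), that gap is
between-fish variance and legitimately inflates BIC. The decompositions are
therefore fit per cluster as the default reading of "per group", with the
population fit reported alongside.

## Individual WIC values and the GLM

Per isotope, an OLS line predicts one tissue from the other across fish with
both tissues; each fish's individual WIC is its absolute residual. The
regression direction is not derivable from the protocol's wording, so both
are implemented; the default predicts plasma (fast tissue) from RBC (slow) —
"given the longer-term signal, how far did the recent signal move" — and
`direction = "rbc_on_plasma"` swaps it.

The GLM models log₁₀ WIC (Gaussian, identity link) on cluster, fork length
and year (categorical). WIC values of exactly 0 would break the transform;
they are floored at half the smallest positive observed WIC with a logged
count. Estimates and standard errors are reported on the log scale and
back-transformed as 10^value. Interaction terms can be added and are pruned
by `simplify_by_aic()`: among interaction terms with term-level p ≥ 0.05
(F test via `drop1`), the weakest (smallest |t|-equivalent) is dropped
unless removal raises AIC by more than 2, in which case it is restored and
locked; main effects are never dropped. AIC uses the `stats::AIC` Gaussian
convention (−2 logLik + 2k with the ML variance); only AIC *differences*
matter for the rule, so the additive constant is immaterial.

# The synthetic-data generator

`synthetic_truth()` fixes the study conditions: 45 fish split 26/19 across
two morphotypes; fork lengths Normal(388.58, 57.63²) mm; two shape templates
(a stylized 21-landmark gadid outline and a small-headed, slender variant,
head-offset magnitude 0.08 in fork-length units); Gaussian digitization
noise of 1.5 mm per coordinate (about the precision of manual landmarking on
a scaled photograph); isotope variance components σ²_B = 0.36, σ²_W = 0.24 ‰²
(true IS = 0.40, within the range of the reference components shipped with
the package); tissue offsets equal to the default discrimination factors; a
mild fork-length trend of 0.002 ‰/mm; years 2018/2019 at the study's
frequencies; and a paired-tissue dropout fraction of 14/45 (the dropout
*count* is deterministic, `round(n · fraction)`, so fixture bookkeeping is
exact). All noise is Gaussian. A single master seed drives per-stage
sub-streams, so the same truth object always yields byte-identical data and
the landmark and isotope generators describe the same fish.

What the generator emulates: two shape classes separated mainly at head
landmarks, isometric or allometric scaling with fork length (global exponent,
default 1), digitization noise, rigid-motion nuisance (random rotation and
translation), image-scale bookkeeping, tissue offsets, between- and
within-individual isotopic variance, fork-length trends, and missing
tissues. What it does not emulate: non-Gaussian digitization error or
outliers, landmark-specific error variances, bending/arching of fish during
photography, correlated measurement error between neighboring landmarks,
seasonal or ontogenetic isotope dynamics, and isotopic baseline shifts.
Passing recovery tests therefore shows the estimators are correct under the
stated model, not that real photographs or tissues satisfy it.

# Testing strategy and problem sizes

Every stage is tested three ways: closed-form and trivial cases; independent
brute-force oracles (rotation-grid GPA mean, exhaustive k-means partitions on
6 points, eigenvalue-based Pillai's trace, dense-grid REML criterion,
normal-equations residuals); and parameter recovery from the generator.
Recovery problem sizes were chosen so Monte Carlo error is small relative to
the assertion tolerance: IS recovery uses 200 fish × 2 tissues × 200
replicates per true IS level (±0.05 on the mean), the Reist slope 200 fish
with 0.1 mm digitization noise (±0.02 per measurement), silhouette
k-selection 100 seeded 45-fish datasets (≥95 selecting k = 2), large-n
variance recovery one 10,000-fish dataset (±5%), and type-I calibration of
the MANOVA and GLM stages 2,000 null replicates each against binomial
bounds. Single-run recovery checks (the pipeline test) use equal isotope
group means and 800 fish so the ±0.05 IS tolerance sits at roughly two
Monte Carlo standard errors.

# Known limitations

- 2-D landmarks only; no semilandmarks, no thin-plate-spline deformation
  grids (extreme-shape displacement vectors are reported instead).
- The silhouette/k-means stage assumes roughly convex, similarly sized
  clusters in PC space; model-based clustering is out of scope.
- The mixed model assumes homoscedastic within-fish error across tissues and
  no isotope–isotope correlation (each isotope is decomposed separately).
- IS point estimates at study scale (tens of fish) carry substantial
  sampling variability, visible in the worked example; the package reports
  components and sample sizes so users can judge precision, but does not
  bootstrap confidence intervals for IS.
- Discrimination factors are borrowed from another species; they shift
  tissues rigidly, so IS-type metrics are robust to their exact values, but
  absolute corrected values are not.
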