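---
title: "Comprehensive drought-resistance evaluation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comprehensive drought-resistance evaluation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtscore)
```

## The problem

A deficit-irrigation screening trial measures each genotype under a
well-watered control and a drought treatment, across many growth and
physiology indices. No single index is decisive: growth suppression,
pigment remodeling, water status and membrane damage each capture a
different facet of the stress response, on incompatible scales and with
different signs of association with resistance. The comprehensive-
evaluation workflow implemented here turns such a panel into a single
defensible ranking (the D value) and a grouping into high / moderate /
low resistance classes. It is the de facto standard in stress-tolerance
screening of crops and ornamentals.

## The model, stage by stage

**Response statistics.** For genotype g and index i, with control and
treatment cell means $\bar{x}^{C}_{gi}$ and $\bar{x}^{T}_{gi}$:
percent change $100(\bar{x}^T-\bar{x}^C)/\bar{x}^C$ and the drought
coefficient $\bar{x}^T/\bar{x}^C$. Replicate-level differences feed a
classical paired two-tailed $t$ test, reported with the "same letter =
not significant" convention of phenotyping tables. No multiplicity
correction is applied by default — each cell is presented as its own
test, as these tables conventionally do — and a Benjamini–Hochberg
option exists for users who want family-wise honesty across the
genotype × index grid.

**Fuzzy membership transform.** For an index positively associated with
resistance, $u(X) = (X - X_{\min})/(X_{\max} - X_{\min})$ across
genotypes; for a negatively associated index (electrolyte leakage,
malondialdehyde — damage markers), $u(X) = 1 - (X - X_{\min})/(X_{\max}
- X_{\min})$. The transform is invariant under positive affine rescaling
of the raw values, so downstream results do not depend on units. This
invariance is asserted end-to-end in the test suite.

**PCA.** The membership matrix (or, optionally, raw treatment means or
percent changes) is column-standardized to the $ZX$ variables and the
correlation matrix is eigen-decomposed. Contribution rates are
$100\,\lambda_i/p$. Component scores are $F_j = \sum_i a_{ij} ZX_i$.

**Scores.** Component weights are the eigenvalue proportions
$W_j = \lambda_j / p$. The composite score is the eigenvalue-weighted
mean $F = \sum_j \lambda_j F_j / \sum_j \lambda_j$. Each retained score
column is membership-transformed across genotypes (positive direction:
a larger component score indicates a stronger performer) and the
comprehensive evaluation value is $D_g = \sum_j u(F_{gj}) W_j$, ranked
descending.

**Classification.** Euclidean, furthest-neighbour (complete-linkage)
agglomerative clustering of the component-score columns, cut at $k = 3$
groups by default. Dendrogram heights are additionally reported on the
0–25 rescaled scale familiar from SPSS output.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `pca_input` | `drought_coefficient` | – | The treatment/control ratio isolates the *response* from baseline vigor; see "Open design decisions". |
| `convention` | `loadings` | – | Score coefficients as eigenvector·√λ (the SPSS "component matrix"); `eigenvector` gives unit-norm columns with Var(F_j) = λ_j. |
| `retention` / `m` | `fixed_m`, 3 | components | Three components is the convention when they separate growth, pigment and water-status axes; `kaiser` (λ > 1) and `cumulative_threshold` are available. |
| `weight_denominator` | `total_variance_p` | – | W_j = λ_j/p, i.e. contribution rate / 100. See below. |
| `linkage` | `complete` | – | Furthest neighbour; `average` (between-groups) by flag. |
| `k` / `h_rescaled` | 3 / – | groups / 0–25 | A three-way high/moderate/low split is the field convention; a rescaled-height cut is dialect-dependent and therefore opt-in. |
| `digits` | 3 | decimals | Report rounding; raw-precision companions are always written. |

Assay calculators take their instrument parameters explicitly — the MDA
formula uses supernatant volume in mL and mass in g with a ×1000 factor
exactly as conventionally printed (reported magnitudes depend on that
convention), and the Arnon relation requires the user's molar absorption
coefficient E (L mol⁻¹ cm⁻¹) rather than imposing a wavelength table.

## Open design decisions (and why we chose as we did)

**Weight denominator.** Method descriptions in this literature often say
weights are eigenvalue proportions "of the extracted components" —
which would make them sum to 1 — while the accompanying tables print
λ_j/p (the proportion of *total* standardized variance). For the bundled
reference panel the printed weights (0.329, 0.239, 0.172) are exactly
λ_j/13, so `total_variance_p` is the default and `extracted_sum` the
option. D values scale by a constant between the two; the ranking is
unchanged.

**What gets membership-transformed before PCA.** Published workflows
transform "the original data" without saying whether that means
treatment means, ratios, or percent changes; the printed tables cannot
distinguish these. We default to the drought coefficient per index
(then membership), because the ratio removes baseline vigor — a large
well-watered plant is not thereby drought resistant — and expose the
other two as modes.

**Loadings vs eigenvectors.** Component-matrix magnitudes in published
tables of this workflow are consistent with loadings (eigenvector·√λ)
even when captions say "eigenvector matrix". Both conventions are
implemented; the default is `loadings`. Note the D pipeline is invariant
to the choice: membership normalization absorbs any per-column positive
scaling of the scores.

**Linkage.** Methods sections in this literature sometimes name the
furthest-neighbour method while results sections describe between-groups
linkage. We follow the stated method (complete) by default and provide
`average`.

**Rescaled dendrogram distances.** The 0–25 axis is implemented as
min–max rescaling $h' = 25\,(h - h_{\min})/(h_{\max} - h_{\min})$, which
pins the first merge at 0 and the last at 25 — matching both stated
properties of the scale (maximum 25, minimum 0). Cutting "at rescaled
height r" inverts this map and cuts the raw tree.

## Numerical conventions

* **Sign convention.** Each eigenvector column is flipped so its
  largest-magnitude coefficient is positive; repeated fits are
  bit-identical. Eigenvalue ties keep original column order.
* **Degenerate membership input.** A constant value vector is an error
  by default (silently emitting constants would corrupt the PCA input);
  an explicit `degenerate = "mid"` substitutes 0.5. Degeneracy is judged
  relative to data magnitude (range ≤ 1e-10 · max|x|), so vectors that
  are constant up to floating-point dust are caught.
* **Degenerate score columns in the pipeline.** On strongly structured
  (e.g. noise-free synthetic) data the membership matrix is nearly rank
  one and trailing component scores are numerically constant; min–max
  normalizing them would amplify floating-point dust into garbage.
  `run_pipeline()` detects such columns, substitutes neutral membership
  0.5, and records them in the manifest. `d_values()` called directly
  keeps the strict error default.
* **Ties.** Identical D values (to full precision) keep genotype input
  order and are flagged in the `tied` column. Cluster-merge ties are
  resolved by the deterministic base agglomeration; for continuous
  features exact ties are non-generic.
* **Zero-variance paired differences.** All-zero differences give
  t = 0, p = 1; constant nonzero differences are the infinite-t limit,
  reported significant with p at the smallest representable positive
  double and a warning — never silently.
* **Reproducibility.** The synthetic generator takes a mandatory seed,
  uses one RNG stream, and restores the caller's RNG state. The pipeline
  manifest hashes the analytic settings (not the output location), and
  contains no timestamp, so identical config + input produce
  byte-identical bundles.

## What the synthetic generator emulates — and what it does not

`generate_panel()` emulates the endpoint of a replicated two-condition
trial: `G = 25` genotypes split 6/7/12 into high / moderate / low
resistance groups, 13 indices with field-plausible baselines, 3
replicates, multiplicative replicate noise (CV 2% by default), and ~10%
genotype-level variation in control baselines. Each genotype carries a
latent resistance score (its group centre 0.90/0.55/0.20 plus a clipped
Gaussian jitter, SD 0.04) — so groups are separated by ~9× the
within-group spread by default. Per-index treatment effects are declared
per group as signed fractions of baseline (growth and RWC shrink more in
susceptible genotypes; pigments rise in resistant ones; EL and MDA rise
most in susceptible ones, respecting each index's declared direction)
and are interpolated piecewise-linearly against the latent score.

The interpolation is a deliberate refinement over a group-constant
effect: it keeps the per-group effect parameters, guarantees the
direction-monotonicity constraint by construction, and makes the
noise-free D ranking *exactly* equal to the planted latent order —
within-group genotypes would otherwise tie, leaving "recovers the
planted ranking" untestable.

What it does **not** emulate: time-course sampling (endpoint only),
index-specific error structures (noise is a common CV), measurement
censoring or missingness (the pipeline treats missing cells as hard
errors by design), genotype × index interaction beyond the planted
monotone structure, and any correlation among replicates. A green
recovery test therefore establishes that the pipeline recovers a planted
monotone resistance signal under realistic noise — not that it is robust
to pathologies the generator never produces.

Two synthetic-world checks are calibrated rather than asserted blindly:
the Spearman correlation between the D ranking and the planted latent
score exceeds 0.90 (threshold frozen below the minimum observed over a
200-replicate calibration of the default world), and the k = 3 cut
recovers the planted groups with adjusted Rand index 1 in at least 95 of
100 seeded runs.

## Validation strategy

Every closed-form operation is tested against an independent oracle:
hand arithmetic for the assay formulas and percent changes, the textbook
sum formulation for Pearson r with `cor.test` as the p-value oracle, the
explicit difference formula for the paired t, squared singular values of
$ZX/\sqrt{n-1}$ for the eigen-decomposition, and an exhaustive
agglomeration over all cluster pairs for complete linkage (G ≤ 6).
Published report tables from a 25-genotype daylily panel are bundled as
fixtures; the scoring stages regenerate all 25 × (3 membership + 1 D)
values and the full rank column from the printed component scores.
Because those printed inputs carry only 3 decimals, the regenerated
values are asserted to within 1.5 × 10⁻³ — one unit in the third
decimal — while the printed weights, the anchor D values (0.588, 0.478,
0.075 after rounding) and all 25 ranks reproduce exactly.

## Known limitations

* The upstream PCA of the bundled reference panel cannot be refit — its
  per-replicate raw data are unpublished — so the PCA engine is
  validated on synthetic and random matrices, and the bundled loadings
  table is a display fixture only.
* Correlation tables involving unpublished raw matrices are exercised
  structurally, not numerically.
* No factor rotation, regression-method factor scores, robust/sparse
  PCA, nonlinear membership variants, grey relational analysis or
  TOPSIS; no imputation or unbalanced-design support.
* Covariate coding for score-vs-covariate correlations (ploidy as the
  chromosome multiplier, petal type as single = 1 / double = 2) is a
  documented convention, not a modeling claim.
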