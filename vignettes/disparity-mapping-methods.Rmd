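---
title: "Methods: statistical pipeline for community health-disparity mapping"
author: "disparitymap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical pipeline for community health-disparity mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disparitymap)
```

## The problem

Health outcomes — cancer mortality rates above all — vary sharply across the
community areas of a metropolitan catchment, and the social determinants of
health (SDOH: poverty, insurance coverage, neighborhood safety, demographic
composition) vary with them. An analyst who simply correlates an outcome rate
with one SDOH variable across ~77 community areas faces three routine traps:
skewed marginals that break normal-theory inference, a handful of gross
outlier communities that drive the estimate, and confounders that manufacture
an association where none exists. `disparitymap` packages the standard
counter-measures into one audited pipeline: per-variable normality-transform
selection, interquartile-fence outlier removal, crude and cleaned correlation
with Fisher-z intervals, a two-step confounder check ending in a partial
correlation, and standardized multivariate models with percent-contribution
importance scores — plus choropleth rendering of any variable over the region
polygons.

The package treats community areas as independent sampling units. That is the
convention of the report format it reproduces; spatial autocorrelation
corrections (e.g. Moran's I) are deliberately out of scope.

## Transform selection

For a variable $x_1,\dots,x_n$ the candidate set is identity, $\log$,
Box–Cox, Yeo–Johnson, and ordered-quantile (rank-to-normal-scores) mapping
$x_{(i)} \mapsto \Phi^{-1}\!\big((i - 0.5)/n\big)$, ties sharing the average
rank. Power-transform parameters are fitted by profile maximum likelihood on
the fixed grid $\lambda \in [-5, 5]$ in steps of $0.01$: a deterministic,
exactly reproducible optimizer whose resolution (0.01 in $\lambda$) is far
below any practical difference in fit at community-area sample sizes.

Fit to normality is scored by the Pearson chi-square statistic over
$k = \lceil 2 n^{0.4} \rceil$ equal-probability classes under
$N(\hat\mu, \hat\sigma)$,

$$P = \sum_{i=1}^{k} \frac{(O_i - n/k)^2}{n/k}, \qquad
  \text{ratio} = \frac{P}{k - 3},$$

with $k - 3$ degrees of freedom (two estimated parameters plus one). The
class-count rule and the dof convention follow the long-standing defaults of
the R ecosystem's Pearson normality test; a ratio near 1 is what a truly
normal sample produces on average. The transform with the smallest ratio
wins; exact ties go to the simpler transform in the fixed order identity,
log, Box–Cox, Yeo–Johnson, ordered-quantile.

Two properties of this criterion are worth knowing. First, the
ordered-quantile transform maps any untied sample onto fixed normal scores,
so its ratio is tiny (often exactly 0 when $k \mid n$) and it wins whenever a
parametric transform cannot essentially normalize the data — the same
behaviour the popular rank-based normalizers show. Second, the Lambert W
family sometimes listed alongside these candidates is omitted here: it has no
closed standard form to pin to, and its practical effect overlaps the
ordered-quantile candidate. The registry is a named list, so an additional
candidate is a two-function entry.

Transforms are fitted on the analysis sample itself (no train/apply split):
the pipeline describes one observed cross-section, it does not predict new
regions. Only the variables entering an analysis are transformed; other
columns pass through untouched.

## Outlier cleaning

After transformation, quartiles are computed by linear interpolation of order
statistics (quantile type 7, the R default) and the fences are
$[Q_1 - 1.5\,\mathrm{IQR},\; Q_3 + 1.5\,\mathrm{IQR}]$. A region is dropped
when **any** analysis variable lies strictly outside its fences; values
exactly on a fence stay. Cleaning is a single pass with fences computed on
the pre-removal data — re-running it could remove more rows, and the pipeline
never does. Missing values never flag a row; each analysis deletes rows
listwise over only the variables it involves, which maximizes the effective
$n$ per analysis. A cleaning step that would remove every row is an error
rather than an empty result.

## Univariate analysis

Pearson (or Spearman, computed as Pearson on average ranks) correlation is
reported twice: on the raw complete pairs, and after transform + clean
("statistical intelligence"). Inference is classical:

$$t = r\sqrt{\frac{n - 2}{1 - r^2}}, \qquad
  \mathrm{CI}_{95} = \tanh\!\Big(\operatorname{atanh} r \pm
  \frac{1.96}{\sqrt{n - 3}}\Big),$$

two-sided $p$ from the $t$ distribution with $n-2$ dof. The interval uses the
normal quantile 1.96 rather than a $t$ quantile — that is the construction
that reproduces the published report intervals this layout mirrors (r = 0.568
with t = 5.982 back-solves to n = 77, giving [0.395, 0.703] within ±0.001 per
endpoint). The Spearman $p$ uses the same $t$ approximation; at $n \approx
77$ the exact permutation null adds nothing.

## Confounder detection and adjustment

A candidate confounder must pass **both** steps:

1. **Screen** on the correlation matrix: $|r(c, \text{outcome})| \ge 0.3$
   and $|r(c, \text{exposure})| \ge 0.3$. The 0.3 default is the usual
   "moderate correlation" convention; it is a tunable argument.
2. **Change-in-estimate**: fit `outcome ~ exposure` and
   `outcome ~ exposure + screened`, and compute
   $100\,|\beta_\text{adj} - \beta_\text{crude}| / |\beta_\text{crude}|$.
   A change above 10% — the generally accepted epidemiological cutoff —
   flags confounding. Absolute values mean a sign flip always flags.

Screened candidates are added jointly, not one at a time (per-candidate
changes are also reported for transparency). The "association after removing
confounders" is the partial correlation by double residualization: regress
both variables on the confounder set (least squares with intercept),
correlate the residuals, and adjust the inference for the $k$ partialled
variables ($n-2-k$ dof in $t$, $\sqrt{n-3-k}$ in the Fisher-z interval).
Partial correlation is the one standard estimator that returns the same
report shape (r, CI, t, p) as the crude analysis; with $k = 0$ it reduces
bit-for-bit to the plain correlation test. Collinear adjustment sets are an
error naming the dependent columns.

## Multivariate models

All variables entering a multivariate fit are transformed, cleaned,
standardized to mean 0 / sd 1 (the binary outcome of a logistic fit is left
as 0/1). Three families are implemented:

* **OLS** — normal-equations solution via `lm`, $t$ and $p$ on $n-p-1$ dof,
  adjusted $R^2 = 1 - (1-R^2)(n-1)/(n-p-1)$.
* **Logistic** — IRLS via `glm` (tolerance $10^{-8}$, ≤ 100 iterations),
  Wald $z$ and $p$. Perfect separation (diverging coefficients, or zero
  deviance with all fitted probabilities pinned at 0/1) raises an error
  advising regularization.
* **Lasso** — cyclic coordinate descent on
  $\tfrac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2 + \lambda\lVert\beta\rVert_1$
  to a coefficient-change tolerance of $10^{-7}$; $\lambda$ defaults to
  5-fold cross-validation over a 50-point log grid from $\lambda_{\max}$ down
  to $\lambda_{\max}/1000$ with a seeded fold assignment. No p-values are
  reported: naive inference after L1 selection is invalid.

Feature importance is the percent contribution
$100\,|\beta_k| / \sum_j |\beta_j|$ over the standardized non-intercept
coefficients; contributions sum to 100 whenever any coefficient is nonzero,
and ranking breaks ties by input order. Display rounding is one decimal,
half-away-from-zero, matching the report tables this layout reproduces.

Automatic model choice follows the data's shape: binary outcome → logistic;
$p \ge n/2$ or any pairwise secondary $|r| > 0.9$ → lasso; otherwise OLS.
Gradient-boosting and neural-network families are reserved registry names
that raise a clear not-implemented error: no published formulation exists to
pin an implementation to, and guessing one would be worse than refusing.

## Choropleth rendering

Numeric variables use a continuous light-lavender → dark-purple gradient,
linearly interpolated in RGB over the observed min–max (darker = higher;
RGB-linear interpolation is a cosmetic choice). Categorical variables get a
fixed qualitative palette. Missing regions take a neutral grey and are listed
in the legend; a constant variable renders mid-scale with a "degenerate
range" warning. The SVG writer formats every coordinate deterministically, so
identical inputs give byte-identical files — that is the tested surface. The
HTML output wraps the same SVG with minimal pan/zoom scaffolding and is a
convenience, not a test target.

## The synthetic-data generator

Real catchment tables cannot ship with the package, so the generator builds
tables with *known* structure at the same shape (~77 regions is the
motivating scale; tests typically use 100–500 rows for power):

* `generate_table()` draws a latent multivariate normal with a requested PSD
  correlation matrix, distorts each marginal monotonically (identity /
  exponential / logistic squash — a Gaussian copula, so rank-based methods
  still see the latent structure), then displaces a chosen fraction of cells
  by a multiple of the column IQR. Everything is reproducible from the seed,
  and the generator restores the global RNG state.
* `generate_confounded_table()` implements the three-variable confounding
  model $C \sim N(0,1)$, $X = \beta_{xc} C + e_1$,
  $Y = \beta_{yc} C + \beta_{xy} X + e_2$. With unit effects, unit noise and
  $\beta_{xy} = 0$ the population crude correlation is exactly 0.5 while the
  partial correlation given $C$ is 0 — the textbook spurious association.
  The defaults (n = 200, unit effects, unit noise) are chosen so the
  crude-significant / adjusted-null reversal is detectable in a single run
  with high probability; the closed-form moments ship with the table as the
  `"truth"` attribute.
* `generate_boundaries()` lays unit squares on a
  $\lceil\sqrt n\rceil \times \lceil\sqrt n\rceil$ grid with matching ids —
  enough geometry to exercise joins and rendering.

What the generator does **not** emulate: spatially autocorrelated noise,
realistic polygon geometry, measurement error correlated with population
size. Passing tests therefore demonstrate the statistical machinery, not
robustness to every pathology of real surveillance data.

## Numerical choices and degenerate inputs

* Quantile type 7 everywhere quartiles appear; rank ties by average rank.
* Zero-variance variables are an error ("degenerate variable") in the
  normality ratio, correlation and standardization — silently producing NaN
  would poison downstream stages.
* $|r| = 1$ yields an infinite $t$, $p = 0$ and a collapsed CI at $\pm 1$
  (the Fisher-z endpoints saturate), not an error.
* The log and Box–Cox candidates on non-positive data return an
  infinite-ratio sentinel so selection can skip them without exception
  plumbing.
* Transform-selection ties use fixed simpler-first precedence, making the
  selector a pure function of the data.
* Lasso fold assignment and every other internal use of randomness is seeded
  through an argument and restores the caller's RNG state.

## What the tests and the acceptance script compute

The test-suite sizes are chosen for statistical power at interactive runtimes
(hundreds of seeds at $n = 200$–$2000$). The acceptance script
(`scripts/acceptance.R`) recomputes, from scratch at a caller-supplied seed:
the percent-contribution cells implied by the published example coefficient
tables; the Fisher-z interval for r = 0.568 at the back-solved n = 77; the
rate (over 100 seeded pipeline runs) at which pure confounding produces a
significant crude and null adjusted correlation with the confounder flagged;
OLS recovery error and 95% interval coverage; the identity-rejection rate of
the transform selector on log-normal data; and the IQR removal rate on
standard-normal samples. No number in this vignette or the README is stated
that those scripts and tests do not themselves compute.

## Known limitations

* Regions are treated as independent; no spatial error models (CAR/SAR).
* The change-in-estimate rule is a screening heuristic, not a causal
  identification strategy; no graphs, propensity scores or mediation.
* Percent contribution is a descriptive importance score on standardized
  coefficients; it inherits all the caveats of collinear regressors.
* The lasso reports no inference by design.
* GeoJSON is the only boundary format; shapefiles and geocoding are out of
  scope.
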