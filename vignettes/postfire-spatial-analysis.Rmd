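---
title: "Bayesian kriging of post-fire soil and microbial spatial structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian kriging of post-fire soil and microbial spatial structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firekrige)
```

## The problem

Stand-replacing fire rearranges soil nitrogen pools and the microbial
communities that cycle them, and it does so patchily: two cores a few
metres apart can differ as much as two plots kilometres apart. This
package implements the statistical workflow for asking, on an intensively
sampled burned plot, (i) at what distance soil and microbial variables
stop being autocorrelated, and (ii) whether microbial community
information (lipid biomarkers) improves plot-level predictions of *in
situ* net N mineralization. The sampling context is an 81-core nested
grid in a 50 m × 50 m plot: 9 rows of 9 cores with within-row intervals
of 2, 4, and 8 m, giving comparable pair counts at short and long lags.

## The spatial model

For one response $Y$ (lipid abundance in nmol, a fungi-to-bacteria
ratio, net N mineralization in mg N kg-soil$^{-1}$ yr$^{-1}$, a cover
percentage, ...) observed at locations $u_i$, the hierarchical model is

* Level 1: $Y(u) = X\beta + S(u) + \varepsilon(u)$,
* Level 2: $S(u) \sim \mathrm{N}\big(0,\ \sigma^2 R(h;\phi)\big)$ with
  exponential correlation $R(h;\phi) = \exp(-h/\phi)$,
* Level 3: flat priors on $\beta$ and $\phi$, a reciprocal prior
  $p(\sigma^2) \propto 1/\sigma^2$, and a nugget
  $\varepsilon \sim \mathrm{N}(0, \tau^2)$ parameterized relative to the
  sill, $\tau^2_{rel} = \tau^2/\sigma^2$.

$X$ is by default the linear trend $(1, x, y)$; intercept-only is a
flag. The autocorrelation *range* of the exponential model is defined as
$3\phi$, the lag at which correlation falls to about 0.05.

The observation model is Gaussian. (The field description of this class
of models sometimes says the observations are "exponentially
distributed"; that wording refers to the exponential *correlation
function* — the Gaussian process with exponential covariance is what the
standard model-based-geostatistics machinery, and this package, fit.)

### Discrete-grid posterior

Conditional on $(\phi, \tau^2_{rel})$, the flat-$\beta$ /
reciprocal-$\sigma^2$ priors are conjugate: $\beta$ and $\sigma^2$
integrate out in closed form, leaving

$$p(\phi, \tau^2_{rel} \mid y) \propto
 |V|^{-1/2}\,|X^{\top}V^{-1}X|^{-1/2}\,(S^2)^{-(n-p)/2},
 \qquad V = R(\phi) + \tau^2_{rel} I,$$

with $\hat\beta$ the GLS estimate and
$S^2 = (y - X\hat\beta)^{\top}V^{-1}(y - X\hat\beta)$. The posterior is
evaluated on a discrete grid of $(\phi, \tau^2_{rel})$ cells — 100 × 100
by default — normalized in log space with max-subtraction. The "flat
prior on $\phi$" is uniform mass over the grid cells, matching the
predefined-grid construction, not a continuum density. Exact posterior
draws then come from sampling cells by mass, $\sigma^2$ from its scaled
inverse-$\chi^2$ conditional, and $\beta$ from its Gaussian conditional;
no MCMC is involved, and 100,000 draws is the default.

Per $\phi$ the symmetric eigendecomposition $R = U\Lambda U^{\top}$ is
shared across the whole $\tau^2_{rel}$ grid (adding a nugget only shifts
eigenvalues), so a 100 × 100 grid costs 100 factorizations rather than
10,000. On an 81-core plot the full grid evaluates in well under a
second.

### Default grid bounds

The grids are unstated in the source workflow, so the package chooses:
$\phi$ log-spaced on `[extent/300, extent]` (extent = larger side of the
observation bounding box; for a 50 m plot that is 0.17–50 m, i.e.
ranges $3\phi$ from half a grain to three plot lengths) and
$\tau^2_{rel}$ linear on `[0, 4]` with 0 included. Both are
configurable through `prior_spec()`; analyses whose truth may sit
outside (e.g. extremely noise-dominated data) should widen the
$\tau^2_{rel}$ grid. The posterior mode is reported with a deterministic
tie-break (smallest $\phi$ wins), and the posterior object flags when
the mode sits on a grid edge — a sign the grid, not the data, is
binding (the long-range/low-information regime behaves this way).

### Numerical hygiene

Eigenvalues are clamped at zero; a cell whose smallest shifted
eigenvalue falls below `1e-12` of the largest (e.g. $\tau^2_{rel} = 0$
with $\phi$ far beyond the plot) receives a relative jitter of
$10^{-10}\lambda_{\max}$ rather than being discarded — discarding such
cells would silently exclude exactly the cells that interpolate
noise-free data. The number of jittered cells is recorded on the
posterior object. Cells that remain numerically singular get zero mass
with a warning; an all-degenerate grid is an error.

### Prediction and summaries

For each posterior draw, the conditional mean and variance of the
*signal* ($X\beta + S$, nugget excluded) at each target follow the usual
kriging identities; the surface reports the across-draw mean and the
total variance (mean of conditional variances plus variance of
conditional means). With $\tau^2_{rel}=0$ the predictor interpolates the
data exactly; far beyond the range it reverts to the GLS trend. Summary
quantities — trend intercept, range $3\phi$, sill $\sigma^2$, nugget
$\tau^2_{rel}\sigma^2$, and the noise ratio
$\tau^2/(\tau^2+\sigma^2)$ — are transformed per draw and then
summarized as mean with 5% and 95% quantiles. Because "trend" can also
be read as the fitted plot mean when the trend is non-constant,
`summarize_posterior()` optionally reports `trend_plot_mean`
($\overline{X}\beta$ per draw) alongside the intercept.

### Leave-one-out cross-validation

Each core is predicted from the remaining $n-1$ with a full posterior
refit. Whether the original workflow refit correlation parameters per
fold is unstated; the package refits on a reduced 25 × 25 grid by
default (a flag restores the full grid) — refitting is the conservative
choice and the reduced grid keeps 81 refits to a few seconds. The
per-fold prediction marginalizes the cell posterior analytically
(mass-weighted conditional means; variances combine within-cell
conditional variance at $E[\sigma^2]$, trend-estimate uncertainty, and
between-cell spread), so LOO is deterministic. The reported $R^2$ is the
squared Pearson correlation of observed and predicted, adjusted as
$1 - (1-R^2)(n-1)/(n-p-1)$ — the adjustment formula is a documented
package decision, since only "adjusted cross-validation $R^2$" is stated
in the source workflow.

## The synthetic-data generator

`generate_design()` reconstructs the nested design: rows at
$y = 0, 2, \ldots, 16$ m and within-row intervals
$(2,2,4,4,8,8,4,2)$ summing to 34 m, with the interval order reversed in
the middle three rows. Two points are deliberate reconstructions rather
than facts: the field description ("9 rows separated by 2 m" inside a
50 m plot) is geometrically inconsistent with rows spanning the plot, so
rows sit at 2 m spacing from the origin; and the exact 2/4/8 interval
order is unstated, so a default was fixed once that guarantees lags at
exactly 2, 4, and 8 m. Both are configurable; the true field coordinates
were never published, so this layout is a faithful-as-possible stand-in,
not the actual one.

`simulate_field()` draws one realisation of the exact model above
(Cholesky of $\sigma^2 R$ plus independent nugget noise), so every
downstream stage can be tested against known truth.
`simulate_lipid_table()` produces core × lipid amounts whose plot-mean
mole percents recover a target profile: totals are a Gaussian field
scaled to the requested mean/sd (negative totals truncated at zero),
compositions are Dirichlet draws centred on the profile with a precision
parameter (default 200, roughly the per-lipid dispersion implied by the
bundled plot summaries' standard errors; `Inf` switches compositional
noise off). Profiles that sum to less than 100% — dominant-lipids-only
tables — get an explicit `unassigned` remainder column so the named
lipids keep their stated mole percents; the remainder counts toward
totals but matches no biomarker.

What the generator does *not* emulate: anisotropy, non-Gaussian
responses, compositional covariance between specific lipids, temporal
dynamics, or the unpublished per-core field data themselves. Passing
tests therefore demonstrate that the machinery recovers known truth
under the stated model at the study's design and sample sizes — not
that the model is correct for any particular real plot.

## PLFA metrics

Filtering precedes everything: cores lacking lipid 16:0 are removed
(and listed), and lipid columns with chain length ≥ 20 are dropped. The
name grammar is `[i|a|cy]CHAIN:unsats[wN][c|t][2OH]`, with iso/anteiso
suffix spellings (`15:0iso`) canonicalized to prefix form (`i15:0`);
chain length is the integer before the colon, which makes the < 20 rule
mechanical. Marker matching is exact-first with cis/trans-suffix
tolerance (`16:1w5` in the fungal set matches a `16:1w5c` column),
because both spellings occur in practice. Missing markers contribute
zero rather than erroring; `marker_coverage()` reports what matched.

The fungi-to-bacteria ratio is
`(18:1w9c + 16:1w5) / (a15:0 + i15:0 + 15:0 + i16:0 + 15:1w8c + 16:1w7c
+ cy17:0 + a17:0 + 17:1w7c)`, computed on mole fractions (identical on
raw amounts by scale invariance). Two plot-level summaries exist and
differ: the mean of per-core ratios (what `plot_metrics_summary()`
reports) and the ratio applied to the plot-mean profile
(`fb_ratio(colMeans(...))`). On the bundled Glade-crown profile the
ratio-of-means is 0.79 while the published per-core mean is 0.93; both
modes are exposed because published per-core values cannot be
reconstructed from plot means. Similarly, Gram-positive/negative sums
computed from the bundled mole-percent profiles do not reproduce the
published per-core Gm summaries (which evidently use a different basis);
the package computes mole-fraction sums of the stated marker sets and
leaves reconciliation to the user's data. The `17:1w8` lipid belongs to
no stated marker set and is excluded from all of them. The i15:0/a15:0
stress ratio is flagged undefined (`NA`), not zero, when a15:0 is
absent.

## Net-rate arithmetic and plot comparisons

Pool-dilution net rates are `gross − consumption` in matching units;
negative values are net immobilization. Because published plot values
are ambiguous between mean-of-differences and difference-of-means
(they disagree at the second decimal in one case), `pool_dilution_net()`
computes per row, and plot-level differences can be taken either way.
Two-plot comparisons use Welch's unequal-variance $t$-test — the test
used in the source workflow is unnamed, and Welch is the safe default
when per-plot variances differ.

## Stepwise selection

`stepwise_select()` performs bidirectional AIC stepping from the full
model (intercept start available): at each step all single-term
deletions and additions are scored and the best strictly-improving move
applied, with a deterministic tie-break (deletion preferred, then
alphabetical). AIC counts the error variance as a parameter
($\mathrm{AIC} = -2\ell + 2k$, $k$ = coefficients + 1); the constant
cancels in comparisons, so either convention selects identically.
Exactly collinear candidates (vegetative and non-vegetative cover sum
to ~100%) are reduced to the largest full-rank subset with a warning
before the search. "Fungi" and "Bacteria" as candidate predictors are
the fungal and bacterial marker sums (the F:B numerator and denominator)
as mole fractions. Published selections report signs and significance
bands but not coefficients, so only qualitative reproduction on
synthetic data is possible; the package reports sign, band
(`*` < 0.05, `**` < 0.01, `***` < 0.001, `****` for p below 1e-16, the
"P = 0" convention), AIC, and adjusted $R^2$.

## Problem sizes in the test suite

The suite and the acceptance script size their simulations for a
single-CPU desk run: moment checks use 1000–2000 replicate fields on
reduced designs; parameter recovery uses 50 replicate 81-core plots at
$\sigma^2 = 1$, $\phi = 2$ m, $\tau^2_{rel} = 0.7$ with a 25 × 25 grid
and 10,000 draws per replicate (the regime of the published
noise-dominated posteriors, true range 6 m, true noise ratio 0.41); the
generator's CLT check runs at 2,500 near-independent cores because
spatially correlated totals require an $n \times n$ factorization. The
oracle checks are small by construction: brute-force integration on 3–5
point toys, dense hand kriging on 3 points, exhaustive best-subset over
8 candidates.

## Known limitations

* Isotropy and the exponential family are fixed; Matérn/spherical
  correlation, anisotropy, and non-Gaussian likelihoods are out of
  scope.
* The discrete grid bounds the posterior: data preferring ranges beyond
  the grid pile mass at the edge (flagged, not corrected).
* The nugget and sub-grain spatial variation are confounded below the
  2 m sampling grain; with $\phi$ allowed below the grain, pure-noise
  data yield a flat $\tau^2_{rel}$ posterior at small $\phi$ rather
  than concentrating — an identifiability property of the design, not a
  bug.
* LOO's analytic predictive variance uses the posterior mean of
  $\sigma^2$ within each cell; it omits the heavier-than-Gaussian tails
  of the $t$-like exact predictive, which is immaterial for the $R^2$
  diagnostics it feeds.
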