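---
title: "Acquiescence and exploratory factor analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acquiescence and exploratory factor analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arsefa)
```

# The problem

Agreement-keyed rating scales invite an *acquiescence response style*
(ARS): some respondents tend to agree with items regardless of content.
In a factor-analytic view this adds a nuisance factor with uniformly
positive loadings on every item. When the measurement model of a scale is
explored with EFA, the ARS factor interferes twice: it can change how many
factors the data appear to have, and — once a given number of factors is
extracted — it violates simple structure, so that rotation criteria built
around simple structure misattribute variance. `arsefa` implements a
complete simulation-and-evaluation pipeline for quantifying both effects.

# Generating model

`population_model()` holds the data-generating truth. Latent responses
follow

$$x^*_{ij} = \sum_{q=1}^{Q} \lambda_{jq}\,\eta_{iq} +
  \lambda_{jA}\, a_i + \varepsilon_{ij},$$

and are discretized by strictly ascending thresholds
$\tau_{j,1} < \dots < \tau_{j,C-1}$:
$x_{ij} = c \iff \tau_{j,c} < x^*_{ij} < \tau_{j,c+1}$ (with
$\tau_{j,0} = -\infty$, $\tau_{j,C} = \infty$). This latent-response
route is equivalent to sampling from the normal-ogive graded response
model and avoids an IRT likelihood entirely.

**Content factors.** $\eta \sim N(0, \phi)$, with $\phi = I$ in
replication mode. Content loadings have magnitude 0.506; items are
assigned to factors cyclically. Balanced scales flip the sign of half the
loadings (one factor: the second half of the items; two factors:
alternating within each factor); unbalanced scales are all-positive.
`J` is the *total* scale length (12 or 24); with two content factors each
factor carries `J/2` items, matching the published 12-item two-factor
layouts.

**ARS factor.** Scores are drawn from a normal distribution *censored at
zero from below*: negative draws become exactly 0, giving a mass point of
non-agreers and a right tail of agreers. Two conventions coexist on
purpose:

* The **simulation cells** (`ars_config()` default) censor a *standard*
  normal. The censored scores then have mean $1/\sqrt{2\pi} \approx 0.399$
  and variance $\tfrac12 - \tfrac1{2\pi} \approx 0.341$, so the
  *realized standardized* ARS loadings are the nominal 0.218 / 0.343 /
  0.506 attenuated by $\sqrt{0.341} \approx 0.58$ — an ARS that is
  deliberately weak relative to content, which is what makes its detection
  a nontrivial question.
* The **worked example** (`build_worked_example()`) scales the underlying
  normal so the *censored* scores have exactly unit variance
  ($\sigma = 1/\sqrt{1/2 - 1/(2\pi)} \approx 1.713$). All three factors
  are then on the same unit scale and a large-sample analysis recovers
  the generating $\pm 0.506$ / $0.295$ values directly, which is the
  point of the illustration.

The underlying mean and SD are exposed in `ars_config()`; the positive
mean is essential — it is what shifts item marginals toward the agreeing
categories as ARS strength grows.

**Uniquenesses** are $\psi_j = 1 - \sum_q \lambda_{jq}^2$, treating all
factors as unit-variance. Under the default (censored standard normal)
ARS the realized item variance is slightly below 1; this mild scale
perturbation is an inherent property of this class of generator and is
left in place rather than "corrected", since the analysis side works on
correlation matrices anyway.

**Thresholds.** `build_thresholds(J, C)` places $C-1$ cut points equally
spaced in $[-1, 1]$, lowers them by 1 for the easiest item, and shifts
item $j$ upward by $2(j-1)/(J-1)$ SD, so the easiest and hardest items
differ by exactly 2 SD and adjacent items by $2/11 \approx 0.182$ at
$J = 12$. For 3 categories this is exactly the published grid
($(-2, 0)$ up to $(0, 2)$). For 5 and 7 categories we deliberately use
the same $[-2, 2]$ envelope rather than wider grids: every boundary
category keeps probability at least $\Phi(-2) \approx 0.023$, so the
category-coverage rule below rejects only a rare dataset. Grids with cut
points beyond $\pm 2.8$ SD would make an extreme category a once-in-500
event and the generate-and-reject loop would essentially never accept a
250-person dataset; equating the envelope across $C$ also keeps the
"number of categories" manipulation from being confounded with item
extremity.

**Category coverage.** `generate_dataset()` redraws the entire dataset
until every item exhibits every category (cap: 1000 redraws, then an
error naming the design as infeasible), mirroring the accept/reject rule
used when such data feed polychoric estimation. At the default grids the
rejection rate is on the order of 1% at $N = 250$.

# Estimation pipeline

**Correlations.** `pearson_matrix()` treats category codes as numeric.
`polychoric_matrix()` is a two-step ML estimator: thresholds from
inverse-normal cumulative marginals, then the latent correlation of each
pair by maximizing the bivariate-normal likelihood of its contingency
table. The bivariate normal CDF is computed by Gauss–Legendre quadrature
(24 nodes) on the correlation path
$\Phi_2(a,b;\rho) = \Phi(a)\Phi(b) + \int_0^\rho \phi_2(a,b;r)\,dr$, and
the per-pair maximization runs as a damped Newton scoring iteration
vectorized across all pairs (the score uses the closed-form
$\partial P/\partial\rho$ = density differences), with a golden-section
fallback for pairs that do not converge. Estimates are clamped at
$\pm(1 - 10^{-6})$; the assembled matrix is eigenvalue-clipped to positive
semidefiniteness (threshold $10^{-8}$) when needed, and the smoothing is
recorded.

**EFA.** `fit_efa()` fits the orthogonal ML factor model through
`stats::factanal` (profile likelihood over uniquenesses, Heywood floor
0.001, restarts on non-convergence) and derives the quantities the rest
of the pipeline needs: the ML discrepancy
$F = \log|\Sigma| + \mathrm{tr}(\Sigma^{-1}R) - \log|R| - J$, a
log-likelihood $-\tfrac{N-1}{2}F$ on a constant convention shared across
candidate $q$ (so BIC *differences* are meaningful; absolute BIC values
are convention-dependent), the free-parameter count
$fp = Jq + J - q(q-1)/2$, and the residual matrix. The same machinery is
applied to polychoric matrices as a pseudo-likelihood, since model
selection is reported under both correlation types. $q = 0$ is the
independence model with the observed matrix as residual.

**Dimensionality.** Three criteria, each under both correlation types:

* `select_bic()`: $\mathrm{BIC}_q = -2\,\mathrm{logLik} + fp \ln N$,
  minimized over $q \ge 1$; ties break toward the smaller model.
* `parallel_analysis()`: observed eigenvalues against the 95th percentile
  of 20 reference sets built by independently resampling each item's
  responses (marginals preserved, structure destroyed). The comparison
  uses *reduced* correlation eigenvalues (SMC communalities on the
  diagonal) on both sides by default — the factor-analysis flavor of
  parallel analysis; principal-component eigenvalues are available via
  `eigen_type = "full"`. The reduced default reproduces the published
  sensitivity pattern (high detection of a medium ARS factor, near-zero
  false positives without ARS); the full-eigenvalue variant is noticeably
  less sensitive to the weak ARS factor.
* `chull_caf()`: $\mathrm{CAF}_q = 1 - \mathrm{KMO}(\text{residual}_q)$
  against the free-parameter count, upper convex hull, scree ratio
  maximized over interior hull points. $q=0$ anchors the hull with
  $fp = J$. Residuals are standardized to unit diagonal before KMO; a
  diagonal matrix has KMO 0 by convention, hence CAF 1. With fewer than
  three hull points the procedure falls back to the largest fit gain per
  parameter, with a warning.

Candidate ranges follow the study: up to 3 factors for unidimensional and
4 for multidimensional designs.

**Rotation.** `oblimin_rotate()` is direct oblimin with $\delta = 0$
(quartimin) by oblique gradient projection from 10 random orthonormal
starts (deterministic given a seed; best criterion kept; ties within
$10^{-10}$ broken first-found). No Kaiser normalization is applied
anywhere. `procrustes_oblique()` implements classical no-rescaling target
rotation: each transformation column is the least-squares solution over
its target column's specified cells; a column whose specified values are
all zero (SST content columns) takes the homogeneous solution — the
smallest eigenvector of the specified-row cross-product; an entirely
unspecified column (the SST ARS column) is completed orthogonally, which
leaves that factor uncorrelated with the solved ones; finally the
transformation is rescaled so all factors have unit variance. We
deliberately do *not* minimize the masked criterion jointly under the
unit-variance constraint: for $\pm 1$ fully specified targets that joint
optimum is degenerate (factors collapse toward each other and the pattern
inflates toward the target values — exactly the "rescaling toward the
target" behavior the no-rescaling method exists to avoid). Single-factor
solutions bypass rotation up to a sign. On unbalanced scales the FST
target with an ARS column is structurally unidentified (the all-ones ARS
column is a linear combination of the all-positive content columns); the
rotation raises an error and the driver records no such variant.

**Alignment and outcome measures.** `align_solution()` matches estimated
to generating content factors by maximizing total absolute Tucker
congruence over assignments (exhaustive search; factor counts never
exceed 4), sign-flips to positive congruence, and pins the ARS column to
the target position for informed rotations (for oblimin it is the
leftover column). Metrics: `rmse_loadings()` (true root mean square, over
content or ARS cells), `max_abs_bias_zero()` (per-replicate maximum over
true-zero content cells; its average across replicates is the MMAB),
`rmse_factor_corr()` ($|\hat\phi_{12}|$ against 0), `tpr()` (retention
proportions). All are invariant to column order and sign of the input by
construction, which the test suite checks property-style.

# Study driver and reproducibility

`run_cell()` executes the full per-replicate protocol — generate, both
correlation matrices, EFA over all candidate $q$, all three criteria,
then, irrespective of the selection outcome, rotation of the $Q$- and
$(Q+1)$-factor solutions with every applicable method (oblimin always;
FST always; SST only for multidimensional designs; for unidimensional
scales with the ARS factor extracted, FST is the only informed option) —
and emits tidy `selection` and `recovery` data frames.
`summarize_tpr()` / `summarize_metric()` reproduce the main-effect table
layout. Seeds derive from `(master seed, cell id, replicate, purpose)`
via a multiplicative string hash (`derive_seed()`), so removing one cell
never changes another's draws and every stochastic component is
independently reproducible. Replicate-level failures are recorded and
skipped; a cell fails only if more than half its replicates do.

# Problem sizes

The package's own verification runs at desk scale: 20 replicates per
sub-condition (the original design used 100), candidate subsets of the
full factorial chosen to span each manipulated factor — e.g. the
null-scenario check uses $Q \in \{1,2\} \times$ balanced/unbalanced
$\times N \in \{250, 500\}$ at $C = 5$, $J = 12$, and the recovery sweep
crosses three ARS strengths with both sample sizes and both scale
lengths at $C = 5$. `scripts/acceptance.R --reps` scales the replication
count back up. At 20 replicates, Monte Carlo standard errors on
proportions are about 0.02–0.05, which the tests' tolerances reflect.

# What the generator does and does not emulate

It emulates: ordinal responses with item-difficulty spread, balanced and
unbalanced keying, a weak-to-moderate agreement factor with a realistic
non-agreer mass point, and the accept/reject conditioning on full
category coverage. It does not emulate: disacquiescence (negative ARS
scores), extreme/midpoint response styles, cross-loadings among content
factors, correlated content factors (available via `phi` but not part of
replication mode), missing data, or person-level heterogeneity in
thresholds. Passing tests therefore speak to ARS-as-modeled; real scales
add distortions this generator deliberately leaves out.

# Known limitations

* The polychoric estimator is two-step and pairwise; joint ML would be
  marginally more efficient and its absence is shared with standard
  practice.
* BIC on polychoric input is a pseudo-likelihood criterion; only
  cross-$q$ comparisons are meaningful.
* The 5- and 7-category threshold grids are a feasibility-preserving
  re-gridding of the published design (see *Thresholds*); detection rates
  in cells with many categories run a few points above the originally
  reported ones because the items are somewhat more informative.
* With only 20 replicates, quantities near their published bounds (e.g.
  oblimin MMAB margins near 0.3) can land on either side of the bound in
  any single run.
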