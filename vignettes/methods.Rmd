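---
title: "Methods: two-stage phylogenetic regression of altriciality on self-control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage phylogenetic regression of altriciality on self-control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altripgls)
```

## The question and the model

Across birds and mammals, species whose offspring depend on parental care
for longer (more *altricial* species) are hypothesized to evolve better
inhibitory control. The package quantifies this with two regressions over
31 homeothermic species, fitted under a phylogenetic error structure
because related species are not independent observations.

A PGLS model is ordinary linear regression with correlated errors:

$$ y = X\beta + \varepsilon, \qquad
   \varepsilon \sim \mathcal{N}\!\left(0,\; \sigma^2\, C(\lambda)\right), $$

where $C$ is the Brownian-motion phylogenetic variance–covariance matrix —
$C_{ij}$ is the root-to-tip depth of the most recent common ancestor of
tips $i$ and $j$, $C_{ii}$ the depth of tip $i$ — and $C(\lambda)$
multiplies the off-diagonal of $C$ by Pagel's $\lambda \in [0, 1]$.
$\lambda = 0$ is phylogenetic independence (OLS), $\lambda = 1$ pure
Brownian motion; intermediate values attenuate the phylogenetic signal of
the residuals. $\lambda$ is estimated by maximizing the profile
log-likelihood

$$ \ell(\lambda) = -\tfrac12\!\left[\, n \log\!\big(2\pi\hat\sigma^2_{ML}\big)
   + \log\lvert C(\lambda)\rvert + n \,\right],
   \qquad \hat\sigma^2_{ML} = \frac{\hat e' C(\lambda)^{-1} \hat e}{n}. $$

**Stage 1** regresses $\ln(\text{fledge/wean age})$ on
$\ln(\text{lifespan})$ (both in days) with $\lambda$ at its ML value. Its
*standardized residuals* define the **degree of altriciality**: how much
longer (positive) or shorter (negative) a species' dependent period is
than its lifespan predicts, after accounting for phylogeny.

**Stage 2** regresses the angular-transformed cylinder-task success score,
$\arcsin\sqrt{p/100}$, on the degree of altriciality, with $\lambda$
re-estimated. An OLS contrast ($\lambda = 0$) is fitted alongside, so the
phylogenetic and non-phylogenetic slopes can be compared on one figure.
The stage-1 residuals enter stage 2 as an observed predictor; the
estimation uncertainty of stage 1 is deliberately not propagated — the
procedure is sequential by design.

```{r}
report <- runStudy()
pglsFitTable(report$stage2_pgls)
report$stage2_pgls$lambda_hat
```

## Numerical path

All fits go through the upper Cholesky factor $U$ of $C(\lambda)$
($C = U'U$): response and design are rotated by $U^{-T}$, reducing GLS to
OLS on whitened data, solved by QR. No explicit matrix inverse is formed
anywhere on the fitting path (an explicit-inverse implementation exists
only as a test oracle). $\log\lvert C\rvert = 2\sum_i \log U_{ii}$ falls
out of the same factorization.

Two residual variances are reported: $\hat\sigma^2_{ML}$ (denominator $n$)
enters the likelihood; $\hat\sigma^2$ with denominator $n - p$ enters the
standard errors, matching conventional PGLS software and the published
$df = 29$ for $n = 31$, $p = 2$. Two-sided p-values use the t distribution
with $n - p$ df. The generalized $R^2$ compares the model's weighted
residual sum of squares to that of the GLS-mean-only model under the same
$C(\hat\lambda)$, so it reduces to the textbook $R^2$ at $\lambda = 0$.

$\lambda$ is maximized on $[0, 1]$ by a 0.01-step grid pre-scan followed by
Brent refinement in the bracketing interval (absolute tolerance $10^{-6}$),
and the better of the refined point and the grid argmax is kept. The
pre-scan matters: the profile need not be unimodal (see below). The upper
bound is fixed at 1, the common software default; larger values can break
positive-definiteness.

A covariance whose Cholesky pivots indicate numerical singularity
(relative pivot below $10^{-5}$) is rejected with advice to jitter or
prune near-identical tips, rather than silently producing garbage.

## Residual diagnostics

* **Standardized residuals** (the altriciality scale): the default
  `"tipvar"` mode divides each raw residual by its model-implied standard
  deviation $\sqrt{\hat\sigma^2 C_{ii}}$; the `"zscore"` mode divides the
  vector by its own sample SD. Which of the two the original analysis used
  is not determinable from the published numbers; on an ultrametric tree
  (all $C_{ii}$ equal — true of the bundled chronogram) they differ only
  by a common factor, and every stage-2 statistic except the slope/SE pair
  (which rescale reciprocally) is invariant to that factor. The package
  defaults to `"tipvar"` for depth-awareness on non-ultrametric inputs and
  exposes the switch.
* **Studentized phylogenetic residuals**: raw residuals are whitened by
  $U^{-T}$ and internally studentized with the leverages of the whitened
  design; $|r_i| \ge 3$ flags an outlier. With identity covariance this is
  exactly `rstandard()` of the OLS fit. The study data flag nothing at
  either stage.
* **Q-Q data**: theoretical quantiles at $(i - 0.5)/n$ against the ordered
  whitened residuals, returned as coordinates; plotting is the caller's
  concern.

## The bundled data and tree

`inst/extdata/table1.csv` transcribes the source table verbatim: 31
species (6 birds, 25 mammals), cylinder-task % success in $[26.5, 100]$,
fledging/weaning age 17–1936 d, lifespan 730–21681 d. Two legacy spellings
("Columbia livia", "Rhinopithecuas roxellana") are preserved in the data
and bridged to tree tips by an explicit alias map, never by fuzzy matching.
A point worth knowing: the summary statistics recomputed from these raw
values agree with the published ones exactly for the cylinder column
(mean 64.471, SD 22.017) but differ in the second decimal for the other
two (e.g. 305.323 vs 305.306) — the source's printed raw table is not
perfectly consistent with its own printed summaries. The package always
reports what it computes from the raw values.

The source publishes the tree topology but not its branch lengths.
`inst/extdata/chronogram_32sp.nwk` is therefore a reconstruction: the
published 32-species topology with node ages compiled once from standard
divergence-time resources (TimeTree-style medians; 10kTrees for the
primate clade; a 15 kya wolf/dog split), recorded per node in
`chronogram_provenance.tsv`. Branch lengths are in millions of years; all
regression statistics except $\hat\sigma^2$ are invariant to the unit
(tested). The pipeline prunes the 32nd species (*Melospiza georgiana*,
which has no trait data) before fitting.

Consequences of reconstructed branch lengths are confined to the
tree-dependent statistics and are worth stating plainly. On this
chronogram the stage-1 profile likelihood is *bimodal*: an interior mode
near $\lambda \approx 0.99$ and the global maximum at the boundary
$\lambda = 1$. The boundary spike is real, not numerical — the 15 kya
wolf/dog split contributes a contrast with variance $0.03$ Myr against a
312 Myr tree depth, and the two species' nearly equal weaning ages make
that tiny-variance contrast very likely under $\lambda \to 1$. The package
honours its contract (global argmax) and reports $\hat\lambda = 1$,
$t = 3.67$, $r^2_{adj} = 0.294$ for stage 1; the published values
($\lambda = 0.987$, $t = 2.781$, $r^2_{adj} = 0.183$) sit close to the
*interior* mode ($\lambda = 0.99 \Rightarrow t = 2.64$,
$r^2_{adj} = 0.166$), which is where a purely local optimizer started in
the interior would converge. Stage-2 statistics, which depend on the tree
only through the residual vector and the covariance, land within a few
hundredths of the published ones, and the OLS contrast — which uses no
branch lengths directly — reproduces them almost exactly
($t = 3.289$ vs published $3.2880$; $r^2_{adj} = 0.2465$ vs $0.2464$).
`lambdaProfile()` exposes the full profile so users can inspect such
surfaces themselves.

## Normality statistics

`lillieforsD()` computes the one-sample Kolmogorov–Smirnov distance
against a normal with mean and SD estimated from the sample, evaluating
both one-sided gaps at every order statistic (this matches the reference
implementation in `nortest` to $10^{-12}$, by test). Because the source
reports only p-value *bounds* at the conventional table levels,
`lillieforsBound()` classifies $D$ against critical values at
$\alpha \in \{0.20, 0.15, 0.10, 0.05, 0.01\}$, simulated under the null
with a fixed internal seed (20 000 replicates, cached per sample size) —
the same construction that produced the published tables. The asymptotic
coefficients $0.736/0.886/1.031$ over $\sqrt{n}$ agree with the simulated
values to a few percent at $n = 31$.

## The synthetic-data generator

The generator exists so every stage is testable with known ground truth.
`simulateTree()` draws a pure-birth (Yule) tree — rate 1 by default, depth
rescaled to exactly 1 — so tree shape varies across replicates;
`simulateTraits()` evolves the predictor as Brownian motion
($x \sim \mathcal{N}(0, C)$) and the response as
$y = \beta_0 + \beta_1 x + \varepsilon$ with
$\varepsilon \sim \mathcal{N}(0, \sigma^2 C(\lambda))$, both drawn through
Cholesky factors. Defaults ($n = 31$ tips, $\beta = (0, 1)$,
$\lambda = 1$, $\sigma^2 = 1$) mirror the study's sample size and a unit
signal. The optional life-history mode maps $x$ and $y$ monotonically onto
magnitudes like the real table: lifespans in $[700, 22000]$ d (log-scale
map), rearing periods in $[15, 2000]$ d and below 95 % of lifespan, and a
logistic-bounded percentage in $(0, 100)$.

What the generator does *not* emulate: measurement error in the cylinder
score, non-Brownian trait evolution, correlated predictors, or the
phylogenetically clumped sampling of the real 31 species (heavy in
primates). Passing recovery tests therefore demonstrates the estimator is
correct under its own model assumptions, not that the empirical study's
conclusions are robust to violations of them.

All randomness is integer-seeded; per-replicate seeds in
`recoveryExperiment()` derive deterministically from the base seed, cell
index and replicate index, and draws restore the session RNG state. The
recovery experiments used by the test suite and the acceptance script run
200 replicates per cell at $n = 100$ tips for estimator bias and 400
replicates for the type-I error of the slope test — sizes at which the
Monte-Carlo standard error of the slope mean is about 0.01 and the
binomial half-width of a 5 % rejection rate about 0.02.

## Known limitations

* Branch lengths of the bundled chronogram are a reconstruction; all
  tree-dependent statistics inherit that uncertainty (quantified above).
* $\lambda$ is restricted to $[0, 1]$; no other branch-length transforms
  (Grafen's $\delta$, $\kappa$, OU) are offered.
* Stage-2 inference treats the altriciality vector as known; a joint or
  errors-in-variables model is out of scope.
* The Lilliefors p-values are reported as table bounds, not exact values,
  matching how such results are conventionally printed.
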