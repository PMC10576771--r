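---
title: "Correlated-factors ACE models for twin data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated-factors ACE models for twin data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
```

This vignette documents the statistical model behind `twinace`, the
numerical choices in its implementation, what the synthetic-data generator
does and does not emulate, and the design decisions that were genuinely
open.

## The biometrical model

The classical twin design decomposes phenotypic variance into additive
genetic (A), shared environmental (C) and nonshared environmental (E)
sources using the contrast between monozygotic (MZ) pairs, who share all
segregating genetic variants, and dizygotic (DZ) pairs, who share half on
average.  C makes co-twins similar regardless of zygosity; E is unique to
each twin and absorbs measurement error, which is why the fitted E variance
must stay positive while A and C need not.

For p traits, the correlated-factors parameterization assigns each trait
its own A, C and E factor with unit variance and lets same-type factors
correlate across traits (rA, rC, rE).  On the phenotype scale this is
equivalent to three symmetric p×p component matrices whose sum is the
within-twin covariance.  The expected covariance of the stacked pair
vector (twin 1's traits, then twin 2's) is

    Sigma_z = | W  X_z |      W = A + C + E,
              | X_z  W |      X_MZ = A + C,  X_DZ = A/2 + C.

All structural quantities reported to the user are derived from the fitted
components: standardized shares `a_j = A_jj / W_jj` (similarly c, e),
etiological correlations `rA_jk = A_jk / sqrt(A_jj A_kk)`, implied
phenotypic correlations
`rph_jk = rA_jk sqrt(a_j a_k) + rC_jk sqrt(c_j c_k) + rE_jk sqrt(e_j e_k)`,
and the per-component shares of each `rph`.

Assumptions inherited from the design: random mating, equal trait-relevant
environments for MZ and DZ pairs, no gene–environment correlation or
interaction, no dominance (the MZ/DZ correlation patterns in the intended
applications are consistent with additive transmission), and multivariate
normal phenotypes.  Twin order within a pair is treated as exchangeable.

## Likelihood and missing data

Models are fitted by full-information maximum likelihood: each pair
contributes

    k_i log(2 pi) + log|Sigma_i| + (y_i - mu_i)' Sigma_i^{-1} (y_i - mu_i)

over its k_i observed values, with `Sigma_i`, `mu_i` the matching submatrix
and subvector of the zygosity-appropriate structure.  This is valid when
values are missing (completely) at random — the only mechanism the
generator produces and the one the method is stated for.  Pairs with all
values missing carry no information and are dropped at load time with a
warning.

Internally, rows are grouped by (zygosity × missingness pattern) and
reduced to per-pattern sufficient statistics (count, sum vector,
cross-product matrix), so one likelihood evaluation costs O(number of
patterns), not O(number of pairs).  The test suite checks this
implementation against a naive per-pair loop and against the closed-form
two-group moment expression on complete data at tolerance 1e-8.

One mean per trait is estimated, shared across twins and zygosity groups;
after sex residualization the data are near-centered anyway, and the
constrained saturated model (below) makes the same assumption, keeping the
mean structure comparable across the whole model chain.

## Direct variance estimation

Free components are parameterized directly by their p(p+1)/2 symmetric
entries.  Diagonals are deliberately *not* squared or Cholesky-factored:
bounding a variance component at zero puts the null hypothesis of a
likelihood-ratio test on the boundary of the parameter space and biases the
test, whereas the direct parameterization leaves the null in the interior.
The cost is that standardized shares can come out slightly negative in
small samples; they are reported signed and annotated, never truncated.
Only the total covariance `A + C + E` is required to be positive definite
at the solution (the fit is flagged otherwise).

## The constrained saturated baseline

The baseline ("constrained saturated") model equates means and variances
across twin order and zygosity and leaves all covariances free per
zygosity: the within-twin cross-trait covariances and the symmetric
cross-twin blocks `X_MZ`, `X_DZ`.  At p = 3 this has 24 free parameters.

Two aspects of this choice were genuinely open:

- *Which covariances to free.*  Equating the within-twin block across
  zygosity as well looks natural but collapses the baseline onto the ACE
  model itself: `{W, X_MZ, X_DZ} -> {A, C, E}` is a linear bijection when
  the components are unrestricted symmetric matrices, so the "saturated"
  model would have exactly the ACE parameter count and the overall-fit test
  would be vacuous (0 df).  Freeing the within-twin covariances per
  zygosity makes ACE a strict submodel (3 df at p = 3): the genetic model
  additionally asserts that the phenotypic covariance structure is the same
  in both zygosity groups.
- *Reporting a single phenotypic correlation.*  With per-zygosity
  within-twin blocks there are two fitted `rph` estimates per trait pair;
  the report pools them with pair-count weights (both blocks remain
  available in the fit object), and profile intervals for `rph` profile the
  pooled quantity directly.  The constraint set is recorded verbatim in the
  fit's metadata.

For a single trait the baseline and the ACE model coincide
(4 parameters each) — a known feature of univariate twin models, not an
error.

## Optimization

Quasi-Newton minimization (`nlminb`, PORT) with numerically approximated
gradients; convergence tolerance 1e-10 (relative) on -2LL.  Starting values
are moment-based: within- and cross-twin sample covariances are mapped to
components through the MZ/DZ expectation equations (for AE,
`A0 = (X_MZ + X_DZ/2)/1.25`, the least-squares solution in the cross
blocks), E is floored to a safely positive-definite matrix, and cross
blocks are clamped just inside the correlation bound so data near a
singular boundary (e.g. near-duplicate co-twins) start close to it.
`fit_ace` runs a default of 5 starts — the moment start plus seeded
perturbations — and keeps the best converged solution.  A non-PD covariance
during search returns a large finite penalty (1e10) rather than an error so
the line search can back off.

Two numerical details matter in practice.  First, with numerical gradients
a large-n objective (|-2LL| ~ 1e6) can stall in PORT with status "false
convergence" at the optimum; the fitter reruns once from the stall point
and accepts the solution if no further improvement is found.  Second,
likelihood dominance across the nested chain (saturated ≤ ACE ≤ AE/CE ≤ E)
is asserted in the tests at tolerance 1e-6; a slightly negative
likelihood-ratio statistic from optimizer noise is clamped to zero for the
p-value with a warning, and flagged as a dominance violation beyond 1e-4.

## Profile-likelihood confidence intervals

A 95% interval for a parameter or derived quantity collects the values at
which the -2LL, re-minimized over all other parameters, rises by
qchisq(0.95, 1) = 3.84 above the minimum.  Derived targets are profiled by
constrained reparameterization — the target is fixed at a trial value and
one matrix entry is solved for it:

- standardized share `a_j = t`: `A_jj = t/(1-t) * (C_jj + E_jj)`;
- etiological correlation `rA_jk = t`: `A_jk = t sqrt(A_jj A_kk)`;
- saturated-model correlations: the corresponding covariance entry, with
  the pooled `rph` solving the weighted-average constraint for the MZ
  entry.

Bound search uses a one-point curvature probe to predict the crossing
(exact if the profile were quadratic), expands the bracket geometrically if
needed, and root-finds the crossing with warm-started inner optimizations.
A bound that cannot be bracketed inside the parameter domain (e.g. a share
profiled toward 1) yields a one-sided interval with a warning rather than
an error.  The tests verify the machinery on a quadratic toy problem
(interval 2 ± sqrt(3.84) recovered to 1e-4), against a dense grid search of
the profiled likelihood (1e-3), and by a 100-replicate coverage study at
study scale (nominal 95%, asserted within 90–99%).  A pair-resampling
bootstrap (resampling within zygosity, seeded) is available as an
alternative interval method for the saturated model's correlations.

## Model comparison conventions

Fit tables follow the behavior-genetics convention of reporting model fit
relative to the data degrees of freedom (observed non-missing values minus
free parameters): `AIC = -2LL - 2 df` and `BIC = -2LL - df ln(n pairs)`.
Because df differences equal free-parameter differences on shared data,
AIC *differences* are identical to the standard `-2LL + 2k` convention,
which is emitted alongside (as is the standard BIC) so users comparing
against other software are not misled.  Model selection applies a combined
rule: among models with AIC within 10 of the minimum *and* a
nonsignificant likelihood-ratio test against the full model at 0.05, the
most parsimonious is chosen; ties are broken by the documented label order
ACE < AE < CE < E and flagged.

## The synthetic-data generator

`simulate_twins` draws latent factor scores exactly as the model assumes:
A scores jointly normal across co-twins with cross-twin correlation 1 (MZ)
or exactly 0.5 (DZ, the additive expectation), C drawn once per pair, E
independently per twin, each with the requested cross-trait correlation
matrix, then scales by the square roots of the standardized shares.
Defaults mirror a large UK adolescent twin register: 429 MZ and 707 DZ
pairs, MZ male-pair fraction 145/429, DZ male/female/opposite-sex mix
138/227/342, and missingness completely at random (default rate 0).  Sex
enters as an additive mean shift only (default 0) — matching a
sex-residualization preprocessing step, not a sex-limitation model.

What the generator does *not* emulate: selective attrition or informative
missingness, assortative mating, dominance, gene–environment correlation or
interaction, sex differences in variance structure, floor/ceiling effects
and the discreteness of Likert-scale scores.  Passing recovery tests on
this generator therefore demonstrates correctness of the estimation
machinery under the model's own assumptions — not robustness of the model
to their violation in real questionnaire data.

## Problem sizes in the test suite

The suite balances statistical resolution against runtime on one CPU:
closed-form identities use exact tolerances (1e-8 to 1e-12); Monte-Carlo
checks of the generator use 1e5–8e5 pairs with tolerances set at or beyond
3 standard errors; parameter-recovery and CI-coverage studies use 100
seeded replicates at the study scale of 429 + 707 pairs (medians asserted
within ±0.02 of truth; coverage within 90–99%).  The acceptance script uses
the same 100-replicate protocol.

## Residualization

Covariate adjustment regresses each trait on sex by OLS, pooling all
individuals (both twins, both zygosity groups) into one long sample per
trait — the conventional preprocessing before twin-model fitting.  Age is
not adjusted (the intended application residualizes on sex only).
Individuals with an observed trait but missing sex have the trait set
missing (logged) rather than imputing the covariate.  The operation is
idempotent and commutes with row order, both asserted in tests.

## Decomposition conventions

The denominator of the per-component shares of a phenotypic correlation is
the *model-implied* `rph`, not the saturated-model estimate: with the
implied denominator the A/C/E shares sum to one exactly, and reproducing a
published decomposition table from its own printed standardized estimates
works through the same identity.  Shares against an observed (saturated)
`rph` are also emitted when one is supplied, since readers sometimes quote
that ratio.  Shares are undefined (flagged, not an error) where
|rph| < 1e-6, and undefined etiological correlations (zero or negative
component variance) propagate as NA with the trait flagged.

## Known limitations

- Ordinal/threshold liability models are out of scope; Likert-type scores
  are treated as continuous, as is common at 5+ categories.
- No sex-limitation (scalar or non-scalar) or dominance (ADE) models;
  opposite-sex DZ pairs are pooled with same-sex pairs after
  residualization.
- Profile intervals assume the usual chi-square calibration; very small
  samples or boundary solutions may degrade it (the bootstrap alternative
  is available for the saturated model).
- FIML is valid under missingness (completely) at random only.
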