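# twinace

Multivariate twin analysis with correlated-factors ACE models.

`twinace` implements the classical twin design for one or more correlated
phenotypes measured on monozygotic (MZ) and dizygotic (DZ) twin pairs.  It is
aimed at behavior-genetics and epidemiology researchers who want a compact,
scriptable alternative to a full structural-equation stack for the standard
twin workflow: twin correlations, variance decomposition, nested model
comparison, and the decomposition of phenotypic correlations into genetic and
environmental shares.

## The model

Phenotypic variance is decomposed into additive-genetic (A),
shared-environmental (C) and nonshared-environmental (E) components,
identified by the MZ/DZ contrast: MZ co-twins share all segregating additive
genetic variance, DZ co-twins half of it on average, and C by definition
equally.  For p traits the correlated-factors parameterization gives each
trait its own A, C and E factor (unit variance) with free correlations rA,
rC, rE among same-type factors.  Writing a_j, c_j, e_j for the standardized
variance shares of trait j (a_j + c_j + e_j = 1), the model implies

- twin correlations: `rMZ_j = a_j + c_j`, `rDZ_j = a_j/2 + c_j`;
- phenotypic correlations:
  `rph_jk = rA_jk sqrt(a_j a_k) + rC_jk sqrt(c_j c_k) + rE_jk sqrt(e_j e_k)`;
- cross-twin cross-trait (CTCT) correlations: the same expression without
  the E term (MZ) and with the A term halved as well (DZ).

The share of a phenotypic correlation carried by a component is its term in
the sum divided by the implied `rph` — e.g.
`%rph due to A = rA_jk sqrt(a_j a_k) / rph_jk`.

Models are fitted to wide per-pair tables by full-information maximum
likelihood (each pair contributes a multivariate-normal density over its
non-missing values only), with the components parameterized directly by
their symmetric matrix entries ("direct variance estimation"): variance
components are not squared or Cholesky-factored, may go slightly negative,
and therefore support unbiased likelihood-ratio tests.  A constrained
saturated model (means and variances equated across twin order and
zygosity, covariances free per zygosity) provides the baseline likelihood;
ACE and its AE/CE/E submodels are compared by chi-square difference tests
and the fit-table information criteria `AIC = -2LL - 2 df`,
`BIC = -2LL - df ln(n pairs)` (the standard +2k conventions are reported
alongside).  Confidence intervals come from profile likelihood, with a
pair-resampling bootstrap as an alternative.

A seeded simulator generates twin-pair tables from any correlated-factors
structure (with sex mean shifts and completely-at-random missingness), so
every stage can be validated against known ground truth.

## Worked example

Simulate a study-sized trivariate sample (429 MZ and 707 DZ pairs; traits
named after a presence/wellbeing battery) from an AE structure with
heritabilities 0.34/0.42/0.57 and genetic correlations 0.22/0.36/0.80, then
run the full workflow:

```r
library(twinace)

params <- generating_params(
  a  = c(0.34, 0.42, 0.57), e = c(0.66, 0.58, 0.43),
  rA = matrix(c(1, 0.22, 0.36, 0.22, 1, 0.80, 0.36, 0.80, 1), 3),
  rE = matrix(c(1, 0.15, 0.14, 0.15, 1, 0.47, 0.14, 0.47, 1), 3),
  nMZ = 429, nDZ = 707, seed = 2011)
twins <- simulate_twins(params, traits = c("presence", "happiness", "lifesat"))
twins <- residualize(twins, "sex")

sat <- fit_constrained_saturated(twins)
correlation_report(sat, ci = "none")
#> Phenotypic correlations (rph):
#>           presence happiness lifesat
#> presence      1.00      0.17    0.21
#> happiness     0.17      1.00    0.63
#> lifesat       0.21      0.63    1.00
#> Twin correlations:
#>    presence happiness lifesat
#> MZ     0.35      0.40    0.60
#> DZ     0.12      0.18    0.24
#> ...
```

MZ correlations roughly double the DZ ones: additive genetic plus nonshared
environmental influences.  Compare the nested models:

```r
fits <- lapply(c("ACE", "AE", "CE", "E"), function(m) fit_ace(twins, m, seed = 1))
comp <- do.call(compare_models, c(list(sat), fits))
comp[, c("label", "minus2ll", "df", "chi2", "delta_df", "p_value", "aic")]
#>       label minus2ll   df     chi2 delta_df    p_value    aic
#> 1 saturated    17864 6792       NA       NA         NA 4279.9
#> 2       ACE    17869 6795   4.7381        3 1.9201e-01 4278.6
#> 3        AE    17877 6801   8.5744        6 1.9897e-01 4275.2
#> 4        CE    17951 6801  82.1831        6 1.2641e-15 4348.8
#> 5         E    18206 6807 337.6366       12 5.6761e-65 4592.2
select_model(comp)$label
#> [1] "AE"
```

Dropping C costs nothing (p = 0.20) while CE and E are firmly rejected; the
parsimony rule (AIC within 10 of the minimum, nonsignificant LRT against the
full model, fewest parameters) selects AE.  Decompose it:

```r
ae <- fits[[2]]
decompose(ae)
#>       presence happiness lifesat
#> std_a     0.33       0.4    0.59
#> std_e     0.67       0.6    0.41
#> Genetic correlations (rA):   presence-lifesat 0.34, happiness-lifesat 0.84
#> Share of rph due to A:       presence-lifesat 0.70, happiness-lifesat 0.64
profile_ci(ae, list(type = "std", comp = "A", trait = 3))
#> (0.54, 0.64)
```

The fitted heritabilities (0.33/0.40/0.59), genetic correlations and
genetic shares of the phenotypic correlations recover the generating values
within sampling error, and the 95% profile interval for the third trait's
heritability covers the generating 0.57.

A thin command-line driver over the same functions lives in
`inst/cli/twinace.R` (subcommands `simulate`, `saturated`, `fit`,
`compare`, `decompose`, `run`); `run_pipeline()` executes the whole chain
from a YAML config and writes JSON reports.

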