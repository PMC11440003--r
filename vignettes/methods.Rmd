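---
title: "Methods: Rasch calibration, fit diagnostics, and lasso-penalised DIF"
author: "raschdif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Rasch calibration, fit diagnostics, and lasso-penalised DIF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raschdif)
```

## The measurement problem

Caregiver-reported screening checklists such as the 57-item Autism
Behavior Checklist (ABC) record, item by item, whether a child shows a
described behaviour. The clinical score is a weighted sum (each endorsed
item contributes its catalogue weight of 1–4 points, with a positive
classification above 67 points), but the weighted total is an ordinal
summary: it says nothing about whether the items jointly measure one
construct, whether individual items behave consistently with that
construct, or whether an item reads differently for a boy than for a
girl at the same severity. This package addresses those three questions
for any dichotomous instrument of this shape: calibration under the
Rasch model, item-level fit assessment, and uniform differential item
functioning (DIF) detection — with a synthetic-data generator so the
whole pipeline can be validated without access to clinical records.

## The Rasch model and its calibration

The dichotomous Rasch model puts persons and items on one interval
(logit) scale:

$$ P(x_{pi} = 1 \mid \beta_p, \delta_i)
   = \frac{e^{\beta_p - \delta_i}}{1 + e^{\beta_p - \delta_i}}, $$

with $\beta_p$ the person's ability (here: severity of the measured
trait) and $\delta_i$ the item's difficulty (here: how severe a case
must be before the behaviour is typically reported). A gap of 2 logits
corresponds to endorsement probabilities of about 12% (item above
person) or 88% (item below person).

`estimate_jml()` maximises the joint likelihood over all $\beta_p$ and
$\delta_i$ — the computation style of WINSTEPS-class software, whose
output conventions the diagnostics below follow. The raw score is
sufficient for $\beta_p$, so persons with equal scores receive equal
abilities. Choices that matter:

* **Gauge.** The model is invariant to a common shift of all parameters;
  we pin it by centering item difficulties to mean zero each cycle, the
  usual convention that makes "0 logits" the mean item difficulty.
* **Estimability.** Persons or items with all-0/all-1 observed responses
  have no finite maximiser. `screen_extremes()` removes them
  iteratively (removing an extreme item can create a newly extreme
  person) and reports every removal; their measures are flagged missing
  rather than extrapolated, because extrapolation constants are a
  software convention, not part of the model.
* **Updates.** Alternating damped Newton steps (per-parameter step cap of
  1 logit) on the person block then the item block; convergence when the
  largest absolute parameter change falls below `tol = 1e-6` logits,
  with `max_iter = 100` cycles. Starting values are the centered logits
  of score proportions, so the procedure is deterministic.
* **Missing data** are treated as not administered and excluded pairwise
  from every sum (likelihood, information, residuals, counts). Nothing
  is imputed.
* **Bias.** Joint maximum likelihood difficulties are biased outward by
  roughly $L/(L-1)$ at small item counts; an optional `(L-1)/L`
  multiplier (`bias_correction`, default off) is provided. It is off by
  default because the reference outputs this package mirrors do not
  apply it.

Standard errors are observed-information ones:
$\mathrm{se}(\delta_i) = 1/\sqrt{\sum_p P_{pi}(1-P_{pi})}$ over the
persons who answered item $i$, and symmetrically for persons. At the
scale of the motivating study (3,319 respondents, $P \approx 0.5$) this
gives item standard errors near $2/\sqrt{n} \approx 0.035$ logits.

## Fit diagnostics

Residuals are standardised per cell,
$z_{pi} = (x_{pi}-P_{pi})/\sqrt{P_{pi}(1-P_{pi})}$. Outfit MNSQ is the
plain mean of $z^2$ over an item's (or person's) observed cells; infit
MNSQ is the information-weighted version
$\sum W z^2 / \sum W$ with $W = P(1-P)$, which damps the influence of
responses far from a person's level. Both have expectation near 1 under
the model; values above 1 indicate noise, below 1 over-determinism.

Zstd standardises an MNSQ by the Wilson–Hilferty cube-root
transformation using the statistic's model variance (for a Bernoulli
cell $\operatorname{var}(z^2) = 1/W - 4$ and
$\operatorname{var}((x-P)^2) = W - 4W^2$). Reported Zstd is clamped to
±9.9, mirroring how fit tables conventionally print extreme values; the
clamp is display behaviour, not truncation of the underlying statistic
within the computation.

`flag_misfit()` applies acceptance windows to the infit columns, by
default MNSQ in [0.75, 1.33] and Zstd in [−2, 2]; both windows are
arguments, so stricter or looser conventions (0.5–1.5, ±3) are one call
away. Separation and reliability come from the variance decomposition:
error variance is the mean squared standard error, true variance the
observed variance of the measures minus error (floored at zero),
$G = \sqrt{\text{true}/\text{error}}$ and
$R = \text{true}/\text{observed} = G^2/(1+G^2)$ identically. These are
*model-based* indices; the misfit-inflated "real" variants some software
also prints use an inflation rule that is not part of this package's
scope, and outputs are labelled accordingly.

## Unidimensionality: PCA of standardised residuals

If one latent dimension drives the responses, the standardised
residuals should be unstructured. `residual_pca()` eigendecomposes the
item × item correlation matrix of standardised residuals
(pairwise-complete over observed cells; item pairs sharing fewer than
`min_overlap = 30` persons are flagged). Correlation rather than
covariance is used because that is the convention of the residual-PCA
implementations this analysis style comes from. Eigenvalues are in item
units and sum to the number of items; a first contrast of 2 or more —
two items' worth of shared residual structure — signals a secondary
dimension. The variance explained by the measures uses the
observation-variance split: each observed cell carries unit residual
variance ($L$ per person in total), while the model-explained portion is
$V = \sum_i \operatorname{mean}_p[P_{pi}(1-P_{pi})(\beta_p-\delta_i)^2]$,
so percent explained $= 100\,V/(V+L)$. The unidimensionality flag
combines the two published rules (≥ 40% explained, first contrast < 2);
the descriptive measure-to-contrast ratios $V/\lambda_k$ are reported
but deliberately excluded from the flag. Loadings are sign-indeterminate
per contrast; we fix the sign so each contrast's largest-loading item is
positive. The conventional 0.4 loading cut-off is the default of
`contrast_loadings()`.

Note that the percent-explained depends on targeting: it grows with the
spread of persons relative to items. Synthetic data from a
standard-normal trait over items spanning ±2 logits sit well below the
~60% a wide clinical sample can reach, so validation checks rest on the
contrast eigenvalue, not on reproducing any particular percentage.

## Uniform DIF by lasso-penalised marginal maximum likelihood

Uniform DIF means an item's difficulty shifts by a constant for a
demographic group at equal latent trait. The model is a two-parameter
logistic with group shifts:

$$ \operatorname{logit} P(x_{pi}=1)
   = \alpha_i\,(\theta_p - \delta_i - x_p^\top \gamma_i), $$

where $x_p$ dummy-codes gender, age group, and symptom class against
reference levels (female, high-school age, severe symptoms — the
majority-complement coding in which a reference person has an all-zero
row), and $\gamma_{ik} \ne 0$ is uniform DIF of item $i$ for group $k$.
A negative $\gamma_{ik}$ makes the item easier (more readily endorsed)
for that group. One coefficient is fitted per dummy column, not per
factor, so each age level can shift an item independently. The latent
trait is standard normal, integrated by Gauss–Hermite quadrature
(21 nodes by default; accuracy is insensitive to the node count beyond
~15 for these well-behaved integrands). With all $\gamma \equiv 0$ the
model is the plain marginal 2PL; a Rasch-constrained variant
(`rasch_constrained = TRUE`, all $\alpha_i = 1$) is available.

The penalised objective is the marginal log-likelihood minus
$\lambda \sum_{i,k} |\gamma_{ik}|$. The L1 penalty shrinks DIF
coefficients exactly to zero, so DIF detection becomes model selection
along a penalty path:

* $\lambda_{\max}$ — the smallest penalty with all $\gamma$ at zero — is
  computed from the score equations at the no-DIF fit, so the first
  path model is exactly the null model.
* The path is log-spaced from $\lambda_{\max}$ down to
  $\lambda_{\max}/1000$ (`n_lambda = 50` by default), each model
  warm-started from the previous.
* Each model's $\mathrm{BIC} = -2\,\ell + \log(n_{\text{persons}})
  \cdot \mathrm{df}$, with df counting item parameters plus DIF
  coefficients whose magnitude exceeds the reporting threshold
  (`zero_threshold = 1e-4`). `select_bic()` takes the minimum, ties
  broken toward the larger $\lambda$ (the sparser model).

Optimisation is an EM algorithm. The E-step computes posterior node
weights per person (persons sharing a covariate pattern are aggregated,
so the M-step works on pattern × node expected counts — a few hundred
rows regardless of sample size). The M-step updates each item by a
damped Newton step on $(\alpha_i, \delta_i)$ followed by coordinate
soft-threshold updates of $\gamma_{i\cdot}$; every update is accepted
only if it does not decrease the item's penalised expected complete-data
objective (backtracking line search), which keeps the EM ascent
guaranteed and was necessary in practice — unguarded Newton steps
oscillate on flat likelihoods. Iteration stops when the largest
parameter change falls below `tol = 1e-4` or the penalised objective
stalls (relative change below 1e-9). Discriminations are floored at
0.02 to keep $\alpha_i > 0$; a fit pressing that floor indicates an item
carrying essentially no information about the trait.

Because lasso estimates are shrunken, a selected coefficient's
magnitude understates the generating shift (simulations with a planted
shift of 1.0 logit recover BIC-selected estimates around 0.4–0.8); the
*detection* decision, not the shrunken magnitude, is the inferential
output. Impact — a true group difference in the trait distribution — is
largely absorbed by the person-level posterior rather than the item
coefficients, which is what makes item-level DIF flags meaningful in
samples with real group differences; the generator exposes
`theta_shift_by_group` precisely so this distinction stays testable.
Non-uniform DIF (group-specific discriminations) is out of scope.

## The synthetic-data generator

`default_abc_config()` encodes the study conditions the package is
validated against: 3,319 persons; 57 items with difficulties equally
spaced on [−2, 2] logits except two near-universal behaviours at −4.22
and −4.27 and one rare behaviour at +1.1 (mimicking the published
difficulty span); unit discriminations; standard-normal trait; and the
published demographic margins (79.69% male; age groups 42.60 / 45.28 /
11.45 / 0.6 / 0.07%; symptom classes 34.20 / 43.57 / 22.23%). The
factors are sampled independently because no joint demographic table is
published; DIF ($\gamma$) and impact (trait-mean shifts per dummy
column) are zero unless configured. Draws happen in a fixed order
(covariates by factor, then traits, then responses) from one seeded
generator, so identical seeds give identical datasets.

What the generator does *not* emulate: item dependence beyond the single
trait (no testlets), polytomous weights (simulation is at the
dichotomous level the analysis consumes), rater effects, non-uniform
DIF, and informative missingness (only optional MCAR). Passing
validation on this generator therefore demonstrates correctness of the
estimators under their own assumptions — not robustness to violations
real clinical data may contain.

## Validation problem sizes

The test suite validates each claim at sizes chosen to balance
statistical resolution against a comfortably fast default run:
calibration recovery at 500 persons × 20 items (the 250–500 range
recommended for ±½-logit calibration); model-true fit statistics at
2,000 × 20; residual PCA null and two-trait alternatives at 1,000 × 20
over 10 seeded replicates each; DIF null, power (planted gender shift of
1.0 logit), and impact-without-DIF runs at 800 persons × 15 items with
balanced groups over 10 seeded replicates each, on a 10-value penalty
path. Exact small-matrix oracles (direct numerical maximisation of the
same likelihoods) pin the estimators at 5 × 4 (joint likelihood) and
~300 × 6 (marginal likelihood).

## Known limitations

* JML estimates carry the well-known small-$L$ bias; the optional
  correction is first-order only.
* "Real" (misfit-inflated) separation/reliability variants are not
  computed.
* The residual-PCA percent-explained convention differs across software
  families; ours is declared above and should not be numerically
  compared against other implementations' percentages.
* BIC on a finite penalty grid can miss a weak DIF effect that a finer
  grid would catch; power at small shifts is grid-resolution dependent.
* The instrument file ships placeholder subscale assignments and weights
  (flagged `"unverified"`) for catalogue completeness; neither enters
  any model fit.
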