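---
title: "Craniometric size/shape decomposition and multivariate analysis of otter skull form"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Craniometric size/shape decomposition and multivariate analysis of otter skull form}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniomorph)
```

## The scientific problem

Otters (Lutrinae) divide into two trophic specializations: mouth-oriented
raptorial piscivores (North American river otters, giant river otters) that
catch elusive fish with their jaws, and hand-oriented invertebrate
specialists (Asian small-clawed otters, sea otters) that capture prey
manually and, in the sea otter's case, crush hard-shelled benthic prey.
Lever mechanics predicts opposite skull architectures for the two modes:
long, narrow skulls and mandibles favour jaw-closing velocity; short, blunt
skulls with large muscle moment arms favour bite force. This package
implements a complete, testable analysis chain for evaluating those
predictions from standard cranio-dental calipers data: 25 linear measures
per skull (occlusal surface area, OSA, as an area in mm²), species and
feeding-mode labels, and, within sea otters, three subspecies
(northern *E. l. kenyoni*, Russian *E. l. lutris*, southern *E. l. nereis*)
whose diets range from partly piscivorous to strongly durophagous.

## Size and shape on the log scale

All analysis happens on natural logs. OSA is first replaced by its square
root so every variable is a linear (mm-scale) dimension; log transformation
then removes the mean–variance coupling typical of distance data.

Size is the log **geometric mean size** (GMS): the mean of the log measures
over the 22 major skull dimensions. The geometric mean of $k$ linear
measures is the $k$-th root of their product — a linearised skull "volume",
homogeneous of degree one under uniform scaling. Two minor zygoma measures
(ZH, ZW, roughly ten-fold smaller than the rest) and the areal OSA are
excluded from the size subset. The exclusion list is configurable
(`gms_subset`): the source analyses describe the subset both as "21 major
dimensions" and by an exclusion list that leaves 22 of the 25 traits; the
package defaults to the 22-trait by-exclusion reading, which is the
internally consistent one.

Shape is the matrix of **Mosimann log-shape ratios**,
$\log(x_{it}) - \log(\mathrm{GMS}_i) = \log(x_{it}/\mathrm{GMS}_i)$.
These are invariant to uniform specimen rescaling and sum to zero across
the GMS subset, so the shape space has one dimension fewer than the trait
count. A literal ratio-of-log-values convention
($\log x / \log \mathrm{GMS}$) is selectable
(`convention = "ratio-of-logs"`) because the phrase "log distance/log GMS"
admits either reading; it is not scale-invariant, is undefined at
GMS = 1 mm (guarded), and is not the default for those reasons. The rank
deficiency is handled exactly as in geometric morphometrics: a covariance
principal-components decomposition drops one dimension, and the retained
scores are the shape variables. Eigenvector signs are fixed by making each
axis's largest-magnitude loading positive, so ordinations are reproducible
across platforms.

The published test table implies 24 shape inputs (23 retained components;
form numerator df 24 once log GMS joins the responses) without naming the
trait left out of the 25. The package's default analysis set
(`analysis_shape_traits()`) drops ZH — the smallest measure, nearly
collinear with ZW — and is configurable if a different reading is wanted.

## Maximum-likelihood imputation

Museum series have sporadic damage; rather than discard specimens missing a
few measures (~1% of cells in the motivating sample), missing log
measurements are imputed by maximum likelihood under a multivariate normal
with mean structure `intercept + effects-coded species design` and an
unstructured residual covariance. The fitting algorithm is EM: the E-step
fills each specimen's missing block with its conditional expectation given
the observed traits and the specimen's group (and accumulates the
conditional covariance), the M-step re-estimates coefficients and
covariance from the completed sufficient statistics. The observed-data
log-likelihood is non-decreasing by construction — the test suite asserts
the trace — and convergence is declared at a relative change below
`tol = 1e-8` (default `max_iter = 500`). Initialisation fills missing cells
with group-conditional fitted values. Imputed cells are conditional means,
so they add no information of their own and exert essentially no leverage
on the downstream tests. A ridge option (`ridge`, default 0) stabilises the
residual covariance when the trait count is large relative to the sample —
at fewer than roughly two specimens per trait the unpenalised ML covariance
can drift toward singularity, and the fitter then stops with advice rather
than returning a degenerate fit. Bilateral measures are averaged *before*
imputation: a single-side reading is already the accepted measure for that
trait, so only cells missing on both sides reach the imputer. Multiple
imputation (propagating imputation uncertainty) is deliberately out of
scope; the downstream statistics treat the completed table as data, as the
original single-imputation workflow did.

## MANOVA with Wilks' Λ and Rao's F

Form (23 shape components + log GMS) and shape (components only) are tested
with a from-first-principles MANOVA. Effects enter in a stated order —
feeding orientation, then species nested in feeding orientation, then (for
shape) the log-GMS covariate and its interactions — and each effect's
hypothesis SSCP $H$ is the sequential (type I) drop in residual SSCP as its
columns join the design; the error SSCP $E$ comes from the full model.
Nested species contrasts are coded one effects column per feeding mode
(2 df). Per effect:

$$\Lambda = \frac{\det E}{\det(E + H)}, \qquad
s = \sqrt{\frac{p^2 q^2 - 4}{p^2 + q^2 - 5}}, \qquad
F = \frac{1 - \Lambda^{1/s}}{\Lambda^{1/s}} \cdot \frac{\mathrm{df}_2}{\mathrm{df}_1},$$

with $\mathrm{df}_1 = pq$,
$\mathrm{df}_2 = s\,[v - (p - q + 1)/2] - (pq - 2)/2$, $v$ the error df,
and $s = 1$ where the square root is undefined. The statistic is exact when
$s \in \{1, 2\}$ — which covers every effect in the published design.
Effect strength is partial $\eta^2 = 1 - \Lambda^{1/s}$, so for $s = 1$ it
equals $1 - \Lambda$ identically.

Allometry-by-group interactions are pruned hierarchically: any prunable
effect with $P \ge 0.05$ is removed (least significant first) and the model
refit, and the pruning trace is always reported. Ordination uses either
canonical axes (eigenvectors of $E^{-1}H$, largest-loading-positive sign
convention) or multivariate regression scores (centred responses projected
on the normalised partial regression vector), the latter preferred for
display because canonical spaces can be distorted by structure in the error
covariance.

## Classification and univariate follow-ups

Group separation is summarised by equal-prior linear discriminant analysis:
pooled within-group covariance, classification to the nearest centroid in
Mahalanobis distance, ties broken deterministically toward the earlier
group label. Because the predictor suite is large relative to the group
sizes, leave-one-out cross-validation refits the means and pooled
covariance without each case in turn — no downdating shortcut, which keeps
the procedure unambiguous at trivial cost for these sample sizes. A
shrinkage option (`shrink`, toward the covariance diagonal) exists for the
features ≥ smallest-group regime, where a warning is always emitted; the
default is no shrinkage, matching the reference analyses.

Univariate work uses standard one-way ANOVA (`stats::lm`) with
Tukey–Kramer HSD contrasts: studentized range
$q = |\bar y_i - \bar y_j| / \sqrt{\mathrm{MSW}\,(1/n_i + 1/n_j)/2}$ with
adjusted p from `ptukey`. The functional indices are the mandibular
bluntness index (MBI = JW/JL; > 1 means a jaw wider than long), masseter
and temporalis mechanical advantage (MAM/OLC, MAT/OLC), and size-adjusted
OSA (residuals of OSA on condylobasal length over the pooled sample).
Mechanical-advantage ratios are arcsine transformed before ANOVA; the
default is the variance-stabilising $\arcsin\sqrt{x}$, with values above 1
(which genuinely occur — river otter MA_temporalis averages about 1.05)
clamped to 1 with a warning, and ANOVAs on the untransformed ratios
reported alongside as a sensitivity output. The OSA regression defaults to
the raw mm² scale with a `sqrt` option, since either is defensible and the
original scale is not recorded; both the residual ANOVA and the
"southern excess" percentage — the southern subspecies' mean residual minus
the unweighted mean of the other two, as a percentage of predicted OSA at
the sample-mean condylobasal length — are computed from whichever scale is
chosen.

## The synthetic generator

`simulate_otters()` exists so that every stage is testable without any
external data. Its default configuration reproduces the study conditions:
six groups with the published sample sizes (43 river, 17 giant river, 23
small-clawed; 40/8/20 northern/Russian/southern sea otters — the group
sizes as printed, which sum to 151), species mean log GMS set to the
published least-squares means, and species trait offsets chosen so the
generating group means reproduce the published functional-index means
(sea otter MBI 1.10, MA_masseter 0.59, southern sea otters ~19% extra OSA
at a given skull length, and so on). Each specimen draws a latent log size
$s_i \sim N(\mu_g, 0.059^2)$ — a ~6% size coefficient of variation,
realistic for an adult skull series — and log traits
$\mathrm{rel}_t + s_i + (a_t - 1)(s_i - s_{\mathrm{ref}}) + d_{g,t} +
\varepsilon_{it}$ with independent residual SD 0.035 per trait, mild
trait-specific allometry $a_t$ pivoting about a reference size (so group
mean log GMS stays at the configured value), bilateral traits emitted as
two replicate readings with 0.2 mm measurement error and averaged, and 1%
MCAR missingness.

What the generator does *not* emulate: correlated residual shape variation
(residuals are independent across traits, where real skulls have rich
integration structure), non-MCAR missingness (damage is probably not
random), phylogenetic covariance among species, and measurement-protocol
artefacts. Passing tests therefore demonstrate that the machinery is
correct and that the pipeline recovers known structure under the model's
own assumptions — not that the model captures every feature of museum
data.

## Numerical choices and degenerate inputs

* Wilks' Λ via log-determinants (`determinant(..., logarithm = TRUE)`),
  with an explicit error when $E$ is singular (too many responses for the
  specimen count).
* EM conditional means via Cholesky solves grouped by missingness pattern;
  singular residual covariance stops with advice to use `ridge`.
* Zero between-group variance reports $F = 0$; zero within-group variance
  with real separation reports $F = \infty$ with a flag rather than `NaN`.
* Classification ties break toward the earlier group label,
  deterministically.
* All observed measurements must be strictly positive; violations error at
  construction, naming specimen and trait.
* Reported degrees of freedom always follow the data actually supplied;
  with the printed group sizes (summing to 151) the error dfs differ by
  one from some published values (which imply 150), and the package makes
  no attempt to hide that.

## Problem sizes used in the test suite

The suite runs entirely on generated data: the full 151-specimen study
configuration for pipeline tests, 100-specimen batches for the
invariant checks, 50 random small instances (p ≤ 4, k ≤ 3) against
brute-force SSCP oracles, a 1000-replicate null simulation (n = 60, p = 5)
for the MANOVA type-I error, a 3000-observation bivariate sample for the
EM closed-form check, and a 200 000-draw Monte-Carlo studentized-range
oracle for the Tukey adjustment. These sizes give comfortable Monte-Carlo
margins for every asserted tolerance while keeping the whole suite fast.

## Known limitations

* Cell-level agreement with other ML imputers is not promised — only the
  model (grouped multivariate normal on logs) and the objective (observed-
  data ML) are specified; different optimisers can differ in late digits.
* Sequential (type I) sums of squares are used with effects in the stated
  order; for the strongly non-orthogonal designs that arise outside this
  nesting structure, effect order matters and should be chosen
  deliberately.
* The LDA assumes a common within-group covariance; with 23–24 features
  and a smallest group of 8, that pooled estimate is noisy, which is
  exactly why LOOCV is reported alongside resubstitution.
* The generator's independence of residuals across traits understates the
  integration of real skulls; MANOVA effect strengths on synthetic data
  are therefore not calibrated to published effect strengths, only the
  group means are.
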