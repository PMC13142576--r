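---
title: "Cognitive dispersion in prodromal synucleinopathy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive dispersion in prodromal synucleinopathy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogdisp)
```

## The problem and the model

A person assessed on a neuropsychological battery produces one score per
test. Two people with the same *average* performance can differ sharply
in how consistent those scores are; that within-person inconsistency —
intraindividual variability, or dispersion — is thought to reflect early
breakdown of distributed neural networks and has repeatedly been found
elevated in synucleinopathies before mean performance leaves the normal
range. `cogdisp` quantifies dispersion as the coefficient of variation
of a subject's demographically corrected T scores:

$$\mathrm{CoV}_i \;=\; \frac{\sqrt{\tfrac1n \sum_{j=1}^{n} (T_{ij} - \bar T_i)^2}}{\bar T_i},$$

with $n = 11$ scores for the total CoV and $n = 5$
(attention/executive: SDMT, TMT-A, LNS, lexical fluency, TMT-B) for the
domain CoV. Two conventions matter and are fixed deliberately:

* **n-divisor SD.** The SD is the square root of the *average* squared
  deviation (population form), not the $n-1$ sample form. A
  `sd_type = "sample"` flag exists for sensitivity analysis only.
* **Positive mean.** CoV is meaningless at $\bar T_i \le 0$. Such panels
  (essentially impossible in the calibrated range, conceivable for
  pathological inputs) are excluded and counted, never returned as NaN.

The analysis asks three questions: does dispersion separate biomarker-
positive prodromal (NSD-ISS Stage 2) subjects from healthy controls; how
does it correlate with motor, mood, and autonomic burden; and does
baseline dispersion predict one-year progression to Stage 3+ after
adjusting for motor severity.

## Internal regression norming

Raw scores are converted to T scores against *internal* norms: per test,
an ordinary least-squares regression on age, sex (single indicator, main
effect only), and education, fit on a reference sample. Correction is
selective: each covariate is kept only if its Wald test in the full
three-covariate fit has $p < \alpha$ (default $\alpha = 0.05$,
configurable), with one refit on the retained set. Then

$$T = 50 + 10\,d\,\frac{x - \hat x}{s}, \qquad d = \begin{cases}-1 & \text{timed tests (seconds)}\\ +1 & \text{otherwise,}\end{cases}$$

where $s$ is the residual scale of the final fit with the unbiased
$n - k - 1$ denominator (standard regression practice; the choice is
invisible at reference sizes above a few hundred). Applying norms to
their own reference reproduces mean 50 exactly and SD
$10\sqrt{(n-k-1)/(n-1)}$ — within 0.01 of 10 for large references, about
9.85 at a 102-subject reference. T scores are invariant to affine
rescaling of a test's raw units, which the test suite asserts.

Two genuinely open choices are resolved as documented defaults: the
reference sample is the eligible healthy-control baseline set
(`norm_reference = "hc"`, with `"all"` available), and the selection
test is the per-covariate Wald test. Published internal norms for real
cohorts are proprietary; reproducing their coefficients is out of scope.

## Staging and conversion labeling

Stage labels are a pure function of one visit record. SAA positivity is
the biological anchor; dopaminergic deficit enters as a precomputed flag
(putamen SBR below 75% of the age/sex-adjusted reference):

| condition | stage |
|---|---|
| SAA− | healthy-control candidate |
| SAA+, no subtle signs | 1 |
| SAA+, signs, no impairment, no DAT deficit | 2A |
| SAA+, signs, no impairment, DAT deficit | 2B |
| SAA+, slight-or-greater functional impairment | 3+ |

"Subtle signs" are not enumerated by the staging literature at the
granularity a simulator needs; the default rule — any of hyposmia flag,
RBDSQ ≥ 5, MDS-UPDRS III > 0 — is an explicit assumption, and real-data
users can pass their own indicator (`assign_stage(..., signs = )`).

Control eligibility additionally requires baseline MoCA ≥ 27, Year-1
MoCA ≥ 26, decline ≤ 2 points, no hyposmia, and SAA−. Baseline is the
first visit with a complete battery; conversion is labeled from the
earliest complete-battery visit with offset in the window
$[0.75, 1.25]$ years (real analyses use exact restricted dates, which a
public pipeline cannot).

## Group statistics and multiplicity

Continuous two-group rows use a two-sided equality-of-variance F test as
a gate: $p < .05$ selects Welch's t with Satterthwaite df, otherwise the
pooled-variance t. Cohen's d always uses the pooled SD — also on Welch
rows — matching the convention of the published tables the package was
validated against, with the sign convention group 1 (controls /
non-converters) minus group 2. Categorical rows get an uncorrected
Pearson χ². The Benjamini–Hochberg step-up rule is applied across the
rows of one table (each table is one family; the family boundary is a
design decision, not a published rule), and because published tables are
ambiguous about whether their p columns are raw or adjusted, the report
emits both `p` and `p_adjusted` plus the `significant` flag.

## The conversion models

Both logistic models are fit by hand-rolled IRLS (intercept included;
convergence when the largest coefficient update drops below $10^{-8}$,
at most 100 iterations; standard errors from the inverse observed
information at the optimum; score-equation residual stored and asserted
below $10^{-6}$ after every fit). Complete or quasi-separation is
detected by runaway linear predictors and reported via
`converged = FALSE` with a warning. The suite cross-checks coefficients,
standard errors, and likelihoods against `stats::glm`, which is never
used as the implementation.

Fit statistics follow the conventional definitions: LR
$\chi^2 = 2(\ell_1 - \ell_0)$ against the intercept-only model on the
same subjects; Cox–Snell $R^2 = 1 - e^{2(\ell_0-\ell_1)/n}$ rescaled by
its maximum to give Nagelkerke $R^2$; Hosmer–Lemeshow over $g = 10$
decile-of-risk groups (ties kept together, empty groups reduce $g$ with
a message) with $df = g - 2$ and the CI multiplier fixed at 1.959964.

CoV enters the model in raw units. A published odds ratio of ~1.44 "per
unit of CoV" is modest only because one CoV unit is enormous — about ten
times the between-subject SD (0.08–0.10); whether the source analyses
standardised CoV before entry is not stated, so a `standardize` flag
implements the alternative. At the realistic followed-cohort size
(n ≈ 440) the implied standard error of the CoV slope is ≈ 1.2, so
single-cohort estimates of it are noise; the package recovers the slope
reliably only at simulation scale, which is exactly what the test suite
does.

## The synthetic cohort: what it emulates

The generator's defaults state one world (all printed values below are
the emulation targets, not tuned quantities):

* 102 controls and 832 Stage 2 subjects, baseline plus a Year-1 visit
  (all controls; a followed fraction 440/832 of Stage 2), Year-1 offset
  $\mathcal N(1.0, 0.1^2)$ years.
* Per-subject latent model $T^{lat}_{ij} = 50 + \delta_g + \theta_i +
  \sigma_i \varepsilon_{ij}$ with $\varepsilon \sim \mathcal N(0,1)$,
  subject dispersion $\sigma_i$ from a zero-truncated normal per group
  (the simplest family matching a mean/SD target), and a Stage-2
  composite deficit of $\delta = 3.43$ T units.
* Group CoV targets: 0.18 (0.07) for controls, 0.21 (0.10) for Stage 2.
* Demographics (age 64.6 (12.1) vs 67.8 (6.4), education ≈ 16.3 (2.8),
  ~57–58% male) and nine clinical scales with group-specific means/SDs
  at instrument bounds; GDS-15, STAI-state, age, and education are
  drawn correlated with $\sigma_i$ so that the printed CoV–covariate
  correlations (≈ .135, .154, .107, −.201) are reproduced after
  attenuation correction.
* Biomarkers: Stage 2 is SAA+ with a 50% DAT-deficit (2B) fraction —
  the 2A/2B split is not printed in the emulated tables, so an even
  split is assumed — and 90% hyposmia; controls are SAA− with MoCA
  drawn from the ≥ 27 inclusion-conditioned distribution.
* Conversion: Year-1 functional impairment is Bernoulli with
  $\mathrm{logit}\,p = \beta_0 + 0.362\,\mathrm{CoV}_i + 0.09\,
  \mathrm{UPDRS}_i$, with $\beta_0$ calibrated so that the expected
  conversion fraction among followed Stage 2 is $100/440$.

Raw scores are produced from the latent panel through per-test scales
and linear demographic effects (documented in `test_registry()`); their
exact values are irrelevant because norming standardises them, and a few
tests have null education/sex effects so that selective correction is
exercised. Test scores are kept continuous — real batteries are
integer-valued, but rounding would inject test-specific noise of the
order of the calibration tolerances.

### Deterministic calibration

Because $\varepsilon$ is Gaussian, the panel SD is independent of the
panel mean, and the first two moments of CoV reduce to one-dimensional
normal integrals nested in a truncated-normal integral. These are
evaluated by Gauss–Hermite/Gauss–Legendre quadrature (nodes via the
Golub–Welsch eigenvalue construction, 40/80 nodes, accurate to ~1e-10
within the model) and inverted by Nelder–Mead. The same machinery yields
the CoV–$\sigma$ correlation used for attenuation-correcting the
covariate correlations and the expected conversion rate used to solve
for $\beta_0$ (`calibrate_conversion_intercept()`). Everything is
deterministic: identical configuration and seed give a byte-identical
cohort, and the test suite verifies realized moments against the
forward model within 3 Monte-Carlo standard errors at $n = 10^5$ per
group.

```{r calibration}
cfg <- simulation_config(seed = 1, quiet = TRUE)
cfg$calibration$s2[c("achieved_mean", "achieved_sd")]
```

### What the generator does *not* emulate

A green test on this world establishes that the pipeline's statistics
behave correctly on data with the stated structure — not that the world
reproduces every printed cohort feature. Known, deliberate departures:

* **The control CoV pair sits on a constraint boundary.** Norming on
  the control reference pins every test's control T-score SD to 10,
  which caps $E[\sigma_i^2]$ and — because the norming rescale cancels
  the dispersion scale — collapses the attainable control (mean, SD)
  CoV pairs onto a one-dimensional curve. The target (0.18, 0.07) lies
  essentially on that curve; the constrained optimum achieves
  (0.179, 0.070), which still rounds to the printed two-decimal values.
  The Stage 2 targets are met exactly (its norms come from the control
  fit, so both parameters are free).
* **Between-subject ability spread is zero** ($\tau = 0$ by default).
  Raising $\tau$ only shrinks the attainable control CoV further, so
  the calibrated world attributes all within-group composite variance
  to within-battery noise; simulated composite SDs (~3–3.5) are
  therefore smaller than the printed ~5.6–6.3 and mean-composite effect
  sizes correspondingly larger. Sign patterns are unaffected.
* **Domain-specific dispersion is not modeled**: one $\sigma_i$ drives
  all 11 tests, so the simulated Stage-2 attention/executive CoV
  (~0.19) exceeds the printed 0.17.
* **Skewed scales are approximated** by clamped, rounded normals;
  heavily zero-inflated scales (control UPDRS-III with printed mean
  1.82, SD 3.04) realise somewhat different moments, as a truncated
  normal cannot reach that coefficient of variation.
* **The printed conversion-model slope and the printed converter CoV
  gap are mutually inconsistent**: a log-odds slope of 0.362 per CoV
  unit implies a converter/non-converter CoV difference of ~0.003, an
  order of magnitude below the printed 0.03 — consistent with the
  source having standardised CoV before model entry. The generator
  follows the printed coefficients, so its simulated converter contrast
  in CoV is much weaker than the printed one.

`simulate_cohort(..., keep_latent = TRUE)` attaches the generator's
ground-truth baseline CoV (`cov_latent`) — the exact values its
conversion draws used. Parameter-recovery tests refit against this
column, making them correctly specified maximum-likelihood problems;
refitting against the *measured* CoV adds shared norming measurement
error, which at wide dispersion configurations inflates the estimator
variance well beyond its nominal standard error.

## Numerical and degenerate-input choices

* RNG streams per generation stage are derived from the single
  top-level seed by fixed offsets, so adding a stage never perturbs
  earlier streams; truncated normals are drawn by inverse CDF.
* Zero pooled variance: $t = 0$ when means agree, an error otherwise;
  a zero variance forces $p = 0$ in the F gate (Welch branch).
* BH on an empty vector returns an empty flag vector; ties share fate
  by construction of the step-up rule.
* Constant norming covariates are dropped with a warning; references
  under 30 complete records are rejected.
* Incomplete panels are excluded from dispersion with a counted reason
  (`attr(result, "excluded")`), and pipeline accounting reconciles
  enrolled = analyzed + excluded.
* Hosmer–Lemeshow is treated as a diagnostic in the pipeline: if fitted
  probabilities saturate numerically (extreme synthetic configurations),
  it is reported as unavailable rather than aborting the fit.

## Limitations

The package analyses complete batteries only (the completeness rule is
the inclusion criterion, not an imputation target); practice effects,
item-level simulation, genetic strata, and alternative dispersion
metrics (intraindividual SD, residualised variability) are out of
scope. The synthetic world is a calibrated stand-in: conclusions about
real cohorts require real data through the same pipeline
(`read_cohort()` accepts any file matching `cohort_dictionary()`).
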