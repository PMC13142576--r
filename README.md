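# cogdisp

Intraindividual cognitive variability — *dispersion* — is the
within-person inconsistency of performance across the different tests of
one neuropsychological battery at a single assessment. In prodromal
neuronal α-synuclein disease (NSD), where mean cognitive performance is
still in the normal range, dispersion is a candidate early marker: it
rises before mean-level deficits appear and it predicts short-term
progression through the NSD integrated staging system (NSD-ISS).

`cogdisp` is an R package for biostatisticians and neuropsychology
researchers working with longitudinal prodromal cohorts (or synthetic
stand-ins for them). It implements the full analysis chain:

1. **Internal regression norming.** Each of 11 raw test scores (eight
   instruments; HVLT-R contributes three scores) is regressed on age,
   sex, and education in a reference sample; corrections are applied
   *selectively* (a covariate is kept only when its Wald test has
   p < α in the full fit). Raw scores become T scores,

   T = 50 + 10 · (x − x̂) / s_resid,

   sign-flipped first for timed tests (TMT-A/B in seconds), so higher T
   is always better and the reference sample maps to mean 50, SD 10.

2. **Dispersion.** For a complete panel the coefficient of variation is

   CoV = ( √( (1/n) Σᵢ (Tᵢ − T̄)² ) ) / T̄,

   the *n*-divisor (population) SD of the subject's T scores divided by
   their mean composite; `cov_total` uses all 11 scores, `cov_ae` the
   five attention/executive scores (SDMT, TMT-A, LNS, lexical fluency,
   TMT-B).

3. **Staging and conversion.** NSD-ISS labels per visit (SAA+ with
   subtle signs and no functional impairment → Stage 2A/2B by DAT
   deficit; slight impairment → Stage 3+), healthy-control eligibility
   (baseline MoCA ≥ 27, Year-1 MoCA ≥ 26, decline ≤ 2, no hyposmia,
   SAA−), and one-year conversion outcomes with stage-transition counts.

4. **Group statistics.** Two-group comparisons with an equality-of-
   variance F gate (p < .05 → Welch, otherwise pooled t), pooled-SD
   Cohen's d, Pearson χ² for categorical variables, Pearson
   correlations, and Benjamini–Hochberg FDR flags over each table
   family.

5. **Conversion models.** Binomial logistic regression written from
   first principles (IRLS, Wald inference, likelihood-ratio χ² against
   the intercept-only model, Nagelkerke R², Hosmer–Lemeshow
   decile-of-risk calibration): conversion ~ CoV + MDS-UPDRS III, and
   the same with the attention/executive CoV.

6. **Synthetic cohorts.** A seeded generator emulating the statistical
   structure of a prodromal cohort (102 controls, 832 Stage 2, CoV
   0.18 (0.07) vs 0.21 (0.10), ~100 of ~440 followed Stage 2 converting
   in one year with log-odds 0.362 per CoV unit and 0.09 per UPDRS-III
   point), calibrated by a deterministic quadrature layer rather than
   trial and error. Real cohort extracts with the same column schema
   (see `cohort_dictionary()`) drop straight into the pipeline.

## Worked example

```r
library(cogdisp)
config <- simulation_config(seed = 11, quiet = TRUE)
report <- run_full_pipeline(config)
print(report)
#> Cognitive dispersion report
#>   934 participants: 101 eligible controls, 828 Stage 2 (433 followed, 87 converted)
#>   baseline CoV: HC 0.179 (0.064) vs Stage 2 0.214 (0.101), t = -4.86, d = -0.36
#>   conversion model: B(CoV) = 0.410, OR 1.51 [0.15, 14.90]; Nagelkerke R2 = 0.033
```

The control group realises CoV ≈ 0.18 and the Stage 2 group ≈ 0.21 with
a negative t (controls minus Stage 2): Stage 2 shows more dispersion and
a lower mean composite even though both groups are cognitively "normal"
on average. Individual tables are plain data frames:

```r
t1 <- report$table1
emit_table(t1[t1$variable %in% c("moca", "mean_composite", "cov_total"),
              c("variable", "mean1", "sd1", "mean2", "sd2", "test",
                "statistic", "p_adjusted", "significant", "cohens_d")])
#> variable        mean1  sd1   mean2  sd2   test      statistic  p_adjusted  significant  cohens_d
#> moca            28.65  1.04  26.71  2.10  welch-t   15.28      0.000       TRUE         0.96
#> mean_composite  50.00  3.00  46.37  3.44  pooled-t  10.14      0.000       TRUE         1.07
#> cov_total       0.18   0.06  0.21   0.10  welch-t   -4.86      0.000       TRUE         -0.36

print(report$models$total)
#> Logistic fit: n = 433, LL = -212.683 (null -217.228)
#>   LR chi-square(2) = 9.09, p = 0.01063; Nagelkerke R2 = 0.033
#>   (Intercept)    B =  -1.9025 (SE 0.3319)  p = 9.928e-09  OR 0.149 [0.078, 0.286]
#>   cov_total      B =   0.4096 (SE 1.1693)  p = 0.7261  OR 1.506 [0.152, 14.902]
#>   updrs3         B =   0.0537 (SE 0.0178)  p = 0.002526  OR 1.055 [1.019, 1.093]
```

At n = 433 followed subjects a log-odds slope of 0.362 per CoV unit is
far below the detection threshold (SE ≈ 1.2 — one CoV *unit* is ten
times the CoV SD), so the per-cohort CoV coefficient is noisy by
design; the motor-severity effect is detected reliably. The low-level
statistics are exported directly, e.g.

```r
pooled_t(48.53, 6.22, 340, 45.66, 6.28, 100)$t   # 4.047
coefficient_of_variation(c(40, 50, 60))          # 0.1633
```

`run_full_pipeline(config, out_dir = "out")` additionally writes every
table as CSV plus an aligned-text mirror, the fitted norms, and a
seed/configuration echo; rerunning with the same seed regenerates the
bundle byte-identically.

## Acceptance script

`scripts/acceptance.R` re-runs the whole analysis from scratch against
the installed package — simulating the default calibrated cohort from
the given seed, norming, computing dispersion, staging, comparing
groups, and fitting both conversion models — and writes its JSON result
summary to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/cognitive-dispersion.Rmd`) describes
the model, the selective-norming and staging assumptions, what the
synthetic generator does and does not emulate, and the package's
numerical choices. Function-level documentation lives in the roxygen
comments in `R/`.
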