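# mdisbone

Dietary inflammatory scoring and bone mineral density association
analysis for senior cohorts.

Chronic low-grade inflammation promotes osteoclast activity and bone
loss, and habitual diet is one of its main modifiable drivers. `mdisbone`
implements the full analysis chain used to study that link in
nutritional epidemiology:

1. **M-DIS scoring** — the modified dietary inflammatory score of a
   participant is the weighted sum of z-standardized intakes over 32
   nutrient/food parameters,

   MDIS = Σᵢ wᵢ (xᵢ − μᵢ)/σᵢ,  wᵢ ∈ {−1, 0, +1},

   where positive weights mark parameters that raise circulating
   inflammatory biomarkers and negative weights those that lower them.
   Negative totals indicate an anti-inflammatory diet. Standardization
   can be in-sample or against an external reference population.
2. **Bone assessment** — DXA areal BMD (g/cm²) at the total femur,
   trochanter and lumbar spine L1–L4 is converted to T-scores against a
   sex- and site-specific reference, t = (BMD − μ_ref)/σ_ref, and
   dichotomized into **low BMD** (t ≤ −1, pooling osteopenia and
   osteoporosis) versus normal.
3. **Association pipeline** — exposure tertiles of the score;
   descriptive tertile comparisons (ANOVA / chi-square); covariate
   adjusted ANCOVA means with Tukey HSD contrasts; crude and adjusted
   linear (BMD) and logistic (low-BMD) regressions with Wald 95% CIs;
   p-for-trend with the score continuous; likelihood-ratio interaction
   tests (sex, diabetes, BMI); and stratified sensitivity analyses.
4. **Synthetic cohorts** — a seedable generator emulating a senior
   Mediterranean population with overweight/obesity and metabolic
   syndrome (correlated log-normal intakes sharing an energy factor, a
   latent inflammation factor with a tunable effect on BMD, stored
   generative truth), so the whole pipeline is testable end to end and
   parameter recovery can be verified.

See `vignettes/methods.Rmd` for the model details and design decisions.

## Worked example

```r
library(mdisbone)

cfg    <- cohort_config(seed = 42)          # n = 1134 senior cohort
g      <- generate_cohort(cfg)
scores <- compute_mdis(g$cohort, ref = external_reference_stats(cfg))
cohort <- dplyr::inner_join(g$cohort, scores, by = "participant_id")
cohort$tertile <- assign_tertiles(cohort$mdis, cohort$participant_id)
cohort <- score_bone(cohort, make_reference_fixture(cfg))

mean(cohort$mdis); sd(cohort$mdis)
#> -3.89  5.49           # anti-inflammatory on average
table(cohort$tertile)
#>   1   2   3
#> 378 378 378

fit_logistic_low_bmd(cohort, "tf", adjustment_covariates())
#> # A tibble: 3 × 9
#>   outcome scale model    term      estimate ci_low ci_high p_value     n
#> 1 low_tf  or    adjusted tertile_1    1     NA       NA     NA      1134
#> 2 low_tf  or    adjusted tertile_2    0.977  0.648    1.47   0.910  1134
#> 3 low_tf  or    adjusted tertile_3    1.31   0.876    1.96   0.188  1134
```

The odds ratio row for `tertile_3` compares participants eating the most
pro-inflammatory diets against the most anti-inflammatory third: here the
adjusted odds of low femoral BMD are 1.31 times higher (95% CI
0.88–1.96), a point estimate in the direction of the generative effect
(`score_effect_bmd = -0.03` g/cm² per SD of latent inflammation) that
this single replicate cannot distinguish from 1. The ANCOVA view of the
same contrast:

```r
am <- ancova_adjusted_means(cohort, "tf", adjustment_covariates())
am$adjusted_means          # covariate-adjusted mean BMD per tertile
#>   tertile adj_mean     se    df
#> 1 1           1.05 0.0166  1114
#> 2 2           1.05 0.0162  1114
#> 3 3           1.02 0.0166  1114
am$tukey                   # Tukey HSD pairwise contrasts
#>   contrast            estimate      se  p_value
#> 1 tertile1 - tertile2 -0.00791 0.00951 0.683
#> 2 tertile1 - tertile3  0.0272  0.00963 0.0134
#> 3 tertile2 - tertile3  0.0351  0.00967 0.000862
```

The top tertile carries about 0.03 g/cm² less adjusted femoral BMD than
the reference tertile (Tukey p = 0.013).

`run_pipeline()` (or the CLI at `inst/cli/mdisbone.R`) runs the whole
chain from CSV inputs and writes `scored_cohort.csv`, descriptive and
association tables, stratified results, and a machine-readable
`summary.json`; outputs are byte-identical across reruns of the same
configuration.

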