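---
title: "Dietary inflammatory scoring and bone density: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary inflammatory scoring and bone density: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdisbone)
```

## The scientific problem

Chronic low-grade inflammation accelerates bone resorption: cytokines such
as IL-6 and TNF-alpha tip the OPG/RANK/RANKL balance toward osteoclast
activity. Because habitual diet modulates these inflammatory pathways, a
diet's overall inflammatory potential can be summarized from a food
frequency questionnaire and related to bone mineral density (BMD) measured
by dual-energy X-ray absorptiometry (DXA). `mdisbone` implements that whole
chain for senior cohorts: a modified dietary inflammatory score (M-DIS),
T-score classification of DXA measurements at the total femur (TF),
trochanter (TR) and lumbar spine L1–L4 (LS), and the tertile-based
epidemiological association pipeline connecting the two.

## The M-DIS model

For participant $j$ with intake $x_{ij}$ of parameter $i$,

$$\mathrm{MDIS}_j \;=\; \sum_{i=1}^{32} w_i \,
\frac{x_{ij} - \mu_i}{\sigma_i},$$

where $w_i \in \{-1, 0, +1\}$ encodes whether parameter $i$ raises,
leaves unchanged, or lowers circulating inflammatory biomarkers, and
$(\mu_i, \sigma_i)$ are reference means and SDs. Negative totals indicate
an anti-inflammatory diet; positive totals a pro-inflammatory one.

Design choices that the score's definition leaves open, and what this
package does:

* **Weights.** Score publications of this family do not always print the
  signs for the 32-parameter reduction. The shipped default
  (`mdis_weights()`) marks nine parameters pro-inflammatory (+1: vitamin
  B12, carbohydrates, cholesterol, energy, total/saturated/trans fatty
  acids, iron, protein) and the remaining 23 anti-inflammatory (−1),
  following the usual convention for this index. The table is explicitly a
  reconstructed default: any study-specific assignment can be supplied as
  a `parameter,weight,unit` CSV via `read_mdis_weights()`.
* **Standardization reference.** In-sample means/SDs
  (`estimate_reference_stats()`) are the default because they are
  self-contained and reproducible; an external reference population can be
  supplied as a `parameter,mean,sd` CSV. The choice matters: in-sample
  standardization forces the cohort mean score to zero, so a cohort with a
  markedly negative average score (an anti-inflammatory population) has
  necessarily been standardized against an external, more pro-inflammatory
  reference. The synthetic module exploits exactly this to emulate such
  cohorts (`external_reference_stats()`).
* **Zero boundary.** A score of exactly 0 is classified pro-inflammatory
  ("positive" read as non-negative); configurable via `boundary =`.
* **Tertiles.** `assign_tertiles()` sorts stably by (score, participant
  id) and cuts at indices $\lceil n/3 \rceil$ and $\lceil 2n/3 \rceil$;
  tertile 1 holds the most anti-inflammatory diets. This deterministic
  rule reproduces group sizes of the form 368/368/368 at $n = 1104$ and
  362/361/361 at $n = 1084$, and makes tie handling reproducible.
* **Missing intakes.** Strict error by default; `missing =
  "complete_case"` drops incomplete participants and reports the count.
* **45 vs 32 parameters.** When a questionnaire cannot support the full
  45-parameter index, the reduced sum is used as-is without rescaling —
  the score is a sum, not a mean, so comparisons are only made within one
  parameter set.

## Bone density and low-BMD status

`compute_t_score()` expresses BMD as
$t = (\mathrm{BMD} - \mu_{\mathrm{ref}})/\sigma_{\mathrm{ref}}$ against a
sex- and site-specific reference population. Vendor DXA software
conditions its references on age, weight and height as well; those
adjustments are proprietary and out of scope, so the reference table
(`site,sex,ref_mean,ref_sd`, all six cells required) is a user input
rather than a shipped constant, and the synthetic module provides a
self-consistent fixture.

Because frank osteoporosis ($t \le -2.5$) is rare in screened senior
cohorts, osteopenia and osteoporosis are pooled into one dichotomy:
**low BMD** when $t \le -1$ (boundary included), **normal** otherwise.
`score_bone()` appends `t_<site>` and `low_<site>` columns per site.

## The association pipeline

All models treat tertile 1 as reference and use the full adjustment set
(`adjustment_covariates()`): sex, type-2 diabetes, age, BMI, education
(3 levels), smoking (3 levels), physical activity (METs/day), four
medication flags, estrogen use, recruitment center, and total energy
intake. Numerical conventions:

* **Confidence intervals** are Wald intervals on the coefficient /
  log-odds scale with $z = 1.959964$, matching standard epidemiological
  reporting; `crude_or_2x2()` is the closed 2×2 form with
  $\mathrm{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}$. Zero cells error by
  default; `zero_cell = "haldane"` applies the 0.5 correction.
* **ANCOVA adjusted means** (`ancova_adjusted_means()`) are
  model-predicted tertile means at covariate grand means with equal
  weights across factor levels, computed through `emmeans`; pairwise
  contrasts use the Tukey HSD studentized-range distribution on the
  residual degrees of freedom.
* **Trend** (`p_for_trend()`): the continuous score replaces the tertile
  factor in the otherwise identical model; two-sided Wald p.
* **Interaction** (`lr_interaction_test()`): likelihood-ratio test of the
  model with a score-by-modifier product term against the nested model,
  $\chi^2$ with df equal to the number of added terms.
* **Stratified sensitivity analyses** (`stratified_ors()`): age (< 70 /
  ≥ 70 y), sex, BMI (< 30 / ≥ 30 kg/m²) and diabetes, each stratum fitted
  with the adjustment set minus the stratifying variable. Strata that
  cannot support the model (single outcome class, empty tertile,
  separation) are flagged and retained.
* **Complete cases and tertile scope.** Each model is fitted on rows
  complete for all its terms, and its n is recorded. By default tertiles
  are *recomputed* within each outcome's complete-case subsample (so the
  three exposure groups stay balanced per site); `tertile_scope =
  "frozen"` instead reuses whole-cohort tertiles. Site-specific
  missingness makes the per-site analytic ns differ — the pipeline logs
  its own ns rather than forcing any particular published pattern.
* **Degenerate designs.** Covariates constant within an analysis
  subsample (e.g. a rare medication flag in a small stratum) are dropped
  from the design and recorded; genuinely collinear terms raise an error
  naming them. Logistic fits check convergence and fitted probabilities
  and report separation instead of returning unstable estimates.
* No multiplicity correction is applied across sites or strata beyond
  Tukey's adjustment within an ANCOVA; $\alpha = 0.05$ two-sided
  throughout.

## The synthetic cohort generator

`generate_cohort()` emulates the marginal structure of a multicenter
senior Mediterranean population with overweight/obesity and metabolic
syndrome: default n = 1134, 48% women, age 65 ± 5 y truncated to 55–75,
BMI 32.6 ± 3.4 truncated to 27–40, energy 2469 ± 592 kcal/d, physical
activity 380 ± 340 METs/d, 22% diabetes, four recruitment centers, and
medication prevalences at the levels seen in such cohorts.

Nutrient intakes are correlated log-normals driven by two standard-normal
factors: a shared *diet size* factor $F_E$ (loading 0.8 on
pro-inflammatory parameters and 0.313 on anti-inflammatory ones — chosen
so the weight-aligned loading sum is near zero) and a latent *inflammation*
factor $F_I$ loaded at 0.05 with the sign of each parameter's weight. On
the standardized scale the implied score variance is approximately
$32 - \sum_i a_i^2 + (\sum_i b_i)^2 \approx 26.5$, i.e. a score SD near
5.1, and offsetting the external reference means along the weight
direction by $3.87\,\sigma_i w_i/32$ centers the externally standardized
score at −3.87 — the dispersion and center typical of an
anti-inflammatory senior cohort. These loadings were fixed analytically
from that target before any downstream checks and are not tuned
elsewhere.

BMD is generated as
$\mathrm{BMD}_{sj} = \beta_{0,s(\mathrm{sex})} + \delta F_{I,j}
+ \beta_a (\mathrm{age}_j - 65) + \beta_b (\mathrm{BMI}_j - 32.6)
+ \varepsilon_{sj}$, with sex-specific baselines around 1.04/0.86/1.18
g/cm² (TF/TR/LS population means), default $\delta = -0.03$ g/cm² per SD
of latent inflammation, $\beta_a = -0.004$, $\beta_b = +0.005$, and
residual SDs of 0.13–0.18 g/cm². The latent factors and noiseless means
are stored in a separate truth record that never enters the analysis
table, which is what makes parameter-recovery and null-calibration
studies possible. `make_reference_fixture()` returns the matching T-score
reference, so that under a null configuration T-scores are standard
normal and low-BMD prevalence is $\Phi(-1) \approx 15.9\%$.

What the generator deliberately does **not** emulate: real food-matrix
correlation structure beyond the two factors, informative (non-MCAR)
missingness, seasonal or center-level dietary differences, and the
age/weight/height conditioning of vendor T-score references. Passing
calibration and recovery checks on these cohorts therefore demonstrates
that the statistical machinery is correct and unbiased under the stated
generative model — not that any particular real-world estimate is
reproduced.

## Problem sizes of the shipped checks

The package's simulation checks use 100 cohorts of n = 1134 for
parameter recovery (adjusted tertile-3 coefficient within 2 SE of the
per-replicate truth, and elevated low-BMD odds under a negative diet
effect of −0.04 g/cm² per SD, a 2-SE-detectable value at this n), 200
null cohorts for CI coverage of 1.0 and uniformity of the trend p-value
(Kolmogorov–Smirnov at α = 0.01), 500 replicates for interaction-LRT null
uniformity, n = 8000 for score-calibration checks and n = 10,000 for the
normal-tail prevalence check. These sizes give the binomial/KS checks
3-SE headroom while keeping the whole suite fast.

## Known limitations

* The default weight table is a reconstruction of the index's published
  convention, not a study-specific derivation; analyses of real data
  should supply their own table.
* T-score references are sex- and site-specific only.
* The crude 2×2 odds-ratio path and the published-count checks assume the
  printed counts are the analytic sample; published tables occasionally
  round from slightly different internal samples, and one shipped example
  cell differs from its closed form by one unit in the second decimal.
* Missing covariates are handled by complete-case analysis only; no
  imputation is provided.
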