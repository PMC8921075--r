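#' Default log-normal intake model for the 32 dietary parameters
#'
#' Per-parameter log-scale location and scale, plus two factor loadings on
#' the standardized log scale: a shared "diet size" (energy) factor that
#' induces the positive correlation FFQ-derived intakes show with total
#' energy, and a latent inflammation factor loaded with the sign of each
#' parameter's inflammatory weight, so that diets high in pro-inflammatory
#' and low in anti-inflammatory parameters share a common latent exposure.
#'
#' Energy-factor loadings are balanced between the pro- and
#' anti-inflammatory groups (the weighted loading sum is zero), which keeps
#' the score variance close to the dispersion typical of senior
#' Mediterranean cohorts.
#'
#' @param energy_mean,energy_sd Marginal mean and SD of daily energy intake
#'   (kcal/d) used to parameterize the energy row.
#' @param weights Weight table aligning the loading signs.
#' @return Tibble `parameter, log_mean, log_sd, energy_loading,
#'   inflammation_loading`.
#' @export
default_nutrient_spec <- function(energy_mean = 2469, energy_sd = 592,
                                  weights = mdis_weights()) {
  typical <- c(
    caffeine = 0.12, alcohol = 8, vitamin_b1 = 1.5, vitamin_b2 = 1.8,
    vitamin_b3 = 33, vitamin_b6 = 2.2, vitamin_b12 = 8, vitamin_a = 900,
    vitamin_c = 140, vitamin_e = 12, vitamin_d = 4, carbohydrates = 230,
    protein = 95, cholesterol = 350, total_fatty_acids = 105, mufa = 50,
    pufa = 17, sfa = 27, trans_fatty_acids = 1, energy = energy_mean,
    fiber = 25, folic_acid = 320, garlic = 2, iron = 14, magnesium = 340,
    selenium = 100, zinc = 11, n3_fatty_acids = 1.8, n6_fatty_acids = 12,
    beta_carotene = 3500, onions = 30, tea = 20
  )
  log_sd <- c(
    caffeine = 0.8, alcohol = 1.2, vitamin_b1 = 0.35, vitamin_b2 = 0.35,
    vitamin_b3 = 0.35, vitamin_b6 = 0.35, vitamin_b12 = 0.5,
    vitamin_a = 0.5, vitamin_c = 0.5, vitamin_e = 0.4, vitamin_d = 0.6,
    carbohydrates = 0.3, protein = 0.3, cholesterol = 0.35,
    total_fatty_acids = 0.3, mufa = 0.35, pufa = 0.4, sfa = 0.35,
    trans_fatty_acids = 0.7, energy = NA, fiber = 0.35, folic_acid = 0.35,
    garlic = 1.0, iron = 0.3, magnesium = 0.3, selenium = 0.4, zinc = 0.3,
    n3_fatty_acids = 0.45, n6_fatty_acids = 0.4, beta_carotene = 0.6,
    onions = 0.8, tea = 1.5
  )
  # energy log-scale parameters reproduce the requested marginal moments
  cv <- energy_sd / energy_mean
  log_sd[["energy"]] <- sqrt(log(1 + cv^2))
  weights <- validate_mdis_weights(weights)
  pars <- weights$parameter
  stopifnot(all(pars %in% names(typical)))
  w <- weights$weight
  pro <- w > 0
  a <- ifelse(pro, 0.8, 0.8 * sum(pro) / sum(!pro))
  s <- unname(log_sd[pars])
  m <- log(unname(typical[pars])) - s^2 / 2
  tibble::tibble(
    parameter = pars,
    log_mean = m,
    log_sd = s,
    energy_loading = a,
    inflammation_loading = 0.05
  )
}

#' Configuration of the synthetic-cohort generator
#'
#' Bundles the marginal structure the generator emulates — a multicenter
#' senior Mediterranean population with overweight/obesity and metabolic
#' syndrome — together with the generative effect sizes, so that every
#' downstream stage can be exercised and parameter recovery can be checked
#' against stored truth.
#'
#' @param n Cohort size (>= 30); default 1134.
#' @param seed Integer seed; every draw in [generate_cohort()] is
#'   reproducible from it.
#' @param prop_women Fraction of women; default 0.48.
#' @param age_mean,age_sd Age marginal, years (truncated to 55–75).
#' @param bmi_mean,bmi_sd BMI marginal, kg/m2 (truncated to 27–40).
#' @param energy_mean,energy_sd Energy intake marginal, kcal/d.
#' @param pa_mean,pa_sd Physical-activity marginal, METs/d (log-normal).
#' @param t2d_prev Type-2 diabetes prevalence.
#' @param score_center Expected M-DIS of the cohort when standardized
#'   against the external reference population emitted by
#'   [external_reference_stats()]; default -3.87 (an anti-inflammatory
#'   cohort relative to that reference).
#' @param score_effect_bmd Generative effect on BMD, g/cm2 per SD of the
#'   latent inflammation exposure (signed; negative = pro-inflammatory
#'   diets lose bone); default -0.03.
#' @param bmd_age_slope,bmd_bmi_slope Linear age and BMI effects on BMD,
#'   g/cm2 per year and per kg/m2.
#' @param nutrient_spec Intake model, see [default_nutrient_spec()].
#' @param site_baselines Tibble `site, sex, mean, sd`: sex-specific BMD
#'   baselines (g/cm2) and residual SDs per site.
#' @param weights Inflammatory weight table.
#' @param missing_rate Fraction of BMD measurements set missing completely
#'   at random; default 0.
#' @return Validated list of class `mdis_cohort_config`.
#' @export
cohort_config <- function(n = 1134L, seed = 1L, prop_women = 0.48,
                          age_mean = 65, age_sd = 5,
                          bmi_mean = 32.6, bmi_sd = 3.4,
                          energy_mean = 2469, energy_sd = 592,
                          pa_mean = 380, pa_sd = 340,
                          t2d_prev = 0.22,
                          score_center = -3.87,
                          score_effect_bmd = -0.03,
                          bmd_age_slope = -0.004, bmd_bmi_slope = 0.005,
                          nutrient_spec = NULL,
                          site_baselines = default_site_baselines(),
                          weights = mdis_weights(),
                          missing_rate = 0) {
  if (is.null(nutrient_spec)) {
    nutrient_spec <- default_nutrient_spec(energy_mean, energy_sd, weights)
  }
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed), prop_women = prop_women,
    age_mean = age_mean, age_sd = age_sd,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    energy_mean = energy_mean, energy_sd = energy_sd,
    pa_mean = pa_mean, pa_sd = pa_sd,
    t2d_prev = t2d_prev, score_center = score_center,
    score_effect_bmd = score_effect_bmd,
    bmd_age_slope = bmd_age_slope, bmd_bmi_slope = bmd_bmi_slope,
    nutrient_spec = nutrient_spec, site_baselines = site_baselines,
    weights = validate_mdis_weights(weights),
    missing_rate = missing_rate
  )
  class(cfg) <- "mdis_cohort_config"
  validate_cohort_config(cfg)
}

#' Default sex-specific BMD baselines of the generator
#'
#' Baseline means chosen at the level typical for seniors (men above
#' women), with residual SDs close to the dispersion DXA studies report.
#'
#' @return Tibble `site, sex, mean, sd` (g/cm2).
#' @export
default_site_baselines <- function() {
  tibble::tibble(
    site = rep(bmd_sites(), each = 2L),
    sex = rep(c("man", "woman"), times = 3L),
    mean = c(1.09, 0.98, 0.92, 0.80, 1.22, 1.13),
    sd = c(0.13, 0.13, 0.135, 0.135, 0.18, 0.18)
  )
}

#' Validate a generator configuration
#'
#' @param config Object from [cohort_config()].
#' @return The config, invisibly checked; errors name the offending field.
#' @export
validate_cohort_config <- function(config) {
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop("invalid config field '", nm, "': must be a fraction in [0, 1]",
           call. = FALSE)
    }
  }
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
      stop("invalid config field '", nm, "': must be > 0", call. = FALSE)
    }
  }
  if (!is.numeric(config$n) || config$n < 30) {
    stop("invalid config field 'n': need n >= 30", call. = FALSE)
  }
  chk_frac(config$prop_women, "prop_women")
  chk_frac(config$t2d_prev, "t2d_prev")
  chk_frac(config$missing_rate, "missing_rate")
  for (nm in c("age_sd", "bmi_sd", "energy_sd", "pa_sd")) {
    chk_pos(config[[nm]], nm)
  }
  ns <- config$nutrient_spec
  if (!all(c("parameter", "log_mean", "log_sd", "energy_loading",
             "inflammation_loading") %in% names(ns))) {
    stop("invalid config field 'nutrient_spec': missing columns",
         call. = FALSE)
  }
  if (!setequal(ns$parameter, config$weights$parameter)) {
    stop("invalid config field 'nutrient_spec': parameters must match ",
         "the weight table", call. = FALSE)
  }
  if (any(ns$log_sd <= 0)) {
    stop("invalid config field 'nutrient_spec': log_sd must be > 0",
         call. = FALSE)
  }
  if (any(ns$energy_loading^2 + ns$inflammation_loading^2 >= 1)) {
    stop("invalid config field 'nutrient_spec': squared loadings must ",
         "sum below 1", call. = FALSE)
  }
  sb <- config$site_baselines
  need <- paste(rep(bmd_sites(), each = 2L), rep(c("man", "woman"), 3L))
  if (!all(need %in% paste(sb$site, sb$sex))) {
    stop("invalid config field 'site_baselines': all six (site, sex) ",
         "cells required", call. = FALSE)
  }
  if (any(!is.finite(sb$sd)) || any(sb$sd <= 0)) {
    stop("invalid config field 'site_baselines': sd must be > 0",
         call. = FALSE)
  }
  invisible(config)
}

# Truncated-normal draws via inverse-CDF on the truncated uniform range.
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm((lower - mean) / sd)
  hi <- stats::pnorm((upper - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}

#' Generate a synthetic cohort with stored generative truth
#'
#' Draws a cohort of `config$n` participants: correlated log-normal
#' nutrient intakes sharing an energy factor and a latent inflammation
#' factor; demographic, lifestyle, medication and center covariates from
#' the configured marginals; and site-specific BMD built as
#' `baseline(sex) + score_effect_bmd * inflammation + age and BMI terms +
#' Gaussian noise`. The latent factors and noiseless BMD means are returned
#' separately as the truth record and never appear in the analysis table.
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return List with `cohort` (analysis tibble), `truth` (per-participant
#'   latent record) and `config`.
#' @export
generate_cohort <- function(config, seed = NULL) {
  validate_cohort_config(config)
  if (is.null(seed)) seed <- config$seed
  set.seed(as.integer(seed))
  n <- config$n
  id <- sprintf(paste0("p%0", max(4L, nchar(n)), "d"), seq_len(n))

  sex <- ifelse(stats::runif(n) < config$prop_women, "woman", "man")
  age <- .rtruncnorm(n, config$age_mean, config$age_sd, 55, 75)
  bmi <- .rtruncnorm(n, config$bmi_mean, config$bmi_sd, 27, 40)
  t2d <- as.integer(stats::runif(n) < config$t2d_prev)

  f_energy <- stats::rnorm(n)
  f_inflam <- stats::rnorm(n)

  ns <- config$nutrient_spec
  w <- config$weights$weight[match(ns$parameter, config$weights$parameter)]
  resid_load <- sqrt(1 - ns$energy_loading^2 - ns$inflammation_loading^2)
  nutr <- matrix(NA_real_, nrow = n, ncol = nrow(ns),
                 dimnames = list(NULL, ns$parameter))
  for (j in seq_len(nrow(ns))) {
    u <- ns$energy_loading[j] * f_energy +
      ns$inflammation_loading[j] * w[j] * f_inflam +
      resid_load[j] * stats::rnorm(n)
    nutr[, j] <- exp(ns$log_mean[j] + ns$log_sd[j] * u)
  }

  # physical activity: log-normal, mildly lower for inflammatory diets
  pa_cv <- config$pa_sd / config$pa_mean
  pa_sdlog <- sqrt(log(1 + pa_cv^2))
  pa_load <- min(0.15, pa_sdlog / 2)
  pa_meanlog <- log(config$pa_mean) - pa_sdlog^2 / 2
  physical_activity <- exp(pa_meanlog - pa_load * f_inflam +
                             sqrt(pa_sdlog^2 - pa_load^2) * stats::rnorm(n))

  education <- sample(c("illiterate_primary", "secondary", "academic"),
                      n, replace = TRUE, prob = c(0.52, 0.30, 0.18))
  smoking <- sample(c("never", "current", "former"),
                    n, replace = TRUE, prob = c(0.41, 0.125, 0.465))
  center <- sample(paste0("center_", 1:4), n, replace = TRUE)
  insulin <- as.integer(t2d == 1L & stats::runif(n) < 0.15)
  oral_antidiabetics <- as.integer(t2d == 1L & stats::runif(n) < 0.72)
  oral_anticoagulants <- as.integer(stats::runif(n) < 0.19)
  ca_vitd_supplements <- as.integer(stats::runif(n) < 0.043)
  estrogens <- as.integer(sex == "woman" & stats::runif(n) < 0.006)

  sb <- config$site_baselines
  true_means <- matrix(NA_real_, nrow = n, ncol = 3L,
                       dimnames = list(NULL, paste0("true_bmd_",
                                                    bmd_sites())))
  bmd <- matrix(NA_real_, nrow = n, ncol = 3L,
                dimnames = list(NULL, paste0("bmd_", bmd_sites())))
  for (k in seq_along(bmd_sites())) {
    site <- bmd_sites()[k]
    rows <- sb[sb$site == site, ]
    base <- rows$mean[match(sex, rows$sex)]
    noise_sd <- rows$sd[match(sex, rows$sex)]
    mu <- base + config$score_effect_bmd * f_inflam +
      config$bmd_age_slope * (age - config$age_mean) +
      config$bmd_bmi_slope * (bmi - config$bmi_mean)
    true_means[, k] <- mu
    bmd[, k] <- mu + stats::rnorm(n, 0, noise_sd)
  }
  if (config$missing_rate > 0) {
    for (k in seq_len(3L)) {
      bmd[stats::runif(n) < config$missing_rate, k] <- NA_real_
    }
  }

  cohort <- tibble::tibble(
    participant_id = id, sex = sex, age = age, bmi = bmi, t2d = t2d,
    education = education, smoking = smoking,
    physical_activity = physical_activity,
    insulin = insulin, oral_antidiabetics = oral_antidiabetics,
    oral_anticoagulants = oral_anticoagulants,
    ca_vitd_supplements = ca_vitd_supplements, estrogens = estrogens,
    center = center
  )
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(nutr),
                             tibble::as_tibble(bmd))
  truth <- tibble::tibble(
    participant_id = id,
    f_energy = f_energy,
    f_inflammation = f_inflam,
    score_effect_bmd = config$score_effect_bmd
  )
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(true_means))
  list(cohort = cohort, truth = truth, config = config)
}

#' T-score reference fixture matching the generator's baselines
#'
#' Returns a reference table whose means and SDs equal the generator's
#' sex-specific baselines and residual SDs, so that under a null
#' configuration (zero score, age and BMI effects) the T-scores of a
#' generated cohort are standard normal and the expected low-BMD
#' prevalence is `pnorm(-1)`.
#'
#' @param config A [cohort_config()].
#' @return Tibble `site, sex, ref_mean, ref_sd`.
#' @export
make_reference_fixture <- function(config) {
  validate_cohort_config(config)
  sb <- config$site_baselines
  validate_tscore_reference(
    tibble::tibble(site = sb$site, sex = sb$sex,
                   ref_mean = sb$mean, ref_sd = sb$sd)
  )
}

#' External standardization reference implied by the generator
#'
#' Exact log-normal marginal means and SDs of every nutrient parameter
#' under the configuration, with the reference means offset along the
#' weight direction so that a generated cohort standardized against this
#' reference has expected M-DIS equal to `config$score_center`. This
#' emulates scoring against the reference population of the score's source
#' publication rather than in-sample.
#'
#' @param config A [cohort_config()].
#' @return Tibble `parameter, mean, sd, source` with `source = "external"`.
#' @export
external_reference_stats <- function(config) {
  validate_cohort_config(config)
  ns <- config$nutrient_spec
  w <- config$weights$weight[match(ns$parameter, config$weights$parameter)]
  mu <- exp(ns$log_mean + ns$log_sd^2 / 2)
  sigma <- mu * sqrt(exp(ns$log_sd^2) - 1)
  tibble::tibble(
    parameter = ns$parameter,
    mean = mu - config$score_center * sigma * w / length(w),
    sd = sigma,
    source = "external"
  )
}
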