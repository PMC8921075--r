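#' The full covariate adjustment set of the association models
#'
#' Sex, type-2 diabetes, age, BMI, education, smoking, leisure-time physical
#' activity, four medication flags, estrogen use, recruitment center and
#' total energy intake — the standard confounder set for diet–bone analyses
#' in senior cohorts.
#'
#' @return Character vector of cohort column names.
#' @export
adjustment_covariates <- function() {
  c("sex", "t2d", "age", "bmi", "education", "smoking",
    "physical_activity", "insulin", "oral_antidiabetics",
    "oral_anticoagulants", "ca_vitd_supplements", "estrogens",
    "center", "energy")
}

# Canonical factor level orders; the first level is the model reference.
.canonical_levels <- list(
  sex = c("man", "woman"),
  education = c("illiterate_primary", "secondary", "academic"),
  smoking = c("never", "current", "former")
)

# Coerce categorical covariates to factors with the canonical reference
# level first; anything else character-like becomes a default factor.
.set_reference_levels <- function(df) {
  for (nm in names(df)) {
    x <- df[[nm]]
    if (nm %in% names(.canonical_levels)) {
      lev <- .canonical_levels[[nm]]
      vals <- as.character(x)
      if (!all(stats::na.omit(vals) %in% lev)) {
        stop("column '", nm, "' has levels outside ",
             paste(lev, collapse = "/"), call. = FALSE)
      }
      df[[nm]] <- factor(vals, levels = lev[lev %in% vals])
    } else if (nm == "center" && !is.factor(x)) {
      df[[nm]] <- factor(as.character(x))
    }
  }
  df
}

# Assemble the complete-case modelling frame for one site: outcome column,
# score, covariates; tertiles are recomputed within the complete cases
# (default) or taken frozen from an existing `tertile` column.
.prepare_site_data <- function(cohort, site, outcome = c("bmd", "low"),
                               covariates = NULL,
                               tertile_scope = c("recompute", "frozen"),
                               score = "mdis") {
  outcome <- match.arg(outcome)
  tertile_scope <- match.arg(tertile_scope)
  site <- match.arg(tolower(site), bmd_sites())
  ycol <- paste0(outcome, "_", site)
  if (!ycol %in% names(cohort)) {
    stop("cohort is missing outcome column '", ycol, "'", call. = FALSE)
  }
  if (!score %in% names(cohort)) {
    stop("cohort is missing score column '", score, "'", call. = FALSE)
  }
  need <- unique(c("participant_id", ycol, score, covariates,
                   if (tertile_scope == "frozen") "tertile"))
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- cohort[, need, drop = FALSE]
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (tertile_scope == "recompute") {
    df$tertile <- assign_tertiles(df[[score]], df$participant_id)
  }
  df$tertile <- factor(df$tertile, levels = c(1L, 2L, 3L))
  df$.outcome <- df[[ycol]]
  df <- .set_reference_levels(df)
  attr(df, "outcome_col") <- ycol
  df
}

.zcrit <- 1.959964

# glm.fit emits its own warnings for separation/non-convergence; the
# package diagnoses both explicitly (.check_separation), so the native
# warnings are muffled at the fit site.
.quiet_glm <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("glm\\.fit", conditionMessage(w)) ||
        grepl("fitted probabilities|did not converge",
              conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Covariates without variation among the analyzed rows cannot enter the
# design matrix; drop them (standard practice for rare binary flags in
# subsamples) and record what was dropped.
.drop_constant_covariates <- function(df, covariates) {
  if (is.null(covariates)) return(NULL)
  keep <- vapply(covariates, function(cv) {
    x <- df[[cv]]
    length(unique(x[!is.na(x)])) > 1L
  }, logical(1))
  structure(covariates[keep], dropped = covariates[!keep])
}

# Wald-style association tibble from a fitted (g)lm with tertile terms.
.tertile_association <- function(fit, outcome, scale, model, n, exponentiate) {
  # summary.lm warns on an exact fit (zero residual variance); the
  # coefficient table is still what is needed
  coefs <- suppressWarnings(summary(fit)$coefficients)
  terms <- paste0("tertile", 2:3)
  ref_est <- if (exponentiate) 1 else 0
  rows <- lapply(terms, function(tm) {
    est <- coefs[tm, 1L]
    se <- coefs[tm, 2L]
    lo <- est - .zcrit * se
    hi <- est + .zcrit * se
    p <- 2 * stats::pnorm(-abs(est / se))
    if (exponentiate) {
      est <- exp(est); lo <- exp(lo); hi <- exp(hi)
    }
    tibble::tibble(term = sub("tertile", "tertile_", tm),
                   estimate = est, ci_low = lo, ci_high = hi, p_value = p)
  })
  out <- dplyr::bind_rows(
    tibble::tibble(term = "tertile_1", estimate = ref_est,
                   ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_),
    dplyr::bind_rows(rows)
  )
  out$outcome <- outcome
  out$scale <- scale
  out$model <- model
  out$n <- n
  out[, c("outcome", "scale", "model", "term",
          "estimate", "ci_low", "ci_high", "p_value", "n")]
}

.check_full_rank <- function(fit) {
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear model terms dropped: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(fit)
}

.check_separation <- function(fit) {
  if (!fit$converged) {
    stop("logistic fit did not converge (possible separation)", call. = FALSE)
  }
  p <- stats::fitted(fit)
  eps <- 1e-8
  if (any(p < eps) || any(p > 1 - eps)) {
    stop("logistic fit shows fitted probabilities of 0 or 1 ",
         "(separation); check the tertile x outcome cells", call. = FALSE)
  }
  invisible(fit)
}

#' Linear regression of site BMD on score tertiles
#'
#' Fits `bmd_<site> ~ tertile (+ covariates)` by least squares on the
#' complete cases for all model terms, with tertile 1 (most
#' anti-inflammatory) as the reference level. The crude model omits the
#' covariates; the adjusted model uses the full set in
#' [adjustment_covariates()].
#'
#' @param cohort Scored cohort table (must contain `mdis` and
#'   `bmd_<site>`).
#' @param site One of [bmd_sites()].
#' @param covariates Character vector of adjustment columns, or `NULL` for
#'   the crude model.
#' @param tertile_scope `"recompute"` (default) re-derives tertiles within
#'   the site's complete-case subsample; `"frozen"` uses an existing
#'   `tertile` column.
#' @return Tibble with one row per tertile: `outcome, scale, model, term,
#'   estimate` (beta in g/cm2, 0 for the reference), `ci_low, ci_high`
#'   (Wald 95% CI), `p_value`, `n` (complete cases used).
#' @export
fit_linear_bmd <- function(cohort, site, covariates = NULL,
                           tertile_scope = c("recompute", "frozen")) {
  df <- .prepare_site_data(cohort, site, "bmd", covariates,
                           match.arg(tertile_scope))
  covs <- .drop_constant_covariates(df, covariates)
  fml <- stats::reformulate(c("tertile", covs), response = ".outcome")
  fit <- stats::lm(fml, data = df)
  .check_full_rank(fit)
  .tertile_association(
    fit, outcome = paste0("bmd_", tolower(site)), scale = "beta",
    model = if (is.null(covariates)) "crude" else "adjusted",
    n = nrow(df), exponentiate = FALSE
  )
}

#' Logistic regression of low-BMD status on score tertiles
#'
#' Fits `low_<site> ~ tertile (+ covariates)` by maximum likelihood with
#' tertile 1 as the reference; estimates are odds ratios with Wald 95%
#' confidence intervals on the log-odds scale.
#'
#' @inheritParams fit_linear_bmd
#' @return Tibble as in [fit_linear_bmd()] with `scale = "or"` and the
#'   reference estimate equal to 1.
#' @export
fit_logistic_low_bmd <- function(cohort, site, covariates = NULL,
                                 tertile_scope = c("recompute", "frozen")) {
  df <- .prepare_site_data(cohort, site, "low", covariates,
                           match.arg(tertile_scope))
  y <- df$.outcome
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; logistic model not identifiable",
         call. = FALSE)
  }
  covs <- .drop_constant_covariates(df, covariates)
  fml <- stats::reformulate(c("tertile", covs), response = ".outcome")
  fit <- .quiet_glm(stats::glm(fml, data = df, family = stats::binomial()))
  .check_full_rank(fit)
  .check_separation(fit)
  .tertile_association(
    fit, outcome = paste0("low_", tolower(site)), scale = "or",
    model = if (is.null(covariates)) "crude" else "adjusted",
    n = nrow(df), exponentiate = TRUE
  )
}

#' Crude odds ratio from a 2x2 exposure-by-outcome table
#'
#' Closed-form unadjusted odds ratio comparing an exposed tertile against
#' the reference tertile:
#' `OR = (exposed_low / exposed_normal) / (ref_low / ref_normal)`, with a
#' Wald 95% confidence interval on the log scale
#' (`SE = sqrt(1/a + 1/b + 1/c + 1/d)`).
#'
#' @param exposed_low,exposed_normal Low-BMD and normal counts in the
#'   exposed tertile.
#' @param ref_low,ref_normal Counts in the reference tertile.
#' @param zero_cell Zero-cell policy: `"error"` (default) or `"haldane"`
#'   (add 0.5 to every cell).
#' @return Tibble `or, ci_low, ci_high, p_value, n`.
#' @export
crude_or_2x2 <- function(exposed_low, exposed_normal, ref_low, ref_normal,
                         zero_cell = c("error", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  cells <- c(exposed_low, exposed_normal, ref_low, ref_normal)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("all four counts must be finite and non-negative", call. = FALSE)
  }
  if (exposed_low + exposed_normal == 0 || ref_low + ref_normal == 0) {
    stop("each tertile must contain at least one participant", call. = FALSE)
  }
  if (any(cells == 0)) {
    if (zero_cell == "error") {
      stop("zero cell in the 2x2 table; set zero_cell = \"haldane\" ",
           "for the 0.5 continuity correction", call. = FALSE)
    }
    cells <- cells + 0.5
  }
  log_or <- log(cells[1L]) - log(cells[2L]) - log(cells[3L]) + log(cells[4L])
  se <- sqrt(sum(1 / cells))
  tibble::tibble(
    or = exp(log_or),
    ci_low = exp(log_or - .zcrit * se),
    ci_high = exp(log_or + .zcrit * se),
    p_value = 2 * stats::pnorm(-abs(log_or / se)),
    n = sum(cells)
  )
}

#' Descriptive characteristics by score tertile
#'
#' One row per variable level with per-tertile summaries — `mean +/- SD` for
#' quantitative variables, `% (n)` for categorical ones — and a p-value
#' from one-way ANOVA (quantitative) or the Pearson chi-square test
#' (categorical). A variable constant everywhere keeps its row with
#' `p_value = NA`.
#'
#' @param cohort Cohort table containing `tertile` and the requested
#'   variables.
#' @param variables Character vector of column names to describe; defaults
#'   to every column except identifiers, tertile and nutrient intakes.
#' @param tertile_col Name of the tertile column.
#' @return Tibble `variable, level, tertile_1, tertile_2, tertile_3, test,
#'   p_value`.
#' @export
descriptive_table <- function(cohort, variables = NULL,
                              tertile_col = "tertile") {
  if (!tertile_col %in% names(cohort)) {
    stop("cohort is missing the tertile column '", tertile_col, "'",
         call. = FALSE)
  }
  tert <- factor(cohort[[tertile_col]])
  if (nlevels(droplevels(tert[!is.na(tert)])) < 2L) {
    stop("need at least two non-empty tertiles", call. = FALSE)
  }
  if (is.null(variables)) {
    skip <- c("participant_id", tertile_col, mdis_parameters()$parameter)
    skip <- setdiff(skip, "energy")  # energy intake is a Table-1 variable
    variables <- setdiff(names(cohort), skip)
  }
  levs <- levels(tert)
  rows <- list()
  for (v in variables) {
    x <- cohort[[v]]
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2L) {
      cell <- vapply(levs, function(l) {
        xi <- x[tert == l & !is.na(tert)]
        sprintf("%.2f +/- %.2f", mean(xi, na.rm = TRUE),
                stats::sd(xi, na.rm = TRUE))
      }, character(1))
      p <- if (stats::sd(x, na.rm = TRUE) > 0) {
        stats::anova(stats::lm(x ~ tert))[["Pr(>F)"]][1L]
      } else NA_real_
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, level = NA_character_,
        tertile_1 = cell[1L], tertile_2 = cell[2L], tertile_3 = cell[3L],
        test = "anova", p_value = p
      )
    } else {
      f <- factor(x)
      tab <- table(f, tert)
      p <- if (nrow(tab) > 1L) {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      } else NA_real_
      for (lv in rownames(tab)) {
        cnt <- tab[lv, ]
        tot <- colSums(tab)
        cell <- sprintf("%.2f (%d)", 100 * cnt / pmax(tot, 1L), cnt)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          variable = v, level = lv,
          tertile_1 = cell[1L], tertile_2 = cell[2L], tertile_3 = cell[3L],
          test = "chisq", p_value = p
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Covariate-adjusted mean BMD per tertile with Tukey pairwise contrasts
#'
#' Fits the ANCOVA model `bmd_<site> ~ tertile + covariates` and reports
#' model-predicted (marginal) means per tertile evaluated at the covariate
#' grand means with equal weights over factor levels, plus Tukey
#' honest-significant-difference p-values for the three pairwise tertile
#' contrasts (studentized-range distribution on the residual degrees of
#' freedom).
#'
#' @inheritParams fit_linear_bmd
#' @return List with `adjusted_means` (tibble `tertile, adj_mean, se, df`),
#'   `tukey` (tibble `contrast, estimate, se, p_value`) and `n`.
#' @export
ancova_adjusted_means <- function(cohort, site, covariates = NULL,
                                  tertile_scope = c("recompute", "frozen")) {
  df <- .prepare_site_data(cohort, site, "bmd", covariates,
                           match.arg(tertile_scope))
  covs <- .drop_constant_covariates(df, covariates)
  fml <- stats::reformulate(c("tertile", covs), response = ".outcome")
  fit <- stats::lm(fml, data = df)
  .check_full_rank(fit)
  emm <- emmeans::emmeans(fit, "tertile", weights = "equal")
  means <- as.data.frame(emm)
  cmp <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  list(
    adjusted_means = tibble::tibble(
      tertile = as.character(means$tertile),
      adj_mean = means$emmean, se = means$SE, df = means$df
    ),
    tukey = tibble::tibble(
      contrast = cmp$contrast, estimate = cmp$estimate,
      se = cmp$SE, p_value = cmp$p.value
    ),
    n = nrow(df)
  )
}

#' P for trend: the score modelled continuously
#'
#' Two-sided p-value for the coefficient of the continuous score in the
#' linear (Gaussian outcome) or logistic (binary 0/1 outcome) model carrying
#' the same adjustment set as the corresponding tertile model.
#'
#' @param cohort Cohort table.
#' @param outcome Name of the outcome column (`bmd_<site>` or
#'   `low_<site>`).
#' @param score Name of the continuous exposure column (default `"mdis"`).
#' @param covariates Adjustment columns or `NULL`.
#' @return Single p-value with attributes `estimate`, `se` and `n`.
#' @export
p_for_trend <- function(cohort, outcome, score = "mdis", covariates = NULL) {
  need <- unique(c(outcome, score, covariates))
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- cohort[stats::complete.cases(cohort[, need, drop = FALSE]), need,
               drop = FALSE]
  df <- .set_reference_levels(df)
  if (stats::sd(df[[score]]) == 0) {
    stop("degenerate exposure: score has zero variance among complete cases",
         call. = FALSE)
  }
  y <- df[[outcome]]
  binary <- all(y %in% c(0L, 1L))
  covariates <- .drop_constant_covariates(df, covariates)
  fml <- stats::reformulate(c(score, covariates), response = outcome)
  fit <- if (binary) {
    .quiet_glm(stats::glm(fml, data = df, family = stats::binomial()))
  } else {
    stats::lm(fml, data = df)
  }
  .check_full_rank(fit)
  co <- summary(fit)$coefficients[score, ]
  p <- 2 * stats::pnorm(-abs(co[1L] / co[2L]))
  structure(unname(p), estimate = unname(co[1L]), se = unname(co[2L]),
            n = nrow(df))
}

#' Likelihood-ratio test for effect modification
#'
#' Compares the adjusted model with and without a score-by-modifier product
#' term; the test statistic is twice the log-likelihood difference,
#' referred to a chi-square distribution with degrees of freedom equal to
#' the number of added product terms.
#'
#' @param cohort Cohort table.
#' @param outcome Outcome column name (continuous or binary 0/1).
#' @param score Continuous exposure column (default `"mdis"`).
#' @param modifier One of `"sex"`, `"t2d"`, `"bmi"` (any non-constant
#'   cohort column is accepted).
#' @param covariates Adjustment columns; the modifier is added to the main
#'   effects if absent.
#' @return P-value with attributes `statistic` (LR chi-square) and `df`.
#' @export
lr_interaction_test <- function(cohort, outcome, score = "mdis", modifier,
                                covariates = NULL) {
  main <- unique(c(score, modifier, covariates))
  need <- unique(c(outcome, main))
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- cohort[stats::complete.cases(cohort[, need, drop = FALSE]), need,
               drop = FALSE]
  df <- .set_reference_levels(df)
  if (length(unique(df[[modifier]])) < 2L) {
    stop("modifier '", modifier, "' is constant among complete cases",
         call. = FALSE)
  }
  main <- unique(c(score, modifier,
                   .drop_constant_covariates(df, covariates)))
  y <- df[[outcome]]
  binary <- all(y %in% c(0L, 1L))
  f0 <- stats::reformulate(main, response = outcome)
  f1 <- stats::reformulate(c(main, paste0(score, ":", modifier)),
                           response = outcome)
  fitter <- function(f) {
    if (binary) {
      .quiet_glm(stats::glm(f, data = df, family = stats::binomial()))
    } else {
      stats::lm(f, data = df)
    }
  }
  fit0 <- fitter(f0)
  fit1 <- fitter(f1)
  if (binary) {
    if (!fit0$converged || !fit1$converged) {
      stop("interaction models did not converge", call. = FALSE)
    }
  }
  df_diff <- length(stats::coef(fit1)) - length(stats::coef(fit0))
  if (df_diff < 1L) {
    stop("interaction model adds no parameters; models are not nested",
         call. = FALSE)
  }
  stat <- 2 * (as.numeric(stats::logLik(fit1)) -
                 as.numeric(stats::logLik(fit0)))
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df = df_diff, lower.tail = FALSE)
  structure(p, statistic = stat, df = df_diff)
}

# Stratification scheme of the sensitivity analyses: label, splitting
# function, and the covariate(s) removed from the adjustment set.
.strata_scheme <- function() {
  list(
    age = list(
      split = function(df) ifelse(df$age < 70, "age_lt70", "age_ge70"),
      drop = "age"
    ),
    sex = list(
      split = function(df) as.character(df$sex),
      drop = "sex"
    ),
    bmi = list(
      split = function(df) ifelse(df$bmi < 30, "bmi_lt30", "bmi_ge30"),
      drop = "bmi"
    ),
    t2d = list(
      split = function(df) ifelse(df$t2d == 1, "t2d", "no_t2d"),
      drop = "t2d"
    )
  )
}

#' Stratified tertile-3 odds ratios (sensitivity analyses)
#'
#' Refits the adjusted logistic model for low-BMD status within strata of
#' age (< 70 / >= 70 years), sex, BMI (< 30 / >= 30 kg/m2) and type-2
#' diabetes, removing the stratifying variable from the adjustment set.
#' Tertile assignment is taken from the full site sample, so strata are
#' compared on a common exposure scale. Strata whose data cannot support
#' the model (single outcome class, an empty tertile, or a failed fit) are
#' flagged and retained rather than dropped.
#'
#' @inheritParams fit_linear_bmd
#' @param covariates Adjustment set; defaults to [adjustment_covariates()].
#' @return Tibble `stratifier, stratum, n, n_low, or, ci_low, ci_high,
#'   p_value, flag` with one row per stratum (tertile 3 vs tertile 1).
#' @export
stratified_ors <- function(cohort, site,
                           covariates = adjustment_covariates(),
                           tertile_scope = c("recompute", "frozen")) {
  df <- .prepare_site_data(cohort, site, "low", covariates,
                           match.arg(tertile_scope))
  scheme <- .strata_scheme()
  out <- list()
  for (nm in names(scheme)) {
    sc <- scheme[[nm]]
    lab <- sc$split(df)
    covs <- setdiff(covariates, sc$drop)
    for (lv in unique(lab)) {
      sub <- df[lab == lv, , drop = FALSE]
      flag <- NA_character_
      est <- c(or = NA_real_, lo = NA_real_, hi = NA_real_, p = NA_real_)
      if (length(unique(sub$.outcome)) < 2L) {
        flag <- "single outcome class"
      } else if (any(table(sub$tertile) == 0L)) {
        flag <- "empty tertile"
      } else {
        fit <- tryCatch({
          covs_s <- .drop_constant_covariates(sub, covs)
          f <- stats::reformulate(c("tertile", covs_s),
                                  response = ".outcome")
          g <- .quiet_glm(stats::glm(f, data = droplevels(sub),
                                     family = stats::binomial()))
          .check_separation(g)
          g
        }, error = function(e) e)
        if (inherits(fit, "error")) {
          flag <- conditionMessage(fit)
        } else {
          co <- summary(fit)$coefficients
          if (!"tertile3" %in% rownames(co)) {
            flag <- "tertile 3 term not estimable"
          } else {
            b <- co["tertile3", 1L]
            se <- co["tertile3", 2L]
            est <- c(or = exp(b), lo = exp(b - .zcrit * se),
                     hi = exp(b + .zcrit * se),
                     p = 2 * stats::pnorm(-abs(b / se)))
          }
        }
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        stratifier = nm, stratum = lv, n = nrow(sub),
        n_low = sum(sub$.outcome == 1L),
        or = est[["or"]], ci_low = est[["lo"]], ci_high = est[["hi"]],
        p_value = est[["p"]], flag = flag
      )
    }
  }
  dplyr::bind_rows(out)
}
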