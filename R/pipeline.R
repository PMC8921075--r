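#' Assemble an end-to-end run configuration
#'
#' @param cohort Cohort table (data frame) or path to a cohort CSV.
#' @param tscore_reference T-score reference table or path to its CSV.
#' @param out_dir Output directory; created if absent.
#' @param weights Weight table, path to one, or `NULL` for the package
#'   default [mdis_weights()].
#' @param reference_stats Standardization reference (`parameter,mean,sd`),
#'   path, or `NULL` for in-sample statistics.
#' @param covariates Adjustment set; default [adjustment_covariates()].
#' @param tertile_scope `"recompute"` (per-outcome complete-case tertiles,
#'   default) or `"frozen"` (whole-cohort tertiles reused in every model).
#' @param missing Missing-intake policy passed to [compute_mdis()].
#' @param zero_cell Zero-cell policy passed to [crude_or_2x2()].
#' @param boundary Zero-score classification passed to [compute_mdis()].
#' @param seed Integer recorded in the run summary (the analysis itself is
#'   deterministic).
#' @return List of class `mdis_run_config`.
#' @export
run_config <- function(cohort, tscore_reference, out_dir,
                       weights = NULL, reference_stats = NULL,
                       covariates = adjustment_covariates(),
                       tertile_scope = c("recompute", "frozen"),
                       missing = c("error", "complete_case"),
                       zero_cell = c("error", "haldane"),
                       boundary = c("pro_inflammatory", "anti_inflammatory"),
                       seed = 1L) {
  cfg <- list(
    cohort = cohort, tscore_reference = tscore_reference,
    out_dir = out_dir, weights = weights,
    reference_stats = reference_stats, covariates = covariates,
    tertile_scope = match.arg(tertile_scope),
    missing = match.arg(missing),
    zero_cell = match.arg(zero_cell),
    boundary = match.arg(boundary),
    seed = as.integer(seed)
  )
  class(cfg) <- "mdis_run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Path-valued fields are interpreted relative to the YAML file's
#' directory.
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [run_config()].
#' @return List of class `mdis_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p) || is.na(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  args <- list(
    cohort = rel(raw$cohort),
    tscore_reference = rel(raw$tscore_reference),
    out_dir = if (!is.null(raw$out_dir)) raw$out_dir else
      file.path(base, "mdisbone_out"),
    weights = rel(raw$weights),
    reference_stats = rel(raw$reference_stats)
  )
  for (nm in c("covariates", "tertile_scope", "missing", "zero_cell",
               "boundary", "seed")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  do.call(run_config, args)
}

#' Validate a cohort table against the pipeline schema
#'
#' Checks column presence, identifier uniqueness, and plausibility ranges
#' (age 18–120 years, BMI 10–80 kg/m2, BMD 0.2–2.5 g/cm2, non-negative
#' intakes), plus a per-column missingness census.
#'
#' @param cohort Parsed cohort data frame.
#' @param weights Weight table defining the expected intake columns.
#' @return List with `violations` (tibble `column, row, issue`) and
#'   `missingness` (tibble `column, n_missing`); a clean table yields zero
#'   violation rows.
#' @export
validate_cohort <- function(cohort, weights = mdis_weights()) {
  weights <- validate_mdis_weights(weights, n_expected = NULL)
  required <- c("participant_id", "sex", weights$parameter)
  viol <- list()
  add <- function(column, row, issue) {
    viol[[length(viol) + 1L]] <<- tibble::tibble(
      column = column, row = as.integer(row), issue = issue
    )
  }
  for (col in setdiff(required, names(cohort))) {
    add(col, NA_integer_, "required column missing")
  }
  if ("participant_id" %in% names(cohort)) {
    dup <- cohort$participant_id[duplicated(cohort$participant_id)]
    for (d in unique(dup)) {
      add("participant_id", which(cohort$participant_id == d)[2L],
          paste0("duplicated id '", d, "'"))
    }
  }
  rng <- function(col, lo, hi) {
    if (!col %in% names(cohort)) return()
    x <- cohort[[col]]
    bad <- which(!is.na(x) & (x < lo | x > hi))
    for (i in bad) {
      add(col, i, sprintf("value %g outside [%g, %g]", x[i], lo, hi))
    }
  }
  rng("age", 18, 120)
  rng("bmi", 10, 80)
  for (site in bmd_sites()) rng(paste0("bmd_", site), 0.2, 2.5)
  for (p in intersect(weights$parameter, names(cohort))) {
    rng(p, 0, Inf)
  }
  missingness <- tibble::tibble(
    column = names(cohort),
    n_missing = vapply(cohort, function(x) sum(is.na(x)), integer(1))
  )
  list(
    violations = if (length(viol)) dplyr::bind_rows(viol) else
      tibble::tibble(column = character(), row = integer(),
                     issue = character()),
    missingness = missingness
  )
}

.load_table <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

# One logistic/linear block of the association tables; failures become a
# log line and the run continues.
.try_model <- function(expr, log, what) {
  tryCatch(expr, error = function(e) {
    log(paste0("MODEL FAILURE [", what, "]: ", conditionMessage(e)))
    NULL
  })
}

#' Run the full scoring and association pipeline
#'
#' Sequences dietary scoring, T-score classification and the association
#' analyses, writing to `config$out_dir`: `scored_cohort.csv`,
#' `table1.csv` (descriptives by tertile), `table2.csv` (linear BMD
#' models), `ancova_means.csv` (adjusted means and Tukey contrasts),
#' `table3.csv` (logistic low-BMD models with per-tertile counts),
#' `stratified_forest.csv` (sensitivity strata), `summary.json`
#' (machine-readable settings and per-model ns) and `run_log.txt`.
#' Outputs are deterministic for fixed inputs: rerunning a config
#' reproduces the files byte for byte.
#'
#' @param config An [run_config()] object or path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, the run summary list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "mdis_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log <- function(msg) log_lines <<- c(log_lines, msg)
  out <- function(name) file.path(config$out_dir, name)

  cohort <- .load_table(config$cohort, function(p) {
    tibble::as_tibble(utils::read.csv(p, stringsAsFactors = FALSE))
  })
  weights <- if (is.null(config$weights)) mdis_weights() else
    .load_table(config$weights, read_mdis_weights)
  ref <- if (is.null(config$reference_stats)) NULL else
    .load_table(config$reference_stats, read_reference_stats)
  tref <- .load_table(config$tscore_reference, read_tscore_reference)
  tref <- validate_tscore_reference(tref)

  log("mdisbone pipeline run")
  log(paste0("settings: tertile_scope=", config$tertile_scope,
             " missing=", config$missing,
             " zero_cell=", config$zero_cell,
             " boundary=", config$boundary,
             " seed=", config$seed))
  log(paste0("weights: ",
             paste(weights$parameter, weights$weight, sep = "=",
                   collapse = " ")))
  log(paste0("standardization: ",
             if (is.null(ref)) "in_sample" else
               paste0(ref$source[1L], " reference (",
                      nrow(ref), " parameters)")))

  val <- validate_cohort(cohort, weights)
  if (nrow(val$violations) > 0L) {
    utils::write.csv(val$violations, out("validation_violations.csv"),
                     row.names = FALSE)
    stop("cohort failed schema validation (",
         nrow(val$violations), " violation(s)); first: ",
         val$violations$issue[1L], " [column ", val$violations$column[1L],
         if (!is.na(val$violations$row[1L]))
           paste0(", row ", val$violations$row[1L]) else "",
         "]", call. = FALSE)
  }
  log(paste0("cohort: ", nrow(cohort), " participants, 0 violations"))

  scored <- compute_mdis(cohort, weights, ref,
                         missing = config$missing,
                         boundary = config$boundary)
  cohort <- dplyr::inner_join(cohort, scored, by = "participant_id")
  cohort$tertile <- assign_tertiles(cohort$mdis, cohort$participant_id)
  cohort <- score_bone(cohort, tref)
  utils::write.csv(cohort, out("scored_cohort.csv"), row.names = FALSE)
  log(paste0("scored: mean M-DIS ",
             formatC(mean(cohort$mdis), digits = 4, format = "f"),
             ", SD ", formatC(stats::sd(cohort$mdis), digits = 4,
                              format = "f")))

  table1 <- descriptive_table(
    cohort,
    variables = intersect(
      c("mdis", "age", "sex", "bmi", "physical_activity", "smoking",
        "education", "t2d", "energy", "insulin", "oral_anticoagulants",
        "oral_antidiabetics", "estrogens", "ca_vitd_supplements"),
      names(cohort)
    )
  )
  utils::write.csv(table1, out("table1.csv"), row.names = FALSE)

  scope <- config$tertile_scope
  covs <- config$covariates
  t2_rows <- list(); t3_rows <- list(); am_rows <- list()
  strat_rows <- list(); model_ns <- list()
  for (site in bmd_sites()) {
    for (model in c("crude", "adjusted")) {
      mc <- if (model == "crude") NULL else covs
      lin <- .try_model(
        fit_linear_bmd(cohort, site, mc, tertile_scope = scope),
        log, paste("linear", site, model))
      if (!is.null(lin)) {
        pt <- .try_model(
          p_for_trend(cohort, paste0("bmd_", site), "mdis", mc),
          log, paste("trend linear", site, model))
        lin$p_trend <- if (length(pt)) as.numeric(pt) else NA_real_
        t2_rows[[length(t2_rows) + 1L]] <- lin
        model_ns[[paste("linear", site, model, sep = "_")]] <- lin$n[1L]
      }
      lgt <- .try_model(
        fit_logistic_low_bmd(cohort, site, mc, tertile_scope = scope),
        log, paste("logistic", site, model))
      if (!is.null(lgt)) {
        pt <- .try_model(
          p_for_trend(cohort, paste0("low_", site), "mdis", mc),
          log, paste("trend logistic", site, model))
        lgt$p_trend <- if (length(pt)) as.numeric(pt) else NA_real_
        df_site <- .prepare_site_data(cohort, site, "low", mc, scope)
        counts <- table(df_site$tertile, df_site$.outcome)
        idx <- match(sub("tertile_", "", lgt$term), rownames(counts))
        lgt$n_tertile <- rowSums(counts)[idx]
        lgt$n_low <- counts[, "1"][idx]
        t3_rows[[length(t3_rows) + 1L]] <- lgt
        model_ns[[paste("logistic", site, model, sep = "_")]] <- lgt$n[1L]
      }
    }
    am <- .try_model(
      ancova_adjusted_means(cohort, site, covs, tertile_scope = scope),
      log, paste("ancova", site))
    if (!is.null(am)) {
      means <- am$adjusted_means
      means$site <- site
      means$tukey_contrast <- NA_character_
      means$tukey_p <- NA_real_
      tk <- tibble::tibble(
        tertile = NA_character_, adj_mean = am$tukey$estimate,
        se = am$tukey$se, df = NA_real_, site = site,
        tukey_contrast = am$tukey$contrast, tukey_p = am$tukey$p_value
      )
      am_rows[[length(am_rows) + 1L]] <- dplyr::bind_rows(means, tk)
      model_ns[[paste("ancova", site, sep = "_")]] <- am$n
    }
    st <- .try_model(
      stratified_ors(cohort, site, covs, tertile_scope = scope),
      log, paste("stratified", site))
    if (!is.null(st)) {
      st$site <- site
      strat_rows[[length(strat_rows) + 1L]] <- st
    }
  }
  utils::write.csv(dplyr::bind_rows(t2_rows), out("table2.csv"),
                   row.names = FALSE)
  utils::write.csv(dplyr::bind_rows(am_rows), out("ancova_means.csv"),
                   row.names = FALSE)
  utils::write.csv(dplyr::bind_rows(t3_rows), out("table3.csv"),
                   row.names = FALSE)
  utils::write.csv(dplyr::bind_rows(strat_rows),
                   out("stratified_forest.csv"), row.names = FALSE)
  for (nm in names(model_ns)) {
    log(paste0("complete cases [", nm, "]: ", model_ns[[nm]]))
  }

  summary <- list(
    n_cohort = nrow(cohort),
    mdis_mean = mean(cohort$mdis),
    mdis_sd = stats::sd(cohort$mdis),
    settings = list(
      tertile_scope = config$tertile_scope, missing = config$missing,
      zero_cell = config$zero_cell, boundary = config$boundary,
      seed = config$seed,
      standardization = if (is.null(ref)) "in_sample" else ref$source[1L],
      covariates = covs
    ),
    weights = stats::setNames(as.list(weights$weight), weights$parameter),
    model_n = model_ns
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, out("run_log.txt"))
  invisible(summary)
}
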