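#' Convert bone mineral density to a T-score
#'
#' A T-score expresses an areal BMD value (g/cm2) as the number of
#' reference-population standard deviations it lies from the reference mean:
#' `t = (bmd - ref_mean) / ref_sd`.
#'
#' @param bmd Measured BMD in g/cm2; vectorized.
#' @param ref_mean,ref_sd Reference-population mean and SD in g/cm2;
#'   `ref_sd` strictly positive.
#' @return Numeric T-score(s) in SD units.
#' @export
compute_t_score <- function(bmd, ref_mean, ref_sd) {
  if (any(!is.finite(ref_sd)) || any(ref_sd <= 0)) {
    stop("invalid reference: ref_sd must be finite and > 0", call. = FALSE)
  }
  (bmd - ref_mean) / ref_sd
}

#' Classify low versus normal bone mineral density
#'
#' Low-BMD status pools osteopenia and osteoporosis into one class:
#' `"low"` when the T-score is equal to or lower than -1 (the boundary is
#' included in the low class), `"normal"` when it is strictly above -1.
#'
#' @param t Numeric T-score(s); must be finite (`NA` propagates).
#' @param cutoff Classification threshold in SD units; default -1.
#' @return Character vector, `"low"` or `"normal"`.
#' @export
classify_bmd_status <- function(t, cutoff = -1) {
  if (any(is.infinite(t) | is.nan(t))) {
    stop("invalid input: T-scores must be finite", call. = FALSE)
  }
  ifelse(is.na(t), NA_character_, ifelse(t <= cutoff, "low", "normal"))
}

#' The three skeletal measurement sites
#'
#' @return Character vector: `"tf"` (total femur), `"tr"` (trochanter),
#'   `"ls"` (lumbar spine L1-L4).
#' @export
bmd_sites <- function() c("tf", "tr", "ls")

#' Read a sex-specific T-score reference table
#'
#' @param path CSV file with header `site,sex,ref_mean,ref_sd` covering all
#'   six (site, sex) combinations.
#' @return Validated tibble.
#' @export
read_tscore_reference <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_tscore_reference(tab)
}

#' Validate a T-score reference table
#'
#' @param reference Data frame with columns `site`, `sex`, `ref_mean`,
#'   `ref_sd`; one row per (site, sex) cell, sites in [bmd_sites()], sexes
#'   `man`/`woman`.
#' @return The table as a tibble.
#' @export
validate_tscore_reference <- function(reference) {
  required <- c("site", "sex", "ref_mean", "ref_sd")
  missing_cols <- setdiff(required, names(reference))
  if (length(missing_cols) > 0L) {
    stop("T-score reference is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  reference$site <- tolower(as.character(reference$site))
  reference$sex <- tolower(as.character(reference$sex))
  cells <- expand.grid(site = bmd_sites(), sex = c("man", "woman"),
                       stringsAsFactors = FALSE)
  have <- paste(reference$site, reference$sex)
  need <- paste(cells$site, cells$sex)
  if (!all(need %in% have)) {
    stop("T-score reference must cover all six (site, sex) cells; missing: ",
         paste(setdiff(need, have), collapse = "; "), call. = FALSE)
  }
  if (any(!is.finite(reference$ref_sd)) || any(reference$ref_sd <= 0)) {
    stop("invalid reference: every ref_sd must be finite and > 0",
         call. = FALSE)
  }
  tibble::as_tibble(reference[, required])
}

#' Append T-scores and low-BMD status to a cohort table
#'
#' For each site with a `bmd_<site>` column, computes the sex-specific
#' T-score and the dichotomous low/normal status, appending columns
#' `t_<site>` and `low_<site>` (0/1 integer; `low_<site> = 1` when the
#' T-score is <= -1).
#'
#' @param cohort Data frame with a `sex` column (`man`/`woman`) and BMD
#'   columns `bmd_tf`, `bmd_tr`, `bmd_ls` in g/cm2 (missing measurements as
#'   `NA`).
#' @param reference T-score reference table, see [read_tscore_reference()].
#' @return `cohort` with six appended columns.
#' @export
score_bone <- function(cohort, reference) {
  reference <- validate_tscore_reference(reference)
  if (!"sex" %in% names(cohort)) {
    stop("cohort must have a 'sex' column", call. = FALSE)
  }
  sex <- tolower(as.character(cohort$sex))
  if (!all(sex %in% c("man", "woman"))) {
    stop("sex must be coded 'man'/'woman'", call. = FALSE)
  }
  for (site in bmd_sites()) {
    col <- paste0("bmd_", site)
    if (!col %in% names(cohort)) next
    bmd <- cohort[[col]]
    if (any(!is.na(bmd) & bmd <= 0)) {
      stop("BMD values must be positive (column ", col, ")", call. = FALSE)
    }
    ref_rows <- reference[reference$site == site, ]
    idx <- match(sex, ref_rows$sex)
    t <- compute_t_score(bmd, ref_rows$ref_mean[idx], ref_rows$ref_sd[idx])
    cohort[[paste0("t_", site)]] <- t
    cohort[[paste0("low_", site)]] <-
      ifelse(is.na(t), NA_integer_, as.integer(t <= -1))
  }
  tibble::as_tibble(cohort)
}
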