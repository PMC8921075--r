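#' The 32 dietary parameters of the modified dietary inflammatory score
#'
#' Returns the canonical parameter names, in the order used throughout the
#' package, together with the intake unit of each parameter.
#'
#' @return A tibble with columns `parameter` and `unit`.
#' @export
mdis_parameters <- function() {
  tibble::tibble(
    parameter = c(
      "caffeine", "alcohol", "vitamin_b1", "vitamin_b2", "vitamin_b3",
      "vitamin_b6", "vitamin_b12", "vitamin_a", "vitamin_c", "vitamin_e",
      "vitamin_d", "carbohydrates", "protein", "cholesterol",
      "total_fatty_acids", "mufa", "pufa", "sfa", "trans_fatty_acids",
      "energy", "fiber", "folic_acid", "garlic", "iron", "magnesium",
      "selenium", "zinc", "n3_fatty_acids", "n6_fatty_acids",
      "beta_carotene", "onions", "tea"
    ),
    unit = c(
      "g/d", "g/d", "mg/d", "mg/d", "mg/d",
      "mg/d", "ug/d", "RE/d", "mg/d", "mg/d",
      "ug/d", "g/d", "g/d", "mg/d",
      "g/d", "g/d", "g/d", "g/d", "g/d",
      "kcal/d", "g/d", "ug/d", "g/d", "mg/d", "mg/d",
      "ug/d", "mg/d", "g/d", "g/d",
      "ug/d", "g/d", "g/d"
    )
  )
}

# Parameters conventionally scored as pro-inflammatory (+1); the remaining
# 23 parameters carry weight -1. The default table is a reconstruction of
# the score's usual convention and is meant to be replaced by a user file
# when a study-specific weight set is available.
.pro_inflammatory_defaults <- c(
  "vitamin_b12", "carbohydrates", "cholesterol", "energy",
  "total_fatty_acids", "iron", "protein", "sfa", "trans_fatty_acids"
)

#' Default M-DIS inflammatory weight table
#'
#' Each of the 32 dietary parameters carries a signed weight reflecting its
#' literature-assessed effect on circulating inflammatory biomarkers: +1 for
#' parameters that raise them, -1 for parameters that lower them, 0 for no
#' effect. The default shipped here is a reconstructed convention (nine
#' pro-inflammatory macronutrient-type parameters, twenty-three
#' anti-inflammatory ones); studies with their own weight assignment should
#' load it with [read_mdis_weights()].
#'
#' @return A tibble with columns `parameter`, `weight` (integer in
#'   \{-1, 0, 1\}) and `unit`.
#' @seealso [read_mdis_weights()], [compute_mdis()]
#' @export
mdis_weights <- function() {
  pars <- mdis_parameters()
  pars$weight <- ifelse(pars$parameter %in% .pro_inflammatory_defaults, 1L, -1L)
  pars[, c("parameter", "weight", "unit")]
}

#' Read an M-DIS weight table from a delimited file
#'
#' @param path CSV file with header `parameter,weight,unit`.
#' @param n_expected Number of distinct parameters the table must contain;
#'   `NULL` skips the count check. Defaults to 32, the size of the score
#'   used by this package.
#' @return Validated tibble as in [mdis_weights()].
#' @export
read_mdis_weights <- function(path, n_expected = 32L) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_mdis_weights(tab, n_expected = n_expected)
}

#' Validate an M-DIS weight table
#'
#' @param weights Data frame with columns `parameter`, `weight`, `unit`.
#' @param n_expected Expected number of parameters, or `NULL`.
#' @return The table as a tibble, invisibly checked.
#' @export
validate_mdis_weights <- function(weights, n_expected = 32L) {
  required <- c("parameter", "weight")
  missing_cols <- setdiff(required, names(weights))
  if (length(missing_cols) > 0L) {
    stop("weight table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(weights$parameter)) {
    stop("weight table has duplicated parameter names", call. = FALSE)
  }
  if (!all(weights$weight %in% c(-1L, 0L, 1L))) {
    stop("every weight must be -1, 0 or +1", call. = FALSE)
  }
  if (!is.null(n_expected) && nrow(weights) != n_expected) {
    stop("weight table has ", nrow(weights), " parameters; expected ",
         n_expected, call. = FALSE)
  }
  if (!"unit" %in% names(weights)) weights$unit <- NA_character_
  tibble::as_tibble(weights[, c("parameter", "weight", "unit")])
}

#' Standardize an intake value as a z-score
#'
#' @param value Intake in the parameter's own units; vectorized.
#' @param mean,sd Reference mean and standard deviation in the same units;
#'   `sd` must be strictly positive.
#' @return `(value - mean) / sd`.
#' @export
standardize_intake <- function(value, mean, sd) {
  if (any(!is.finite(sd)) || any(sd <= 0)) {
    stop("invalid reference: sd must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(value))) {
    stop("invalid input: intake values must be finite", call. = FALSE)
  }
  (value - mean) / sd
}

#' Estimate in-sample standardization statistics
#'
#' Computes the per-parameter sample mean and sample standard deviation
#' (denominator n - 1) of the analyzed cohort, to be used as the
#' standardization reference when no external reference population is
#' supplied.
#'
#' @param cohort Data frame with one column per weight-table parameter.
#' @param weights Weight table; defaults to [mdis_weights()].
#' @return A tibble `parameter, mean, sd, source` with `source = "in_sample"`.
#' @export
estimate_reference_stats <- function(cohort, weights = mdis_weights()) {
  weights <- validate_mdis_weights(weights, n_expected = NULL)
  missing_cols <- setdiff(weights$parameter, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing parameter column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stats <- lapply(weights$parameter, function(p) {
    x <- cohort[[p]]
    x <- x[!is.na(x)]
    if (length(x) < 2L) {
      stop("degenerate parameter '", p, "': fewer than 2 non-missing values",
           call. = FALSE)
    }
    s <- stats::sd(x)
    if (!is.finite(s) || s <= 0) {
      stop("degenerate parameter '", p, "': zero variance", call. = FALSE)
    }
    c(mean = mean(x), sd = s)
  })
  stats <- do.call(rbind, stats)
  tibble::tibble(
    parameter = weights$parameter,
    mean = stats[, "mean"],
    sd = stats[, "sd"],
    source = "in_sample"
  )
}

#' Read an external standardization reference from a delimited file
#'
#' @param path CSV file with header `parameter,mean,sd`.
#' @return A tibble `parameter, mean, sd, source` with `source = "external"`.
#' @export
read_reference_stats <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("parameter", "mean", "sd")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("reference stats file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(tab$sd)) || any(tab$sd <= 0)) {
    stop("invalid reference: every sd must be finite and > 0", call. = FALSE)
  }
  tab$source <- "external"
  tibble::as_tibble(tab[, c("parameter", "mean", "sd", "source")])
}

#' Compute the modified dietary inflammatory score
#'
#' For each participant the intake of every weight-table parameter is
#' standardized against the reference mean and SD, multiplied by the
#' parameter's inflammatory weight, and summed:
#' \deqn{\mathrm{M\mbox{-}DIS} = \sum_i w_i (x_i - \mu_i)/\sigma_i.}
#' Negative scores classify the diet as anti-inflammatory, non-negative
#' scores as pro-inflammatory (the zero boundary is configurable).
#'
#' @param cohort Data frame with a `participant_id` column and one column
#'   per weight-table parameter (intakes in the parameter's units).
#' @param weights Weight table, see [mdis_weights()].
#' @param ref Standardization reference (`parameter, mean, sd`); `NULL`
#'   (default) estimates in-sample statistics from `cohort`.
#' @param missing Missing-intake policy: `"error"` (default) fails on any
#'   missing parameter value; `"complete_case"` drops incomplete rows and
#'   reports the dropped count via a message.
#' @param boundary Classification of a score of exactly zero:
#'   `"pro_inflammatory"` (default; "positive" read as non-negative) or
#'   `"anti_inflammatory"`.
#' @return A tibble `participant_id, mdis, classification`.
#' @export
compute_mdis <- function(cohort, weights = mdis_weights(), ref = NULL,
                         missing = c("error", "complete_case"),
                         boundary = c("pro_inflammatory", "anti_inflammatory")) {
  missing <- match.arg(missing)
  boundary <- match.arg(boundary)
  weights <- validate_mdis_weights(weights, n_expected = NULL)
  if (!"participant_id" %in% names(cohort)) {
    stop("cohort must have a 'participant_id' column", call. = FALSE)
  }
  missing_cols <- setdiff(weights$parameter, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("missing parameter column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(cohort[, weights$parameter, drop = FALSE])
  incomplete <- rowSums(is.na(x)) > 0L
  if (any(incomplete)) {
    if (missing == "error") {
      stop("missing intake values for ", sum(incomplete),
           " participant(s); set missing = \"complete_case\" to drop them",
           call. = FALSE)
    }
    message("compute_mdis: dropping ", sum(incomplete),
            " incomplete participant(s)")
    cohort <- cohort[!incomplete, , drop = FALSE]
    x <- x[!incomplete, , drop = FALSE]
  }
  if (is.null(ref)) ref <- estimate_reference_stats(cohort, weights)
  idx <- match(weights$parameter, ref$parameter)
  if (anyNA(idx)) {
    stop("reference stats missing parameter(s): ",
         paste(weights$parameter[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  mu <- ref$mean[idx]
  sigma <- ref$sd[idx]
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("invalid reference: sd must be finite and > 0", call. = FALSE)
  }
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sigma, "/")
  score <- as.vector(z %*% as.numeric(weights$weight))
  cls <- if (boundary == "pro_inflammatory") {
    ifelse(score >= 0, "pro_inflammatory", "anti_inflammatory")
  } else {
    ifelse(score > 0, "pro_inflammatory", "anti_inflammatory")
  }
  tibble::tibble(
    participant_id = cohort$participant_id,
    mdis = score,
    classification = cls
  )
}

#' Assign exposure tertiles from a vector of scores
#'
#' Participants are ranked by score (ties broken by participant id, giving a
#' deterministic stable order) and split at indices `ceiling(n/3)` and
#' `ceiling(2n/3)`. Tertile 1 holds the lowest (most anti-inflammatory)
#' scores.
#'
#' @param score Numeric vector of finite scores, length >= 3.
#' @param id Optional participant identifiers used as the tie-break key;
#'   defaults to input position.
#' @return Integer vector of tertile labels in \{1, 2, 3\}, aligned with the
#'   input order.
#' @export
assign_tertiles <- function(score, id = seq_along(score)) {
  if (length(score) < 3L) {
    stop("need at least 3 scores to form tertiles", call. = FALSE)
  }
  if (any(!is.finite(score))) {
    stop("invalid input: all scores must be finite", call. = FALSE)
  }
  if (length(unique(score)) == 1L) {
    stop("degenerate score distribution: all scores identical", call. = FALSE)
  }
  n <- length(score)
  ord <- order(score, id)
  cut1 <- ceiling(n / 3)
  cut2 <- ceiling(2 * n / 3)
  lab <- integer(n)
  lab[ord] <- rep.int(c(1L, 2L, 3L), c(cut1, cut2 - cut1, n - cut2))
  lab
}
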