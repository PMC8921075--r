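# Shared fixtures and independent oracles used across the test files.

# Loop-based scoring oracle: standardize and sum term by term, one
# parameter at a time, independent of the vectorized implementation.
oracle_mdis_row <- function(row, weights, ref) {
  total <- 0
  for (i in seq_len(nrow(weights))) {
    p <- weights$parameter[i]
    j <- which(ref$parameter == p)
    z <- (row[[p]] - ref$mean[j]) / ref$sd[j]
    total <- total + weights$weight[i] * z
  }
  total
}

# Sort-and-slice tertile oracle: stable sort by (score, id), then split
# the sorted index range into three consecutive blocks.
oracle_tertiles <- function(score, id = seq_along(score)) {
  n <- length(score)
  ord <- order(score, id)
  cut1 <- ceiling(n / 3)
  cut2 <- ceiling(2 * n / 3)
  lab <- integer(n)
  lab[ord[seq_len(cut1)]] <- 1L
  lab[ord[seq.int(cut1 + 1L, cut2)]] <- 2L
  lab[ord[seq.int(cut2 + 1L, n)]] <- 3L
  lab
}

# Random nutrient-intake table over the full parameter set.
random_profiles <- function(n, seed) {
  set.seed(seed)
  pars <- mdis_weights()$parameter
  tab <- as.data.frame(
    matrix(exp(rnorm(n * length(pars), 2, 1)), nrow = n,
           dimnames = list(NULL, pars))
  )
  tab$participant_id <- sprintf("p%04d", seq_len(n))
  tibble::as_tibble(tab)
}

# Fully scored synthetic cohort (intakes, M-DIS, tertile, T-scores).
scored_synthetic_cohort <- function(cfg = cohort_config(), seed = NULL) {
  g <- generate_cohort(cfg, seed = seed)
  ch <- g$cohort
  sc <- compute_mdis(ch)
  ch <- dplyr::inner_join(ch, sc, by = "participant_id")
  ch$tertile <- assign_tertiles(ch$mdis, ch$participant_id)
  ch <- score_bone(ch, make_reference_fixture(cfg))
  list(cohort = ch, truth = g$truth, config = cfg)
}

# Cohort realizing given per-tertile (low, normal) counts for one site.
# Scores increase monotonically across the tertile blocks and an explicit
# tertile column is provided for frozen-scope fits with unequal groups.
counts_cohort <- function(site, low, normal) {
  stopifnot(length(low) == 3L, length(normal) == 3L)
  n <- low + normal
  y <- unlist(lapply(1:3, function(k) {
    rep(c(1L, 0L), c(low[k], normal[k]))
  }))
  tibble::tibble(
    participant_id = sprintf("p%05d", seq_len(sum(n))),
    mdis = seq_len(sum(n)),
    tertile = rep(1:3, n),
    !!paste0("low_", site) := y
  )
}

# Published per-tertile low-BMD counts used by the crude-OR checks
# (three skeletal sites of a senior Mediterranean DXA cohort).
published_lowbmd_counts <- function() {
  path <- system.file("extdata", "example_lowbmd_counts.csv",
                      package = "mdisbone")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
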