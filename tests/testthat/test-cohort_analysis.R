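test_that("descriptive table: identical groups give F = 0, p = 1", {
  ch <- tibble::tibble(tertile = rep(1:3, each = 10),
                       x = rep(c(1, 5, 2, 8, 3, 4, 6, 7, 9, 10), 3))
  row <- descriptive_table(ch, variables = "x")
  expect_equal(row$p_value, 1, tolerance = 1e-12)
  expect_match(row$tertile_1, "\\+/-")
})

test_that("descriptive chi-square equals the direct contingency formula", {
  ch <- tibble::tibble(
    tertile = rep(1:2, c(30, 30)),
    g = rep(c("a", "b", "a", "b"), c(10, 20, 20, 10))
  )
  row <- descriptive_table(ch, variables = "g")
  a <- 10; b <- 20; c <- 20; d <- 10; n <- 60
  chi2 <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(unique(row$p_value),
               pchisq(chi2, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("descriptive ANOVA detects a 2-SD group shift almost surely", {
  hits <- vapply(1:200, function(i) {
    set.seed(3000 + i)
    ch <- tibble::tibble(tertile = rep(1:3, each = 50),
                         x = rnorm(150, rep(c(0, 0, 2), each = 50), 1))
    descriptive_table(ch, variables = "x")$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("descriptive table keeps constant variables with NA p", {
  ch <- tibble::tibble(tertile = rep(1:3, each = 5), k = rep(1, 15),
                       f = rep("x", 15))
  tab <- descriptive_table(ch, variables = c("k", "f"))
  expect_equal(nrow(tab), 2L)
  expect_true(all(is.na(tab$p_value)))
})

test_that("crude 2x2 odds ratio: closed form, CI ordering, zero cells", {
  res <- crude_or_2x2(10, 10, 10, 10)
  expect_equal(res$or, 1)
  expect_true(res$ci_low <= res$or && res$or <= res$ci_high)

  res2 <- crude_or_2x2(20, 80, 10, 90)
  expect_equal(res2$or, (20 / 80) / (10 / 90))
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  expect_equal(res2$ci_high, exp(log(res2$or) + 1.959964 * se))

  expect_error(crude_or_2x2(0, 10, 5, 5), "zero cell")
  cor <- crude_or_2x2(0, 10, 5, 5, zero_cell = "haldane")
  expect_equal(cor$or, (0.5 / 10.5) / (5.5 / 5.5))
  expect_error(crude_or_2x2(-1, 10, 5, 5), "non-negative")
})

test_that("covariate-free logistic reproduces the closed-form 2x2 OR", {
  ch <- counts_cohort("tf", low = c(20, 25, 33), normal = c(80, 75, 67))
  fit <- fit_logistic_low_bmd(ch, "tf")
  for (k in 2:3) {
    cf <- crude_or_2x2(
      exposed_low = c(25, 33)[k - 1], exposed_normal = c(75, 67)[k - 1],
      ref_low = 20, ref_normal = 80
    )
    row <- fit[fit$term == paste0("tertile_", k), ]
    expect_equal(row$estimate, cf$or, tolerance = 1e-6)
    expect_equal(row$ci_low, cf$ci_low, tolerance = 1e-6)
    expect_equal(row$ci_high, cf$ci_high, tolerance = 1e-6)
  }
})

test_that("linear tertile model recovers group means exactly", {
  ch <- tibble::tibble(
    participant_id = sprintf("p%03d", 1:30),
    mdis = 1:30,
    bmd_tf = rep(c(1.0, 0.98, 0.96), each = 10)
  )
  fit <- fit_linear_bmd(ch, "tf")
  expect_equal(fit$estimate[fit$term == "tertile_1"], 0)
  expect_equal(fit$estimate[fit$term == "tertile_2"], -0.02)
  expect_equal(fit$estimate[fit$term == "tertile_3"], -0.04)
  expect_equal(fit$n[1], 30L)

  ch$bmd_tf <- 1.1
  fit0 <- fit_linear_bmd(ch, "tf")
  expect_equal(fit0$estimate[-1], c(0, 0))
})

test_that("rank-deficient designs raise a collinearity error naming terms", {
  sc <- scored_synthetic_cohort(cohort_config(n = 120, seed = 30))
  ch <- sc$cohort
  ch$age_copy <- ch$age
  expect_error(fit_linear_bmd(ch, "tf", c("age", "age_copy")),
               "collinear.*age_copy")
})

test_that("logistic fit reports separation instead of silent estimates", {
  ch <- counts_cohort("tf", low = c(5, 6, 20), normal = c(15, 14, 0))
  expect_error(fit_logistic_low_bmd(ch, "tf"), "separation")
})

test_that("ANCOVA without covariates returns raw tertile means", {
  ch <- tibble::tibble(
    participant_id = sprintf("p%03d", 1:30),
    mdis = 1:30,
    bmd_tf = rep(c(1.0, 0.98, 0.96), each = 10) + rep(seq(-0.01, 0.01, length.out = 10), 3)
  )
  res <- ancova_adjusted_means(ch, "tf")
  tert <- assign_tertiles(ch$mdis, ch$participant_id)
  raw <- tapply(ch$bmd_tf, tert, mean)
  expect_equal(res$adjusted_means$adj_mean, as.numeric(raw),
               tolerance = 1e-12)
})

test_that("equal-mean groups give Tukey p close to 1", {
  set.seed(31)
  ch <- tibble::tibble(
    participant_id = sprintf("p%03d", 1:60),
    mdis = 1:60,
    bmd_tf = rep(c(1.0, 1.0, 1.0), each = 20) + rep(rnorm(20, 0, 0.1), 3)
  )
  res <- ancova_adjusted_means(ch, "tf")
  expect_true(all(res$tukey$p_value > 0.99))
})

test_that("Tukey p-values match the studentized-range oracle", {
  sc <- scored_synthetic_cohort(cohort_config(n = 400, seed = 32))
  covs <- c("sex", "age", "bmi")
  res <- ancova_adjusted_means(sc$cohort, "tf", covs)

  df <- sc$cohort
  df$tert <- factor(assign_tertiles(df$mdis, df$participant_id))
  fit <- lm(bmd_tf ~ tert + sex + age + bmi, data = df)
  V <- vcov(fit)
  b <- coef(fit)
  # pairwise contrasts in emmeans order: 1-2, 1-3, 2-3
  est <- c(-b["tert2"], -b["tert3"], b["tert2"] - b["tert3"])
  se <- c(sqrt(V["tert2", "tert2"]), sqrt(V["tert3", "tert3"]),
          sqrt(V["tert2", "tert2"] + V["tert3", "tert3"] -
                 2 * V["tert2", "tert3"]))
  p_oracle <- ptukey(sqrt(2) * abs(est / se), nmeans = 3,
                     df = fit$df.residual, lower.tail = FALSE)
  expect_equal(res$tukey$estimate, unname(est), tolerance = 1e-8)
  expect_equal(res$tukey$p_value, unname(p_oracle), tolerance = 1e-8)
})

test_that("trend p-value is invariant to affine score transforms", {
  sc <- scored_synthetic_cohort(cohort_config(n = 300, seed = 33))
  ch <- sc$cohort
  p1 <- p_for_trend(ch, "bmd_tf", "mdis", c("sex", "age"))
  ch$mdis2 <- 5 - 3 * ch$mdis
  p2 <- p_for_trend(ch, "bmd_tf", "mdis2", c("sex", "age"))
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-9)

  ch$flat <- 1
  expect_error(p_for_trend(ch, "bmd_tf", "flat"), "degenerate exposure")
})

test_that("a strong monotone trend is detected with high power", {
  hits <- vapply(1:100, function(i) {
    set.seed(4000 + i)
    n <- 200
    x <- rnorm(n)
    ch <- tibble::tibble(y = 4 / sqrt(n) * x + rnorm(n), s = x)
    p_for_trend(ch, "y", "s") < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("LR interaction p equals the chi-square tail of its statistic", {
  sc <- scored_synthetic_cohort(cohort_config(n = 400, seed = 34))
  p <- lr_interaction_test(sc$cohort, "low_tf", "mdis", "sex",
                           c("age", "bmi"))
  expect_equal(as.numeric(p),
               pchisq(attr(p, "statistic"), df = attr(p, "df"),
                      lower.tail = FALSE))
  expect_equal(attr(p, "df"), 1L)
  ch <- sc$cohort; ch$sex <- "man"
  expect_error(lr_interaction_test(ch, "low_tf", "mdis", "sex"),
               "constant")
})

test_that("sex-specific slopes differing by 4 SE are detected", {
  hits <- vapply(1:100, function(i) {
    set.seed(5000 + i)
    n <- 300
    x <- rnorm(n)
    sexw <- rep(0:1, length.out = n)
    se_int <- 2 / sqrt(n / 4)
    y <- 0.1 * x + 2 * se_int * x * sexw + rnorm(n)
    ch <- tibble::tibble(y = y, s = x,
                         sex = ifelse(sexw == 1, "woman", "man"))
    lr_interaction_test(ch, "y", "s", "sex") < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("crude and adjusted models agree when covariates are independent", {
  inside <- vapply(1:50, function(i) {
    sc <- scored_synthetic_cohort(cohort_config(n = 600),
                                  seed = 6000 + i)
    crude <- fit_linear_bmd(sc$cohort, "tf")
    adj <- fit_linear_bmd(sc$cohort, "tf", c("smoking", "education",
                                             "center"))
    b_c <- crude$estimate[crude$term == "tertile_3"]
    row <- adj[adj$term == "tertile_3", ]
    se <- (row$ci_high - row$ci_low) / (2 * 1.959964)
    abs(b_c - row$estimate) <= 2 * se
  }, logical(1))
  expect_gte(mean(inside), 0.90)
})

test_that("constant outcome shifts move adjusted means, not effects", {
  sc <- scored_synthetic_cohort(cohort_config(n = 300, seed = 35))
  ch <- sc$cohort
  covs <- c("sex", "age", "bmi")
  base_lin <- fit_linear_bmd(ch, "tf", covs)
  base_am <- ancova_adjusted_means(ch, "tf", covs)
  ch2 <- ch; ch2$bmd_tf <- ch2$bmd_tf + 0.5
  shift_lin <- fit_linear_bmd(ch2, "tf", covs)
  shift_am <- ancova_adjusted_means(ch2, "tf", covs)
  expect_equal(shift_lin$estimate, base_lin$estimate, tolerance = 1e-9)
  expect_equal(shift_lin$p_value, base_lin$p_value, tolerance = 1e-9)
  expect_equal(shift_am$adjusted_means$adj_mean,
               base_am$adjusted_means$adj_mean + 0.5, tolerance = 1e-9)
  expect_equal(shift_am$tukey$p_value, base_am$tukey$p_value,
               tolerance = 1e-9)
})

test_that("all intervals bracket their estimates and p-values are in [0,1]", {
  sc <- scored_synthetic_cohort(cohort_config(n = 500, seed = 36))
  for (site in bmd_sites()) {
    for (covs in list(NULL, c("sex", "age", "bmi", "smoking"))) {
      lin <- fit_linear_bmd(sc$cohort, site, covs)
      lgt <- fit_logistic_low_bmd(sc$cohort, site, covs)
      for (tab in list(lin, lgt)) {
        est <- tab[tab$term != "tertile_1", ]
        expect_true(all(est$ci_low <= est$estimate &
                          est$estimate <= est$ci_high))
        expect_true(all(est$p_value >= 0 & est$p_value <= 1))
      }
    }
  }
})

test_that("identical strata yield identical stratified ORs", {
  sc <- scored_synthetic_cohort(cohort_config(n = 400, seed = 37))
  ch <- sc$cohort
  ch$tertile <- assign_tertiles(ch$mdis, ch$participant_id)
  young <- ch; young$age <- 60
  old <- ch; old$age <- 72
  old$participant_id <- paste0("d", old$participant_id)
  both <- dplyr::bind_rows(young, old)
  res <- stratified_ors(both, "tf",
                        covariates = c("sex", "age", "bmi", "t2d"),
                        tertile_scope = "frozen")
  age_rows <- res[res$stratifier == "age", ]
  expect_equal(age_rows$or[1], age_rows$or[2], tolerance = 1e-6)
})

test_that("degenerate strata are flagged, not dropped", {
  sc <- scored_synthetic_cohort(cohort_config(n = 400, seed = 38))
  ch <- sc$cohort
  ch$low_tf[ch$t2d == 1] <- 0L   # no events among diabetics
  res <- stratified_ors(ch, "tf", covariates = c("sex", "age", "bmi",
                                                 "t2d"))
  t2d_row <- res[res$stratifier == "t2d" & res$stratum == "t2d", ]
  expect_equal(t2d_row$flag, "single outcome class")
  expect_true(is.na(t2d_row$or))
  # the remaining strata are still estimated
  expect_true(sum(is.na(res$or)) < nrow(res))
})
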