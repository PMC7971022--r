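# Descriptives, per-level summaries, mixed model and contrasts.

test_that("asthma severity groups count the criteria beyond diagnosis", {
  roster <- data.frame(
    participant_id = paste0("P", 1:4), site = "Cyprus",
    age_years = c(7, 8, 9, 10), gender = c("M", "F", "M", "F"),
    wheezing = c(TRUE, TRUE, TRUE, FALSE),
    preventive_medication = c(FALSE, FALSE, TRUE, FALSE),
    unscheduled_visits = c(FALSE, FALSE, TRUE, FALSE),
    er_visits = c(FALSE, TRUE, TRUE, FALSE)
  )
  expect_warning(res <- describe_cohort(roster), "rejecting 1")
  expect_equal(res$participants$severity, c(1, 2, 3))  # P4 ineligible
  expect_equal(res$summary$n, 3)
  expect_equal(res$summary$n_severity1, 1)
  expect_equal(res$summary$n_severity2, 1)
  expect_equal(res$summary$n_severity3, 1)
})

test_that("severity group counts match a brute-force tally on a random roster", {
  co <- simulate_cohort(small_cfg(seed = 41, n = 40), intervals = FALSE)
  res <- describe_cohort(co$participants)
  crit <- rowSums(res$participants[, c("wheezing", "preventive_medication",
                                       "unscheduled_visits", "er_visits")])
  expect_equal(res$summary$n_severity1, sum(crit == 1))
  expect_equal(res$summary$n_severity2, sum(crit == 2))
  expect_equal(res$summary$n_severity3, sum(crit >= 3))
  expect_equal(res$summary$age_mean, mean(res$participants$age_years))
  expect_equal(res$summary$pct_male,
               100 * mean(res$participants$gender == "M"))
})

toy_table <- function() {
  # two levels, known values
  data.frame(
    site = "Cyprus",
    level = rep(c(0, 1), each = 6),
    fraction_home = c(0.40, 0.45, 0.42, 0.38, 0.44, 0.41,
                      0.90, 0.85, 0.88, 0.92, 0.87, 0.89),
    total_steps = rep(8000, 12)
  )
}

test_that("ANOVA F equals the hand-computed sum-of-squares oracle", {
  tab <- toy_table()
  lm <- level_means(tab, "fraction_home", site = "Cyprus")
  expect_equal(attr(lm, "anova_F"),
               oracle_anova_F(tab$fraction_home, tab$level))
  expect_equal(lm$mean, tapply(tab$fraction_home, tab$level, mean),
               ignore_attr = TRUE)
  # normal-theory CI bounds
  v0 <- tab$fraction_home[tab$level == 0]
  se0 <- sd(v0) / sqrt(length(v0))
  expect_equal(lm$ci95_low[1], mean(v0) - qnorm(0.975) * se0)
  expect_equal(lm$ci95_high[1], mean(v0) + qnorm(0.975) * se0)
})

test_that("identical observations across levels give capped p-values of 1", {
  tab <- toy_table()
  tab$fraction_home <- 0.5
  lm <- level_means(tab, "fraction_home", site = "Cyprus")
  expect_equal(lm$p_vs_baseline[2], 1)
  expect_equal(lm$p_vs_previous[2], 1)
})

test_that("Bonferroni adjustment multiplies by the number of level pairs and caps at 1", {
  set.seed(55)
  tab <- data.frame(
    site = "Cyprus",
    level = rep(0:3, each = 30),
    fraction_home = rnorm(120, rep(c(0.44, 0.80, 0.90, 0.92), each = 30), 0.05),
    total_steps = 8000
  )
  lm <- level_means(tab, "fraction_home", site = "Cyprus")
  raw <- pairwise.t.test(tab$fraction_home, factor(tab$level),
                         p.adjust.method = "none", pool.sd = TRUE)$p.value
  expect_equal(lm$p_vs_baseline[2], min(1, raw["1", "0"] * 6))
  expect_equal(lm$p_vs_previous[4], min(1, raw["3", "2"] * 6))
})

test_that("per-level means recover the generator's configured truth", {
  co <- simulate_cohort(small_cfg(seed = 61, n = 25, end = "2020-04-26"),
                        intervals = FALSE)
  tab <- truth_table(co)
  lm <- level_means(tab, "fraction_home", site = "Cyprus")
  # weekday/weekend mixture makes the observed mean sit between the
  # configured weekday value and weekday value + weekend delta
  cfg <- co$config
  base <- cfg$sites$Cyprus$baseline_home_fraction
  expect_gt(lm$mean[1], base - 0.02)
  expect_lt(lm$mean[1], base + cfg$weekend_home_delta_baseline)
  lvl3 <- base + cfg$sites$Cyprus$level_home_shift[3]
  expect_lt(abs(lm$mean[4] - lvl3), 0.05)
  expect_true(all(lm$ci95_low <= lm$mean & lm$mean <= lm$ci95_high))
})

test_that("the mixed model collapses to the normal-equations OLS oracle", {
  cfg <- small_cfg(seed = 71, n = 15, end = "2020-04-26")
  cfg$participant_sd_home <- 0
  cfg$participant_sd_steps <- 0
  co <- simulate_cohort(cfg, intervals = FALSE)
  tab <- truth_table(co)
  fit <- fit_mobility_model(tab, "fraction_home", site = "Cyprus")
  # variance component collapses to (numerically) nothing
  expect_lt(fit$varcor["participant"], 0.01 * fit$varcor["residual"])
  X <- model.matrix(fit$fit)   # the fit's own fixed-effect design
  beta_oracle <- oracle_ols(X, tab$fraction_home)
  expect_lt(max(abs(coef(fit)[colnames(X)] - beta_oracle)), 1e-4)
  # explicit OLS path agrees to machine precision
  fo <- fit_mobility_model(tab, "fraction_home", site = "Cyprus",
                           random_intercept = FALSE)
  expect_lt(max(abs(coef(fo)[colnames(X)] - beta_oracle)), 1e-10)
})

test_that("level contrasts are linear in the level coefficients", {
  co <- simulate_cohort(small_cfg(seed = 81, n = 12, end = "2020-04-26"),
                        intervals = FALSE)
  tab <- truth_table(co)
  fit <- fit_mobility_model(tab, "fraction_home", site = "Cyprus")
  ct <- level_contrasts(fit)
  b <- coef(fit)
  expect_equal(ct$estimate[ct$comparison == "level 1 vs baseline"],
               unname(b["level1"]))
  expect_equal(ct$estimate[ct$comparison == "level 3 vs level 2"],
               unname(b["level3"] - b["level2"]))
  # a level against itself: estimate 0, p = 1
  self <- level_contrasts(fit, pairs = list(c(2, 2)))
  expect_equal(self$estimate, 0)
  expect_equal(self$p, 1)
  # capped Bonferroni
  expect_true(all(ct$p_adj <= 1))
  expect_equal(ct$p_adj, pmin(1, ct$p * nrow(ct)))
})

test_that("contrast estimates and SEs match multcomp::glht on the same fit", {
  co <- simulate_cohort(small_cfg(seed = 91, n = 12, end = "2020-04-26"),
                        intervals = FALSE)
  tab <- truth_table(co)
  fit <- fit_mobility_model(tab, "fraction_home", site = "Cyprus")
  ct <- level_contrasts(fit, adjust = "none")
  K <- matrix(0, 2, length(coef(fit)),
              dimnames = list(c("l1", "l3v2"), names(coef(fit))))
  K["l1", "level1"] <- 1
  K["l3v2", "level3"] <- 1; K["l3v2", "level2"] <- -1
  g <- summary(multcomp::glht(fit$fit, linfct = K),
               test = multcomp::adjusted("none"))
  expect_equal(ct$estimate[ct$comparison == "level 1 vs baseline"],
               unname(g$test$coefficients["l1"]), tolerance = 1e-8)
  expect_equal(ct$se[ct$comparison == "level 3 vs level 2"],
               unname(g$test$sigma["l3v2"]), tolerance = 1e-8)
})

test_that("rows with missing covariates are dropped and counted", {
  co <- simulate_cohort(small_cfg(seed = 15, n = 8, end = "2020-03-15"),
                        intervals = FALSE)
  tab <- truth_table(co)
  tab$temp_c[1:5] <- NA
  fit <- fit_mobility_model(tab, "fraction_home", site = "Cyprus")
  expect_equal(fit$n_dropped, 5)
  expect_equal(fit$n_obs, nrow(tab) - 5)
})

test_that("dropping harmonic terms on harmonic-free data barely moves level effects", {
  co <- simulate_cohort(small_cfg(seed = 25, n = 20, end = "2020-04-26"),
                        intervals = FALSE)
  tab <- truth_table(co)
  fit <- fit_mobility_model(tab, "fraction_home", site = "Cyprus")
  alt <- lme4::lmer(fraction_home ~ level + gender + age_years +
                      weekend + temp_c + rh_pct + weekend:level +
                      (1 | participant_id), data = tab, REML = TRUE)
  for (k in paste0("level", 1:3)) {
    expect_lt(abs(coef(fit)[k] - lme4::fixef(alt)[k]), 0.01)
  }
})

test_that("2019 weekly series is flat relative to the 2020 level shifts", {
  cfg <- small_cfg(seed = 35, n = 15, sites = "Cyprus",
                   start = "2020-02-03", end = "2020-04-26")
  cfg$study_windows <- data.frame(
    year = c(2019, 2020),
    start = c("2019-02-03", "2020-02-03"),
    end = c("2019-04-26", "2020-04-26"))
  cfg$sites$Cyprus$dds_days <- c("2019" = 0, "2020" = 0)
  co <- simulate_cohort(cfg, intervals = FALSE)
  ws <- weekly_series(truth_table(co))
  v19 <- var(ws$fraction_home[ws$year == "2019"])
  v20 <- var(ws$fraction_home[ws$year == "2020"])
  expect_lt(v19 * 10, v20)
})
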