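test_that("walking speed is the mean of per-bout ratios", {
  bouts <- data.frame(subject_id = rep("a", 10),
                      distance = rep(10, 10), time = rep(20, 10))
  expect_equal(walking_speed(bouts)$speed, 0.5)

  two <- data.frame(subject_id = c("b", "b"),
                    distance = c(10, 20), time = c(20, 20))
  # mean of ratios (0.75), not ratio of sums (30/40)
  expect_equal(walking_speed(two, min_bouts = 2)$speed, 0.75)

  nine <- data.frame(subject_id = rep("c", 9),
                     distance = rep(5, 9), time = rep(10, 9))
  ws <- walking_speed(nine)
  expect_false(ws$included)

  bad <- data.frame(subject_id = "d", distance = 5, time = 0)
  expect_error(walking_speed(bad), "non-positive")
})

test_that("motor performance averages per-trial rates with the failure cap", {
  one <- data.frame(subject_id = "a", raisins = 12, elapsed = 30,
                    failed = FALSE)
  expect_equal(motor_performance(one)$rate, 0.4)

  two <- data.frame(subject_id = rep("b", 2), raisins = c(12, 12),
                    elapsed = c(40, 24), failed = c(FALSE, FALSE))
  expect_equal(motor_performance(two)$rate, 0.4)

  # failed trial contributes raisins over the 180 s cap; droppable
  mix <- data.frame(subject_id = rep("c", 2), raisins = c(12, 9),
                    elapsed = c(30, 180), failed = c(FALSE, TRUE))
  expect_equal(motor_performance(mix)$rate, mean(c(0.4, 0.05)))
  expect_equal(motor_performance(mix, include_failed = FALSE)$rate, 0.4)
  all_failed <- data.frame(subject_id = "d", raisins = 3, elapsed = 180,
                           failed = TRUE)
  expect_equal(nrow(motor_performance(all_failed, include_failed = FALSE)),
               0)
})

test_that("noiseless regression recovery is exact", {
  set.seed(51)
  n <- 60
  df <- data.frame(
    age = runif(n, 1, 20),
    sex = factor(sample(c("female", "male"), n, TRUE),
                 levels = c("female", "male")),
    rearing = factor(sample(c("mother", "nursery"), n, TRUE),
                     levels = c("mother", "nursery", "unknown")))
  df$speed <- 0.70 - 0.009 * df$age + 0.103 * (df$sex == "male")
  # the exact-fit regime triggers lm's "essentially perfect fit" warning
  suppressWarnings(fit <- fit_age_regression(df, "speed", "age"))
  expect_equal(unname(coef(fit)),
               c(0.70, 0.103, 0, -0.009), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n, n)

  # outcome independent of everything: coefficients near zero, adj R2 can
  # drop below zero
  df$flat <- 0.5 + rnorm(n, 0, 0.01)
  flat <- fit_age_regression(df, "flat", "age")
  expect_lt(max(abs(coef(flat)[-1])), 0.05)
  expect_lt(flat$adj_r_squared, 0.2)
})

test_that("unknown rearing is excluded and collinearity is reported", {
  df <- data.frame(
    age = c(1, 5, 9, 13, 17, 19),
    sex = factor(rep(c("female", "male"), 3),
                 levels = c("female", "male")),
    rearing = factor(c("mother", "nursery", "unknown", "mother",
                       "nursery", "mother"),
                     levels = c("mother", "nursery", "unknown")),
    speed = c(0.7, 0.65, 0.6, 0.58, 0.55, 0.5))
  fit <- fit_age_regression(df, "speed", "age")
  expect_equal(fit$n, 5)

  dup <- df
  dup$age2 <- dup$age
  expect_error({
    dup$sex <- factor("female", levels = c("female", "male"))
    fit_age_regression(dup, "speed", "age")
  }, "collinear|redundant|too few")
})

test_that("balanced two-group ANOVA F equals the squared pooled t", {
  set.seed(52)
  df <- data.frame(
    category = rep(c(-1, 1), each = 12),
    sex = factor("female", levels = c("female", "male")),
    rearing = factor("mother", levels = c("mother", "nursery", "unknown")),
    speed = c(rnorm(12, 0.6, 0.05), rnorm(12, 0.7, 0.05)))
  suppressWarnings(an <- anova_category(df, "speed"))
  tt <- t.test(speed ~ category, data = df, var.equal = TRUE)
  expect_equal(an$factors$F[an$factors$term == "category"],
               unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(nrow(an$posthoc), 1)
  expect_equal(an$posthoc$p_raw, tt$p.value, tolerance = 1e-8)
})

test_that("ANOVA has calibrated nulls and detects huge shifts", {
  set.seed(53)
  pvals <- replicate(40, {
    df <- data.frame(
      category = sample(c(-1, 0, 1), 45, TRUE),
      sex = factor(sample(c("female", "male"), 45, TRUE),
                   levels = c("female", "male")),
      rearing = factor(sample(c("mother", "nursery"), 45, TRUE),
                       levels = c("mother", "nursery", "unknown")),
      speed = rnorm(45, 0.6, 0.1))
    an <- anova_category(df, "speed")
    an$factors$p[an$factors$term == "category"]
  })
  # null p-values should look uniform: mean within 3 SD of 0.5
  expect_lt(abs(mean(pvals) - 0.5), 3 * 0.289 / sqrt(40))

  df <- data.frame(
    category = rep(c(-1, 0, 1), each = 10),
    sex = factor(sample(c("female", "male"), 30, TRUE),
                 levels = c("female", "male")),
    rearing = factor(sample(c("mother", "nursery"), 30, TRUE),
                     levels = c("mother", "nursery", "unknown")),
    speed = rnorm(30, 0.6, 0.05) + rep(c(0, 0, 0.5), each = 10))
  an <- anova_category(df, "speed")
  expect_lt(an$factors$p[an$factors$term == "category"], 1e-6)
  # Bonferroni adjustment never shrinks and is capped at 1
  expect_true(all(an$posthoc$p_bonferroni >= an$posthoc$p_raw))
  expect_true(all(an$posthoc$p_bonferroni <= 1))
})

test_that("delta-age demographics ANOVA separates a shifted geriatric group", {
  set.seed(54)
  co <- simulate_cohort(cohort_spec(n_subjects = 120,
                                    unknown_rearing_count = 0, seed = 55))
  rec <- data.frame(subject_id = co$subject_id,
                    age_group = co$age_group,
                    delta_diff = rnorm(120, 0, 0.8))
  rec$delta_diff[rec$age_group == "geriatric"] <-
    rec$delta_diff[rec$age_group == "geriatric"] - 2
  an <- anova_delta_by_demographics(rec, co, "diff")
  expect_lt(an$factors$p[an$factors$term == "age_group"], 1e-4)
  gmeans <- an$group_stats
  expect_equal(gmeans$level[which.min(gmeans$mean)], "geriatric")
  ph <- an$posthoc
  sig <- ph[(ph$level_a == "geriatric" & ph$level_b == "young_adult") |
              (ph$level_a == "young_adult" & ph$level_b == "geriatric"), ]
  expect_lt(sig$p_bonferroni, 0.01)
  expect_equal(nrow(ph), 6)

  adults <- anova_delta_by_demographics(rec, co, "diff", adults_only = TRUE)
  expect_true(all(adults$group_stats$level %in%
                    c("young_adult", "older_adult")))
})

test_that("chronological and epigenetic age predict a bio-age outcome alike", {
  set.seed(56)
  n <- 129
  df <- data.frame(
    age = runif(n, 1.17, 19.33),
    sex = factor(sample(c("female", "male"), n, TRUE, prob = c(.85, .15)),
                 levels = c("female", "male")),
    rearing = factor(sample(c("mother", "nursery"), n, TRUE),
                     levels = c("mother", "nursery", "unknown")))
  df$epigenetic_age <- df$age + rnorm(n, 0, 1.5)
  df$speed <- 0.70 - 0.009 * df$age + 0.103 * (df$sex == "male") +
    rnorm(n, 0, 0.1)
  chron <- fit_age_regression(df, "speed", "age")
  epi <- fit_age_regression(df, "speed", "epigenetic_age")
  expect_lt(abs(chron$adj_r_squared - epi$adj_r_squared), 0.15)
  expect_lt(epi$coefficients$p[epi$coefficients$term == "epigenetic_age"],
            0.05)
})

test_that("correlation helper matches construction oracles", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, x)$r, 1)
  set.seed(57)
  y <- rnorm(30)
  x2 <- rnorm(30)
  resid_y <- residuals(lm(y ~ x2))
  expect_lt(abs(correlate(x2, resid_y)$r), 1e-10)
  ct <- cor.test(x2, y)
  got <- correlate(x2, y)
  expect_equal(got$r, unname(ct$estimate))
  expect_equal(got$p, ct$p.value)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("speed converts to inches per minute exactly", {
  expect_equal(round(speed_to_inches_per_minute(0.009)), 21)
  expect_equal(speed_to_inches_per_minute(0), 0)
  expect_equal(speed_to_inches_per_minute(1), 2362.206)
  expect_equal(round(speed_to_inches_per_minute(0.010), 1), 23.6)
})
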