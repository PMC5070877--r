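test_that("group summaries average participant-level accuracy and error", {
  sc <- standard_scale()
  trials <- simulate_cohort(
    cohort_config(n_per_group = 4, p_AT_id = 1, p_AT_prod = 1,
                  sigma_mem = 0, lambda_smt = 0),
    sc, seed = 2
  )
  gs <- summarize_groups(score_trials(trials, sc))
  expect_equal(gs$pct_correct_mean, rep(100, 4))
  expect_equal(gs$pct_correct_sd, rep(0, 4))
  expect_equal(gs$mean_error[gs$task == "production"], rep(0, 2),
               tolerance = 1e-9)

  # percentages are 100 * mean correct count / trials per participant
  noisy <- simulate_cohort(cohort_config(n_per_group = 6), sc, seed = 3)
  scored <- score_trials(noisy, sc)
  gs2 <- summarize_groups(scored)
  counts <- participant_counts(scored, NULL, NULL)
  for (g in unique(gs2$group)) {
    cell <- gs2[gs2$group == g & gs2$task == "identification", ]
    ids <- counts$participant_id[counts$group == g]
    expect_equal(cell$pct_correct_mean,
                 mean(100 * counts$n_correct_id[counts$participant_id %in% ids] / 7))
  }
})

test_that("fit_response_line equals the closed-form normal equations", {
  x <- c(71, 80, 90, 101, 113, 127)
  y <- c(75, 78, 95, 99, 120, 121)
  scored <- data.frame(target_bpm = x, response_bpm = y)
  fit <- fit_response_line(scored)
  # normal-equations oracle
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  s2 <- sum(resid^2) / (n - 2)
  slope_se <- sqrt(s2 / sum((x - mean(x))^2))
  intercept_se <- sqrt(s2 * (1 / n + mean(x)^2 / sum((x - mean(x))^2)))
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, intercept, tolerance = 1e-12)
  expect_equal(fit$slope_se, slope_se, tolerance = 1e-12)
  expect_equal(fit$intercept_se, intercept_se, tolerance = 1e-12)
  expect_equal(fit$pearson_r, cor(x, y), tolerance = 1e-12)

  ident <- data.frame(target_bpm = x, response_bpm = x)
  perfect <- fit_response_line(ident)
  expect_equal(perfect$slope, 1, tolerance = 1e-12)
  expect_equal(perfect$intercept, 0, tolerance = 1e-9)
  expect_equal(perfect$pearson_r, 1, tolerance = 1e-12)

  degenerate <- data.frame(target_bpm = rep(100, 5), response_bpm = 1:5)
  expect_warning(bad <- fit_response_line(degenerate), "constant target")
  expect_true(is.na(bad$slope))
})

test_that("the split-plot ANOVA matches the textbook sums-of-squares oracle", {
  d <- data.frame(
    participant_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
    group = rep(c("m", "m", "n", "n"), each = 2),
    task = rep(c("identification", "production"), 4),
    score = c(5, 2, 6, 3, 3, 2, 4, 1)
  )
  res <- mixed_anova_2x2(d)
  oracle <- splitplot_ss_oracle(d)
  tb <- res$table
  for (eff in c("group", "subjects_within_groups", "task", "group_task",
                "task_subjects_within_groups")) {
    expect_equal(tb$ss[tb$effect == eff], oracle[[eff]], tolerance = 1e-9,
                 label = eff)
  }
  expect_equal(sum(tb$ss), res$ss_total, tolerance = 1e-9)
  expect_equal(sum(tb$ss), oracle$total, tolerance = 1e-9)
  # F ratios against the stratum-appropriate error terms
  ms <- tb$ms
  expect_equal(tb$F[tb$effect == "group"],
               ms[tb$effect == "group"] / ms[tb$effect == "subjects_within_groups"],
               tolerance = 1e-12)
  expect_equal(tb$F[tb$effect == "task"],
               ms[tb$effect == "task"] /
                 ms[tb$effect == "task_subjects_within_groups"],
               tolerance = 1e-12)
  # partial eta squared uses the effect's own error term
  expect_equal(tb$partial_eta_sq[tb$effect == "task"],
               oracle$task / (oracle$task + oracle$task_subjects_within_groups),
               tolerance = 1e-9)
})

test_that("the ANOVA is invariant to row order and refuses unbalanced input", {
  sc <- standard_scale()
  trials <- simulate_cohort(cohort_config(n_per_group = 8), sc, seed = 10)
  counts <- participant_counts(score_trials(trials, sc), NULL, NULL)
  long <- rbind(
    data.frame(participant_id = counts$participant_id, group = counts$group,
               task = "identification", score = counts$n_correct_id),
    data.frame(participant_id = counts$participant_id, group = counts$group,
               task = "production", score = counts$n_correct_prod)
  )
  a <- mixed_anova_2x2(long)
  set.seed(1)
  b <- mixed_anova_2x2(long[sample(nrow(long)), ])
  expect_equal(a$table$ss, b$table$ss, tolerance = 1e-9)
  expect_equal(a$table$F, b$table$F, tolerance = 1e-9)

  expect_error(mixed_anova_2x2(long[-1, ]), "unbalanced")
  long$score <- 3
  expect_equal(mixed_anova_2x2(long)$table$F[1:3], rep(0, 3))
})
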