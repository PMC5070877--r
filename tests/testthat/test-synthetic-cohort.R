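test_that("cohort simulation is seed-deterministic", {
  sc <- standard_scale()
  cfg <- cohort_config(n_per_group = 5)
  a <- simulate_cohort(cfg, sc, seed = 77)
  b <- simulate_cohort(cfg, sc, seed = 77)
  expect_identical(a, b)
  c <- simulate_cohort(cfg, sc, seed = 78)
  expect_false(identical(a, c))
  # structure: 7 + 7 trials per participant, targets a permutation per task
  expect_equal(nrow(a), 10 * 14)
  one <- a[a$participant_id == "P001", ]
  expect_setequal(one$target_label[one$task == "identification"], 1:7)
  expect_setequal(one$target_label[one$task == "production"], 1:7)
})

test_that("config validation rejects invalid generative parameters", {
  expect_error(cohort_config(p_AT_id = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(sigma_mem = -0.1), ">= 0")
  expect_error(cohort_config(lambda_smt = 2), "\\[0, 1\\]")
  expect_error(cohort_config(guess_range_bpm = c(233, 23)), "increasing")
})

test_that("the noise-free all-AT cohort scores 7/7 on both tasks", {
  sc <- standard_scale()
  cfg <- cohort_config(n_per_group = 5, p_AT_id = 1, p_AT_prod = 1,
                       sigma_mem = 0, lambda_smt = 0)
  scored <- score_trials(simulate_cohort(cfg, sc, seed = 4), sc)
  counts <- participant_counts(scored, 4, 3)
  expect_true(all(counts$n_correct_id == 7))
  expect_true(all(counts$n_correct_prod == 7))
  expect_true(all(counts$class == "both"))
})

test_that("guessers calibrate to the binomial and log-uniform chance rates", {
  sc <- standard_scale()
  cfg <- cohort_config(n_per_group = 5000, p_AT_id = 0, p_AT_prod = 0)
  scored <- score_trials(simulate_cohort(cfg, sc, seed = 11), sc)
  counts <- participant_counts(scored, 4, 3)
  n <- nrow(counts)

  # identification correct counts follow Binomial(7, 1/7): the above-chance
  # false-positive rate matches the tail at T = 4 within Monte-Carlo error
  p4 <- binomial_tail(7, 1 / 7)$tail[["4"]]
  rate <- mean(counts$n_correct_id >= 4)
  expect_lt(abs(rate - p4), 3 * sqrt(p4 * (1 - p4) / n))
  # and the per-trial correct rate is 1/7
  id_rate <- mean(scored$correct[scored$task == "identification"])
  expect_lt(abs(id_rate - 1 / 7), 3 * sqrt((1 / 7) * (6 / 7) / (7 * n)))

  # production guesses are log-uniform over 23-233 bpm: the per-trial correct
  # rate converges to the analytic range null's p
  u <- uniform_range_null(23, 233, 67, 150.4, 7)
  prod_rate <- mean(scored$correct[scored$task == "production"])
  expect_lt(abs(prod_rate - u$p), 3 * sqrt(u$p * (1 - u$p) / (7 * n)) + 0.002)
})

test_that("tap trains have the expected onsets and recover their tempo", {
  train <- generate_tap_train(120, 10, 0)
  expect_length(train, 21)
  expect_equal(diff(train), rep(0.5, 20), tolerance = 1e-12)
  expect_equal(produced_bpm(train), 120, tolerance = 1e-9)

  # jittered trains recover the generator tempo within 1% on average
  set.seed(33)
  rel_err <- replicate(100, {
    tr <- generate_tap_train(101, 10, 10)
    abs(produced_bpm(tr) - 101) / 101
  })
  expect_lt(mean(rel_err), 0.01)
  expect_error(generate_tap_train(-10), "positive")
  # jitter far larger than the inter-onset interval cannot stay ordered
  expect_error(generate_tap_train(300, 10, 500, seed = 1), "jitter")
})

test_that("generative production parameters are recoverable", {
  sc <- standard_scale()
  exact <- simulate_cohort(
    cohort_config(n_per_group = 10, p_AT_id = 1, p_AT_prod = 1,
                  sigma_mem = 0, lambda_smt = 0), sc, seed = 5)
  rec0 <- recover_parameters(exact, sc)
  expect_equal(rec0$lambda_smt, 0, tolerance = 1e-9)
  expect_equal(rec0$sigma_mem, 0, tolerance = 1e-9)

  cfg <- cohort_config(n_per_group = 100, p_AT_id = 1, p_AT_prod = 1,
                       sigma_mem = 0.05, lambda_smt = 0.2)
  rec <- recover_parameters(simulate_cohort(cfg, sc, seed = 6), sc)
  expect_lt(abs(rec$lambda_smt - 0.2), 0.03)
  expect_lt(abs(rec$sigma_mem - 0.05), 0.03)

  single <- exact[exact$task == "production" & exact$target_label == 4, ]
  expect_error(recover_parameters(single, sc), "degenerate")
})

test_that("the generative model reproduces the serial-position dissociation", {
  sc <- standard_scale()
  # memory noise in the mid range: identification accuracy bows upward
  # (edges beat the centre, one-sided competition at the ends)
  id_cfg <- cohort_config(n_per_group = 300, p_AT_id = 1, p_AT_prod = 0,
                          sigma_mem = 0.10)
  scored_id <- score_trials(simulate_cohort(id_cfg, sc, seed = 8), sc)
  id_counts <- counts_by_position(scored_id)$identification$correct
  expect_gt(bow_index(id_counts), 0)
  expect_gt(id_counts[1], id_counts[4])
  expect_gt(id_counts[7], id_counts[4])

  # central-tendency pull toward the 100-bpm spontaneous tempo: production
  # accuracy peaks at the central (101 bpm) item, an inverted U
  prod_cfg <- cohort_config(n_per_group = 300, p_AT_id = 0, p_AT_prod = 1,
                            sigma_mem = 0.10, lambda_smt = 0.5)
  scored_prod <- score_trials(simulate_cohort(prod_cfg, sc, seed = 9), sc)
  prod_counts <- counts_by_position(scored_prod)$production$correct
  expect_lt(bow_index(prod_counts), 0)
  expect_equal(which.max(prod_counts), 4)
})
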