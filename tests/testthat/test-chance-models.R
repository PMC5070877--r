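test_that("binomial tails match the printed seven-trial guessing table", {
  bt <- binomial_tail(7, 1 / 7)
  expect_equal(unname(bt$tail[1]), 1)
  expect_equal(round(unname(bt$tail[2]), 9), 0.660083323)
  expect_equal(round(unname(bt$tail[3]), 9), 0.263513866)
  expect_equal(round(unname(bt$tail[4]), 9), 0.065229138)
  expect_equal(round(unname(bt$tail[5]), 9), 0.010150047)
  expect_equal(round(unname(bt$tail[6]), 9), 0.000970198)
  # exact rational values for the top of the tail
  expect_equal(unname(bt$tail[7]), 43 / 7^7, tolerance = 1e-12)
  expect_equal(unname(bt$tail[8]), 1 / 7^7, tolerance = 1e-12)
})

test_that("binomial tails agree with exhaustive outcome enumeration", {
  for (p in c(1 / 7, 0.12, 0.05, 0.5, 0.9)) {
    bt <- binomial_tail(7, p)
    expect_equal(unname(bt$tail), enum_binomial_tail(7, p), tolerance = 1e-12)
  }
  # degenerate probabilities
  expect_equal(unname(binomial_tail(7, 0)$tail), c(1, rep(0, 7)))
  expect_equal(unname(binomial_tail(7, 1)$tail), rep(1, 8))
  expect_error(binomial_tail(7, 1.2), "probability")
})

test_that("tails are non-increasing and thresholds monotone in p", {
  set.seed(3)
  last_T <- 1L
  for (p in sort(runif(30))) {
    bt <- binomial_tail(7, p)
    expect_true(all(diff(bt$tail) <= 1e-15))
    T <- select_threshold(7, p)$T
    if (!is.na(T)) {
      expect_gte(T, last_T)
      last_T <- T
    }
  }
})

test_that("the strict threshold rule reproduces the study's choices", {
  expect_identical(select_threshold(7, 1 / 7, 0.05)$T, 4L)
  expect_identical(select_threshold(7, 0.12, 0.05)$T, 3L)
  # under the analytic null's p = .05 the same rule gives T = 2 (tail .044)
  thr <- select_threshold(7, 0.05, 0.05)
  expect_identical(thr$T, 2L)
  expect_equal(round(thr$tail_at_T, 3), 0.044)
  expect_identical(select_threshold(7, 0, 0.05)$T, 1L)
  expect_true(is.na(select_threshold(7, 0.9, 0.05)$T))
})

test_that("the permutation null matches the exact pairwise expectation", {
  sc <- standard_scale()
  set.seed(21)
  n <- 42
  targets <- sc$bpm[sample(1:7, n, replace = TRUE)]
  pool <- 2^runif(n, log2(50), log2(220))
  scored <- data.frame(task = "production", target_bpm = targets,
                       response_bpm = pool)
  # brute-force oracle: every (slot, pooled production) pair
  exact <- mean(outer(targets, pool,
                      function(t, r) abs(12 * log2(r / t)) <= 1 + 1e-9))
  est <- permutation_null(scored, n_cycles = 2000, seed = 9)
  se <- sqrt(exact * (1 - exact) / est$n_assignments)
  expect_lt(abs(est$p_hat - exact), 3 * se + 1e-12)
  expect_equal(est$expected_exact, exact, tolerance = 1e-12)
  expect_equal(est$p_hat, est$n_correct / est$n_assignments)
})

test_that("the permutation null is seed-deterministic and seed-stable", {
  sc <- standard_scale()
  trials <- simulate_cohort(cohort_config(), sc, seed = 500)
  scored <- score_trials(trials, sc)
  a <- permutation_null(scored, n_cycles = 100, seed = 1)
  b <- permutation_null(scored, n_cycles = 100, seed = 1)
  expect_identical(a$n_correct, b$n_correct)
  # two long runs with different seeds agree within pooled Monte-Carlo error
  c1 <- permutation_null(scored, n_cycles = 10000, seed = 1)
  c2 <- permutation_null(scored, n_cycles = 10000, seed = 2)
  p <- (c1$p_hat + c2$p_hat) / 2
  se_pooled <- sqrt(2 * p * (1 - p) / c1$n_assignments)
  expect_lt(abs(c1$p_hat - c2$p_hat), 3 * se_pooled)
})

test_that("permutation null handles the degenerate all-in-band pool", {
  scored <- data.frame(task = "production",
                       target_bpm = rep(100, 10),
                       response_bpm = rep(100, 10))
  expect_equal(permutation_null(scored, n_cycles = 5, seed = 1)$p_hat, 1)
  empty <- data.frame(task = "identification", target_bpm = 1, response_bpm = 1)
  expect_error(permutation_null(empty, seed = 1), "no usable")
})

test_that("the log-uniform range null reproduces the analytic probabilities", {
  u <- uniform_range_null(23, 233, 67, 150.4, 7)
  expect_equal(round(u$range_semitempi, 1), 40.1)
  expect_equal(round(u$band_semitempi, 1), 14)
  expect_equal(round(u$p1, 2), 0.35)
  expect_equal(round(u$p, 2), 0.05)
  # band equal to range: every draw lands in the band
  full <- uniform_range_null(23, 233, 23, 233, 7)
  expect_equal(full$p1, 1)
  expect_equal(full$p, 1 / 7)
  expect_error(uniform_range_null(23, 233, 10, 150.4), "inside the range")
})

test_that("the range null's p1 matches a log-uniform Monte-Carlo oracle", {
  set.seed(12)
  draws <- 2^runif(1e5, log2(23), log2(233))
  frac <- mean(draws >= 67 & draws <= 150.4)
  u <- uniform_range_null(23, 233, 67, 150.4, 7)
  se <- sqrt(u$p1 * (1 - u$p1) / 1e5)
  expect_lt(abs(frac - u$p1), 3 * se)
})

test_that("quadrant classification partitions every cohort", {
  expect_identical(as.character(classify_participant(4, 3)), "both")
  expect_identical(as.character(classify_participant(7, 0)),
                   "identification_only")
  expect_identical(as.character(classify_participant(0, 7)),
                   "production_only")
  expect_identical(as.character(classify_participant(3, 2)), "chance")
  set.seed(4)
  id <- sample(0:7, 200, replace = TRUE)
  prod <- sample(0:7, 200, replace = TRUE)
  cls <- classify_participant(id, prod)
  expect_equal(sum(table(cls)), 200)  # exactly one class each
  expect_false(anyNA(cls))
})
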