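# Chance-performance null models: binomial tails, above-chance thresholds,
# a permutation null for production, an analytic log-uniform range null, and
# the quadrant classification of participants.

#' Upper-tail probabilities of the binomial distribution
#'
#' For a participant guessing on each of `n` trials with per-trial success
#' probability `p`, computes the vector `P(X >= k)` for k = 0..n. With the
#' seven-alternative identification task (`n = 7`, `p = 1/7`),
#' `P(X >= 4) = 0.010150047`.
#'
#' @param n number of trials (>= 1).
#' @param p per-trial success probability, in `[0, 1]`.
#' @return An object of class `"binomial_tail"`: list with `n`, `p` and
#'   `tail` (named numeric vector of length `n + 1`, `tail[k + 1] = P(X >= k)`).
#' @examples
#' binomial_tail(7, 1/7)$tail
#' @export
binomial_tail <- function(n, p) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != as.integer(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]", call. = FALSE)
  }
  k <- 0:n
  tail <- stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
  names(tail) <- k
  structure(list(n = as.integer(n), p = p, tail = tail),
            class = "binomial_tail")
}

#' @export
print.binomial_tail <- function(x, ...) {
  cat(sprintf("Binomial upper tail, n = %d trials, p = %.6g per trial\n",
              x$n, x$p))
  print(data.frame(k = 0:x$n, `P(X>=k)` = unname(x$tail),
                   check.names = FALSE), row.names = FALSE)
  invisible(x)
}

#' Smallest above-chance threshold under a binomial null
#'
#' The above-chance criterion is the smallest count `T` of correct responses
#' such that the probability of reaching at least `T` by guessing is strictly
#' below `alpha`. With 7 trials this gives `T = 4` at `p = 1/7`
#' (identification) and `T = 3` at `p = 0.12` (the permutation estimate for
#' production).
#'
#' @inheritParams binomial_tail
#' @param alpha significance level in (0, 1), default 0.05.
#' @return List with `T` (the threshold, or `NA` if no count of correct
#'   responses is improbable enough), `alpha`, `tail_at_T`, and the full
#'   `tail` vector.
#' @examples
#' select_threshold(7, 1/7)$T   # 4
#' select_threshold(7, 0.12)$T  # 3
#' @export
select_threshold <- function(n, p, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  bt <- binomial_tail(n, p)
  hit <- which(bt$tail < alpha)
  if (!length(hit)) {
    return(list(T = NA_integer_, alpha = alpha, tail_at_T = NA_real_,
                tail = bt$tail, attainable = FALSE))
  }
  T <- as.integer(names(bt$tail)[hit[1L]])
  list(T = T, alpha = alpha, tail_at_T = unname(bt$tail[hit[1L]]),
       tail = bt$tail, attainable = TRUE)
}

#' Permutation null for the production task
#'
#' Estimates the probability that a produced tempo is "correct" by chance by
#' repeatedly permuting the pool of all produced bpm values across the trial
#' slots (an unrestricted uniform permutation, fixed points allowed) and
#' scoring each reassigned production against the slot's target with the
#' +/- `band` semitempo criterion. The estimate pools all cycles:
#' `p_hat = n_correct / (n_cycles * pool size)`.
#'
#' @param scored data frame of scored production trials (see
#'   [score_trials()]); needs columns `task`, `target_bpm` and `response_bpm`.
#'   Rows of other tasks or with missing productions are ignored.
#' @param n_cycles number of permutation cycles (default 100).
#' @param seed integer RNG seed (required; the estimate is deterministic
#'   given the seed).
#' @param band correctness half-width in semitempi (default 1).
#' @return An object of class `"permutation_null"`: list with `p_hat`,
#'   `n_correct`, `n_assignments`, `n_cycles`, `seed`, and `expected_exact`,
#'   the closed-form expectation of `p_hat` (the mean of the pairwise
#'   correctness matrix, since a uniform permutation puts each pooled
#'   production in each slot with probability 1/N).
#' @export
permutation_null <- function(scored, n_cycles = 100, seed, band = 1) {
  stopifnot(is.data.frame(scored))
  seed <- check_seed(seed)
  if (!is.numeric(n_cycles) || n_cycles < 1) {
    stop("`n_cycles` must be >= 1", call. = FALSE)
  }
  use <- scored$task == "production" & !is.na(scored$response_bpm)
  pool <- scored$response_bpm[use]
  targets <- scored$target_bpm[use]
  n <- length(pool)
  if (n == 0L) stop("no usable production responses", call. = FALSE)

  # Pairwise log distances once; each cycle is then a single indexing pass.
  lp <- 12 * log2(pool)
  lt <- 12 * log2(targets)
  n_correct <- with_seed(seed, {
    total <- 0L
    for (cycle in seq_len(n_cycles)) {
      perm <- sample.int(n)
      total <- total + sum(abs(lp[perm] - lt) <= band + .band_tol)
    }
    total
  })
  # exact expectation over all (slot, production) pairs
  cmat <- abs(outer(lt, lp, "-")) <= band + .band_tol
  structure(
    list(
      p_hat = n_correct / (n_cycles * n),
      n_correct = n_correct,
      n_assignments = n_cycles * n,
      n_cycles = n_cycles,
      seed = seed,
      expected_exact = mean(cmat)
    ),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "Permutation null: %d correct of %d assignments (%d cycles), p_hat = %.4f\n",
    x$n_correct, x$n_assignments, x$n_cycles, x$p_hat
  ))
  cat(sprintf("Exact expectation over all pairs: %.4f\n", x$expected_exact))
  invisible(x)
}

#' Analytic log-uniform range null for the production task
#'
#' Models a guessing producer as drawing a tempo uniformly in log-bpm
#' (semitempo) space over the empirical production range and asks for the
#' probability of a correct response: `p1`, the probability of landing inside
#' the band of potentially correct tempi, times `p2 = 1/n_alternatives`, the
#' probability that a tempo in that band matches the particular target. The
#' defaults are the observed production extremes 23-233 bpm (40.1 semitempi)
#' and the band 67-150.4 bpm (14 semitempi) covering all seven targets with
#' their one-semitempo margins, giving `p1 = 0.35` and `p = 0.05`.
#'
#' @param range_lo,range_hi guessing range endpoints in bpm (defaults 23, 233).
#' @param band_lo,band_hi correct-response band endpoints in bpm
#'   (defaults 67, 150.4).
#' @param n_alternatives number of equally likely targets (default 7).
#' @return List with `p1`, `p2`, `p = p1 * p2`, and the widths of band and
#'   range in semitempi.
#' @examples
#' uniform_range_null()$p  # about 0.05
#' @export
uniform_range_null <- function(range_lo = 23, range_hi = 233,
                               band_lo = 67, band_hi = 150.4,
                               n_alternatives = 7) {
  if (!(range_lo > 0 && range_lo < range_hi)) {
    stop("need 0 < range_lo < range_hi", call. = FALSE)
  }
  if (!(band_lo >= range_lo && band_lo < band_hi && band_hi <= range_hi)) {
    stop("band must lie inside the range", call. = FALSE)
  }
  if (n_alternatives < 1) stop("`n_alternatives` must be >= 1", call. = FALSE)
  band_width <- 12 * log2(band_hi / band_lo)
  range_width <- 12 * log2(range_hi / range_lo)
  p1 <- band_width / range_width
  p2 <- 1 / n_alternatives
  list(
    p1 = p1, p2 = p2, p = p1 * p2,
    band_semitempi = band_width, range_semitempi = range_width,
    range_bpm = c(range_lo, range_hi), band_bpm = c(band_lo, band_hi),
    n_alternatives = n_alternatives
  )
}

#' Classify participants into above-chance quadrants
#'
#' Given each participant's number of correct identifications and correct
#' productions (out of `n_trials` each) and the two thresholds, assigns one
#' of four classes: above chance in `both` tasks, `identification_only`,
#' `production_only`, or `chance` in both. The classes partition the cohort.
#'
#' @param n_correct_id,n_correct_prod integer vectors of correct-response
#'   counts (recycled against each other).
#' @param T_id,T_prod above-chance thresholds (counts, inclusive), defaults
#'   4 and 3.
#' @return Factor with levels `both`, `identification_only`,
#'   `production_only`, `chance`.
#' @examples
#' classify_participant(c(7, 4, 0), c(0, 3, 5))
#' @export
classify_participant <- function(n_correct_id, n_correct_prod,
                                 T_id = 4, T_prod = 3) {
  if (T_id < 1 || T_prod < 1) stop("thresholds must be >= 1", call. = FALSE)
  k <- cbind(n_correct_id, n_correct_prod)  # recycles
  id_above <- k[, 1L] >= T_id
  prod_above <- k[, 2L] >= T_prod
  cls <- ifelse(id_above & prod_above, "both",
         ifelse(id_above, "identification_only",
         ifelse(prod_above, "production_only", "chance")))
  factor(cls, levels = c("both", "identification_only",
                         "production_only", "chance"))
}

#' Per-participant correct counts by task
#'
#' Aggregates a scored trial table to one row per participant with the
#' number of correct identifications and productions, the group label, and
#' (given thresholds) the quadrant class.
#'
#' @param scored a scored trial table (see [score_trials()]).
#' @param T_id,T_prod above-chance thresholds; pass `NULL` to skip
#'   classification.
#' @return Data frame with columns `participant_id`, `group` (if present),
#'   `n_correct_id`, `n_correct_prod` and `class`.
#' @export
participant_counts <- function(scored, T_id = 4, T_prod = 3) {
  stopifnot(is.data.frame(scored))
  ids <- unique(scored$participant_id)
  count_for <- function(task) {
    sub <- scored[scored$task == task & !is.na(scored$correct), ]
    tab <- tapply(sub$correct, factor(sub$participant_id, levels = ids), sum)
    as.integer(ifelse(is.na(tab), 0L, tab))
  }
  out <- data.frame(
    participant_id = ids,
    n_correct_id = count_for("identification"),
    n_correct_prod = count_for("production"),
    stringsAsFactors = FALSE
  )
  if (!is.null(scored$group)) {
    out$group <- scored$group[match(ids, scored$participant_id)]
    out <- out[, c("participant_id", "group", "n_correct_id", "n_correct_prod")]
  }
  if (!is.null(T_id) && !is.null(T_prod)) {
    out$class <- classify_participant(out$n_correct_id, out$n_correct_prod,
                                      T_id, T_prod)
  }
  out
}
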