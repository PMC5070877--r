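# Generative cohort model: simulated identification and production trials
# from noisy-memory rememberers and random guessers, plus tap-train
# generation and recovery of the generative parameters.

#' Configuration for a simulated cohort
#'
#' Bundles and validates the parameters of the generative model. Participants
#' either possess absolute tempo (AT) for a task or guess. AT identification
#' responders remember the target on a log2-bpm scale with additive Gaussian
#' noise `sigma_mem` (scalar-timing/Weber behaviour: constant relative
#' precision is additive noise on a log scale) and answer with the nearest
#' scale tempo. AT producers regress toward the spontaneous motor tempo
#' `smt_bpm` with weight `lambda_smt` (central-tendency bias). Guessers pick
#' a uniform label (identification) or a log-uniform bpm over
#' `guess_range_bpm` (production, mirroring the analytic range null).
#'
#' @param n_per_group participants per group (default 15).
#' @param groups group labels (default `c("musician", "non_musician")`).
#' @param p_AT_id,p_AT_prod probability that a participant possesses AT in
#'   identification / production. Defaults 14/30 and 7/30, the observed
#'   above-chance proportions in a 30-participant cohort.
#' @param sigma_mem memory-noise SD on log2 bpm (semitempi / 12); default 0.10,
#'   mid-range for a clear identification bow.
#' @param lambda_smt central-tendency weight toward `smt_bpm`, in `[0, 1]`;
#'   default 0.35.
#' @param smt_bpm spontaneous motor tempo (default 100 bpm).
#' @param guess_range_bpm production guessing range (default `c(23, 233)`).
#' @param tap_jitter_ms per-tap Gaussian timing SD for generated tap trains
#'   (default 10 ms).
#' @param clip_duration_s trial duration in seconds (default 10).
#' @param n_trials trials per task (default 7: one per scale tempo).
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_per_group = 15,
                          groups = c("musician", "non_musician"),
                          p_AT_id = 14 / 30, p_AT_prod = 7 / 30,
                          sigma_mem = 0.10, lambda_smt = 0.35,
                          smt_bpm = 100, guess_range_bpm = c(23, 233),
                          tap_jitter_ms = 10, clip_duration_s = 10,
                          n_trials = 7) {
  stopifnot(n_per_group >= 1, length(groups) >= 1)
  for (p in list(p_AT_id = p_AT_id, p_AT_prod = p_AT_prod)) {
    if (p < 0 || p > 1) stop("AT probabilities must be in [0, 1]", call. = FALSE)
  }
  if (sigma_mem < 0) stop("`sigma_mem` must be >= 0", call. = FALSE)
  if (lambda_smt < 0 || lambda_smt > 1) {
    stop("`lambda_smt` must be in [0, 1]", call. = FALSE)
  }
  if (smt_bpm <= 0) stop("`smt_bpm` must be positive", call. = FALSE)
  if (length(guess_range_bpm) != 2L || guess_range_bpm[1L] <= 0 ||
      guess_range_bpm[1L] >= guess_range_bpm[2L]) {
    stop("`guess_range_bpm` must be an increasing positive pair", call. = FALSE)
  }
  if (tap_jitter_ms < 0) stop("`tap_jitter_ms` must be >= 0", call. = FALSE)
  structure(
    list(
      n_per_group = as.integer(n_per_group), groups = groups,
      p_AT_id = p_AT_id, p_AT_prod = p_AT_prod,
      sigma_mem = sigma_mem, lambda_smt = lambda_smt, smt_bpm = smt_bpm,
      guess_range_bpm = guess_range_bpm, tap_jitter_ms = tap_jitter_ms,
      clip_duration_s = clip_duration_s, n_trials = as.integer(n_trials)
    ),
    class = "cohort_config"
  )
}

#' Simulate a cohort of identification and production trials
#'
#' Draws a full trial table from the generative model in [cohort_config()]:
#' for each participant, AT status per task, a random target order (a
#' permutation of the scale labels per task), and responses. Identical
#' config and seed give an identical table.
#'
#' @param config a [cohort_config()].
#' @param scale a [tempo_scale()] object.
#' @param seed integer RNG seed (required).
#' @param tap_trains if `TRUE`, production rows also carry a list column
#'   `onsets` of jittered tap trains realising the produced tempo (see
#'   [generate_tap_train()]); `response_bpm` is then left `NA` so scoring
#'   exercises the tap-train path.
#' @return Data frame with columns `participant_id`, `group`, `has_AT_id`,
#'   `has_AT_prod`, `task`, `trial_index`, `target_label`, `response_label`,
#'   `response_bpm` (and optionally `onsets`).
#' @examples
#' sc <- tempo_scale()
#' trials <- simulate_cohort(cohort_config(n_per_group = 2), sc, seed = 1)
#' @export
simulate_cohort <- function(config, scale, seed, tap_trains = FALSE) {
  stopifnot(inherits(config, "cohort_config"), inherits(scale, "tempo_scale"))
  seed <- check_seed(seed)
  n_lab <- length(scale$labels)
  if (config$n_trials > n_lab) {
    stop("more trials per task than scale tempi", call. = FALSE)
  }
  log_scale <- log2(scale$bpm)

  with_seed(seed, {
    n_total <- config$n_per_group * length(config$groups)
    pid <- sprintf("P%03d", seq_len(n_total))
    group <- rep(config$groups, each = config$n_per_group)
    has_id <- stats::runif(n_total) < config$p_AT_id
    has_prod <- stats::runif(n_total) < config$p_AT_prod

    nt <- config$n_trials
    targ_id <- matrix(0L, nt, n_total)
    targ_prod <- matrix(0L, nt, n_total)
    resp_id <- matrix(NA_integer_, nt, n_total)
    prod_bpm <- matrix(NA_real_, nt, n_total)
    lg_lo <- log2(config$guess_range_bpm[1L])
    lg_hi <- log2(config$guess_range_bpm[2L])
    for (i in seq_len(n_total)) {
      targ_id[, i] <- sample.int(n_lab)[seq_len(nt)]
      targ_prod[, i] <- sample.int(n_lab)[seq_len(nt)]

      # identification
      if (has_id[i]) {
        m <- log_scale[targ_id[, i]] + stats::rnorm(nt, 0, config$sigma_mem)
        # nearest scale tempo in log space; first (slower) index wins ties
        resp_id[, i] <- vapply(m, function(v) which.min(abs(log_scale - v)), 1L)
      } else {
        resp_id[, i] <- sample.int(n_lab, nt, replace = TRUE)
      }

      # production
      log_bpm <- if (has_prod[i]) {
        noisy <- log_scale[targ_prod[, i]] + stats::rnorm(nt, 0, config$sigma_mem)
        (1 - config$lambda_smt) * noisy +
          config$lambda_smt * log2(config$smt_bpm)
      } else {
        stats::runif(nt, lg_lo, lg_hi)
      }
      prod_bpm[, i] <- 2^log_bpm
    }
    out <- data.frame(
      participant_id = rep(pid, each = 2L * nt),
      group = rep(group, each = 2L * nt),
      has_AT_id = rep(has_id, each = 2L * nt),
      has_AT_prod = rep(has_prod, each = 2L * nt),
      task = rep(rep(c("identification", "production"), each = nt), n_total),
      trial_index = rep(seq_len(nt), 2L * n_total),
      target_label = as.integer(rbind(targ_id, targ_prod)),
      response_label = as.integer(rbind(resp_id, matrix(NA_integer_, nt, n_total))),
      response_bpm = as.numeric(rbind(matrix(NA_real_, nt, n_total), prod_bpm)),
      stringsAsFactors = FALSE
    )

    if (tap_trains) {
      onsets <- vector("list", nrow(out))
      prod_rows <- which(out$task == "production")
      for (j in prod_rows) {
        onsets[[j]] <- generate_tap_train(
          out$response_bpm[j], config$clip_duration_s, config$tap_jitter_ms
        )
      }
      out$onsets <- onsets
      out$response_bpm[prod_rows] <- NA_real_
    }
    out
  })
}

#' Generate a (jittered) tap-onset train at a given tempo
#'
#' Produces onset times at multiples of the inter-onset interval that fall
#' within the clip duration (the first tap at t = 0), each perturbed by
#' independent Gaussian timing noise. Jitter large enough to reorder onsets
#' is resampled; if strict ordering cannot be achieved the function errors.
#'
#' @param bpm positive tempo.
#' @param clip_duration_s clip length in seconds (default 10).
#' @param tap_jitter_ms Gaussian SD of each onset's timing error, in
#'   milliseconds (default 0).
#' @param seed optional integer seed for a reproducible train in isolation;
#'   inside [simulate_cohort()] the cohort seed governs.
#' @return Numeric vector of strictly increasing onset times in seconds;
#'   a noiseless train at 120 bpm in a 10-s clip has 21 onsets 0.5 s apart.
#' @export
generate_tap_train <- function(bpm, clip_duration_s = 10, tap_jitter_ms = 0,
                               seed = NULL) {
  if (!is.finite(bpm) || bpm <= 0) stop("`bpm` must be positive", call. = FALSE)
  if (clip_duration_s <= 0) stop("duration must be positive", call. = FALSE)
  ioi <- 60 / bpm
  grid <- seq(0, clip_duration_s + 1e-9, by = ioi)
  if (tap_jitter_ms == 0) return(grid)
  with_seed(seed, {
    onsets <- NULL
    for (attempt in 1:100) {
      cand <- grid + stats::rnorm(length(grid), 0, tap_jitter_ms / 1000)
      if (all(diff(cand) > 0)) {
        onsets <- cand
        break
      }
    }
    if (is.null(onsets)) {
      stop("tap jitter too large to keep onsets strictly increasing",
           call. = FALSE)
    }
    onsets
  })
}

#' Recover generative production parameters from a simulated table
#'
#' Given production trials generated by the AT production model (noisy log
#' memory with central-tendency weight `lambda_smt` toward the spontaneous
#' tempo), estimates `lambda_smt` as one minus the OLS slope of produced
#' log2 bpm on target log2 bpm, and `sigma_mem` as the residual standard
#' deviation rescaled by the slope.
#'
#' @param trials data frame of production rows with `target_label` and
#'   `response_bpm` (e.g. an AT-only [simulate_cohort()] output).
#' @param scale the [tempo_scale()] used for generation.
#' @return List with `lambda_smt`, `sigma_mem`, `slope`, `n`.
#' @export
recover_parameters <- function(trials, scale) {
  stopifnot(is.data.frame(trials), inherits(scale, "tempo_scale"))
  sub <- trials[trials$task == "production" & !is.na(trials$response_bpm), ]
  x <- log2(scale$bpm[sub$target_label])
  y <- log2(sub$response_bpm)
  if (length(unique(x)) < 2L) {
    stop("degenerate input: need at least two distinct targets", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  resid_sd <- sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  lambda <- 1 - slope
  sigma <- if (slope > 0) resid_sd / slope else NA_real_
  list(lambda_smt = lambda, sigma_mem = sigma, slope = slope, n = length(y))
}
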