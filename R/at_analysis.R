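# Top-level analysis: scores a trial table and assembles the chance models,
# classification, serial-position and group-level results into one object.

#' Absolute-tempo analysis of a trial table
#'
#' Runs the full analysis on a table of identification and production trials:
#' scoring in semitempo units, the identification binomial threshold, the
#' production thresholds from both the permutation null and the analytic
#' log-uniform range null, per-participant quadrant classification,
#' serial-position counts with the central-versus-other contrast and bow
#' index, group summaries, target-response regressions, and (when both tasks
#' and two groups are present) the 2x2 split-plot ANOVA on correct counts.
#'
#' The production threshold used for classification defaults to the
#' permutation-derived value (`T_prod = 3` in the reference design); both
#' null models' raw thresholds are always reported so the choice is visible.
#' Thresholds can be overridden.
#'
#' @param trials trial table (see [score_trials()] for columns), or an
#'   already-scored table.
#' @param scale a [tempo_scale()]; default the standard seven-tempo scale.
#' @param alpha significance level for above-chance thresholds (default 0.05).
#' @param n_cycles permutation cycles for the production null (default 100).
#' @param seed integer seed for the permutation null (required).
#' @param band correctness half-width in semitempi (default 1).
#' @param T_id,T_prod optional threshold overrides (counts out of the 7
#'   trials); `NULL` selects them from the null models (`T_id` from the
#'   1/`n_labels` binomial, `T_prod` from the permutation estimate).
#' @param range_null arguments for [uniform_range_null()] as a list, or
#'   `NULL` to derive the guessing range from the observed production
#'   extremes and the band from the slowest/fastest rounded targets with
#'   their one-semitempo margins.
#' @return An object of class `"at_analysis"`: list with `scored`, `scale`,
#'   `thresholds` (identification tail and T; production permutation and
#'   range nulls with their implied thresholds; the `T_id`, `T_prod` used),
#'   `participants` (counts + quadrant class), `class_counts`,
#'   `serial_position` (per task: counts, contrast, bow index),
#'   `group_summary`, `regressions`, `anova`, `config` (the resolved
#'   parameters, for reproducibility).
#' @examples
#' sc <- tempo_scale()
#' trials <- simulate_cohort(cohort_config(n_per_group = 5), sc, seed = 7)
#' fit <- at_analysis(trials, sc, seed = 7)
#' print(fit)
#' @export
at_analysis <- function(trials, scale = tempo_scale(), alpha = 0.05,
                        n_cycles = 100, seed, band = 1,
                        T_id = NULL, T_prod = NULL, range_null = NULL) {
  seed <- check_seed(seed)
  scored <- if (is.null(trials$correct)) {
    score_trials(trials, scale, band = band)
  } else {
    trials
  }
  n_trials <- max(table(scored$participant_id, scored$task))
  n_lab <- length(scale$labels)

  # identification null: uniform guessing over the labels
  thr_id <- select_threshold(n_trials, 1 / n_lab, alpha)

  # production nulls
  has_prod <- any(scored$task == "production" & !is.na(scored$response_bpm))
  perm <- thr_perm <- rng <- thr_rng <- NULL
  if (has_prod) {
    perm <- permutation_null(scored, n_cycles = n_cycles, seed = seed,
                             band = band)
    thr_perm <- select_threshold(n_trials, perm$p_hat, alpha)
    if (is.null(range_null)) {
      prod_bpm <- scored$response_bpm[scored$task == "production"]
      prod_bpm <- prod_bpm[!is.na(prod_bpm)]
      mult <- 2^(band / 12)
      range_null <- list(
        range_lo = min(prod_bpm), range_hi = max(prod_bpm),
        band_lo = round_half_up(min(scale$bpm_rounded) / mult, 1),
        band_hi = round_half_up(max(scale$bpm_rounded) * mult, 1),
        n_alternatives = n_lab
      )
      # guessing range must contain the correctness band
      range_null$range_lo <- min(range_null$range_lo, range_null$band_lo)
      range_null$range_hi <- max(range_null$range_hi, range_null$band_hi)
    }
    rng <- do.call(uniform_range_null, range_null)
    thr_rng <- select_threshold(n_trials, rng$p, alpha)
  }

  T_id_use <- if (!is.null(T_id)) T_id else thr_id$T
  T_prod_use <- if (!is.null(T_prod)) {
    T_prod
  } else if (!is.null(thr_perm)) {
    thr_perm$T
  } else {
    NA_integer_
  }

  participants <- participant_counts(scored, T_id_use, T_prod_use)
  class_counts <- table(participants$class)

  sp <- counts_by_position(scored, n_labels = n_lab)
  serial <- lapply(sp, function(el) {
    list(
      counts = el$correct,
      n_per_position = el$n_per_position,
      contrast = central_contrast(el$correct, el$n_per_position),
      bow = bow_index(el$correct)
    )
  })

  group_summary <- if (!is.null(scored$group)) summarize_groups(scored) else NULL

  regressions <- NULL
  if (!is.null(scored$group)) {
    cells <- unique(scored[, c("group", "task")])
    regressions <- lapply(seq_len(nrow(cells)), function(i) {
      fit <- tryCatch(
        fit_response_line(scored, cells$group[i], cells$task[i], scale = scale),
        error = function(e) NULL
      )
      c(list(group = cells$group[i], task = cells$task[i]),
        fit[c("slope", "intercept", "slope_se", "intercept_se",
              "pearson_r", "n")])
    })
  }

  anova <- NULL
  if (!is.null(scored$group) &&
      length(unique(scored$group)) == 2L &&
      all(c("identification", "production") %in% scored$task)) {
    long <- rbind(
      data.frame(participant_id = participants$participant_id,
                 group = participants$group, task = "identification",
                 score = participants$n_correct_id),
      data.frame(participant_id = participants$participant_id,
                 group = participants$group, task = "production",
                 score = participants$n_correct_prod)
    )
    anova <- tryCatch(mixed_anova_2x2(long), error = function(e) NULL)
  }

  structure(
    list(
      scored = scored,
      scale = scale,
      thresholds = list(
        identification = thr_id,
        production_permutation = thr_perm,
        production_range = thr_rng,
        permutation = perm,
        range_null = rng,
        T_id = T_id_use,
        T_prod = T_prod_use
      ),
      participants = participants,
      class_counts = class_counts,
      serial_position = serial,
      group_summary = group_summary,
      regressions = regressions,
      anova = anova,
      config = list(alpha = alpha, n_cycles = n_cycles, seed = seed,
                    band = band, n_trials = n_trials,
                    T_id_override = T_id, T_prod_override = T_prod)
    ),
    class = "at_analysis"
  )
}

#' @export
print.at_analysis <- function(x, ...) {
  cat("Absolute-tempo analysis\n")
  cat(sprintf("  %d participants, %d scored trials\n",
              nrow(x$participants), sum(!is.na(x$scored$correct))))
  cat(sprintf("  thresholds: T_id = %s, T_prod = %s (alpha = %g)\n",
              x$thresholds$T_id, x$thresholds$T_prod, x$config$alpha))
  if (!is.null(x$thresholds$permutation)) {
    cat(sprintf("  permutation null p_hat = %.3f; range null p = %.3f\n",
                x$thresholds$permutation$p_hat, x$thresholds$range_null$p))
  }
  cat("  classification: ",
      paste(sprintf("%s %d", names(x$class_counts), x$class_counts),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.at_analysis <- function(object, ...) {
  print(object)
  if (!is.null(object$group_summary)) {
    cat("\nGroup summaries (percent correct; mean error in semitempi):\n")
    gs <- object$group_summary
    gs$pct_correct_mean <- round(gs$pct_correct_mean, 1)
    gs$pct_correct_sd <- round(gs$pct_correct_sd, 1)
    gs$mean_error <- round(gs$mean_error, 2)
    gs$mean_error_sd <- round(gs$mean_error_sd, 2)
    print(gs, row.names = FALSE)
  }
  for (tk in names(object$serial_position)) {
    el <- object$serial_position[[tk]]
    cat(sprintf("\nSerial position, %s: counts %s | chi2(1) = %.2f, phi = %.2f, bow %s\n",
                tk, paste(el$counts, collapse = " "),
                el$contrast$chi_sq, el$contrast$phi,
                if (is.na(el$bow)) "NA" else if (el$bow > 0) "U" else "inverted U"))
  }
  if (!is.null(object$anova)) {
    cat("\n")
    print(object$anova)
  }
  invisible(object)
}

#' Plot an absolute-tempo analysis
#'
#' Three base-graphics panels: response versus target tempo on log axes,
#' the per-participant quadrant plot with the above-chance thresholds, and
#' the serial-position accuracy curves for both tasks.
#'
#' @param x an [at_analysis()] object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.at_analysis <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  sc <- x$scored
  sc$resp_plot <- sc$response_bpm
  idf <- sc$task == "identification" & is.na(sc$resp_plot) &
    !is.na(sc$response_label)
  sc$resp_plot[idf] <- x$scale$bpm[sc$response_label[idf]]
  ok <- !is.na(sc$resp_plot)
  graphics::plot(sc$target_bpm[ok], sc$resp_plot[ok], log = "xy",
                 col = ifelse(sc$task[ok] == "identification", 1, 2),
                 xlab = "target bpm", ylab = "response bpm",
                 main = "responses", ...)
  graphics::abline(0, 1, lty = 2)

  p <- x$participants
  graphics::plot(jitter(p$n_correct_id, 0.4), jitter(p$n_correct_prod, 0.4),
                 xlim = c(0, x$config$n_trials), ylim = c(0, x$config$n_trials),
                 xlab = "correct identifications", ylab = "correct productions",
                 main = "quadrants")
  graphics::abline(v = x$thresholds$T_id - 0.5,
                   h = x$thresholds$T_prod - 0.5, lty = 3)

  tasks <- names(x$serial_position)
  counts <- lapply(x$serial_position, `[[`, "counts")
  graphics::matplot(seq_along(counts[[1L]]), do.call(cbind, counts),
                    type = "b", pch = 1:2, lty = 1, col = 1:2,
                    xlab = "position in learning set", ylab = "correct",
                    main = "serial position")
  graphics::legend("top", legend = tasks, col = 1:2, pch = 1:2, bty = "n")
  invisible(x)
}
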