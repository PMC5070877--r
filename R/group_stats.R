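# Group-level summaries: percent-correct and mean-error tables, target vs
# response regression, and the 2x2 split-plot (mixed) ANOVA.

#' Group x task summary of accuracy and error
#'
#' For every group x task cell, computes each participant's percent correct
#' (100 x correct trials / trials) and mean signed error in semitempi, then
#' the mean and standard deviation of both across participants.
#'
#' @param scored a scored trial table (see [score_trials()]) with `group`.
#' @return Data frame with one row per group x task: `n_participants`,
#'   `pct_correct_mean`, `pct_correct_sd`, `mean_error`, `mean_error_sd`.
#'   Cells with no data are absent.
#' @export
summarize_groups <- function(scored) {
  stopifnot(is.data.frame(scored))
  if (is.null(scored$group)) stop("scored table lacks `group`", call. = FALSE)
  use <- scored[!is.na(scored$correct), ]
  cells <- unique(use[, c("group", "task")])
  cells <- cells[order(cells$group, cells$task), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- use[use$group == cells$group[i] & use$task == cells$task[i], ]
    pct <- tapply(sub$correct, sub$participant_id,
                  function(z) 100 * mean(z))
    err <- tapply(sub$error_semitempi, sub$participant_id, mean)
    data.frame(
      group = cells$group[i], task = cells$task[i],
      n_participants = length(pct),
      pct_correct_mean = mean(pct), pct_correct_sd = stats::sd(pct),
      mean_error = mean(err, na.rm = TRUE),
      mean_error_sd = stats::sd(err, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Ordinary least-squares fit of response tempo on target tempo
#'
#' Fits `response_bpm ~ target_bpm` by OLS for one group x task cell (or for
#' all rows if `group`/`task` are omitted) and reports slope and intercept
#' with their standard errors plus the Pearson correlation. For
#' identification rows, the response tempo is the scale tempo of the
#' response label (supply a scored table carrying `response_bpm`, or a
#' `scale` from which it is filled).
#'
#' @param scored scored trial table with `target_bpm` and `response_bpm`.
#' @param group,task optional filters.
#' @param scale optional [tempo_scale()]; when given, identification rows
#'   with missing `response_bpm` are assigned their response label's tempo.
#' @return List with `slope`, `intercept`, `slope_se`, `intercept_se`,
#'   `pearson_r`, `n`, and the underlying `lm` fit. A degenerate input
#'   (constant target) returns `NA` coefficients with a warning.
#' @export
fit_response_line <- function(scored, group = NULL, task = NULL, scale = NULL) {
  stopifnot(is.data.frame(scored))
  sub <- scored
  if (!is.null(group)) sub <- sub[sub$group == group, ]
  if (!is.null(task)) sub <- sub[sub$task == task, ]
  if (!is.null(scale)) {
    fill <- sub$task == "identification" & is.na(sub$response_bpm) &
      !is.na(sub$response_label)
    sub$response_bpm[fill] <- scale$bpm[sub$response_label[fill]]
  }
  sub <- sub[!is.na(sub$response_bpm) & !is.na(sub$target_bpm), ]
  if (nrow(sub) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(sub$target_bpm) == 0) {
    warning("constant target tempo: slope undefined", call. = FALSE)
    return(list(slope = NA_real_, intercept = NA_real_, slope_se = NA_real_,
                intercept_se = NA_real_, pearson_r = NA_real_, n = nrow(sub),
                fit = NULL))
  }
  fit <- stats::lm(response_bpm ~ target_bpm, data = sub)
  cf <- summary(fit)$coefficients
  list(
    slope = cf["target_bpm", "Estimate"],
    intercept = cf["(Intercept)", "Estimate"],
    slope_se = cf["target_bpm", "Std. Error"],
    intercept_se = cf["(Intercept)", "Std. Error"],
    pearson_r = stats::cor(sub$target_bpm, sub$response_bpm),
    n = nrow(sub),
    fit = fit
  )
}

#' Two-by-two split-plot (mixed) ANOVA
#'
#' Analyses per-participant scores in a balanced design with one
#' between-participants factor (two groups) and one within-participants
#' factor (two tasks): the classic split-plot decomposition where the group
#' effect is tested against participants-within-groups and the task and
#' interaction effects against the task x participants-within-groups
#' residual, each on (1, n - 2) degrees of freedom for n participants.
#' Partial eta squared uses each effect's own error term. Normality
#' (Shapiro-Wilk on cell-centred scores) and homoskedasticity (Bartlett on
#' group variances of the participant means) diagnostics are reported
#' descriptively.
#'
#' @param counts data frame with one row per participant x task:
#'   `participant_id`, `group` (two levels), `task` (two levels), `score`
#'   (e.g. number of correct responses out of 7).
#' @return An object of class `"mixed_anova"`: list with the sums-of-squares
#'   `table` (SS, df, MS, F, p, partial eta squared per row), `ss_total`, and
#'   `diagnostics`. Unbalanced inputs are refused.
#' @export
mixed_anova_2x2 <- function(counts) {
  stopifnot(is.data.frame(counts))
  need <- c("participant_id", "group", "task", "score")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop("counts table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d <- counts
  d$group <- factor(d$group)
  d$task <- factor(d$task)
  d$participant_id <- factor(d$participant_id)
  if (nlevels(d$group) != 2L || nlevels(d$task) != 2L) {
    stop("need exactly two groups and two tasks", call. = FALSE)
  }
  tab <- table(d$participant_id, d$task)
  if (any(tab != 1L)) {
    stop("unbalanced design: every participant needs exactly one score per task",
         call. = FALSE)
  }
  per_group <- table(unique(d[, c("participant_id", "group")])$group)
  if (length(unique(per_group)) != 1L) {
    stop("unbalanced design: groups differ in size", call. = FALSE)
  }

  fit <- stats::aov(score ~ group * task + Error(participant_id / task),
                    data = d)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: participant_id"]][[1L]])
  within <- as.data.frame(sm[["Error: participant_id:task"]][[1L]])
  rn_b <- trimws(rownames(between))
  rn_w <- trimws(rownames(within))

  ss <- c(
    group = between[rn_b == "group", "Sum Sq"],
    subjects_within_groups = between[rn_b == "Residuals", "Sum Sq"],
    task = within[rn_w == "task", "Sum Sq"],
    group_task = within[rn_w == "group:task", "Sum Sq"],
    task_subjects_within_groups = within[rn_w == "Residuals", "Sum Sq"]
  )
  df <- c(
    group = between[rn_b == "group", "Df"],
    subjects_within_groups = between[rn_b == "Residuals", "Df"],
    task = within[rn_w == "task", "Df"],
    group_task = within[rn_w == "group:task", "Df"],
    task_subjects_within_groups = within[rn_w == "Residuals", "Df"]
  )
  ms <- ss / df
  # a null effect on a degenerate (zero-variance) error term is F = 0, not NaN
  ss_zero <- 1e-12 * max(sum(ss), 1)
  f_of <- function(eff, err) {
    if (ss[eff] <= ss_zero) 0 else ms[eff] / ms[err]
  }
  p_of <- function(eff, err) {
    stats::pf(f_of(eff, err), df[eff], df[err], lower.tail = FALSE)
  }
  eta_of <- function(eff, err) ss[eff] / (ss[eff] + ss[err])
  eff <- c("group", "task", "group_task")
  err <- c("subjects_within_groups", "task_subjects_within_groups",
           "task_subjects_within_groups")
  table_out <- data.frame(
    effect = c(eff, "subjects_within_groups", "task_subjects_within_groups"),
    ss = unname(c(ss[eff], ss["subjects_within_groups"],
                  ss["task_subjects_within_groups"])),
    df = unname(c(df[eff], df["subjects_within_groups"],
                  df["task_subjects_within_groups"])),
    ms = unname(c(ms[eff], ms["subjects_within_groups"],
                  ms["task_subjects_within_groups"])),
    F = c(unname(mapply(f_of, eff, err)), NA, NA),
    df_error = c(unname(df[err]), NA, NA),
    p = c(unname(mapply(p_of, eff, err)), NA, NA),
    partial_eta_sq = c(unname(mapply(eta_of, eff, err)), NA, NA),
    stringsAsFactors = FALSE
  )

  grand <- mean(d$score)
  participant_means <- tapply(d$score, d$participant_id, mean)
  pgroup <- unique(d[, c("participant_id", "group")])
  gm <- pgroup$group[match(names(participant_means), pgroup$participant_id)]
  diagnostics <- list(
    shapiro = tryCatch({
      cell_mean <- stats::ave(d$score, d$group, d$task)
      stats::shapiro.test(d$score - cell_mean)
    }, error = function(e) NULL),
    bartlett = tryCatch(
      stats::bartlett.test(as.numeric(participant_means), gm),
      error = function(e) NULL
    )
  )
  structure(
    list(table = table_out, ss_total = sum((d$score - grand)^2),
         diagnostics = diagnostics, n_participants = nlevels(d$participant_id)),
    class = "mixed_anova"
  )
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Split-plot 2x2 ANOVA (%d participants)\n", x$n_participants))
  tb <- x$table
  tb$ss <- signif(tb$ss, 6)
  tb$ms <- signif(tb$ms, 6)
  tb$F <- signif(tb$F, 4)
  tb$p <- signif(tb$p, 3)
  tb$partial_eta_sq <- signif(tb$partial_eta_sq, 3)
  print(tb, row.names = FALSE)
  invisible(x)
}
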