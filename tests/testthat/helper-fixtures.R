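# Shared fixtures, built in code.

standard_scale <- function() tempo_scale()

# The per-position correct counts reported for the 30-participant study
# (order slowest to fastest, central position 4).
study_position_counts <- function() {
  list(
    identification = c(19, 15, 12, 7, 12, 16, 21),
    production = c(6, 8, 8, 11, 5, 3, 5),
    n_per_position = 30
  )
}

# A tiny hand-checkable trial table: two participants, both tasks.
tiny_trials <- function() {
  data.frame(
    participant_id = rep(c("a", "b"), each = 4),
    group = rep(c("musician", "non_musician"), each = 4),
    task = rep(c("identification", "identification", "production", "production"), 2),
    trial_index = rep(1:2, 4),
    target_label = c(3, 5, 4, 1, 2, 2, 7, 6),
    response_label = c(3, 4, NA, NA, 2, 6, NA, NA),
    response_bpm = c(NA, NA, 118, 71.5, NA, NA, 80, 135),
    stringsAsFactors = FALSE
  )
}

# Exhaustive binomial upper tail: enumerate all 2^n outcome vectors and sum
# the masses of those with at least k successes. Independent of pbinom.
enum_binomial_tail <- function(n, p) {
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  mass <- apply(outcomes, 1, function(o) prod(ifelse(o == 1, p, 1 - p)))
  k_success <- rowSums(outcomes)
  vapply(0:n, function(k) sum(mass[k_success >= k]), numeric(1))
}

# Textbook split-plot sums of squares for a balanced 2 (group) x 2 (task)
# design with one score per participant x task.
splitplot_ss_oracle <- function(d) {
  grand <- mean(d$score)
  subj <- tapply(d$score, d$participant_id, mean)
  subj_group <- tapply(d$group, d$participant_id, function(g) g[1])
  n_subj <- length(subj)
  n_per_group <- n_subj / 2
  gmean <- tapply(d$score, d$group, mean)
  tmean <- tapply(d$score, d$task, mean)
  cellmean <- tapply(d$score, list(d$group, d$task), mean)

  ss_between <- 2 * sum((subj - grand)^2)
  ss_group <- 2 * n_per_group * sum((gmean - grand)^2)
  ss_subj_within <- ss_between - ss_group
  ss_task <- n_subj * sum((tmean - grand)^2)
  ss_int <- n_per_group * sum(
    (cellmean - outer(gmean, rep(grand, 2)) -
       outer(rep(grand, 2), tmean) + 2 * grand - grand +
       (grand - grand))^2
  )
  # clearer: interaction deviations cell - group - task + grand
  dev <- sweep(sweep(cellmean, 1, gmean), 2, tmean) + grand
  ss_int <- n_per_group * sum(dev^2)
  ss_total <- sum((d$score - grand)^2)
  ss_within_resid <- ss_total - ss_between - ss_task - ss_int
  list(group = ss_group, subjects_within_groups = ss_subj_within,
       task = ss_task, group_task = ss_int,
       task_subjects_within_groups = ss_within_resid, total = ss_total)
}
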