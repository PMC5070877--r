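# Serial-position (bow-effect) analysis: correct counts by ordinal position
# in the learning set and the central-versus-other contingency contrast.

#' Correct responses by serial position
#'
#' Counts correct responses per target label (the target's ordinal position
#' in the slowest-to-fastest learning set), separately for each task present
#' in the table. In absolute-identification tasks accuracy typically bows:
#' the end items are identified best and the central item worst.
#'
#' @param scored a scored trial table (see [score_trials()]).
#' @param n_labels number of scale positions (default 7).
#' @return An object of class `"position_counts"`: a list, one element per
#'   task, each with `correct` (integer vector over positions 1..n_labels),
#'   `n_per_position` (responses observed per position) and `task`. Positions
#'   with no trials get zero counts with a warning.
#' @export
counts_by_position <- function(scored, n_labels = 7) {
  stopifnot(is.data.frame(scored))
  out <- lapply(unique(scored$task), function(tk) {
    sub <- scored[scored$task == tk & !is.na(scored$correct), ]
    pos <- factor(sub$target_label, levels = seq_len(n_labels))
    n_per <- as.integer(table(pos))
    if (any(n_per == 0L)) {
      warning(sprintf("task %s: no trials at position(s) %s", tk,
                      paste(which(n_per == 0L), collapse = ", ")),
              call. = FALSE)
    }
    correct <- as.integer(tapply(sub$correct, pos, sum, default = 0L))
    list(task = tk, correct = correct, n_per_position = n_per)
  })
  names(out) <- unique(scored$task)
  structure(out, class = "position_counts")
}

#' @export
print.position_counts <- function(x, ...) {
  for (el in x) {
    cat(sprintf("%s: correct by position  %s   (n per position: %s)\n",
                el$task, paste(el$correct, collapse = " "),
                paste(unique(el$n_per_position), collapse = "/")))
  }
  invisible(x)
}

#' Central-versus-other contingency contrast
#'
#' Tests whether accuracy at the central scale position differs from the
#' other positions pooled: a 2x2 table of {central, other six} x {correct,
#' incorrect} analysed with the uncorrected Pearson chi-square (df = 1) and
#' the phi effect size, `phi = sqrt(chi_sq / N)` with N the total number of
#' responses in the table. No continuity correction is applied.
#'
#' @param correct integer vector of correct counts per position (length >= 3).
#' @param n_per_position responses per position: a single count or a vector
#'   matching `correct`.
#' @param central index of the central position (default: the middle).
#' @return An object of class `"central_contrast"`: list with the 2x2 `table`
#'   (rows central/other, columns correct/incorrect), `chi_sq`, `df`,
#'   `p_value`, `phi` and `n`. When a margin of the table is zero the
#'   statistic is undefined and returned as `NA` with a warning.
#' @examples
#' central_contrast(c(19, 15, 12, 7, 12, 16, 21), 30)  # chi_sq 8.92, phi .21
#' @export
central_contrast <- function(correct, n_per_position,
                             central = (length(correct) + 1) %/% 2) {
  k <- length(correct)
  if (k < 3) stop("need at least 3 positions", call. = FALSE)
  if (length(n_per_position) == 1L) n_per_position <- rep(n_per_position, k)
  stopifnot(length(n_per_position) == k, all(correct >= 0),
            all(correct <= n_per_position))
  a <- correct[central]
  b <- n_per_position[central] - a
  c <- sum(correct[-central])
  d <- sum(n_per_position[-central]) - c
  tab <- matrix(c(a, c, b, d), nrow = 2,
                dimnames = list(c("central", "other"),
                                c("correct", "incorrect")))
  n <- sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("a margin of the 2x2 table is zero; statistic undefined",
            call. = FALSE)
    return(structure(list(table = tab, chi_sq = NA_real_, df = 1L,
                          p_value = NA_real_, phi = NA_real_, n = n),
                     class = "central_contrast"))
  }
  # the classical asymptotic statistic is intended; silence the small-count
  # approximation note chisq.test would raise on sparse tables
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(
    list(table = tab, chi_sq = unname(ct$statistic), df = 1L,
         p_value = ct$p.value, phi = sqrt(unname(ct$statistic) / n), n = n),
    class = "central_contrast"
  )
}

#' @export
print.central_contrast <- function(x, ...) {
  print(x$table)
  cat(sprintf("chi-square(1) = %.2f, p = %.3g, phi = %.2f (N = %d)\n",
              x$chi_sq, x$p_value, x$phi, x$n))
  invisible(x)
}

#' Bow index: quadratic curvature of a serial-position curve
#'
#' Summarises the shape of a serial-position accuracy curve by its orthogonal
#' quadratic polynomial contrast: positive when the curve is U-shaped (end
#' positions better than the centre, the identification bow), negative for an
#' inverted U (centre best, as when productions gravitate toward the
#' spontaneous motor tempo), zero for a flat or purely linear curve.
#'
#' @param correct numeric vector of correct counts (or rates) per position.
#' @return The signed quadratic contrast coefficient.
#' @examples
#' bow_index(c(19, 15, 12, 7, 12, 16, 21)) > 0   # U-shaped
#' @export
bow_index <- function(correct) {
  k <- length(correct)
  if (k < 3) stop("need at least 3 positions", call. = FALSE)
  quad <- stats::contr.poly(k)[, 2L]
  sum(quad * correct)
}
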