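# Produced-tempo estimation from tap trains and semitempo error scoring.

#' Estimate produced tempo from a train of tap onsets
#'
#' The produced tempo of a tapping trial is estimated from the onset times of
#' the taps after discarding the first and the last tap (which are typically
#' contaminated by reaction time and by the stop signal). With k onsets
#' remaining, the estimate is the mean beat rate over the trimmed window:
#' `60 * (k - 1) / (onset_k - onset_1)` beats per minute, i.e. inter-onset
#' intervals per unit time. On a perfectly periodic train this recovers the
#' generating tempo exactly.
#'
#' @param onsets_s strictly increasing numeric vector of tap-onset times in
#'   seconds; at least 4 onsets are required (trimming must leave at least
#'   one interval).
#' @return Produced tempo in beats per minute.
#' @examples
#' produced_bpm(seq(0, 10, by = 0.5))  # 120
#' @export
produced_bpm <- function(onsets_s) {
  if (!is.numeric(onsets_s) || any(!is.finite(onsets_s))) {
    stop("`onsets_s` must be finite numeric onset times", call. = FALSE)
  }
  if (length(onsets_s) < 4L) {
    stop("need at least 4 onsets to estimate a produced tempo", call. = FALSE)
  }
  if (any(diff(onsets_s) <= 0)) {
    stop("`onsets_s` must be strictly increasing", call. = FALSE)
  }
  trimmed <- onsets_s[-c(1L, length(onsets_s))]
  k <- length(trimmed)
  60 * (k - 1) / (trimmed[k] - trimmed[1L])
}

#' Signed error between two tempi in semitempo units
#'
#' One semitempo is a tempo ratio of 2^(1/12) (about 6%), so the signed error
#' of a response against a target is `12 * log2(response / target)`:
#' positive when the response is faster than the target, 12 for a doubling.
#' A 118-bpm response to a 101-bpm target is an error of 2.7 semitempi.
#'
#' @param response_bpm,target_bpm positive tempi in beats per minute
#'   (vectorised, recycled).
#' @return Signed error in semitempi.
#' @examples
#' semitempo_error(118, 101)  # 2.69...
#' @export
semitempo_error <- function(response_bpm, target_bpm) {
  if (any(!is.finite(response_bpm)) || any(!is.finite(target_bpm)) ||
      any(response_bpm <= 0) || any(target_bpm <= 0)) {
    stop("tempi must be positive", call. = FALSE)
  }
  12 * log2(response_bpm / target_bpm)
}

# Inclusive band check with absolute tolerance on the semitempo value, so a
# response exactly one semitempo off does not flip on representation noise.
.band_tol <- 1e-9

#' Is a produced tempo correct?
#'
#' A production response counts as correct when it falls within one semitempo
#' of the target (a bpm shift of about +/- 6%), the same resolution as one
#' semitone in absolute-pitch studies and half the two-semitempo spacing of
#' adjacent scale tempi. The band is inclusive.
#'
#' @inheritParams semitempo_error
#' @param band half-width of the correctness band in semitempi (default 1).
#' @return Logical vector.
#' @export
is_correct_production <- function(response_bpm, target_bpm, band = 1) {
  abs(semitempo_error(response_bpm, target_bpm)) <= band + .band_tol
}

#' Score a table of identification and production trials
#'
#' Attaches the target tempo, the signed semitempo error and the correctness
#' flag to every trial. Identification responses are label matches: the error
#' is twice the label distance (adjacent scale tempi are two semitempi apart)
#' and a response is correct only when the labels coincide. Production
#' responses are compared in bpm against the unrounded target tempo with the
#' +/- `band` semitempo criterion; rows that carry tap onsets instead of a
#' bpm are first run through [produced_bpm()].
#'
#' @param trials data frame with columns `participant_id`, `group`, `task`
#'   (`"identification"` or `"production"`), `trial_index`, `target_label`
#'   (1..7), and per task `response_label` or `response_bpm`; an optional
#'   list column `onsets` (numeric vectors of onset seconds) or character
#'   column `onsets_file` (paths to one-column CSV/JSON onset files) supplies
#'   raw tap trains for production rows.
#' @param scale a [tempo_scale()] object.
#' @param band correctness half-width in semitempi for production (default 1).
#' @return The input data frame with columns `target_bpm`, `response_bpm`
#'   (filled in for tap trains), `error_semitempi` and `correct` appended.
#'   Rows that cannot be scored (no usable response) get `NA` and are listed
#'   in `attr(, "problems")` rather than aborting the run.
#' @export
score_trials <- function(trials, scale, band = 1) {
  stopifnot(is.data.frame(trials), inherits(scale, "tempo_scale"))
  need <- c("participant_id", "task", "target_label")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n_lab <- length(scale$labels)
  bad_task <- !trials$task %in% c("identification", "production")
  if (any(bad_task)) {
    stop("unknown task values: ",
         paste(unique(trials$task[bad_task]), collapse = ", "), call. = FALSE)
  }
  bad_target <- !(trials$target_label %in% scale$labels)
  if (any(bad_target)) {
    stop("target labels outside 1..", n_lab, call. = FALSE)
  }

  out <- trials
  if (is.null(out$response_label)) out$response_label <- NA_integer_
  if (is.null(out$response_bpm)) out$response_bpm <- NA_real_
  out$target_bpm <- scale$bpm[out$target_label]
  out$error_semitempi <- NA_real_
  out$correct <- NA
  problems <- character(0)

  # fill production bpm from raw tap trains where provided
  needs_bpm <- out$task == "production" & is.na(out$response_bpm)
  for (i in which(needs_bpm)) {
    onsets <- NULL
    if (!is.null(out$onsets) && i <= length(out$onsets)) onsets <- out$onsets[[i]]
    if (is.null(onsets) && !is.null(out$onsets_file) &&
        !is.na(out$onsets_file[i]) && nzchar(out$onsets_file[i])) {
      onsets <- read_tap_train(out$onsets_file[i])
    }
    if (!is.null(onsets)) {
      bpm <- tryCatch(produced_bpm(onsets), error = function(e) {
        problems <<- c(problems, sprintf("row %d: %s", i, conditionMessage(e)))
        NA_real_
      })
      out$response_bpm[i] <- bpm
    }
  }

  id <- out$task == "identification"
  has_lab <- id & !is.na(out$response_label)
  out$error_semitempi[has_lab] <-
    2 * (out$response_label[has_lab] - out$target_label[has_lab])
  out$correct[has_lab] <-
    out$response_label[has_lab] == out$target_label[has_lab]

  prod <- out$task == "production"
  has_bpm <- prod & !is.na(out$response_bpm)
  out$error_semitempi[has_bpm] <-
    semitempo_error(out$response_bpm[has_bpm], out$target_bpm[has_bpm])
  out$correct[has_bpm] <- abs(out$error_semitempi[has_bpm]) <= band + .band_tol

  unscored <- which(is.na(out$correct))
  if (length(unscored)) {
    problems <- c(problems, sprintf("row %d: no usable response", unscored))
  }
  attr(out, "problems") <- problems
  out
}

#' Read a tap train from a one-trial onset file
#'
#' Accepts either a JSON array of onset times or a delimited text file whose
#' first (or `onset_s`-named) column holds onset times in seconds.
#'
#' @param path path to a `.json`, `.csv` or `.tsv` file.
#' @return Numeric vector of onset times in seconds.
#' @export
read_tap_train <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    onsets <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    tab <- utils::read.csv(path, sep = if (grepl("\\.tsv$", path)) "\t" else ",")
    col <- if ("onset_s" %in% names(tab)) "onset_s" else names(tab)[1L]
    onsets <- tab[[col]]
  }
  as.numeric(onsets)
}
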