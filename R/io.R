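# Trial-table I/O and the end-to-end pipeline runner.

.trial_columns <- c("participant_id", "group", "task", "trial_index",
                    "target_label", "response_label", "response_bpm",
                    "onsets_file")

#' Read a trial table from delimited text
#'
#' Reads a comma- or tab-delimited trial table, optionally renaming columns
#' through `column_map` (so spreadsheet exports with other headers — e.g. a
#' converted copy of a study's deposited raw data — can be ingested without
#' editing the file). Rows failing validation (unknown task, label outside
#' 1..`n_labels`, non-positive bpm) are dropped and reported in
#' `attr(, "problems")`; missing mandatory columns are fatal.
#'
#' @param path file path; `.tsv` files are read as tab-separated.
#' @param column_map optional named character vector mapping standard names
#'   to the file's column names, e.g.
#'   `c(participant_id = "subj", response_bpm = "bpm")`.
#' @param n_labels number of scale labels (default 7).
#' @return Data frame with the standard trial columns (missing optional
#'   columns filled with `NA`).
#' @export
read_trials <- function(path, column_map = NULL, n_labels = 7) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(raw)) {
        stop("column map points at missing column: ", src, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  mandatory <- c("participant_id", "task", "target_label")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    stop("missing mandatory columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(.trial_columns, names(raw))) {
    raw[[col]] <- if (col == "response_bpm") NA_real_ else NA
  }
  raw <- raw[, union(.trial_columns, names(raw))]

  problems <- character(0)
  bad <- rep(FALSE, nrow(raw))
  chk <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx)) {
      problems <<- c(problems, sprintf("row %d: %s", idx, msg))
      bad[idx] <<- TRUE
    }
  }
  chk(!raw$task %in% c("identification", "production"), "unknown task")
  chk(is.na(raw$target_label) | !raw$target_label %in% seq_len(n_labels),
      sprintf("target label outside 1..%d", n_labels))
  chk(!is.na(raw$response_label) & !raw$response_label %in% seq_len(n_labels),
      sprintf("response label outside 1..%d", n_labels))
  chk(!is.na(raw$response_bpm) & raw$response_bpm <= 0,
      "non-positive response bpm")
  out <- raw[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "problems") <- problems
  out
}

#' Write a trial table to CSV
#'
#' The inverse of [read_trials()]: bpm values are written at full precision
#' (15 significant digits) so a write-read round trip is lossless.
#'
#' @param trials trial (or scored) data frame; any list column is dropped.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  keep <- !vapply(trials, is.list, logical(1))
  tab <- trials[, keep, drop = FALSE]
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(z) {
    ifelse(is.na(z), NA, formatC(z, digits = 15, format = "g"))
  })
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run the full analysis pipeline from files or a trial table
#'
#' Scores the trials, fits the chance models, classifies participants, runs
#' the serial-position and group analyses, and (optionally) writes a JSON
#' report plus CSV tables. The resolved configuration, including every seed,
#' is echoed into the report so a run can be reproduced exactly.
#'
#' @param trials a trial data frame or a path readable by [read_trials()].
#' @param scale a [tempo_scale()], or a path to a scale JSON file.
#' @param seed integer seed (required; governs the permutation null).
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `scored.csv` and `participants.csv` there.
#' @param ... further arguments to [at_analysis()].
#' @return The [at_analysis()] object, with the report list in
#'   `attr(, "report")`.
#' @export
run_pipeline <- function(trials, scale = tempo_scale(), seed, out_dir = NULL,
                         ...) {
  if (is.character(trials)) trials <- read_trials(trials)
  if (is.character(scale)) scale <- read_scale_json(scale)
  fit <- at_analysis(trials, scale, seed = seed, ...)

  report <- list(
    schema = "tempomem-report/1",
    config = fit$config,
    scale = list(bpm_unrounded = fit$scale$bpm,
                 bpm_rounded = fit$scale$bpm_rounded,
                 ioi_ms = fit$scale$ioi_ms,
                 clip_beats = fit$scale$clip_beats),
    thresholds = list(
      T_id = fit$thresholds$T_id,
      T_prod = fit$thresholds$T_prod,
      identification_tail = unname(fit$thresholds$identification$tail),
      permutation = fit$thresholds$permutation[
        c("p_hat", "n_correct", "n_assignments", "n_cycles", "seed")],
      range_null = fit$thresholds$range_null[
        c("p1", "p2", "p", "band_semitempi", "range_semitempi")]
    ),
    class_counts = as.list(fit$class_counts),
    serial_position = lapply(fit$serial_position, function(el) {
      list(counts = el$counts, chi_sq = el$contrast$chi_sq,
           p_value = el$contrast$p_value, phi = el$contrast$phi,
           bow = el$bow)
    }),
    group_summary = fit$group_summary,
    regressions = fit$regressions,
    anova = if (!is.null(fit$anova)) fit$anova$table else NULL
  )
  attr(fit, "report") <- report

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
    write_trials(fit$scored, file.path(out_dir, "scored.csv"))
    utils::write.csv(fit$participants, file.path(out_dir, "participants.csv"),
                     row.names = FALSE)
  }
  fit
}
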