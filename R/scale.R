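# Logarithmic semitempo series and the seven-step experimental tempo scale.

#' Half-up decimal rounding
#'
#' Rounds to the nearest value at the requested number of decimal digits,
#' with exact halves rounded away from zero ("half-up"). Base R's `round()`
#' uses banker's rounding, which does not reproduce conventional printed
#' tables (e.g. 63.496 must display as 63, 100.79 as 101).
#'
#' @param x numeric vector.
#' @param digits integer, decimal digits to keep (default 0).
#' @return numeric vector, rounded.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))   # 1 2 3
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Build a semitempo series
#'
#' A semitempo series is a geometric sequence of tempi in beats per minute,
#' starting at `base_bpm` and multiplied at each step by 2^(1/12) (about +6%
#' per step) -- the tempo analogue of the equal-tempered semitone. Twelve
#' semitempi double the tempo (one tempo "octave"). The default 37-step
#' series spans three octaves from 40 to 320 bpm.
#'
#' @param base_bpm positive tempo of the first element, beats per minute.
#' @param n_steps number of elements (>= 1); element k (1-based) equals
#'   `base_bpm * 2^((k - 1)/12)`.
#' @return An object of class `"semitempo_series"`: a list with `base_bpm`,
#'   `multiplier` (2^(1/12)), `n_steps`, `bpm` (unrounded values) and
#'   `bpm_rounded` (half-up integer values for display).
#' @examples
#' s <- semitempo_series()
#' s$bpm_rounded[1:12]
#' @seealso [tempo_scale()] to pick the experimental subset.
#' @export
semitempo_series <- function(base_bpm = 40, n_steps = 37) {
  if (!is.numeric(base_bpm) || length(base_bpm) != 1L || !is.finite(base_bpm) ||
      base_bpm <= 0) {
    stop("`base_bpm` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1 ||
      n_steps != as.integer(n_steps)) {
    stop("`n_steps` must be a positive integer", call. = FALSE)
  }
  mult <- 2^(1 / 12)
  bpm <- base_bpm * mult^(seq_len(n_steps) - 1)
  structure(
    list(
      base_bpm = base_bpm,
      multiplier = mult,
      n_steps = as.integer(n_steps),
      bpm = bpm,
      bpm_rounded = as.integer(round_half_up(bpm))
    ),
    class = "semitempo_series"
  )
}

#' @export
print.semitempo_series <- function(x, ...) {
  cat(sprintf(
    "Semitempo series: %d steps from %g bpm, ratio 2^(1/12) per step\n",
    x$n_steps, x$base_bpm
  ))
  cat(paste(x$bpm_rounded, collapse = ", "), "\n")
  invisible(x)
}

#' Select the experimental tempo scale from a semitempo series
#'
#' Picks `count` tempi from a semitempo series, one every `stride` steps
#' starting at (1-based) element `start`, and labels them 1 (slowest) to
#' `count` (fastest). The defaults select seven tempi two semitempi apart
#' across one octave roughly centred on 100 bpm -- displayed as
#' 71, 80, 90, 101, 113, 127, 143 bpm. All downstream computation uses the
#' unrounded bpm; the rounded bpm, the inter-onset intervals (from the
#' rounded bpm, the display convention) and the nominal beat counts of a
#' 10-s clip are carried for presentation.
#'
#' @param series a [semitempo_series()] object (default: the standard
#'   37-step series from 40 bpm).
#' @param start 1-based index into the series of the slowest tempo
#'   (default 11, the 71-bpm element).
#' @param stride step between selected elements, in semitempi (default 2).
#' @param count number of tempi (default 7).
#' @param clip_duration_s duration of a stimulus clip in seconds (default 10).
#' @return An object of class `"tempo_scale"`: a list with `labels` (1..count),
#'   `bpm` (unrounded), `bpm_rounded`, `ioi_ms` (inter-onset interval,
#'   60000/bpm_rounded, 1 decimal), `clip_beats` (see [beats_in_clip()]),
#'   `clip_duration_s`, and the selection parameters.
#' @examples
#' sc <- tempo_scale()
#' sc$bpm_rounded   # 71 80 90 101 113 127 143
#' sc$clip_beats    # 12 13 15 17 19 21 24
#' @export
tempo_scale <- function(series = semitempo_series(), start = 11, stride = 2,
                        count = 7, clip_duration_s = 10) {
  stopifnot(inherits(series, "semitempo_series"))
  if (start < 1 || stride < 1 || count < 1) {
    stop("`start`, `stride` and `count` must be positive", call. = FALSE)
  }
  idx <- start + stride * (seq_len(count) - 1)
  if (max(idx) > series$n_steps) {
    stop(sprintf(
      "selection runs past the series: need element %d of %d",
      max(idx), series$n_steps
    ), call. = FALSE)
  }
  bpm <- series$bpm[idx]
  bpm_rounded <- series$bpm_rounded[idx]
  structure(
    list(
      labels = seq_len(count),
      bpm = bpm,
      bpm_rounded = bpm_rounded,
      ioi_ms = round_half_up(60000 / bpm_rounded, 1),
      clip_beats = beats_in_clip(bpm, clip_duration_s),
      clip_duration_s = clip_duration_s,
      base_bpm = series$base_bpm,
      start = start,
      stride = stride
    ),
    class = "tempo_scale"
  )
}

#' @export
print.tempo_scale <- function(x, ...) {
  cat(sprintf("Experimental tempo scale (%d tempi, %g semitempi apart)\n",
              length(x$labels), x$stride))
  print(data.frame(
    label = x$labels,
    bpm = x$bpm_rounded,
    ioi_ms = x$ioi_ms,
    clip_beats = x$clip_beats
  ), row.names = FALSE)
  invisible(x)
}

#' Convert beats per minute to inter-onset interval
#'
#' @param bpm positive tempo in beats per minute.
#' @return Inter-onset interval in milliseconds, `60000 / bpm`.
#' @examples
#' bpm_to_ioi_ms(120)  # 500
#' @export
bpm_to_ioi_ms <- function(bpm) {
  if (any(!is.finite(bpm)) || any(bpm <= 0)) {
    stop("`bpm` must be positive", call. = FALSE)
  }
  60000 / bpm
}

#' Convert inter-onset interval to beats per minute
#'
#' @param ioi_ms positive inter-onset interval in milliseconds.
#' @return Tempo in beats per minute, `60000 / ioi_ms`.
#' @export
ioi_ms_to_bpm <- function(ioi_ms) {
  if (any(!is.finite(ioi_ms)) || any(ioi_ms <= 0)) {
    stop("`ioi_ms` must be positive", call. = FALSE)
  }
  60000 / ioi_ms
}

#' Nominal number of beats in a clip
#'
#' The number of beats a metronome clip of the given duration contains,
#' rounded half-up to integer: `round(bpm * duration_s / 60)`. For the seven
#' standard scale tempi and 10-s clips this gives 12, 13, 15, 17, 19, 21, 24.
#'
#' @param bpm positive tempo in beats per minute (vectorised).
#' @param duration_s positive clip duration in seconds.
#' @return Integer vector of beat counts.
#' @export
beats_in_clip <- function(bpm, duration_s = 10) {
  if (any(!is.finite(bpm)) || any(bpm <= 0) || duration_s <= 0) {
    stop("`bpm` and `duration_s` must be positive", call. = FALSE)
  }
  as.integer(round_half_up(bpm * duration_s / 60))
}

#' Write a tempo scale to a JSON file
#'
#' @param scale a [tempo_scale()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scale_json <- function(scale, path) {
  stopifnot(inherits(scale, "tempo_scale"))
  doc <- list(
    base_bpm = scale$base_bpm,
    multiplier_exponent_denominator = 12L,
    start = scale$start,
    stride = scale$stride,
    clip_duration_s = scale$clip_duration_s,
    labels = scale$labels,
    bpm_unrounded = scale$bpm,
    bpm_rounded = scale$bpm_rounded,
    ioi_ms = scale$ioi_ms,
    clip_beats = scale$clip_beats
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tempo scale from a JSON file
#'
#' Reconstructs the scale from the stored selection parameters so unrounded
#' values are exact, then checks the stored display values.
#'
#' @param path JSON file written by [write_scale_json()].
#' @return A [tempo_scale()] object.
#' @export
read_scale_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("base_bpm", "start", "stride", "labels", "clip_duration_s")
  if (!all(need %in% names(doc))) {
    stop("not a tempo scale JSON document: missing ",
         paste(setdiff(need, names(doc)), collapse = ", "), call. = FALSE)
  }
  n_steps <- doc$start + doc$stride * (length(doc$labels) - 1)
  sc <- tempo_scale(
    semitempo_series(doc$base_bpm, n_steps),
    start = doc$start, stride = doc$stride, count = length(doc$labels),
    clip_duration_s = doc$clip_duration_s
  )
  if (!is.null(doc$bpm_rounded) &&
      !identical(as.integer(doc$bpm_rounded), sc$bpm_rounded)) {
    stop("stored rounded bpm disagree with the reconstructed scale",
         call. = FALSE)
  }
  sc
}
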