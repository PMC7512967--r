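#' Beat-count sliding-window specification
#'
#' Windows of a fixed number of beats advanced by a fixed step, the scheme
#' used to track fast index dynamics (e.g. the first 150 beats of a task
#' analyzed as 100-beat windows shifted by 10, giving sections 1-100,
#' 11-110, ..., 51-150).
#'
#' @param length_beats Window length L in beats (default 100).
#' @param step_beats Shift S between consecutive windows (default 10).
#' @return A `window_spec` object.
#' @export
window_spec <- function(length_beats = 100, step_beats = 10) {
  length_beats <- as.integer(length_beats)
  step_beats <- as.integer(step_beats)
  if (is.na(length_beats) || length_beats < 1L)
    stop("'length_beats' must be an integer >= 1", call. = FALSE)
  if (is.na(step_beats) || step_beats < 1L)
    stop("'step_beats' must be an integer >= 1", call. = FALSE)
  structure(list(length_beats = length_beats, step_beats = step_beats),
            class = "window_spec")
}

#' Fixed-duration segmentation specification
#'
#' Sections of fixed wall-clock duration (default 5 minutes), defined by
#' cumulative beat time rather than beat count because mean RR — and hence
#' beats per section — differs across conditions.
#'
#' @param seconds Section duration T in seconds (default 300).
#' @param trailing `"drop"` (default) discards a trailing partial section;
#'   `"keep"` retains it.
#' @return A `duration_spec` object.
#' @export
duration_spec <- function(seconds = 300, trailing = c("drop", "keep")) {
  trailing <- match.arg(trailing)
  seconds <- as.numeric(seconds)
  if (length(seconds) != 1L || !is.finite(seconds) || seconds <= 0)
    stop("'seconds' must be a single positive duration", call. = FALSE)
  structure(list(seconds = seconds, trailing = trailing),
            class = "duration_spec")
}

#' Enumerate sliding windows over an RR series
#'
#' Windows start at beat offsets 0, S, 2S, ... and span L beats each, so a
#' series of N beats yields `floor((N - L) / S) + 1` windows. Labels use the
#' 1-based inclusive convention (`"1-100"`, `"11-110"`, ...).
#'
#' @param series An [rr_series()] or numeric vector (ms).
#' @param spec A [window_spec()].
#' @return A `data.frame` with columns `window` (index), `start`, `end`
#'   (1-based inclusive beat indexes) and `label`. If N < L the result has
#'   zero rows and a warning is issued.
#' @export
sliding_windows <- function(series, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  n <- length(rr_values(series))
  L <- spec$length_beats
  S <- spec$step_beats
  if (n < L) {
    warning(sprintf("series has %d beats, shorter than the %d-beat window; no windows emitted",
                    n, L))
    return(data.frame(window = integer(), start = integer(), end = integer(),
                      label = character(), stringsAsFactors = FALSE))
  }
  starts <- seq.int(1L, n - L + 1L, by = S)
  data.frame(window = seq_along(starts),
             start = starts,
             end = starts + L - 1L,
             label = sprintf("%d-%d", starts, starts + L - 1L),
             stringsAsFactors = FALSE)
}

#' Carve an RR series into fixed-duration sections
#'
#' Beat k is assigned to section `floor(t_k / T)` where `t_k` is the
#' cumulative time elapsed before beat k (so the first beat always falls in
#' section 1). With `trailing = "drop"` a final section whose beats do not
#' span the full duration T is discarded.
#'
#' @param series An [rr_series()] or numeric vector (ms).
#' @param spec A [duration_spec()].
#' @return A `data.frame` with columns `segment`, `start`, `end` (beat
#'   indexes), `n_beats`, `t_start_s`, `t_end_s`, `complete`.
#' @export
duration_segments <- function(series, spec = duration_spec()) {
  stopifnot(inherits(spec, "duration_spec"))
  x <- rr_values(series)
  T_s <- spec$seconds
  t_before <- c(0, beat_times(x)[-length(x)])
  seg <- floor(t_before / T_s)
  total <- sum(x) / 1000
  segs <- sort(unique(seg))
  out <- do.call(rbind, lapply(segs, function(s) {
    idx <- which(seg == s)
    data.frame(segment = s + 1L,
               start = idx[1L], end = idx[length(idx)],
               n_beats = length(idx),
               t_start_s = s * T_s,
               t_end_s = min((s + 1) * T_s, total),
               complete = total >= (s + 1) * T_s - 1e-9)
  }))
  if (spec$trailing == "drop") out <- out[out$complete, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-window HRV summary
#'
#' Applies [hrv_summary()] to each sliding window; the Sample Entropy
#' tolerance is resolved from the SDNN of each window itself (set
#' `params$r_mode = "absolute"` to impose a session-level tolerance
#' instead).
#'
#' @inheritParams sliding_windows
#' @param params An [entropy_params()].
#' @return A `data.frame`: one row per window with its label and the
#'   [hrv_summary()] columns.
#' @export
hrv_by_window <- function(series, spec = window_spec(),
                          params = entropy_params()) {
  x <- rr_values(series)
  win <- sliding_windows(x, spec)
  if (nrow(win) == 0L) return(cbind(win, hrv_summary_prototype()))
  cbind(win, do.call(rbind, lapply(seq_len(nrow(win)), function(i)
    hrv_summary(x[win$start[i]:win$end[i]], params))))
}

#' Per-section HRV summary
#'
#' Applies [hrv_summary()] to each fixed-duration section.
#'
#' @inheritParams duration_segments
#' @param params An [entropy_params()].
#' @return A `data.frame`: one row per section.
#' @export
hrv_by_segment <- function(series, spec = duration_spec(),
                           params = entropy_params()) {
  x <- rr_values(series)
  seg <- duration_segments(x, spec)
  if (nrow(seg) == 0L) return(cbind(seg, hrv_summary_prototype()))
  cbind(seg, do.call(rbind, lapply(seq_len(nrow(seg)), function(i)
    hrv_summary(x[seg$start[i]:seg$end[i]], params))))
}

hrv_summary_prototype <- function() {
  data.frame(n_beats = integer(), av_rr_ms = numeric(), sdnn_ms = numeric(),
             sampen = numeric(), r_ms = numeric())
}
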