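#' Artifact-screening rule for RR series
#'
#' Ectopic beats, coughs and motion artifacts show up in an RR recording as
#' abrupt jumps between successive intervals. The screen used here flags a
#' beat when its interval differs from the local level by more than a fixed
#' fraction of that level.
#'
#' Two modes are offered. `"local_mean"` (the default) flags beat i (i >= 2)
#' when `|RR_i - RR_{i-1}| >= coefficient * RR_{i-1}`: the preceding interval
#' serves as the local-level reference. The reference deliberately excludes
#' the tested beat itself — a variant using the mean of the two beats lets a
#' large artifact inflate its own threshold, so a multiplicative spike would
#' escape until its factor exceeds `(2 + c)/(2 - c)` (about 2.08 at c = 0.7),
#' whereas the one-sided reference catches any spike with factor
#' `>= 1 + c` (1.7 at the default). Whether the local level should instead be
#' a running mean over a longer context is a genuinely open choice; only the
#' single-predecessor form is implemented, and it is stated here rather than
#' resolved silently.
#'
#' `"literal"` applies, verbatim, a form of the inequality that circulates in
#' print with a signed difference on the right-hand side
#' (`|RR_i - RR_{i-1}| < c * (RR_i - RR_{i-1}) / 2`): the condition is
#' unsatisfiable whenever the successive difference is nonzero, so this mode
#' flags every beat of any non-constant series. It is retained only to make
#' that behaviour demonstrable.
#'
#' @param mode `"local_mean"` or `"literal"`.
#' @param coefficient Positive dimensionless threshold fraction; default 0.7.
#' @return A `filter_rule` object.
#' @seealso [detect_artifacts()], [is_clean()], [drop_artifacts()]
#' @export
filter_rule <- function(mode = c("local_mean", "literal"), coefficient = 0.7) {
  mode <- match.arg(mode)
  coefficient <- as.numeric(coefficient)
  if (length(coefficient) != 1L || !is.finite(coefficient) || coefficient <= 0)
    stop("'coefficient' must be a single positive number", call. = FALSE)
  structure(list(mode = mode, coefficient = coefficient),
            class = "filter_rule")
}

#' Flag abnormal beats in an RR series
#'
#' Applies a [filter_rule()] to a series and returns a per-beat logical mask
#' (`TRUE` = artifact). The first beat has no predecessor and is never
#' flagged; there is no look-ahead.
#'
#' @param series An [rr_series()] or numeric vector (ms) with at least 2
#'   beats.
#' @param rule A [filter_rule()].
#' @return An `artifact_mask`: logical vector aligned to the series, with
#'   attribute `flagged_count`.
#' @examples
#' detect_artifacts(c(700, 1500, 700))  # spike flagged
#' @export
detect_artifacts <- function(series, rule = filter_rule()) {
  stopifnot(inherits(rule, "filter_rule"))
  x <- rr_values(series)
  n <- length(x)
  if (n < 2L)
    stop("artifact screening needs at least 2 beats", call. = FALSE)
  d <- diff(x)
  flagged <- switch(rule$mode,
    local_mean = abs(d) >= rule$coefficient * x[-n],
    # the printed signed-RHS inequality, exactly as it appears; a zero
    # difference satisfies it at equality, any other difference fails it
    literal = !(abs(d) < rule$coefficient * d / 2 | d == 0)
  )
  mask <- c(FALSE, flagged)
  structure(mask, flagged_count = sum(mask), class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("artifact mask: %d of %d beats flagged\n",
              attr(x, "flagged_count"), length(x)))
  invisible(x)
}

#' Is an RR series free from artifacts?
#'
#' The default analysis policy is whole-sequence: a series with any flagged
#' beat is rejected outright rather than repaired. Beat dropping
#' ([drop_artifacts()]) is an explicit opt-in.
#'
#' @inheritParams detect_artifacts
#' @return `TRUE` iff [detect_artifacts()] flags zero beats.
#' @export
is_clean <- function(series, rule = filter_rule()) {
  attr(detect_artifacts(series, rule), "flagged_count") == 0L
}

#' Remove flagged beats from an RR series
#'
#' @param series An [rr_series()] or numeric vector (ms).
#' @param mask An artifact mask from [detect_artifacts()], aligned to the
#'   series.
#' @return The series with flagged beats removed (metadata preserved).
#' @export
drop_artifacts <- function(series, mask) {
  x <- rr_values(series)
  if (length(mask) != length(x))
    stop("mask length does not match series length", call. = FALSE)
  kept <- x[!as.logical(mask)]
  if (length(kept) == 0L)
    stop("all beats flagged; nothing left to analyze", call. = FALSE)
  rr_series(kept,
            subject = attr(series, "subject"),
            condition = attr(series, "condition"),
            source = attr(series, "source"))
}
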