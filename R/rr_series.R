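#' Construct an RR-interval series
#'
#' An `rr_series` is an ordered vector of inter-beat (RR) intervals in
#' milliseconds, optionally tagged with a subject identifier, an experimental
#' condition, and a provenance string. It is the atomic datum of every
#' analysis in this package.
#'
#' @param values Numeric vector of RR intervals in milliseconds. All values
#'   must be finite and strictly positive; length must be at least 1.
#' @param subject Optional subject label (length-1 character).
#' @param condition Optional condition label (length-1 character).
#' @param source Optional provenance string (e.g. the file of origin).
#' @return An object of class `rr_series`: the numeric vector with metadata
#'   attributes.
#' @examples
#' s <- rr_series(c(700, 710, 695), subject = "s01", condition = "rest")
#' length(s)
#' av_rr(s)
#' @export
rr_series <- function(values, subject = NULL, condition = NULL, source = NULL) {
  values <- as.numeric(values)
  validate_rr_values(values)
  structure(values,
            subject = scalar_label(subject, "subject"),
            condition = scalar_label(condition, "condition"),
            source = scalar_label(source, "source"),
            class = "rr_series")
}

validate_rr_values <- function(values) {
  if (length(values) < 1L)
    stop("an RR series must contain at least one interval", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("RR intervals must all be finite", call. = FALSE)
  if (any(values <= 0))
    stop("RR intervals must be strictly positive (ms); found value <= 0",
         call. = FALSE)
  invisible(values)
}

scalar_label <- function(x, what) {
  if (is.null(x)) return(NULL)
  x <- as.character(x)
  if (length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing label", what),
         call. = FALSE)
  x
}

#' @export
print.rr_series <- function(x, ...) {
  n <- length(x)
  cat(sprintf("RR series: %d beats, %.1f s total", n, sum(x) / 1000))
  meta <- c(subject = attr(x, "subject"), condition = attr(x, "condition"))
  if (length(meta))
    cat(" [", paste(names(meta), meta, sep = "=", collapse = ", "), "]",
        sep = "")
  cat("\n")
  show <- utils::head(unclass(x), 8L)
  cat("  ", paste(format(show, trim = TRUE), collapse = " "),
      if (n > 8L) "..." else "", "\n")
  invisible(x)
}

#' Test for the rr_series class
#' @param x An object.
#' @return `TRUE` if `x` is an `rr_series`.
#' @export
is_rr_series <- function(x) inherits(x, "rr_series")

# Accept either an rr_series or a bare numeric vector; validate and return
# the plain values. Most metric functions funnel through this.
rr_values <- function(x) {
  v <- as.numeric(unclass(x))
  validate_rr_values(v)
  v
}

#' Cumulative beat times
#'
#' Elapsed time, in seconds, at each beat: element k is the sum of the first
#' k RR intervals divided by 1000. Used to carve a recording into
#' fixed-duration (wall-time) sections.
#'
#' @param series An [rr_series()] or numeric vector of RR intervals (ms).
#' @return Numeric vector of strictly increasing times in seconds; the last
#'   element equals `sum(series) / 1000`.
#' @examples
#' beat_times(c(1000, 1000, 1000))  # 1 2 3
#' @export
beat_times <- function(series) {
  cumsum(rr_values(series)) / 1000
}
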