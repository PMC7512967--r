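#' Mean RR interval (av-RR)
#'
#' The arithmetic mean of the RR intervals, in milliseconds; inversely
#' related to heart rate.
#'
#' @param series An [rr_series()] or numeric vector (ms).
#' @return av-RR in ms.
#' @export
av_rr <- function(series) {
  mean(rr_values(series))
}

#' Standard deviation of RR intervals (SDNN)
#'
#' Standard deviation of the (normal-to-normal) RR intervals in milliseconds,
#' with the sample (N - 1) denominator. SDNN both summarizes variability and
#' sets the Sample Entropy tolerance when `r` is expressed as a fraction of
#' SDNN; the denominator convention perturbs that tolerance only at O(1/N)
#' and is fixed here for reproducibility.
#'
#' @param series An [rr_series()] or numeric vector (ms) with at least 2
#'   beats.
#' @return SDNN in ms.
#' @export
sdnn <- function(series) {
  x <- rr_values(series)
  if (length(x) < 2L)
    stop("SDNN needs at least 2 beats", call. = FALSE)
  stats::sd(x)
}

#' Time-domain and entropy summary of an RR series
#'
#' One row of the per-segment indexes used throughout the package: beat
#' count, av-RR, SDNN, Sample Entropy, and the resolved tolerance. Sample
#' Entropy failures (too few beats, zero SDNN, no template matches) are
#' reported as `NA` in the `sampen` column rather than as errors, so that
#' segment-wise tables can carry missingness explicitly.
#'
#' @param series An [rr_series()] or numeric vector (ms).
#' @param params An [entropy_params()].
#' @return A one-row `data.frame` with columns `n_beats`, `av_rr_ms`,
#'   `sdnn_ms`, `sampen`, `r_ms`.
#' @export
hrv_summary <- function(series, params = entropy_params()) {
  x <- rr_values(series)
  n <- length(x)
  sd_ms <- if (n >= 2L) sdnn(x) else NA_real_
  se <- tryCatch(sample_entropy(x, params), error = function(e) NA_real_)
  data.frame(n_beats = n,
             av_rr_ms = av_rr(x),
             sdnn_ms = sd_ms,
             sampen = as.numeric(se),
             r_ms = if (is.null(attr(se, "r"))) NA_real_ else attr(se, "r"))
}
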