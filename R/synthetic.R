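# Seedable RR-series generators. All generators restore the caller's RNG
# state when given an explicit seed, and enforce RR positivity by resampling
# offending draws from the truncated marginal (count recorded in the
# 'n_resampled' attribute).

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  seed <- as.integer(seed)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

enforce_positive <- function(values, mean_rr, sd_rr) {
  bad <- which(values <= 0)
  for (i in bad) {
    repeat {
      v <- stats::rnorm(1, mean_rr, sd_rr)
      if (v > 0) break
    }
    values[i] <- v
  }
  structure(values, n_resampled = length(bad))
}

#' Generate a stationary AR(1) RR series
#'
#' First-order autoregressive intervals around `mean_rr` with marginal
#' standard deviation `sd_rr` (innovation variance scaled by `1 - phi^2`).
#' Larger `phi` makes the series more predictable, hence lower Sample
#' Entropy; `phi = 0` is i.i.d. Gaussian. A serviceable stand-in for resting
#' RR recordings.
#'
#' @param n_beats Number of beats.
#' @param mean_rr Marginal mean (ms); default 800.
#' @param sd_rr Marginal standard deviation (ms); default 50.
#' @param phi Lag-1 autocorrelation, in (-1, 1); default 0.9.
#' @param seed Optional integer seed; when given, the caller's RNG state is
#'   left untouched and the output is bit-reproducible.
#' @return An [rr_series()] (attribute `n_resampled` counts positivity
#'   resamples, normally 0).
#' @export
gen_ar1_rr <- function(n_beats, mean_rr = 800, sd_rr = 50, phi = 0.9,
                       seed = NULL) {
  if (!is.finite(phi) || abs(phi) >= 1)
    stop("'phi' must lie strictly inside (-1, 1)", call. = FALSE)
  if (sd_rr <= 0 || mean_rr <= 0)
    stop("'mean_rr' and 'sd_rr' must be positive", call. = FALSE)
  n_beats <- as.integer(n_beats)
  with_seed(seed, {
    innov_sd <- sd_rr * sqrt(1 - phi^2)
    x0 <- stats::rnorm(1, 0, sd_rr)
    dev <- as.numeric(stats::filter(stats::rnorm(n_beats, 0, innov_sd),
                                    phi, method = "recursive", init = x0))
    vals <- enforce_positive(mean_rr + dev, mean_rr, sd_rr)
    out <- rr_series(vals)
    attr(out, "n_resampled") <- attr(vals, "n_resampled")
    out
  })
}

#' Generate a MIX(p) RR series
#'
#' The classic regularity benchmark for entropy estimators: with probability
#' `1 - p` a beat follows a deterministic sinusoid, with probability `p` it
#' is replaced by i.i.d. uniform noise of matching variance,
#' `RR_j = mean_rr + sd_rr * ((1 - Z_j) sin(2 pi j / period) + Z_j U_j)`
#' with `Z_j ~ Bernoulli(p)` and `U_j` uniform on `(-sqrt(3), sqrt(3))`.
#' `p = 0` is strictly periodic (Sample Entropy 0 at small absolute
#' tolerance); `p = 1` is pure i.i.d. noise; irregularity increases
#' monotonically in `p`.
#'
#' @param n_beats Number of beats.
#' @param p Randomness proportion in `[0, 1]`.
#' @param mean_rr,sd_rr Level and scale in ms.
#' @param period_beats Sinusoid period in beats; default 12.
#' @inheritParams gen_ar1_rr
#' @return An [rr_series()].
#' @export
gen_mix_rr <- function(n_beats, p, mean_rr = 800, sd_rr = 50,
                       period_beats = 12, seed = NULL) {
  if (!is.finite(p) || p < 0 || p > 1)
    stop("'p' must lie in [0, 1]", call. = FALSE)
  n_beats <- as.integer(n_beats)
  with_seed(seed, {
    j <- seq_len(n_beats)
    z <- stats::rbinom(n_beats, 1L, p)
    u <- stats::runif(n_beats, -sqrt(3), sqrt(3))
    s <- sin(2 * pi * j / period_beats)
    vals <- enforce_positive(mean_rr + sd_rr * ((1 - z) * s + z * u),
                             mean_rr, sd_rr)
    out <- rr_series(vals)
    attr(out, "n_resampled") <- attr(vals, "n_resampled")
    out
  })
}

#' Generate an RR series with respiratory sinus arrhythmia
#'
#' A breathing-locked sinusoidal modulation of the instantaneous RR interval
#' plus white noise, evaluated at nominal beat times `j * mean_rr / 1000`.
#' With no noise the series is (near-)periodic: large SDNN
#' (about `amplitude / sqrt(2)`) but Sample Entropy near zero — the pattern
#' that makes SDNN and SampEn complementary rather than redundant.
#'
#' @param n_beats Number of beats.
#' @param mean_rr Baseline RR (ms).
#' @param modulation_amplitude Peak modulation depth (ms); default 50.
#' @param modulation_freq Breathing-like frequency in Hz; default 0.25.
#' @param noise_sd White-noise standard deviation (ms); default 0.
#' @inheritParams gen_ar1_rr
#' @return An [rr_series()].
#' @export
gen_rsa_rr <- function(n_beats, mean_rr = 800, modulation_amplitude = 50,
                       modulation_freq = 0.25, noise_sd = 0, seed = NULL) {
  if (modulation_amplitude < 0 || noise_sd < 0)
    stop("'modulation_amplitude' and 'noise_sd' must be >= 0", call. = FALSE)
  n_beats <- as.integer(n_beats)
  with_seed(seed, {
    t_j <- seq_len(n_beats) * mean_rr / 1000
    vals <- mean_rr + modulation_amplitude * sin(2 * pi * modulation_freq * t_j)
    if (noise_sd > 0) vals <- vals + stats::rnorm(n_beats, 0, noise_sd)
    vals <- enforce_positive(vals, mean_rr, max(noise_sd, 1))
    out <- rr_series(vals)
    attr(out, "n_resampled") <- attr(vals, "n_resampled")
    out
  })
}

#' Inject artifacts into a clean RR series
#'
#' Contaminates a series with a known ground truth, for scoring the artifact
#' screen. `"spike"` multiplies single beats by `factor` (default 1.8, the
#' short end of realistic motion/misdetection excursions). `"ectopic_pair"`
#' replaces a beat with a premature short-long pair at 0.6x and 1.4x the
#' local mean (the mean of the two neighbouring intervals), mimicking an
#' ectopic beat followed by a compensatory pause.
#'
#' @param series An [rr_series()] or numeric vector (ms).
#' @param rate Injection rate per beat, in (0, 0.2). The number of injections
#'   is `round(rate * N)` (at least 1); sites are sampled at least 2 beats
#'   apart and away from the series edges.
#' @param kind `"spike"` or `"ectopic_pair"`.
#' @param factor Spike multiplier, >= 1.7; ignored for pairs.
#' @inheritParams gen_ar1_rr
#' @return A list with `series` (the contaminated [rr_series()]; for pairs it
#'   is longer than the input) and `truth` (logical mask of injected beats,
#'   aligned to the contaminated series).
#' @export
inject_artifacts <- function(series, rate, kind = c("spike", "ectopic_pair"),
                             factor = 1.8, seed = NULL) {
  kind <- match.arg(kind)
  x <- rr_values(series)
  n <- length(x)
  if (!is.finite(rate) || rate <= 0 || rate >= 0.2)
    stop("'rate' must lie in (0, 0.2)", call. = FALSE)
  if (kind == "spike" && factor < 1.7)
    stop("'factor' must be >= 1.7 for detectable spikes", call. = FALSE)
  k <- max(1L, as.integer(round(rate * n)))
  with_seed(seed, {
    pos <- pick_separated(2L:(n - 1L), k)
    if (kind == "spike") {
      out <- x
      out[pos] <- out[pos] * factor
      truth <- logical(n)
      truth[pos] <- TRUE
    } else {
      out <- as.list(x)
      truth <- as.list(logical(n))
      for (p in pos) {
        lm <- (x[p - 1L] + x[p + 1L]) / 2
        out[[p]] <- c(0.6 * lm, 1.4 * lm)
        truth[[p]] <- c(TRUE, TRUE)
      }
      out <- unlist(out)
      truth <- unlist(truth)
    }
    list(series = rr_series(out,
                            subject = attr(series, "subject"),
                            condition = attr(series, "condition")),
         truth = truth)
  })
}

# Sample k sites from candidates with pairwise separation >= 2 beats, so
# injected artifacts do not abut and truth scoring stays unambiguous.
pick_separated <- function(candidates, k) {
  chosen <- integer(0)
  pool <- sample(candidates)
  for (p in pool) {
    if (length(chosen) == k) break
    if (all(abs(chosen - p) >= 2L)) chosen <- c(chosen, p)
  }
  if (length(chosen) < k)
    stop("could not place the requested number of artifacts", call. = FALSE)
  sort(chosen)
}
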