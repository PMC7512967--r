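# Normality-gated comparison workflow. All inference delegates to the
# standard routines (shapiro.test, wilcox.test, t.test, friedman.test,
# cor.test); this layer only routes, extracts the reporting-style statistics
# (T, Z, U), and flags degenerate inputs.

comparison_result <- function(test_name, statistic, z = NA_real_, p_value,
                              n, direction = 0, alpha = 0.05,
                              degenerate = FALSE, note = NULL) {
  structure(list(test_name = test_name, statistic = statistic, z = z,
                 p_value = p_value, n = n, direction = direction,
                 alpha = alpha, significant = isTRUE(p_value < alpha),
                 degenerate = degenerate, note = note),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s%s, p = %s, n = %d%s\n",
              x$test_name, format(x$statistic, digits = 4),
              if (is.finite(x$z)) sprintf(", Z = %.2f", x$z) else "",
              format.pval(x$p_value, digits = 3), x$n,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Choose the parametric or nonparametric branch
#'
#' Shapiro-Wilk normality screen: the nonparametric branch is taken when the
#' normality p-value falls below `alpha`. A constant (zero-variance) sample
#' cannot be tested; it is routed nonparametric with a `degenerate` flag and
#' a warning.
#'
#' @param x Numeric sample (for paired designs, pass the paired
#'   differences — that is what the paired t-test assumes normal).
#' @param alpha Gate level; default 0.05.
#' @return A list with `branch` (`"parametric"`/`"nonparametric"`),
#'   `shapiro_p`, and `degenerate`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3L)
    stop("normality screening needs at least 3 values", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("constant sample: normality untestable, routing nonparametric")
    return(list(branch = "nonparametric", shapiro_p = NA_real_,
                degenerate = TRUE))
  }
  p <- stats::shapiro.test(x)$p.value
  list(branch = if (p < alpha) "nonparametric" else "parametric",
       shapiro_p = p, degenerate = FALSE)
}

# Signed-rank reporting statistics: T = smaller of the two rank sums over
# nonzero differences, Z = |normal approximation| (no continuity
# correction), the style in which matched-pairs results are usually printed.
wilcoxon_T_Z <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  T_plus <- sum(r[d > 0])
  T_minus <- sum(r[d < 0])
  T_stat <- min(T_plus, T_minus)
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  list(T = T_stat, Z = if (sigma > 0) abs(T_plus - mu) / sigma else NA_real_,
       n_nonzero = n)
}

#' Paired two-condition comparison
#'
#' With `method = "auto"`, the paired differences pass through
#' [normality_gate()]: normal-looking differences get a dependent-samples
#' t-test, otherwise the Wilcoxon matched-pairs test. Pairs with a missing
#' value in either member are removed first; `n` reports complete pairs.
#'
#' @param a,b Numeric vectors of equal length (conditions per subject).
#' @param method `"auto"`, `"wilcoxon"`, or `"ttest"`.
#' @param alpha Significance level; default 0.05.
#' @return A `comparison_result` with `test_name`, `statistic` (Wilcoxon T,
#'   the smaller signed-rank sum, or Student t), `z` (normal approximation,
#'   Wilcoxon only), `p_value`, `n`, `direction` (sign of the median
#'   difference a - b), and a `degenerate` flag for all-zero differences.
#' @export
compare_paired <- function(a, b, method = c("auto", "wilcoxon", "ttest"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  d <- a - b
  if (all(d == 0))
    return(comparison_result("wilcoxon_paired", statistic = 0, p_value = 1,
                             n = n, alpha = alpha, degenerate = TRUE,
                             note = "all paired differences are zero"))
  if (method == "auto") {
    if (n < 5L) stop("auto routing needs at least 5 complete pairs",
                     call. = FALSE)
    gate <- normality_gate(d, alpha)
    method <- if (gate$branch == "parametric") "ttest" else "wilcoxon"
  }
  direction <- sign(stats::median(d))
  if (method == "wilcoxon") {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    tz <- wilcoxon_T_Z(d)
    comparison_result("wilcoxon_paired", statistic = tz$T, z = tz$Z,
                      p_value = ht$p.value, n = n, direction = direction,
                      alpha = alpha)
  } else {
    ht <- stats::t.test(a, b, paired = TRUE)
    comparison_result("ttest_paired", statistic = unname(ht$statistic),
                      p_value = ht$p.value, n = n,
                      direction = sign(unname(ht$estimate)), alpha = alpha)
  }
}

#' Independent two-group comparison
#'
#' As [compare_paired()] for unpaired samples: the auto route applies
#' [normality_gate()] to both groups and takes the Mann-Whitney U test
#' unless both look normal, in which case Student's t-test (Welch) is used.
#'
#' @param x,y Numeric samples.
#' @param method `"auto"`, `"mannwhitney"`, or `"ttest"`.
#' @param alpha Significance level.
#' @return A `comparison_result`; for Mann-Whitney the `statistic` is
#'   U = min(U_x, U_y) with its normal-approximation `z`.
#' @export
compare_independent <- function(x, y,
                                method = c("auto", "mannwhitney", "ttest"),
                                alpha = 0.05) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop("each group needs at least 3 values", call. = FALSE)
  if (stats::sd(c(x, y)) == 0)
    return(comparison_result("mannwhitney", statistic = NA_real_,
                             p_value = 1, n = length(x) + length(y),
                             alpha = alpha, degenerate = TRUE,
                             note = "all values identical"))
  if (method == "auto") {
    gx <- normality_gate(x, alpha)
    gy <- normality_gate(y, alpha)
    method <- if (gx$branch == "parametric" && gy$branch == "parametric")
      "ttest" else "mannwhitney"
  }
  direction <- sign(stats::median(x) - stats::median(y))
  if (method == "mannwhitney") {
    ht <- suppressWarnings(stats::wilcox.test(x, y))
    nx <- length(x); ny <- length(y)
    U_x <- unname(ht$statistic)           # wilcox.test's W is U for sample x
    U <- min(U_x, nx * ny - U_x)
    mu <- nx * ny / 2
    sigma <- sqrt(nx * ny * (nx + ny + 1) / 12)
    comparison_result("mannwhitney", statistic = U,
                      z = abs(U_x - mu) / sigma, p_value = ht$p.value,
                      n = nx + ny, direction = direction, alpha = alpha)
  } else {
    ht <- stats::t.test(x, y)
    comparison_result("ttest_independent",
                      statistic = unname(ht$statistic),
                      p_value = ht$p.value, n = length(x) + length(y),
                      direction = direction, alpha = alpha)
  }
}

#' Friedman test for repeated-measures dynamics
#'
#' Nonparametric test of whether an index changes across consecutive
#' timepoints measured on the same subjects.
#'
#' @param mat Numeric matrix, subjects in rows, timepoints in columns; at
#'   least 3 of each, no missing cells (filter to complete cases first).
#' @param alpha Significance level.
#' @return A `comparison_result` with the Friedman chi-square statistic and
#'   `df` in `note`.
#' @export
repeated_trend <- function(mat, alpha = 0.05) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3L || ncol(mat) < 3L)
    stop("need at least 3 subjects and 3 timepoints", call. = FALSE)
  if (anyNA(mat))
    stop("missing cells: restrict to complete cases before testing",
         call. = FALSE)
  ht <- stats::friedman.test(mat)
  stat <- unname(ht$statistic)
  if (is.nan(stat))  # every row fully tied: no rank variance, null by construction
    return(comparison_result("friedman", statistic = 0, p_value = 1,
                             n = nrow(mat), alpha = alpha, degenerate = TRUE,
                             note = "all timepoints tied within every subject"))
  comparison_result("friedman", statistic = stat,
                    p_value = ht$p.value, n = nrow(mat), alpha = alpha,
                    note = sprintf("df = %d", unname(ht$parameter)))
}

#' Spearman rank correlation
#'
#' @param x,y Numeric vectors of equal length, n >= 5.
#' @param alpha Significance level.
#' @return A `comparison_result` with `statistic` = rho; constant input is
#'   flagged degenerate with `p = NA`.
#' @export
correlate_spearman <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L)
    stop("need at least 5 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(comparison_result("spearman", statistic = NA_real_,
                             p_value = NA_real_, n = length(x),
                             alpha = alpha, degenerate = TRUE,
                             note = "constant input"))
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  comparison_result("spearman", statistic = unname(ht$estimate),
                    p_value = ht$p.value, n = length(x),
                    direction = sign(unname(ht$estimate)), alpha = alpha)
}

nonpar_descriptives <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7)
  data.frame(median = q[2], q1 = q[1], q3 = q[3])
}

par_descriptives <- function(v) {
  v <- v[is.finite(v)]
  data.frame(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
}

#' Experiment-shaped report tables
#'
#' Builds the per-condition descriptive-plus-test tables the comparison
#' workflow reports: medians and quartiles (or means and standard errors on
#' the parametric branch) of SampEn, av-RR and SDNN per condition or
#' segment, alongside the design's test results. Per-timepoint pairwise
#' tests in timecourse designs are, by default, reported without
#' multiple-testing correction (matching the workflow emulated here);
#' `p_adjust = "holm"` opts into a Holm correction.
#'
#' @param summary_df A summary table from [summarize_experiment()] (columns
#'   `subject`, `condition`, the index columns, plus `segment` or `window`
#'   for segmented designs).
#' @param design `"paired"`, `"groups"`, `"timecourse"`, or
#'   `"learning_onset"`.
#' @param indexes Index columns to report.
#' @param method Test routing passed to the comparison functions.
#' @param p_adjust `"none"` (default) or `"holm"`, applied within an index
#'   across a timecourse's per-segment tests.
#' @param alpha Significance level.
#' @return A list with `descriptives` (one row per index x condition
#'   [x segment]) and `tests` (one row per comparison performed).
#' @export
experiment_report <- function(summary_df,
                              design = c("paired", "groups", "timecourse",
                                         "learning_onset"),
                              indexes = c("sampen", "av_rr_ms", "sdnn_ms"),
                              method = "auto",
                              p_adjust = c("none", "holm"),
                              alpha = 0.05) {
  design <- match.arg(design)
  p_adjust <- match.arg(p_adjust)
  missing_cols <- setdiff(c("subject", "condition", indexes),
                          names(summary_df))
  if (length(missing_cols))
    stop("summary table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  switch(design,
         paired = report_two_condition(summary_df, indexes, paired = TRUE,
                                       method, alpha),
         groups = report_two_condition(summary_df, indexes, paired = FALSE,
                                       method, alpha),
         timecourse = report_timecourse(summary_df, indexes, "segment",
                                        method, p_adjust, alpha),
         learning_onset = report_timecourse(summary_df, indexes, "window",
                                            method, p_adjust, alpha))
}

pivot_pairs <- function(df, index, time_col = NULL) {
  conds <- unique(df$condition)
  key <- if (is.null(time_col)) df$subject
         else interaction(df$subject, df[[time_col]], drop = TRUE)
  a <- df[df$condition == conds[1L], ]
  b <- df[df$condition == conds[2L], ]
  ka <- if (is.null(time_col)) a$subject
        else interaction(a$subject, a[[time_col]], drop = TRUE)
  kb <- if (is.null(time_col)) b$subject
        else interaction(b$subject, b[[time_col]], drop = TRUE)
  common <- intersect(as.character(ka), as.character(kb))
  list(a = a[[index]][match(common, as.character(ka))],
       b = b[[index]][match(common, as.character(kb))],
       conditions = conds)
}

report_two_condition <- function(df, indexes, paired, method, alpha) {
  conds <- unique(df$condition)
  if (length(conds) != 2L)
    stop("two-condition report needs exactly 2 conditions", call. = FALSE)
  desc <- list(); tests <- list()
  for (ix in indexes) {
    pp <- pivot_pairs(df, ix)
    res <- if (paired) compare_paired(pp$a, pp$b, method = method,
                                      alpha = alpha)
           else compare_independent(pp$a, pp$b, method = method,
                                    alpha = alpha)
    parametric <- grepl("^ttest", res$test_name)
    for (ci in 1:2) {
      v <- df[[ix]][df$condition == conds[ci]]
      d <- if (parametric) par_descriptives(v) else nonpar_descriptives(v)
      desc[[length(desc) + 1L]] <-
        cbind(data.frame(index = ix, condition = conds[ci],
                         n = sum(is.finite(v))), d)
    }
    tests[[length(tests) + 1L]] <- data.frame(
      index = ix, comparison = paste(conds, collapse = " vs "),
      test = res$test_name, statistic = res$statistic, z = res$z,
      p_value = res$p_value, n = res$n, significant = res$significant)
  }
  list(descriptives = fill_rbind(desc), tests = fill_rbind(tests))
}

report_timecourse <- function(df, indexes, time_col, method, p_adjust,
                              alpha) {
  if (!time_col %in% names(df))
    stop(sprintf("summary table lacks a '%s' column", time_col),
         call. = FALSE)
  conds <- unique(df$condition)
  times <- sort(unique(df[[time_col]]))
  desc <- list(); tests <- list()
  for (ix in indexes) {
    for (cn in conds) {
      sub <- df[df$condition == cn, ]
      # Friedman over complete subject x time matrices
      wide <- stats::reshape(
        sub[, c("subject", time_col, ix)], direction = "wide",
        idvar = "subject", timevar = time_col)
      m <- as.matrix(wide[, -1, drop = FALSE])
      m <- m[stats::complete.cases(m), , drop = FALSE]
      fr <- repeated_trend(m, alpha = alpha)
      tests[[length(tests) + 1L]] <- data.frame(
        index = ix, comparison = sprintf("dynamics (%s)", cn),
        test = fr$test_name, statistic = fr$statistic, z = NA_real_,
        p_value = fr$p_value, n = fr$n, significant = fr$significant)
      for (tt in times) {
        v <- sub[[ix]][sub[[time_col]] == tt]
        desc[[length(desc) + 1L]] <- cbind(
          data.frame(index = ix, condition = cn, time = tt,
                     n = sum(is.finite(v))),
          nonpar_descriptives(v), par_descriptives(v))
      }
    }
    if (length(conds) == 2L) {
      # per-timepoint pairwise between-arm comparisons
      prow <- list()
      for (tt in times) {
        pp <- pivot_pairs(df[df[[time_col]] == tt, ], ix)
        res <- compare_paired(pp$a, pp$b, method = method, alpha = alpha)
        prow[[length(prow) + 1L]] <- data.frame(
          index = ix,
          comparison = sprintf("%s vs %s @ %s", conds[1L], conds[2L], tt),
          test = res$test_name, statistic = res$statistic, z = res$z,
          p_value = res$p_value, n = res$n, significant = res$significant)
      }
      prow <- fill_rbind(prow)
      if (p_adjust == "holm") {
        prow$p_value <- stats::p.adjust(prow$p_value, "holm")
        prow$significant <- prow$p_value < alpha
      }
      tests[[length(tests) + 1L]] <- prow
    } else if (length(conds) == 1L && length(times) > 1L) {
      # single-arm window designs: first timepoint against each later one
      sub <- df[df$condition == conds, ]
      first <- times[1L]
      for (tt in times[-1L]) {
        a <- sub[sub[[time_col]] == first, c("subject", ix)]
        b <- sub[sub[[time_col]] == tt, c("subject", ix)]
        common <- intersect(a$subject, b$subject)
        res <- compare_paired(a[[ix]][match(common, a$subject)],
                              b[[ix]][match(common, b$subject)],
                              method = method, alpha = alpha)
        tests[[length(tests) + 1L]] <- data.frame(
          index = ix, comparison = sprintf("%s vs %s", first, tt),
          test = res$test_name, statistic = res$statistic, z = res$z,
          p_value = res$p_value, n = res$n, significant = res$significant)
      }
    }
  }
  list(descriptives = fill_rbind(desc), tests = fill_rbind(tests))
}

# rbind data.frames that may differ in column sets
fill_rbind <- function(lst) {
  cols <- unique(unlist(lapply(lst, names)))
  do.call(rbind, lapply(lst, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[, cols, drop = FALSE]
  }))
}
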