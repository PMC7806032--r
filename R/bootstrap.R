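new_boot <- function(values, raw, n_iter, window_s, n_failed, seed,
                     statistic_name) {
  sm <- if (length(values)) summarize_values(values) else
    c(median = NA_real_, q25 = NA_real_, q75 = NA_real_)
  structure(list(statistic_name = statistic_name, values = values, raw = raw,
                 n_iter = n_iter, window_s = window_s,
                 median = sm[["median"]], q25 = sm[["q25"]], q75 = sm[["q75"]],
                 n_failed = n_failed, seed = seed),
            class = "perch_boot")
}

#' Bootstrap a statistic over random contiguous windows of a recording
#'
#' Draws `n_iter` windows of `window_s` seconds with uniformly random start
#' positions (with replacement, so windows may repeat and overlap) and
#' applies `stat_fn` to each windowed recording. `stat_fn` may return a
#' scalar or a numeric vector (e.g. per-axis delays); `values` collects all
#' returned numbers and the summary quantiles pool them. Iterations where
#' `stat_fn` throws are dropped and counted in `n_failed`; the call only
#' fails if every iteration fails.
#'
#' Note that overlapping windows are not independent samples: tests run on
#' bootstrap values are anti-conservative. See [compare_conditions()].
#'
#' @param recording A `perch_recording`.
#' @param stat_fn Function of one argument (a windowed `perch_recording`)
#'   returning numeric.
#' @param n_iter Number of windows (default 100).
#' @param window_s Window length, seconds (default 40); must not exceed the
#'   recording duration.
#' @param seed Integer seed for the window starts.
#' @param statistic_name Label stored in the result.
#' @return Object of class `perch_boot`: `values`, per-iteration `raw` list,
#'   `n_iter`, `window_s`, `median`, `q25`, `q75`, `n_failed`, `seed`.
#' @export
bootstrap_windows <- function(recording, stat_fn, n_iter = 100, window_s = 40,
                              seed = 1L,
                              statistic_name = deparse(substitute(stat_fn))) {
  if (!inherits(recording, "perch_recording")) stop("recording must be a perch_recording")
  if (n_iter < 1) stop("n_iter must be at least 1")
  N <- nrow(recording$foot)
  W <- as.integer(round(window_s * recording$rate_hz))
  if (W < 1 || W > N)
    stop("window_s (", window_s, " s) exceeds the recording duration (",
         N / recording$rate_hz, " s)")
  set.seed(seed)
  starts <- sample.int(N - W + 1L, n_iter, replace = TRUE)
  raw <- vector("list", n_iter)
  failed <- logical(n_iter)
  last_err <- NULL
  for (i in seq_len(n_iter)) {
    res <- tryCatch(stat_fn(window_recording(recording, starts[i], W)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
      last_err <- conditionMessage(res)
    } else {
      raw[[i]] <- res
    }
  }
  if (all(failed))
    stop("all ", n_iter, " bootstrap iterations failed; last error: ", last_err)
  new_boot(values = unlist(raw[!failed], use.names = FALSE),
           raw = raw, n_iter = n_iter, window_s = window_s,
           n_failed = sum(failed), seed = seed,
           statistic_name = statistic_name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.perch_boot <- function(x, ...) {
  cat(sprintf("Bootstrap of '%s': %d windows of %g s (%d failed)\n",
              x$statistic_name, x$n_iter, x$window_s, x$n_failed))
  cat(sprintf("  median %.4g (IQR %.4g-%.4g), %d values\n",
              x$median, x$q25, x$q75, length(x$values)))
  invisible(x)
}

#' Median and interquartile range of a sample
#'
#' Linear-interpolation (type 7) quantiles, the convention fixed for the
#' whole package so summaries are exactly reproducible.
#'
#' @param values Non-empty numeric vector.
#' @return Named vector `c(median, q25, q75)`.
#' @examples
#' summarize_values(1:5)  # 3, 2, 4
#' @export
summarize_values <- function(values) {
  if (!length(values) || !is.numeric(values))
    stop("values must be a non-empty numeric vector")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q25 = q[1], q75 = q[3])
}

#' Two-sample comparison between conditions
#'
#' Student's t-test between two sets of (bootstrap) statistic values: Welch
#' by default, pooled-variance optional; two-sided p-value. When both sides
#' are constant the t-statistic is undefined; by convention equal means give
#' `t = 0, p = 1` and unequal means `t = +/-Inf, p = 0`, flagged as
#' `degenerate`. When the inputs are overlapping-window bootstrap values the
#' test is anti-conservative (the values are not independent); the result
#' carries that caveat in its `note` field.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param labels Length-2 condition labels.
#' @return Object of class `perch_comparison`: `pair`, `t_stat`, `p_value`,
#'   medians and IQRs of both sides, `significant`, `method`, `degenerate`,
#'   `note`.
#' @examples
#' compare_conditions(rnorm(50), rnorm(50, 2))$significant
#' @export
compare_conditions <- function(a, b, alpha = 0.05, var_equal = FALSE,
                               labels = c("a", "b")) {
  if (length(a) < 2 || length(b) < 2)
    stop("each side needs at least 2 values")
  sa <- summarize_values(a); sb <- summarize_values(b)
  degenerate <- FALSE
  if (sd(a) == 0 && sd(b) == 0) {
    degenerate <- TRUE
    if (mean(a) == mean(b)) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- list(statistic = sign(mean(a) - mean(b)) * Inf, p.value = 0)
    }
  } else {
    tt <- t.test(a, b, var.equal = var_equal)
  }
  structure(list(pair = labels,
                 t_stat = unname(tt$statistic), p_value = tt$p.value,
                 median_a = sa[["median"]], iqr_a = sa[c("q25", "q75")],
                 median_b = sb[["median"]], iqr_b = sb[c("q25", "q75")],
                 n_a = length(a), n_b = length(b),
                 alpha = alpha, significant = tt$p.value < alpha,
                 method = if (var_equal) "pooled t-test" else "Welch t-test",
                 degenerate = degenerate,
                 note = paste("p-values on overlapping bootstrap windows are",
                              "anti-conservative")),
            class = "perch_comparison")
}

#' @export
print.perch_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s\n", x$method, x$pair[1], x$pair[2]))
  cat(sprintf("  medians %.4g (%.4g-%.4g) vs %.4g (%.4g-%.4g)\n",
              x$median_a, x$iqr_a[1], x$iqr_a[2],
              x$median_b, x$iqr_b[1], x$iqr_b[2]))
  cat(sprintf("  t = %.3f, p = %.4g (%ssignificant at alpha = %g)\n",
              x$t_stat, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}
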