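constant_recording <- function(value = 2.5, n = 5000, rate = 1000) {
  m <- matrix(value, n, 3)
  structure(list(rate_hz = rate, t = (seq_len(n) - 1) / rate,
                 foot = m, hip = m, head = m, meta = list()),
            class = "perch_recording")
}

test_that("a constant statistic bootstraps to itself with zero IQR", {
  rec <- constant_recording(2.5)
  bt <- bootstrap_windows(rec, function(w) mean(w$foot), n_iter = 20,
                          window_s = 1, seed = 3)
  expect_true(all(bt$values == 2.5))
  expect_identical(bt$q75 - bt$q25, 0)
  expect_identical(bt$n_failed, 0L)
})

test_that("bootstrap counts and determinism hold", {
  rec <- smoke_recording(n_moves = 20)
  b1 <- bootstrap_windows(rec, function(w) sd(w$hip[, 2]), n_iter = 100,
                          window_s = 4, seed = 7)
  b2 <- bootstrap_windows(rec, function(w) sd(w$hip[, 2]), n_iter = 100,
                          window_s = 4, seed = 7)
  expect_identical(length(b1$values), 100L)
  expect_identical(length(b1$values) + b1$n_failed, 100L)
  expect_identical(b1$values, b2$values)
  b3 <- bootstrap_windows(rec, function(w) sd(w$hip[, 2]), n_iter = 100,
                          window_s = 4, seed = 8)
  expect_false(identical(b1$values, b3$values))
})

test_that("windows longer than the recording are a precondition error", {
  rec <- constant_recording(n = 2000)
  expect_error(bootstrap_windows(rec, mean, n_iter = 5, window_s = 10),
               "exceeds the recording")
})

test_that("failing iterations are counted, and total failure is fatal", {
  rec <- constant_recording()
  flaky <- local({
    i <- 0
    function(w) {
      i <<- i + 1
      if (i %% 2 == 0) stop("boom")
      1
    }
  })
  bt <- bootstrap_windows(rec, flaky, n_iter = 10, window_s = 1, seed = 1)
  expect_identical(bt$n_failed, 5L)
  expect_identical(length(bt$values) + bt$n_failed, 10L)
  expect_error(bootstrap_windows(rec, function(w) stop("always"), n_iter = 3,
                                 window_s = 1),
               "all 3 bootstrap iterations failed")
})

test_that("summaries use linear-interpolation quantiles", {
  expect_identical(summarize_values(c(1, 2, 3, 4, 5)),
                   c(median = 3, q25 = 2, q75 = 4))
  expect_identical(summarize_values(7), c(median = 7, q25 = 7, q75 = 7))
  set.seed(10)
  z <- rnorm(10000)
  s <- summarize_values(z)
  expect_lt(abs(s[["median"]]), 0.05)
  expect_lt(abs((s[["q75"]] - s[["q25"]]) - 2 * qnorm(0.75)), 0.1)
  expect_error(summarize_values(numeric(0)), "non-empty")
})

test_that("identical samples compare as indistinguishable", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  cp <- compare_conditions(a, a)
  expect_equal(cp$t_stat, 0)
  expect_equal(cp$p_value, 1)
  expect_false(cp$significant)
})

test_that("a unit shift at n = 100 per side is detected", {
  set.seed(5)
  cp <- compare_conditions(rnorm(100), rnorm(100, mean = 1))
  expect_lt(cp$p_value, 0.05)
  expect_true(cp$significant)
})

test_that("the pooled t-statistic matches the textbook formula", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  cp <- compare_conditions(a, b, var_equal = TRUE)
  # independent brute-force evaluation
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  p_ref <- 2 * pt(abs(t_ref), df = length(a) + length(b) - 2,
                  lower.tail = FALSE)
  expect_equal(cp$t_stat, t_ref, tolerance = 1e-12)
  expect_equal(cp$p_value, p_ref, tolerance = 1e-12)
})

test_that("swapping the sides negates t and preserves p", {
  set.seed(6)
  a <- rnorm(30); b <- rnorm(25, 0.3)
  ab <- compare_conditions(a, b)
  ba <- compare_conditions(b, a)
  expect_equal(ab$t_stat, -ba$t_stat, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
})

test_that("constant samples fall back to the documented conventions", {
  same <- compare_conditions(rep(2, 5), rep(2, 4))
  expect_identical(same$p_value, 1)
  expect_true(same$degenerate)
  diff <- compare_conditions(rep(2, 5), rep(3, 4))
  expect_identical(diff$p_value, 0)
  expect_identical(diff$t_stat, -Inf)
  expect_error(compare_conditions(1, c(1, 2)), "at least 2")
})
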