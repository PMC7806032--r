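test_that("block Hankel matrices have the documented structure", {
  expect_identical(block_hankel(c(1, 2, 3, 4), 2),
                   rbind(c(1, 2, 3), c(2, 3, 4)))
  x <- matrix(rnorm(12), 6, 2)
  expect_identical(block_hankel(x, 1), t(x))
  # brute-force index construction for a 2-channel series, s = 3
  H <- block_hankel(x, 3)
  expect_identical(dim(H), c(6L, 4L))
  for (i in 1:3) for (ch in 1:2) for (j in 1:4)
    expect_identical(H[(i - 1) * 2 + ch, j], x[i + j - 1, ch])
  expect_error(block_hankel(x, 7), "shorter")
  expect_error(block_hankel(x, 0), "positive")
})

test_that("a SISO pole is recovered from noiseless data", {
  set.seed(1)
  u <- rnorm(4000)
  y <- simulate_ss_r(matrix(0.9), matrix(1), matrix(1), matrix(0), cbind(u))
  fit <- moesp(u, y, order = 1, s = 10)
  expect_lt(abs(eigen(fit$A)$values - 0.9), 1e-6)
  expect_gt(as.numeric(vaf(fit$fitted, y)), 99.99)
})

test_that("Markov parameters of a random order-3 MIMO system are recovered", {
  sys <- make_stable_ss(3, 3, 3, seed = 7)
  set.seed(8)
  u <- matrix(rnorm(4000 * 3), ncol = 3)
  y <- simulate_ss_r(sys$A, sys$B, sys$C, sys$D, u)
  fit <- moesp(u, y, order = 3, s = 10)
  err <- max_markov_rel_err(markov_params(fit, 20),
                            markov_direct(sys$A, sys$B, sys$C, sys$D, 20))
  expect_lt(err, 1e-6)
})

test_that("refitting the same data gives identical Markov parameters", {
  sys <- make_stable_ss(3, 2, 2, seed = 11)
  set.seed(12)
  u <- matrix(rnorm(3000 * 2), ncol = 2)
  y <- simulate_ss_r(sys$A, sys$B, sys$C, sys$D, u) +
    matrix(rnorm(3000 * 2, sd = 0.05), ncol = 2)
  f1 <- moesp(u, y, 3, 10)
  f2 <- moesp(u, y, 3, 10)
  expect_lt(max_markov_rel_err(markov_params(f1), markov_params(f2)), 1e-8)
})

test_that("zero output yields a null model, not an error", {
  set.seed(3)
  u <- matrix(rnorm(2000 * 2), ncol = 2)
  fit <- moesp(u, matrix(0, 2000, 2), order = 3, s = 10)
  expect_lt(max(abs(fit$fitted)), 1e-10)
  expect_lt(max(abs(fit$C)), 1e-10)
})

test_that("preconditions on lengths and block rows are enforced", {
  u <- matrix(rnorm(100 * 3), ncol = 3)
  expect_error(moesp(u, matrix(rnorm(100 * 3), ncol = 3), 3, 10), "too short")
  expect_error(moesp(rnorm(50), rnorm(49), 1, 5), "same number")
  expect_error(moesp(rnorm(500), rnorm(500), order = 5, s = 5), "block rows")
})

test_that("order selection finds the spectral gap or obeys a fixed override", {
  expect_identical(select_order(c(10, 5, 2, 1e-9, 1e-10)), 3L)
  expect_identical(select_order(c(10, 5), criterion = "fixed:3"), 3L)
  # singular values of the noiseless order-3 oracle expose the true rank
  sys <- make_stable_ss(3, 2, 2, seed = 21)
  set.seed(22)
  u <- matrix(rnorm(3000 * 2), ncol = 2)
  y <- simulate_ss_r(sys$A, sys$B, sys$C, sys$D, u)
  fit <- moesp(u, y, order = 3, s = 8)
  expect_identical(select_order(fit$sv, max_order = 6), 3L)
  expect_error(select_order(numeric(0)), "empty")
  expect_error(select_order(c(1e-20, 1e-21)), "degenerate")
})

test_that("prediction iterates the recursion from the given state", {
  # feedthrough-only model copies the input
  m0 <- structure(list(A = matrix(0, 2, 2), B = matrix(0, 2, 3),
                       C = matrix(0, 3, 2), D = diag(3), x0 = numeric(2),
                       order = 2L, m = 3L, p = 3L), class = "moesp")
  u <- matrix(rnorm(50 * 3), ncol = 3)
  expect_equal(predict(m0, u), u, ignore_attr = TRUE)
  # zero input from the zero state stays at zero
  sys <- make_stable_ss(3, 2, 2, seed = 31)
  ms <- structure(c(sys, list(x0 = numeric(3), order = 3L, m = 2L, p = 2L)),
                  class = "moesp")
  expect_true(all(predict(ms, matrix(0, 20, 2)) == 0))
  # impulse response equals the Markov parameters
  imp <- matrix(0, 10, 2); imp[1, 1] <- 1
  resp <- predict(ms, imp)
  mk <- markov_direct(sys$A, sys$B, sys$C, sys$D, 10)
  for (k in 1:10) expect_equal(resp[k, ], mk[[k]][, 1], tolerance = 1e-12)
  expect_error(predict(ms, matrix(0, 5, 3)), "channels")
})

test_that("VAF matches its closed forms and hand evaluation", {
  y <- cbind(c(1, 2, 3, 4))
  expect_identical(as.numeric(vaf(y, y)), 100)
  expect_identical(as.numeric(vaf(0 * y, y)), 0)
  # hand evaluation with the population-variance convention
  y_hat <- cbind(c(1, 2, 3, 5))
  popvar <- function(x) sum((x - mean(x))^2) / length(x)
  expected <- 100 * (1 - popvar(c(0, 0, 0, -1)) / popvar(c(1, 2, 3, 4)))
  expect_equal(as.numeric(vaf(y_hat, y)), expected)
  expect_equal(expected, 85)
  # invariance under common scaling
  set.seed(4); z <- matrix(rnorm(200), ncol = 2); zh <- z + 0.1
  expect_equal(as.numeric(vaf(5 * zh, 5 * z)), as.numeric(vaf(zh, z)))
  expect_identical(as.numeric(vaf(-3 * z, -3 * z)), 100)
  expect_error(vaf(y, cbind(rep(2, 4))), "zero variance")
  expect_error(vaf(cbind(1:3), cbind(1:4)), "shape")
})

test_that("duplicated fusion channels add no information", {
  rec <- smoke_recording(n_moves = 40, seed = 17)
  dup <- rec
  dup$head <- rec$hip
  v_hip <- estimate_foot_acc(rec, "hip", train_samples = 4000)$pooled_vaf
  v_dup <- estimate_foot_acc(dup, "fusion", train_samples = 4000)$pooled_vaf
  expect_lt(abs(v_dup - v_hip), 0.1)
})

test_that("a noiseless recording is almost perfectly inverted per axis", {
  pr <- generate_protocol(100, 0.01, seed = 5)
  rec <- simulate_chain(pr, mechanical_params("low"))
  est <- estimate_foot_acc(rec, "hip", order = 4, s = 12, per_axis = TRUE,
                           train_samples = 8000)
  expect_gt(est$pooled_vaf, 99)
})

test_that("hip sensing beats head sensing on the default simulator", {
  rec <- smoke_recording(n_moves = 60, seed = 23)
  v_hip <- estimate_foot_acc(rec, "hip", train_samples = 4000)$pooled_vaf
  v_head <- estimate_foot_acc(rec, "head", train_samples = 4000)$pooled_vaf
  expect_gt(v_hip, v_head)
})

test_that("median VAF degrades monotonically with sensor noise", {
  grid <- c(0, 0.05, 0.15, 0.4, 1)
  med <- sapply(grid, function(ns) {
    median(sapply(1:5, function(i) {
      rec <- smoke_recording(n_moves = 30, seed = 300 + i, noise_sd = ns)
      estimate_foot_acc(rec, "hip", train_samples = 4000)$pooled_vaf
    }))
  })
  expect_true(all(diff(med) < 0))
})

test_that("models round-trip through JSON", {
  sys <- make_stable_ss(3, 2, 2, seed = 41)
  set.seed(42)
  u <- matrix(rnorm(2000 * 2), ncol = 2)
  y <- simulate_ss_r(sys$A, sys$B, sys$C, sys$D, u)
  fit <- moesp(u, y, 3, 10)
  path <- tempfile(fileext = ".json")
  write_moesp(fit, path)
  back <- read_moesp(path)
  expect_equal(back$A, fit$A, tolerance = 1e-12)
  expect_equal(back$D, fit$D, tolerance = 1e-12)
  expect_equal(predict(back, u, fit$x0), predict(fit, u, fit$x0),
               tolerance = 1e-10)
  unlink(path)
})
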