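test_that("a quiescent platform leaves every trace at zero", {
  pr <- generate_protocol(0, 0.01, seed = 1)
  # 2 s of explicit zero input
  pr$platform_pos <- pr$platform_vel <- pr$platform_acc <-
    matrix(0, 2000, 3, dimnames = list(NULL, c("x", "y", "z")))
  rec <- simulate_chain(pr, mechanical_params("low"))
  expect_true(all(rec$foot == 0))
  expect_true(all(rec$hip == 0))
  expect_true(all(rec$head == 0))
})

test_that("the foot trace is the platform acceleration (second difference)", {
  pr <- generate_protocol(10, 0.02, seed = 4)
  rec <- simulate_chain(pr, mechanical_params("low"))
  d2 <- diff(pr$platform_pos[, 2], differences = 2) * pr$rate_hz^2
  # central second difference approximates the analytic acceleration to
  # O(dt^2) wherever the commanded acceleration is continuous; it jumps at
  # move starts and ends, so those samples are excluded
  n_move <- round(pr$move_duration_s * pr$rate_hz)
  bounds <- c(pr$events$start_index, pr$events$start_index + n_move)
  skip_idx <- unique(pmax(1, outer(bounds, -2:2, "+")))
  idx <- setdiff(2:(nrow(rec$foot) - 1), skip_idx)
  expect_lt(max(abs(rec$foot[idx, 2] - d2[idx - 1])) /
              max(abs(rec$foot[, 2])), 1e-3)
})

test_that("doubling the radius doubles every noiseless trace (linearity)", {
  p1 <- generate_protocol(15, 0.005, seed = 8)
  p2 <- generate_protocol(15, 0.010, seed = 8)
  prm <- mechanical_params("high")
  r1 <- simulate_chain(p1, prm)
  r2 <- simulate_chain(p2, prm)
  for (ch in c("foot", "hip", "head"))
    expect_equal(2 * r1[[ch]], r2[[ch]], tolerance = 1e-12)
})

test_that("hip and head are causal: zero before the first event", {
  pr <- generate_protocol(5, 0.01, seed = 2)  # leading 0.1 s dwell
  rec <- simulate_chain(pr, mechanical_params("low"))
  i0 <- pr$events$start_index[1]
  expect_gt(i0, 1)
  # the first-order hold interpolates the input over the interval ending at
  # the first move sample, so the state one sample earlier already feels it;
  # everything before that is exactly zero
  expect_true(all(rec$hip[seq_len(i0 - 2), ] == 0))
  expect_true(all(rec$head[seq_len(i0 - 2), ] == 0))
  expect_lt(max(abs(rec$hip[i0 - 1, ])), 1e-6 * max(abs(rec$hip)))
})

test_that("a rigid neck makes the head move with the hip", {
  pr <- generate_protocol(30, 0.01, seed = 6)
  prm <- mechanical_params("low")
  prm$k_neck <- prm$k_neck * 1e6
  prm$c_neck <- prm$c_neck * 1e3
  rec <- simulate_chain(pr, prm)
  # the stiffened neck mode sits far above Nyquist and decays within ~0.4 ms;
  # the samples right after each commanded-acceleration jump (move start,
  # peak passage is smooth, move end) still catch its ringing, so the limit
  # is checked where the excitation is continuous
  n_move <- round(pr$move_duration_s * pr$rate_hz)
  bounds <- c(pr$events$start_index, pr$events$start_index + n_move)
  i <- setdiff((pr$events$start_index[2]):nrow(rec$hip),
               outer(bounds, 0:2, "+"))
  nrmsd <- sqrt(mean((rec$head[i, ] - rec$hip[i, ])^2)) /
    sqrt(mean(rec$hip[i, ]^2))
  expect_lt(nrmsd, 0.01)
})

test_that("an undamped chain is flagged as non-decaying", {
  pr <- generate_protocol(2, 0.01, seed = 1)
  prm <- mechanical_params("low", c_leg = c(0, 0, 0), c_neck = 0)
  w <- capture_warnings(rec <- simulate_chain(pr, prm))
  expect_true(any(grepl("eigenvalue", w)))
  expect_true(rec$meta$unstable)
})

test_that("sensor noise has the requested level and provenance", {
  zero <- structure(list(rate_hz = 1000, t = (0:99999) / 1000,
                         foot = matrix(0, 1e5, 3), hip = matrix(0, 1e5, 3),
                         head = matrix(0, 1e5, 3), meta = list()),
                    class = "perch_recording")
  noisy <- add_sensor_noise(zero, 0.05, seed = 11)
  for (ch in c("foot", "hip", "head"))
    for (a in 1:3)
      expect_lt(abs(sd(noisy[[ch]][, a]) - 0.05) / 0.05, 0.03)
  expect_identical(noisy$meta$noiseless$foot, zero$foot)
  # zero noise is the identity; same seed reproduces the same noise
  expect_identical(add_sensor_noise(zero, 0), zero)
  expect_identical(add_sensor_noise(zero, 0.05, seed = 11)$hip, noisy$hip)
  expect_error(add_sensor_noise(zero, -1), "non-negative")
})

test_that("run_trial parses Table-style labels and is reproducible", {
  rec <- run_trial("Trial_HS_20", n_moves = 5, seed = 3)
  expect_identical(rec$meta$neck_preset, "high")
  expect_identical(rec$meta$radius_m, 0.02)
  rec2 <- run_trial("Trial_HS_20", n_moves = 5, seed = 3)
  expect_identical(rec$hip, rec2$hip)
  expect_error(run_trial(radius_m = 0.01, neck_preset = "wobbly", n_moves = 2),
               "unknown neck preset")
  expect_error(run_trial("Trial_XX_2", n_moves = 2), "scheme")
})

test_that("the full grid has eight labelled trials", {
  g <- trial_grid()
  expect_identical(nrow(g), 8L)
  expect_setequal(g$trial_label,
                  c("Trial_LS_2", "Trial_LS_5", "Trial_LS_10", "Trial_LS_20",
                    "Trial_HS_2", "Trial_HS_5", "Trial_HS_10", "Trial_HS_20"))
})

test_that("recordings round-trip through CSV plus JSON sidecar", {
  rec <- smoke_recording(n_moves = 4)
  path <- tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$rate_hz, rec$rate_hz)
  expect_equal(back$foot, rec$foot, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$head, rec$head, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$meta$trial_label, rec$meta$trial_label)
  unlink(c(path, paste0(path, ".json")))
})

test_that("serial propagation: foot-to-hip delay below foot-to-head", {
  meds <- sapply(1:5, function(sd) {
    rec <- smoke_recording(n_moves = 50, seed = sd)
    c(median(sensing_delays(rec, "hip")), median(sensing_delays(rec, "head")))
  })
  expect_lt(median(meds[1, ]), median(meds[2, ]))
})
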