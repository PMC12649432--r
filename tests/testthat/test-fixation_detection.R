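test_that("stationary gaze yields a single fixation spanning the trace", {
  tr <- constant_trace(31)
  fx <- detect_fixations(tr)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_ms, 500)
  expect_equal(c(fx$cx_deg, fx$cy_deg), c(0, 0))
})

test_that("two stationary clusters separated by a saccade give two fixations", {
  dt <- 1000 / 60
  n1 <- 19 # 300 ms
  t <- (0:(2 * n1 + 2)) * dt
  x <- c(rep(0, n1), c(1.25, 2.5, 3.75), rep(5, n1))
  y <- rep(0, length(x))
  tr <- gaze_trace(t, x, y)
  fx <- detect_fixations(tr, dispersion_deg = 1.0, min_duration_ms = 100)
  expect_equal(nrow(fx), 2)
  expect_lt(abs(fx$cx_deg[1] - 0), 0.1)
  expect_lt(abs(fx$cx_deg[2] - 5), 0.1)
  expect_lt(max(abs(fx$cy_deg)), 0.1)
})

test_that("sub-minimum-duration gaze and empty traces yield no fixations", {
  expect_equal(nrow(detect_fixations(constant_trace(4))), 0)
  tr <- gaze_trace(c(0, 20, 40), c(NA, NA, NA), c(NA, NA, NA),
                   valid = FALSE)
  expect_equal(nrow(detect_fixations(tr)), 0)
  expect_error(detect_fixations(constant_trace(31), dispersion_deg = 0))
  expect_error(detect_fixations(constant_trace(31), min_duration_ms = -5))
})

test_that("short invalid gaps are bridged, long gaps split fixations", {
  dt <- 1000 / 60
  n <- 40
  t <- (0:(n - 1)) * dt
  x <- rep(0, n)
  y <- rep(0, n)
  valid <- rep(TRUE, n)
  valid[20:22] <- FALSE            # 4*dt = 66.7 ms between valid samples
  x[!valid] <- NA; y[!valid] <- NA
  fx <- detect_fixations(gaze_trace(t, x, y, valid), gap_tolerance_ms = 75)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_ms, t[n] - t[1])    # wall-clock span kept
  expect_equal(fx$n_samples, sum(valid))       # bridged samples excluded
  valid2 <- rep(TRUE, n)
  valid2[18:24] <- FALSE           # 8*dt = 133 ms gap: split
  x2 <- rep(0, n); y2 <- rep(0, n)
  x2[!valid2] <- NA; y2[!valid2] <- NA
  fx2 <- detect_fixations(gaze_trace(t, x2, y2, valid2),
                          gap_tolerance_ms = 75)
  expect_equal(nrow(fx2), 2)
})

test_that("the scanner matches the brute-force I-DT oracle on random traces", {
  set.seed(101)
  for (i in 1:200) {
    tr <- random_trace()
    disp <- sample(c(0.5, 1.0, 1.5), 1)
    mind <- sample(c(80, 100, 150), 1)
    gap <- sample(c(50, 75, 100), 1)
    got <- detect_fixations(tr, disp, mind, gap)
    want <- idt_oracle(tr, disp, mind, gap)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$onset_ms, want$onset_ms)
      expect_equal(got$offset_ms, want$offset_ms)
      expect_equal(got$cx_deg, want$cx_deg)
      expect_equal(got$n_samples, want$n_samples)
    }
  }
})

test_that("emitted fixations respect dispersion, duration and ordering", {
  set.seed(202)
  for (i in 1:50) {
    tr <- random_trace()
    fx <- detect_fixations(tr, 1.0, 100, 75)
    if (nrow(fx) == 0) next
    expect_true(all(fx$duration_ms >= 100))
    expect_true(all(diff(fx$onset_ms) > 0))
    expect_true(all(fx$onset_ms[-1] >= fx$offset_ms[-nrow(fx)]))
    for (k in seq_len(nrow(fx))) {
      m <- tr$valid & tr$t_ms >= fx$onset_ms[k] & tr$t_ms <= fx$offset_ms[k]
      expect_lte(diff(range(tr$x_deg[m])), 1.0 + 1e-12)
      expect_lte(diff(range(tr$y_deg[m])), 1.0 + 1e-12)
    }
  }
})

test_that("quality ratios implement the reliability rule", {
  tr <- constant_trace(61)   # 1000 ms fully fixated
  fx <- detect_fixations(tr)
  q <- compute_quality(tr, fx)
  expect_equal(q$tracking_ratio, 1)
  expect_equal(q$fixation_ratio, 1)
  expect_true(q$reliable)

  # 80% tracking fails regardless of fixation ratio
  n <- 100
  valid <- rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 20)
  x <- ifelse(valid, 0, NA)
  tr2 <- gaze_trace((0:(n - 1)) * 1000 / 60, x, x, valid)
  q2 <- compute_quality(tr2, detect_fixations(tr2))
  expect_equal(q2$tracking_ratio, 0.8)
  expect_false(q2$reliable)

  # full tracking but 50% fixation coverage fails
  t <- (0:120) * 1000 / 60
  x3 <- c(rep(0, 61), seq(2, 61, by = 1))   # drift: no fixation after 1 s
  tr3 <- gaze_trace(t, x3, rep(0, 121))
  q3 <- compute_quality(tr3, detect_fixations(tr3))
  expect_equal(q3$tracking_ratio, 1)
  expect_lt(q3$fixation_ratio, 0.6)
  expect_false(q3$reliable)

  expect_error(compute_quality(gaze_trace(1, 0, 0), NULL), "span")
})

test_that("invalidating samples never raises the tracking ratio", {
  set.seed(33)
  tr <- random_trace()
  q <- compute_quality(tr, detect_fixations(tr))
  iv <- which(tr$valid)[1]
  tr$valid[iv] <- FALSE
  tr$x_deg[iv] <- NA
  tr$y_deg[iv] <- NA
  q2 <- compute_quality(tr, detect_fixations(tr))
  expect_lt(q2$tracking_ratio, q$tracking_ratio)
})
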