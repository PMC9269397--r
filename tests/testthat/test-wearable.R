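make_stream <- function(ax, ay, az, fs = 50) {
  n <- max(lengths(list(ax, ay, az)))
  accel_stream((seq_len(n) - 1) / fs, rep_len(ax, n), rep_len(ay, n),
               rep_len(az, n))
}

test_that("calibration accepts correct wear and rejects rotation or short bouts", {
  t <- seq(0, 30, by = 0.02)
  ok <- accel_stream(t, rnorm(length(t), 0.01, 0.005),
                     rnorm(length(t), 0.98, 0.005),
                     rnorm(length(t), -0.02, 0.005))
  cal <- calibrate_accel(ok)
  expect_true(cal$ok)
  expect_equal(unname(cal$baseline), c(0.01, 0.98, -0.02), tolerance = 0.01)
  rot <- accel_stream(t, rep(0, length(t)), rep(0.10, length(t)),
                      rep(0.95, length(t)))
  bad <- calibrate_accel(rot)
  expect_false(bad$ok)
  expect_match(bad$message, "worn incorrectly")
  short <- make_stream(rep(0, 501), 1, 0)  # 10 s at 50 Hz
  expect_error(calibrate_accel(short), "30")
  # failed calibration blocks feature extraction
  expect_error(wearable_features(ok, bad), "blocked")
})

test_that("FIR pre-processing has unity DC gain and the designed response", {
  const <- make_stream(rep(0, 100), 1, 0)
  out <- preprocess_accel(const)
  expect_equal(out$ay_g, const$ay_g, tolerance = 1e-12)
  expect_equal(out$ax_g, const$ax_g, tolerance = 1e-12)

  fs <- 50; t <- (0:499) / fs
  for (f0 in c(2, 20)) {
    sine <- accel_stream(t, sin(2 * pi * f0 * t), 0 * t, 0 * t)
    filt <- preprocess_accel(sine)
    mid <- 100:400  # interior, away from edge effects
    amp <- sqrt(2 * mean(filt$ax_g[mid]^2))
    # oracle: evaluate the designed filter's frequency response
    expect_equal(amp, fir_response(f0), tolerance = 0.02)
  }
  expect_gt(fir_response(2), 0.9)              # passband: amplitude kept
  expect_lt(fir_response(20), fir_response(2)) # stopband attenuates
})

test_that("filtering is linear and rejects jittered timestamps", {
  set.seed(11)
  t <- (0:199) / 50
  a <- accel_stream(t, rnorm(200), rnorm(200), rnorm(200))
  b <- accel_stream(t, rnorm(200), rnorm(200), rnorm(200))
  ab <- accel_stream(t, a$ax_g + b$ax_g, a$ay_g + b$ay_g, a$az_g + b$az_g)
  fa <- preprocess_accel(a); fb <- preprocess_accel(b)
  fab <- preprocess_accel(ab)
  expect_equal(fab$ax_g, fa$ax_g + fb$ax_g, tolerance = 1e-9)
  expect_equal(fab$az_g, fa$az_g + fb$az_g, tolerance = 1e-9)
  tj <- t; tj[100] <- tj[100] + 0.005  # 25% of the 20 ms interval
  expect_error(preprocess_accel(accel_stream(tj, a$ax_g, a$ay_g, a$az_g)),
               "jitter")
})

test_that("window segmentation matches brute-force enumeration", {
  one_sec <- make_stream(rep(0, 50), 1, 0)  # 1.0 s at 50 Hz
  w <- make_windows(one_sec)
  expect_identical(nrow(w$idx), 15L)  # floor((50-15)/2.5)+1
  expect_identical(ncol(w$idx), 15L)
  exact <- make_stream(rep(0, 15), 1, 0)   # 300 ms exactly
  expect_identical(nrow(make_windows(exact)$idx), 1L)
  short <- make_stream(rep(0, 14), 1, 0)   # 299 ms: partial discarded
  expect_identical(nrow(make_windows(short)$idx), 0L)
  set.seed(3)
  for (n in sample(15:400, 8)) {
    s <- make_stream(rnorm(n), 1, 0)
    expect_identical(nrow(make_windows(s)$idx),
                     count_windows_bruteforce(n, 15, 2.5),
                     info = paste("n =", n))
  }
  expect_error(make_windows(one_sec, length_ms = 40, hop_ms = 50))
})

test_that("window features match a brute-force recomputation of the formulas", {
  cal <- calibrate_accel(make_stream(rep(0, 1501), 1, 0))  # exact (0,1,0)
  # constant window at the exact baseline
  const <- make_stream(rep(0, 15), 1, 0)
  f <- extract_features(const, cal)
  expect_equal(unname(f[c("x_mean", "y_mean", "z_mean")]), c(0, 1, 0))
  expect_equal(unname(f[c("x_energy", "y_energy", "z_energy")]), c(0, 1, 0))
  expect_equal(unname(f[grep("dyn_var|stat_var|kurtosis|skewness", names(f))]),
               rep(0, 12))
  # constant window off the baseline: static variation reads the offset
  off <- make_stream(rep(0, 15), 0.8, 0)
  expect_equal(unname(extract_features(off, cal)["y_stat_var"]), 0.2)
  # 0.1 g, 5 Hz sine on x: compare against independent per-formula oracle
  t <- (0:14) / 50
  x <- 0.1 * sin(2 * pi * 5 * t)
  sine <- accel_stream(t, x, rep(1, 15), rep(0, 15))
  f <- extract_features(sine, cal)
  mu <- mean(x); cent <- x - mu
  m2 <- mean(cent^2); m3 <- mean(cent^3); m4 <- mean(cent^4)
  expect_equal(unname(f["x_mean"]), mu)
  expect_equal(unname(f["x_energy"]), mean(x^2))
  expect_equal(unname(f["x_dyn_var"]), sqrt(m2))
  expect_equal(unname(f["x_stat_var"]), abs(mu - cal$baseline[["x"]]))
  expect_equal(unname(f["x_skewness"]), m3 / m2^1.5)
  expect_equal(unname(f["x_kurtosis"]), m4 / m2^2 - 3)
  expect_error(extract_features(make_stream(c(0, 0), 1, 0), cal), "3 samples")
})

test_that("features obey translation and scaling laws", {
  cal <- shared_calibration()
  set.seed(21)
  t <- (0:14) / 50
  base <- accel_stream(t, rnorm(15, 0, 0.1), rnorm(15, 1, 0.1),
                       rnorm(15, 0, 0.1))
  f0 <- extract_features(base, cal)
  c_ <- 0.3
  shifted <- accel_stream(t, base$ax_g + c_, base$ay_g, base$az_g)
  f1 <- extract_features(shifted, cal)
  expect_equal(unname(f1["x_mean"]), unname(f0["x_mean"]) + c_)
  expect_equal(unname(f1["x_stat_var"]),
               abs(unname(f0["x_mean"]) + c_ - cal$baseline[["x"]]))
  for (nm in c("x_dyn_var", "x_skewness", "x_kurtosis"))
    expect_equal(unname(f1[nm]), unname(f0[nm]), tolerance = 1e-12)
  s_ <- 1.7
  scaled <- accel_stream(t, base$ax_g * s_, base$ay_g, base$az_g)
  f2 <- extract_features(scaled, cal)
  expect_equal(unname(f2["x_mean"]), unname(f0["x_mean"]) * s_)
  expect_equal(unname(f2["x_dyn_var"]), unname(f0["x_dyn_var"]) * s_)
  expect_equal(unname(f2["x_energy"]), unname(f0["x_energy"]) * s_^2)
  expect_equal(unname(f2["x_skewness"]), unname(f0["x_skewness"]),
               tolerance = 1e-9)
  expect_equal(unname(f2["x_kurtosis"]), unname(f0["x_kurtosis"]),
               tolerance = 1e-9)
})

test_that("windowed stream features agree with per-window extraction", {
  cal <- shared_calibration()
  acc <- gen_accel("walk_low", 3, seed = 9)
  filt <- preprocess_accel(acc)
  wf <- wearable_features(acc, cal)
  w <- make_windows(filt)
  i <- c(1, nrow(w$idx) %/% 2, nrow(w$idx))
  for (k in i) {
    win <- accel_stream(filt$t_s[w$idx[k, ]], filt$ax_g[w$idx[k, ]],
                        filt$ay_g[w$idx[k, ]], filt$az_g[w$idx[k, ]])
    expect_equal(unname(wf$features[k, ]),
                 unname(extract_features(win, cal)), tolerance = 1e-12)
  }
  expect_identical(colnames(wf$features), wearable_feature_names())
})

test_that("window labels reduce to 1 Hz ticks by majority with recency ties", {
  t20 <- seq(0.05, 1.00, by = 0.05)
  same <- ticks_from_windows(t20, rep("standing", 20))
  expect_identical(same$label, "standing")
  mix <- ticks_from_windows(t20, rep(c("standing", "sitting"),
                                     times = c(11, 9)))
  expect_identical(mix$label, "standing")
  tie <- ticks_from_windows(t20, c(rep("standing", 10), rep("sitting", 10)))
  expect_identical(tie$label, "sitting")  # tie: most recent window wins
  tie2 <- ticks_from_windows(t20, c(rep("sitting", 10), rep("standing", 10)))
  expect_identical(tie2$label, "standing")
  two <- ticks_from_windows(c(t20, t20 + 1), rep(c("lying", "bending"),
                                                 each = 20))
  expect_identical(two$label, c("lying", "bending"))
  expect_equal(two$t_s, c(0, 1))
})

test_that("wearable classifier separates classes and enforces dimension", {
  sep <- separable_xy(40, 18, seed = 5)
  m <- har_fit(sep$x, sep$y,
               classifier_config("rf", n_estimators = 29, max_depth = 26),
               seed = 6)
  expect_identical(predict(m, sep$x), sep$y)  # separable: 100% self-accuracy
  expect_error(predict(m, sep$x[, 1:17]), "dimension mismatch")
})

test_that("accelerometer streams round-trip through CSV", {
  acc <- gen_accel("walk_medium", 2, seed = 31)
  path <- withr::local_tempfile(fileext = ".csv")
  write_accel(acc, path)
  back <- read_accel(path)
  expect_equal(back$ay_g, acc$ay_g, tolerance = 1e-6)
  expect_equal(back$t_s, acc$t_s, tolerance = 1e-9)
})
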