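test_that("accelerometer generator reproduces class orientation and step frequency", {
  # standing: per-axis means close to (0, 1, 0) g
  st <- gen_accel("standing", 10, seed = 51)
  n <- nrow(st); sd3 <- 3 * 0.015 / sqrt(n)
  expect_lt(abs(mean(st$ax_g) - 0), sd3)
  expect_lt(abs(mean(st$ay_g) - 1), sd3)
  expect_lt(abs(mean(st$az_g) - 0), sd3)
  # walking: periodogram peak at the configured step frequency
  for (cl in c("walk_very_low", "walk_medium")) {
    mod <- accel_class_models()
    f0 <- mod$step_hz[mod$label == cl]
    wk <- gen_accel(cl, 30, seed = 52)
    y <- wk$ay_g - mean(wk$ay_g)
    sp <- stats::spec.pgram(ts(y, frequency = 50), plot = FALSE, taper = 0)
    expect_lt(abs(sp$freq[which.max(sp$spec)] - f0), 0.2)
  }
  expect_error(gen_accel("jogging", 5, seed = 1), "jogging")
  expect_true(all(abs(gen_accel("walk_medium", 5, seed = 3)$ay_g) <= 2))
})

test_that("generators are pure functions of their seed", {
  a1 <- gen_accel("walk_low", 5, seed = 61)
  a2 <- gen_accel("walk_low", 5, seed = 61)
  expect_identical(a1, a2)
  subj <- subject_profile("s", weight = 70, height = 1.7)
  l1 <- gen_landmarks("sitting", 3, subj, seed = 62)
  l2 <- gen_landmarks("sitting", 3, subj, seed = 62)
  expect_identical(l1, l2)
  # different seeds give disjoint noise realisations
  a3 <- gen_accel("walk_low", 5, seed = 63)
  expect_false(any(a3$ay_g == a1$ay_g))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gen_accel("standing", 1, seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("skeleton templates satisfy their geometric invariants", {
  for (s in c(1.5, 1.7, 1.9)) {
    tpl <- skeleton_template("standing", s)
    extent <- max(tpl[, 2]) - min(tpl[, 2])
    expect_lt(abs(extent - s) / s, 0.05)  # standing extent ~ stature
  }
  ly <- skeleton_template("lying", 1.7)
  expect_lt(max(ly[, 2]) - min(ly[, 2]), 0.5)
  si <- skeleton_template("sitting", 1.7)
  expect_lt(si[24, 2], skeleton_template("standing", 1.7)[24, 2])  # hips drop
})

test_that("noise-free landmark frames reproduce template midpoints through the camera", {
  subj <- subject_profile("s", weight = 70, height = 1.7)
  cfg <- sim_config(depth_noise = 0, pixel_noise = 0, occlusion_rate = 0)
  frames <- gen_landmarks("standing", 1, subj, cfg, seed = 71)
  f3d <- frame3d(frames, 1, cfg$intrinsics)
  got <- reduce_landmarks(f3d, subj$height)
  tpl <- skeleton_template("standing", subj$height)
  # camera frame: x right, y down from 1.43 m, z away from the camera
  for (p in list(c("A", 9, 10), c("C", 23, 24), c("D", 25, 26))) {
    mid <- (tpl[as.numeric(p[2]) + 1, ] + tpl[as.numeric(p[3]) + 1, ]) / 2
    expect_equal(got[[paste0(p[1], "y")]], cfg$camera_height - mid[[2]],
                 tolerance = 1e-6)
  }
  # depths positive and near the configured subject distance
  expect_true(all(abs(got[c("Az", "Cz", "Dz")] - 3) < 0.5))
})

test_that("full occlusion of the hip landmarks blocks reduction every frame", {
  subj <- subject_profile("s", weight = 70, height = 1.7)
  cfg <- sim_config(occlusion_rate = 1, occlusion_landmarks = c(23, 24),
                    occlusion_classes = "sitting")
  frames <- gen_landmarks("sitting", 3, subj, cfg, seed = 73)
  for (i in seq_along(frames$t))
    expect_error(reduce_landmarks(frame3d(frames, i, cfg$intrinsics),
                                  subj$height),
                 class = "occlusion_error")
})

test_that("protocol executions carry exact per-second ground truth", {
  subj <- study_subjects()[[2]]
  p1 <- default_protocols()$protocol1
  st <- run_protocol(p1, subj, seed = 81)
  expect_identical(nrow(st$labels), 420L)
  expect_identical(unique(st$labels$label[1:30]), "walk_very_low")
  hist <- table(st$labels$label)
  seg <- tapply(p1$segments$duration_s, p1$segments$activity, sum)
  expect_equal(as.numeric(hist[names(seg)]), as.numeric(seg))
  expect_equal(nrow(st$accel), 420 * 50)
  expect_equal(length(st$frames$t), 420 * 30)
  p3 <- default_protocols()$protocol3
  expect_identical(nrow(run_protocol(p3, subj, seed = 82)$labels), 360L)
})

test_that("training corpora are balanced, aligned and seed-distinct", {
  corpus <- shared_corpus()
  expect_identical(dim(corpus$fused), c(420L, 28L))
  expect_identical(dim(corpus$wearable), c(420L, 18L))
  expect_identical(dim(corpus$ambient), c(420L, 10L))
  expect_true(all(table(corpus$labels) == 60))
  expect_identical(unname(corpus$fused[, 1:18]), unname(corpus$wearable))
  other <- gen_training_corpus(12, seed = 999)
  shared_rows <- intersect(apply(other$fused, 1, paste, collapse = ","),
                           apply(corpus$fused, 1, paste, collapse = ","))
  expect_length(shared_rows, 0)
  expect_error(gen_training_corpus(5, seed = 1), "at least 10")
})

test_that("a noise-free pipeline reproduces the ground-truth label stream", {
  cfg <- sim_config(depth_noise = 0, pixel_noise = 0, tremor_scale = 0,
                    occlusion_rate = 0)
  subj <- study_subjects()[[4]]
  st <- run_protocol(default_protocols()$protocol3, subj,
                     config = cfg, seed = 91)
  pr <- pipeline_ticks(st, shared_models())
  truth <- protocol_labels(st$protocol)
  agree <- mean(pr$ticks$label == truth[pr$ticks$t_s + 1])
  expect_gte(agree, 0.99)
})

test_that("stronger sensor noise monotonically degrades corpus separability", {
  accs <- vapply(c(1, 6, 14), function(scale) {
    cfg <- sim_config(tremor_scale = scale, depth_noise = 0.01 * scale,
                      pixel_noise = 0.5 * scale)
    corpus <- gen_training_corpus(20, config = cfg, seed = 77)
    cv <- har_cv(corpus$fused, corpus$labels, classifier_config("rf"),
                 seed = 78)
    cv$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("simulated sessions write a complete text bundle", {
  subj <- subject_profile("s", weight = 70, height = 1.7)
  st <- run_protocol(protocol("mini", c("standing", "walk_low"), c(2, 2)),
                     subj, seed = 95)
  dir <- withr::local_tempdir()
  write_simulation(st, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "accel.csv", "landmarks.jsonl", "intrinsics.json", "labels.csv",
    "manifest.json")))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_identical(man$protocol, "mini")
  expect_equal(man$seed, 95)
  acc <- read_accel(file.path(dir, "accel.csv"))
  expect_equal(nrow(acc), nrow(st$accel))
})
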