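test_that("feature fusion concatenates wearable-first and slices back exactly", {
  w <- setNames(rnorm(18), wearable_feature_names())
  a <- setNames(rnorm(10), ambient_feature_names())
  f <- fuse_features(w, a)
  expect_length(f, 28)
  expect_identical(names(f), fused_feature_names())
  expect_identical(unname(f[1:18]), unname(w))    # bit-exact recovery
  expect_identical(unname(f[19:28]), unname(a))
  z <- fuse_features(rep(0, 18), rep(0, 10))
  expect_identical(unname(z), rep(0, 28))
  expect_error(fuse_features(rep(0, 17), rep(0, 10)), "18 wearable")
  expect_error(fuse_features(NULL, rep(0, 10)), "fallback")
  # matrix form
  W <- matrix(rnorm(36), 2); A <- matrix(rnorm(20), 2)
  FM <- fuse_features(W, A)
  expect_identical(dim(FM), c(2L, 28L))
  expect_identical(unname(FM[, 1:18]), unname(W))
})

test_that("stream alignment pairs ticks within half a tick period", {
  full <- align_streams(0:9, 0:9)
  expect_true(all(full$modality == "both"))
  expect_identical(full$i_a, full$i_w)
  # ambient missing seconds 3-5 (occlusion): flagged wearable-only
  gap <- align_streams(0:9, setdiff(0:9, 3:5))
  expect_identical(gap$modality[gap$t %in% 3:5], rep("wearable_only", 3))
  expect_identical(sum(gap$modality == "both"), 7L)
  # clocks offset by 0.4 s: nearest-neighbour pairing within 0.5 s
  off <- align_streams(0:9, 0:9 + 0.4)
  expect_true(all(off$modality == "both"))
  expect_identical(off$i_a, off$i_w)
  # clocks offset by 0.6 s: each wearable tick pairs with the previous
  # ambient tick (0.4 s away); only the endpoints stay single-modality
  far <- align_streams(0:4, 0:4 + 0.6)
  expect_identical(far$modality[far$i_w %in% 1], "wearable_only")
  expect_identical(sum(far$modality == "both"), 4L)
  expect_identical(sum(far$modality == "ambient_only"), 1L)
  none <- align_streams(numeric(0), numeric(0))
  expect_identical(nrow(none), 0L)
})

test_that("cross-validation rotates folds with every sample tested once", {
  corpus <- shared_corpus()
  cv <- har_cv(corpus$fused, corpus$labels, classifier_config("rf"),
               seed = 201)
  # fold assignment partitions the data
  expect_identical(sort(unique(cv$folds)), 1:10)
  expect_identical(length(cv$folds), length(corpus$labels))
  # every sample appears in the test role exactly once across rotations
  expect_identical(sum(cv$confusion), length(corpus$labels))
  # fold sizes balanced within one per class
  per_fold <- table(cv$folds, corpus$labels)
  expect_lte(max(per_fold) - min(per_fold), 1)
  expect_equal(cv$accuracy, cm_accuracy(cv$confusion), tolerance = 1e-12)
})

test_that("cross-validation is deterministic under a fixed seed", {
  corpus <- shared_corpus()
  sub <- c(which(corpus$labels == "standing"), which(corpus$labels == "lying"),
           which(corpus$labels == "walk_medium"))
  for (kind in c("rf", "svm", "knn")) {
    cv1 <- har_cv(corpus$fused[sub, ], corpus$labels[sub],
                  classifier_config(kind), seed = 99)
    cv2 <- har_cv(corpus$fused[sub, ], corpus$labels[sub],
                  classifier_config(kind), seed = 99)
    expect_identical(unclass(cv1$confusion), unclass(cv2$confusion))
    expect_identical(cv1$fold_accuracy, cv2$fold_accuracy)
  }
})

test_that("cross-validation demands at least one sample per class per fold", {
  sep <- separable_xy(40, 28, seed = 7)
  y <- sep$y; y[1:5] <- "bending"  # 5 samples: fewer than 10 folds
  expect_error(har_cv(sep$x, y, classifier_config("rf"), seed = 1),
               "bending")
  cv <- har_cv(sep$x, sep$y, classifier_config("rf"), seed = 1)
  expect_equal(cv$mean_accuracy, 1.0)  # perfectly separable data
})

test_that("fused accuracy is not materially below the best single branch", {
  corpus <- shared_corpus()
  cvf <- har_cv(corpus$fused, corpus$labels, classifier_config("rf"),
                seed = 301)
  cvw <- har_cv(corpus$wearable, corpus$labels,
                classifier_config("rf", n_estimators = 29, max_depth = 26),
                seed = 301)
  cva <- har_cv(corpus$ambient, corpus$labels,
                classifier_config("svm", kernel_coef = 0.61), seed = 301)
  expect_gte(cvf$mean_accuracy,
             max(cvw$mean_accuracy, cva$mean_accuracy) - 0.02)
  # both branches individually strong on the packaged corpus
  expect_gte(cvw$mean_accuracy, 0.90)
  expect_gte(cva$mean_accuracy, 0.90)
})

test_that("tick classification falls back by available modality", {
  models <- shared_models()
  corpus <- shared_corpus()
  i <- which(corpus$labels == "walk_medium")[1]
  w <- corpus$wearable[i, ]; a <- corpus$ambient[i, ]
  both <- classify_fused(w, a, models)
  expect_identical(both$provenance, "fused")
  expect_true(both$label %in% activity_classes())
  wonly <- classify_fused(w, NULL, models)
  expect_identical(wonly$provenance, "wearable")
  aonly <- classify_fused(NULL, a, models)
  expect_identical(aonly$provenance, "ambient")
  occluded <- classify_fused(w, rep(NA_real_, 10), models)
  expect_identical(occluded$provenance, "wearable")
  gap <- classify_fused(NULL, NULL, models)
  expect_identical(gap$provenance, "gap")
  expect_true(is.na(gap$label))
})

test_that("model bundles persist with feature orderings and configs", {
  models <- shared_models()
  path <- withr::local_tempfile(fileext = ".rds")
  save_har_models(models, path)
  back <- load_har_models(path)
  expect_identical(back$fused$feature_names, fused_feature_names())
  expect_identical(back$wearable$feature_names, wearable_feature_names())
  expect_identical(back$ambient$feature_names, ambient_feature_names())
  expect_identical(back$ambient$config$kernel_coef, 0.61)
  expect_identical(back$wearable$config$n_estimators, 29)
  corpus <- shared_corpus()
  expect_identical(predict(back$fused, corpus$fused[1:5, ]),
                   predict(models$fused, corpus$fused[1:5, ]))
})

test_that("classifier configs carry the fixed hyperparameter defaults", {
  rf <- classifier_config("rf")
  expect_identical(rf$n_estimators, 25)
  expect_identical(rf$max_depth, 30)
  svm <- classifier_config("svm")
  expect_identical(svm$degree, 3)
  expect_identical(svm$max_iter, 50)
  knn <- classifier_config("knn")
  expect_identical(knn$n_neighbors, 13)
  expect_identical(knn$minkowski_p, 2)
  expect_error(classifier_config("rf", bogus = 1), "unknown")
})
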