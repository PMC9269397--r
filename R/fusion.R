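#' Names of the 28 fused features, in declared order
#'
#' Wearable block first (18 features), ambient block second (10 features).
#' The ordering is fixed and embedded in persisted models.
#'
#' @return Character vector of length 28.
#' @export
fused_feature_names <- function() {
  c(wearable_feature_names(), ambient_feature_names())
}

#' Feature-level fusion of the two branches
#'
#' Concatenates a wearable feature vector (or matrix) and an ambient one,
#' wearable block first, giving the 28-dimensional fused representation.
#'
#' @param w Wearable features: length-18 vector or n x 18 matrix.
#' @param a Ambient features: length-10 vector or n x 10 matrix.
#' @return Length-28 named vector, or n x 28 matrix.
#' @export
#' @examples
#' fuse_features(rep(0, 18), rep(0, 10))
fuse_features <- function(w, a) {
  if (is.null(w) || is.null(a))
    stop("both modalities must be present; use the single-branch fallback")
  if (is.null(dim(w)) && is.null(dim(a))) {
    if (length(w) != 18L || length(a) != 10L)
      stop("expected 18 wearable and 10 ambient features")
    return(stats::setNames(c(w, a), fused_feature_names()))
  }
  w <- as.matrix(w); a <- as.matrix(a)
  if (ncol(w) != 18L || ncol(a) != 10L || nrow(w) != nrow(a))
    stop("expected aligned n x 18 and n x 10 matrices")
  out <- cbind(w, a)
  colnames(out) <- fused_feature_names()
  out
}

#' Align two timestamped tick sequences on a common clock
#'
#' Pairs records whose timestamps agree within half a tick period;
#' seconds carried by only one modality are flagged single-modality.
#'
#' @param t_w,t_a Timestamps (s) of the wearable and ambient records.
#' @param rate Tick rate in Hz (default 1); the pairing tolerance is half
#'   a tick, `1/(2*rate)` s.
#' @return A data.frame with columns `t` (the wearable time where paired,
#'   otherwise the lone modality's time), `i_w`, `i_a` (indices into the
#'   input sequences, NA where absent) and `modality` ("both",
#'   "wearable_only", "ambient_only").
#' @export
align_streams <- function(t_w, t_a, rate = 1) {
  tol <- 1 / (2 * rate)
  used_a <- rep(FALSE, length(t_a))
  i_a_of_w <- rep(NA_integer_, length(t_w))
  for (i in seq_along(t_w)) {
    if (!length(t_a)) break
    d <- abs(t_a - t_w[i])
    d[used_a] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) { i_a_of_w[i] <- j; used_a[j] <- TRUE }
  }
  out <- data.frame(t = t_w, i_w = seq_along(t_w), i_a = i_a_of_w,
                    modality = ifelse(is.na(i_a_of_w), "wearable_only", "both"),
                    stringsAsFactors = FALSE)
  lone_a <- which(!used_a)
  if (length(lone_a)) {
    out <- rbind(out, data.frame(t = t_a[lone_a], i_w = NA_integer_,
                                 i_a = lone_a, modality = "ambient_only",
                                 stringsAsFactors = FALSE))
    out <- out[order(out$t), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Classify one tick from whatever modalities are present
#'
#' Both branches present: the fused model on the concatenated 28-vector.
#' One branch missing (e.g. camera occlusion): the corresponding
#' single-branch fallback model. Neither present: a gap (NA label).
#'
#' @param w Wearable 18-feature vector, or NULL.
#' @param a Ambient 10-feature vector, or NULL.
#' @param models A model bundle from [train_har_models()].
#' @return List with `label` (activity or NA for a gap) and `provenance`
#'   ("fused", "wearable", "ambient", "gap").
#' @export
classify_fused <- function(w, a, models) {
  if (!is.null(a) && anyNA(a)) a <- NULL
  if (!is.null(w) && anyNA(w)) w <- NULL
  if (!is.null(w) && !is.null(a))
    list(label = predict(models$fused, fuse_features(w, a)),
         provenance = "fused")
  else if (!is.null(w))
    list(label = predict(models$wearable, w), provenance = "wearable")
  else if (!is.null(a))
    list(label = predict(models$ambient, a), provenance = "ambient")
  else list(label = NA_character_, provenance = "gap")
}

#' Train the fused and fallback models
#'
#' Fits the fused 28-feature classifier together with the two
#' single-branch fallback models used when a modality is missing: the
#' wearable random forest (29 trees, depth cap 26) and the ambient
#' polynomial SVM (degree 3, kernel coefficient 0.61).
#'
#' @param corpus A labelled corpus from [gen_training_corpus()] (or any
#'   list with `wearable`, `ambient`, `fused` matrices and `labels`).
#' @param fused_config [classifier_config()] for the fused model (default
#'   rf, 25 trees, depth cap 30).
#' @param seed Integer seed.
#' @return A model bundle: list of class `har_models` with `fused`,
#'   `wearable`, `ambient` models plus `seed`.
#' @export
train_har_models <- function(corpus, fused_config = classifier_config("rf"),
                             seed = 1) {
  structure(list(
    fused = har_fit(corpus$fused, corpus$labels, fused_config,
                    seed = child_seed(seed, 1)),
    wearable = har_fit(corpus$wearable, corpus$labels,
                       classifier_config("rf", n_estimators = 29,
                                         max_depth = 26),
                       seed = child_seed(seed, 2)),
    ambient = har_fit(corpus$ambient, corpus$labels,
                      classifier_config("svm", kernel_coef = 0.61),
                      seed = child_seed(seed, 3)),
    seed = seed), class = "har_models")
}

#' @export
print.har_models <- function(x, ...) {
  cat("Model bundle:\n  fused:    "); print(x$fused)
  cat("  wearable: "); print(x$wearable)
  cat("  ambient:  "); print(x$ambient)
  invisible(x)
}

#' Save / load a model bundle
#'
#' The bundle (fused + fallback models, feature orderings, scaler
#' statistics, configs and seed) is persisted with R's native serialiser.
#'
#' @param models A [train_har_models()] bundle.
#' @param path File path.
#' @export
save_har_models <- function(models, path) {
  saveRDS(models, path)
  invisible(path)
}

#' @rdname save_har_models
#' @export
load_har_models <- function(path) readRDS(path)

# ---- end-to-end inference ---------------------------------------------------

#' Run the full two-branch pipeline on a multimodal stream
#'
#' Extracts windowed wearable features and per-frame ambient features,
#' fuses them per wearable window (nearest ambient frame within half a
#' frame period), classifies every window -- falling back to the
#' single-branch model when the other modality is missing or occluded --
#' and majority-votes window labels into 1 Hz classification ticks.
#'
#' @param stream A multimodal stream from [run_protocol()] (or a list
#'   with `accel`, `frames`, `subject`, `config`).
#' @param models A [train_har_models()] bundle.
#' @param calibration A [calibrate_accel()] result; by default a synthetic
#'   standing calibration bout generated from the stream's config.
#' @return A list of class `pipeline_result`: `ticks` (a [tick_stream()]),
#'   `provenance` (per-tick majority provenance), `window_labels`.
#' @export
pipeline_ticks <- function(stream, models, calibration = NULL) {
  cfg <- stream$config
  if (is.null(calibration)) {
    cal_stream <- gen_accel("standing", 31, cfg,
                            seed = child_seed(stream$seed %||% 1, 99))
    calibration <- calibrate_accel(cal_stream)
  }
  wf <- wearable_features(stream$accel, calibration)
  af <- ambient_features(stream$frames, stream$subject$height, cfg$intrinsics)
  n <- length(wf$t_end)
  labels <- character(n); prov <- character(n)
  # nearest ambient frame per window end, NA when too far or occluded
  fidx <- findInterval(wf$t_end, af$t)
  half <- if (length(af$t) > 1) stats::median(diff(af$t)) / 2 else Inf
  amb_ok <- logical(n); amb_row <- integer(n)
  for (i in seq_len(n)) {
    j <- fidx[i]
    cand <- c(j, j + 1L)
    cand <- cand[cand >= 1L & cand <= length(af$t)]
    if (length(cand)) {
      j <- cand[which.min(abs(af$t[cand] - wf$t_end[i]))]
      if (abs(af$t[j] - wf$t_end[i]) <= half + 1e-9 &&
          !anyNA(af$features[j, ])) {
        amb_ok[i] <- TRUE; amb_row[i] <- j
      }
    }
  }
  # batch the three prediction paths for speed
  both <- which(amb_ok)
  wonly <- which(!amb_ok)
  if (length(both)) {
    fx <- fuse_features(wf$features[both, , drop = FALSE],
                        af$features[amb_row[both], , drop = FALSE])
    labels[both] <- predict(models$fused, fx)
    prov[both] <- "fused"
  }
  if (length(wonly)) {
    labels[wonly] <- predict(models$wearable,
                             wf$features[wonly, , drop = FALSE])
    prov[wonly] <- "wearable"
  }
  ticks <- ticks_from_windows(wf$t_end, labels)
  sec <- floor(wf$t_end - 1e-9)
  prov_tick <- vapply(ticks$t_s, function(s) {
    tb <- table(prov[sec == s])
    names(tb)[which.max(tb)]
  }, character(1))
  structure(list(ticks = ticks, provenance = prov_tick,
                 window_labels = data.frame(t_end = wf$t_end, label = labels,
                                            provenance = prov,
                                            stringsAsFactors = FALSE)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d ticks (%s)\n", nrow(x$ticks),
              paste(names(table(x$provenance)), table(x$provenance),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Estimate energy expenditure of a multimodal stream
#'
#' Convenience wrapper: [pipeline_ticks()] followed by [quantify_ee()]
#' with the stream subject's weight.
#'
#' @inheritParams pipeline_ticks
#' @param table A [met_table()].
#' @return An `ee_result` (see [quantify_ee()]) with the pipeline result
#'   attached as attribute `pipeline`.
#' @export
estimate_ee <- function(stream, models, calibration = NULL,
                        table = met_table()) {
  pr <- pipeline_ticks(stream, models, calibration)
  res <- quantify_ee(pr$ticks, stream$subject$weight, table)
  attr(res, "pipeline") <- pr
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
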