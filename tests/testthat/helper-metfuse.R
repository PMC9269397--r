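# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# small labelled corpus + trained model bundle shared by classifier tests
shared_corpus <- function() {
  if (is.null(.fixtures$corpus))
    .fixtures$corpus <- gen_training_corpus(60, seed = 101)
  .fixtures$corpus
}

shared_models <- function() {
  if (is.null(.fixtures$models))
    .fixtures$models <- train_har_models(shared_corpus(), seed = 102)
  .fixtures$models
}

# an ideal-wear calibration from a synthetic standing bout
shared_calibration <- function() {
  if (is.null(.fixtures$calibration))
    .fixtures$calibration <-
      calibrate_accel(gen_accel("standing", 31, seed = 103))
  .fixtures$calibration
}

# two tiny, perfectly separable synthetic classes in d dimensions
separable_xy <- function(n = 40, d = 18, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n / 2 * d, 0, 0.1), ncol = d),
             matrix(rnorm(n / 2 * d, 5, 0.1), ncol = d))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, y = rep(c("standing", "sitting"), each = n / 2))
}

# brute-force window-count oracle: slide a window sample-by-sample
count_windows_bruteforce <- function(n, n_samp, hop_samp) {
  if (n < n_samp) return(0L)
  starts <- unique(as.integer(floor(seq(1, n - n_samp + 1, by = hop_samp))))
  length(starts)
}
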