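#' Construct an accelerometer stream
#'
#' Tri-axial chest-worn accelerometer samples in gravitational units,
#' nominally 50 Hz, full scale +/- 2 g. The trunk-aligned axis is y: a
#' subject standing still reads approximately (0, +1, 0) g.
#'
#' @param t Sample times (s), strictly increasing.
#' @param ax,ay,az Per-axis acceleration in g.
#' @return A data.frame of class `accel_stream` with columns `t_s`, `ax_g`,
#'   `ay_g`, `az_g`.
#' @export
accel_stream <- function(t, ax, ay, az) {
  n <- length(t)
  if (any(lengths(list(ax, ay, az)) != n)) stop("axis lengths differ from 't'")
  if (n > 1L && any(diff(t) <= 0)) stop("samples must be ordered by time")
  structure(data.frame(t_s = as.numeric(t), ax_g = as.numeric(ax),
                       ay_g = as.numeric(ay), az_g = as.numeric(az)),
            class = c("accel_stream", "data.frame"))
}

#' Read / write accelerometer streams as CSV
#'
#' Columns `t_s,ax_g,ay_g,az_g`, header mandatory. Gravitational-unit
#' conversion is assumed already applied upstream.
#'
#' @param x An [accel_stream()].
#' @param path File path.
#' @export
write_accel <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("t_s", "ax_g", "ay_g", "az_g")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_accel
#' @export
read_accel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "ax_g", "ay_g", "az_g")
  if (!all(need %in% names(df)))
    stop("accelerometer CSV must have columns t_s, ax_g, ay_g, az_g")
  accel_stream(df$t_s, df$ax_g, df$ay_g, df$az_g)
}

#' Calibrate the wearable device
#'
#' Memorises the static per-axis acceleration of a motionless standing
#' subject. Calibration succeeds when the per-axis mean over the
#' calibration interval lies within `tolerance` of the expected standing
#' orientation (0, +1, 0) g on every axis; failure signals the device is
#' worn incorrectly and blocks feature extraction.
#'
#' @param samples An [accel_stream()] spanning at least `duration` seconds.
#' @param duration Calibration duration in seconds (default 30).
#' @param tolerance Per-axis tolerance in g (default 0.2).
#' @param expected Expected standing baseline, default `c(0, 1, 0)` g.
#' @return An object of class `accel_calibration`: list with `baseline`
#'   (named x/y/z means in g), `ok`, `message`.
#' @export
calibrate_accel <- function(samples, duration = 30, tolerance = 0.2,
                            expected = c(0, 1, 0)) {
  span <- diff(range(samples$t_s))
  if (nrow(samples) < 2L || span < duration - 1e-9)
    stop(sprintf("calibration needs >= %g s of samples, got %.2f s",
                 duration, if (nrow(samples)) span else 0))
  keep <- samples$t_s <= samples$t_s[1] + duration
  baseline <- c(x = mean(samples$ax_g[keep]),
                y = mean(samples$ay_g[keep]),
                z = mean(samples$az_g[keep]))
  dev <- abs(baseline - expected)
  ok <- all(dev <= tolerance)
  msg <- if (ok) "calibration ok" else
    sprintf("device worn incorrectly: axis deviation (%.2f, %.2f, %.2f) g exceeds %.2f g",
            dev[1], dev[2], dev[3], tolerance)
  structure(list(baseline = baseline, ok = ok, message = msg,
                 tolerance = tolerance, expected = expected),
            class = "accel_calibration")
}

#' @export
print.accel_calibration <- function(x, ...) {
  cat(sprintf("Accelerometer calibration [%s]: baseline (%.3f, %.3f, %.3f) g\n",
              if (x$ok) "ok" else "FAILED",
              x$baseline[1], x$baseline[2], x$baseline[3]))
  if (!x$ok) cat(" ", x$message, "\n")
  invisible(x)
}

# ---- FIR pre-processing -----------------------------------------------------

# 9-tap (order 8) Hamming-window linear-phase low-pass, cutoff `cutoff` Hz
# at sampling rate `fs`, coefficients normalized to exact unity DC gain.
fir_lowpass <- function(order = 8, cutoff = 10, fs = 50) {
  h <- signal::fir1(order, cutoff / (fs / 2), type = "low")
  as.numeric(h) / sum(h)
}

#' Frequency response magnitude of the pre-processing filter
#'
#' @param f Frequencies in Hz.
#' @param order Filter order (taps = order + 1).
#' @param cutoff Cutoff frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @return Magnitude response |H(f)| at each frequency.
#' @export
fir_response <- function(f, order = 8, cutoff = 10, fs = 50) {
  h <- fir_lowpass(order, cutoff, fs)
  k <- seq_along(h) - 1
  vapply(f, function(fi) Mod(sum(h * exp(-2i * pi * fi * k / fs))), numeric(1))
}

#' Low-pass pre-processing of an accelerometer stream
#'
#' Filters each axis with a linear-phase FIR low-pass (order 8, 10 Hz
#' cutoff by default, unity DC gain). The filter is applied single-pass
#' with reflected edge padding and the linear-phase group delay removed,
#' so the output aligns with the input timestamps and has the designed
#' magnitude response.
#'
#' @param samples An [accel_stream()] at uniform sampling rate.
#' @param order,cutoff FIR design parameters.
#' @param max_jitter Maximum tolerated relative deviation of sample
#'   intervals from their median (default 0.1).
#' @return An [accel_stream()] of identical length and timestamps.
#' @export
preprocess_accel <- function(samples, order = 8, cutoff = 10,
                             max_jitter = 0.1) {
  n <- nrow(samples)
  if (n < 2L) return(samples)
  dt <- diff(samples$t_s)
  md <- stats::median(dt)
  if (any(abs(dt - md) > max_jitter * md))
    stop("non-uniform sampling: timestamp jitter exceeds ",
         max_jitter * 100, "% of the median interval")
  fs <- 1 / md
  h <- fir_lowpass(order, cutoff, fs)
  delay <- order / 2  # integer for even order
  filt1 <- function(x) {
    nx <- length(x); p <- length(h)
    li <- pmin(pmax(seq(p + 1, 2), 1), nx)       # reflected left pad
    ri <- pmin(pmax(seq(nx - 1, nx - p), 1), nx)  # reflected right pad
    xe <- c(x[li], x, x[ri])
    y <- stats::filter(xe, h, method = "convolution", sides = 1)
    as.numeric(y[(p + 1 + delay):(p + delay + nx)])
  }
  accel_stream(samples$t_s, filt1(samples$ax_g), filt1(samples$ay_g),
               filt1(samples$az_g))
}

# ---- sliding windows --------------------------------------------------------

#' Sliding-window segmentation of an accelerometer stream
#'
#' Cuts the stream into fixed-length windows advanced by a fixed hop
#' (defaults 300 ms length, 50 ms hop: 15-sample windows advancing by
#' 2.5 samples' worth of time at 50 Hz). Windows are defined on the time
#' axis; a trailing partial window is discarded.
#'
#' @param samples An [accel_stream()].
#' @param length_ms Window length in ms.
#' @param hop_ms Window hop in ms (`length_ms >= hop_ms > 0`).
#' @return List with `idx` (n_win x n_samp integer matrix of sample
#'   indices), `t_end` (window end times, s). Zero windows gives
#'   zero-row `idx`.
#' @export
make_windows <- function(samples, length_ms = 300, hop_ms = 50) {
  if (hop_ms <= 0 || length_ms < hop_ms)
    stop("require length_ms >= hop_ms > 0")
  n <- nrow(samples)
  if (n < 2L) return(list(idx = matrix(integer(0), 0, 0), t_end = numeric(0)))
  dt <- stats::median(diff(samples$t_s))
  n_samp <- round(length_ms / 1000 / dt)
  if (n_samp < 1L || n < n_samp)
    return(list(idx = matrix(integer(0), 0, max(n_samp, 0)),
                t_end = numeric(0)))
  hop_samp <- hop_ms / 1000 / dt          # may be fractional
  starts <- seq(1, n - n_samp + 1, by = hop_samp)
  starts <- unique(as.integer(floor(starts)))
  idx <- outer(starts, 0:(n_samp - 1), "+")
  list(idx = idx, t_end = samples$t_s[idx[, n_samp]] + dt)
}

# ---- features ---------------------------------------------------------------

#' Names of the 18 wearable features, in declared order
#'
#' Axis-major ordering: the six features of axis x, then y, then z. Per
#' axis: mean (g), energy (mean square, g^2), dynamic variation (standard
#' deviation of the mean-removed window, g), static variation (absolute
#' deviation of the window mean from the calibration baseline, g),
#' kurtosis (excess), skewness (Fisher-Pearson g1).
#'
#' @return Character vector of length 18.
#' @export
wearable_feature_names <- function() {
  as.vector(t(outer(c("x", "y", "z"),
                    c("mean", "energy", "dyn_var", "stat_var",
                      "kurtosis", "skewness"),
                    function(a, f) paste(a, f, sep = "_"))))
}

# feature block for one axis: columns mean, energy, dyn_var, stat_var,
# kurtosis, skewness; X is n_win x n_samp matrix of window values
axis_features <- function(X, baseline) {
  n <- ncol(X)
  mu <- rowMeans(X)
  energy <- rowMeans(X^2)
  cent <- X - mu
  m2 <- rowMeans(cent^2)
  sd_pop <- sqrt(m2)
  m3 <- rowMeans(cent^3)
  m4 <- rowMeans(cent^4)
  ok <- sd_pop >= 1e-8   # degenerate-window guard
  skew <- ifelse(ok, m3 / m2^1.5, 0)
  kurt <- ifelse(ok, m4 / m2^2 - 3, 0)
  cbind(mean = mu, energy = energy, dyn_var = sd_pop,
        stat_var = abs(mu - baseline), kurtosis = kurt, skewness = skew)
}

#' Extract the 18 wearable features of one window
#'
#' Per axis: mean, energy (mean square), dynamic variation (population
#' standard deviation of the mean-removed window), static variation
#' (absolute deviation of the window mean from the calibration baseline),
#' excess kurtosis and Fisher-Pearson skewness (both 0 when the per-axis
#' standard deviation is below 1e-8 g).
#'
#' @param window An [accel_stream()] slice of at least 3 samples.
#' @param calibration A successful [calibrate_accel()] result.
#' @return Named numeric vector of length 18 in [wearable_feature_names()]
#'   order.
#' @export
extract_features <- function(window, calibration) {
  if (!isTRUE(calibration$ok))
    stop("calibration failed; feature extraction blocked")
  if (nrow(window) < 3L) stop("window must contain at least 3 samples")
  m <- rbind(
    axis_features(matrix(window$ax_g, 1), calibration$baseline[["x"]]),
    axis_features(matrix(window$ay_g, 1), calibration$baseline[["y"]]),
    axis_features(matrix(window$az_g, 1), calibration$baseline[["z"]]))
  v <- as.vector(t(m))
  names(v) <- wearable_feature_names()
  v
}

#' Windowed wearable feature matrix of a whole stream
#'
#' Pre-processes the stream, segments it into sliding windows and extracts
#' the 18 features of every window.
#'
#' @param samples An [accel_stream()].
#' @param calibration A successful [calibrate_accel()] result.
#' @param length_ms,hop_ms Window geometry, see [make_windows()].
#' @param preprocess Apply the FIR low-pass first (default TRUE).
#' @return List with `features` (n_win x 18 matrix), `t_end` (window end
#'   times).
#' @export
wearable_features <- function(samples, calibration, length_ms = 300,
                              hop_ms = 50, preprocess = TRUE) {
  if (!isTRUE(calibration$ok))
    stop("calibration failed; feature extraction blocked")
  if (preprocess) samples <- preprocess_accel(samples)
  w <- make_windows(samples, length_ms, hop_ms)
  if (nrow(w$idx) == 0L)
    return(list(features = matrix(numeric(0), 0, 18,
                                  dimnames = list(NULL, wearable_feature_names())),
                t_end = numeric(0)))
  f <- cbind(
    axis_features(matrix(samples$ax_g[w$idx], nrow(w$idx)),
                  calibration$baseline[["x"]]),
    axis_features(matrix(samples$ay_g[w$idx], nrow(w$idx)),
                  calibration$baseline[["y"]]),
    axis_features(matrix(samples$az_g[w$idx], nrow(w$idx)),
                  calibration$baseline[["z"]]))
  colnames(f) <- wearable_feature_names()
  list(features = f, t_end = w$t_end)
}

#' Reduce window-level labels to 1 Hz classification ticks
#'
#' One tick per second; the tick label is the majority vote among windows
#' whose end time falls in that second, ties broken in favour of the most
#' recent window's label. Seconds without any window produce no tick.
#'
#' @param t_end Window end times (s), ordered.
#' @param labels Window labels (character), same length.
#' @param dt Tick duration (s), default 1.
#' @return A [tick_stream()].
#' @export
ticks_from_windows <- function(t_end, labels, dt = 1) {
  if (length(t_end) != length(labels)) stop("lengths differ")
  if (length(t_end) == 0L) return(tick_stream(numeric(0), character(0)))
  if (is.unsorted(t_end)) stop("window labels must be ordered by time")
  sec <- floor(t_end / dt - 1e-9)
  out_t <- sort(unique(sec))
  lab <- vapply(out_t, function(s) {
    li <- labels[sec == s]
    tab <- table(li)
    win <- names(tab)[tab == max(tab)]
    if (length(win) == 1L) win else {
      recent <- li[length(li):1]
      recent[recent %in% win][1]   # tie: most recent window's label
    }
  }, character(1))
  tick_stream(out_t * dt, lab, dt)
}
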