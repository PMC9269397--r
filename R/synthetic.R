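#' Simulation configuration
#'
#' Parameters of the synthetic sensor generators: an 848x480-class depth
#' camera on a 1.43 m tripod with ~1% depth error, a 50 Hz chest-worn
#' accelerometer, and occlusion episodes emulating furniture between the
#' camera and a seated subject.
#'
#' @param intrinsics A [camera_intrinsics()] (defaults fx=fy=600, cx=424,
#'   cy=240, approximating an 848x480 depth stream).
#' @param camera_height Camera height above the floor (m).
#' @param subject_depth Nominal subject distance from the camera (m).
#' @param depth_noise Multiplicative depth noise fraction (default 0.01).
#' @param pixel_noise Landmark pixel jitter standard deviation (px).
#' @param tremor_scale Multiplier on the per-class accelerometer tremor
#'   standard deviations (1 = nominal, 0 = noise-free).
#' @param occlusion_rate Per-second probability that an occlusion episode
#'   starts (1 = continuous occlusion).
#' @param occlusion_duration Episode duration (s).
#' @param occlusion_landmarks 0-based landmark indices hidden during an
#'   episode (default hips and knees, 23-26).
#' @param occlusion_classes Activities subject to occlusion (default
#'   sitting, emulating a chair behind a desk).
#' @param accel_rate Accelerometer sampling rate (Hz).
#' @param frame_rate Camera frame rate (Hz).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(intrinsics = camera_intrinsics(),
                       camera_height = 1.43, subject_depth = 3.0,
                       depth_noise = 0.01, pixel_noise = 0.5,
                       tremor_scale = 1,
                       occlusion_rate = 0.02, occlusion_duration = 3,
                       occlusion_landmarks = c(23, 24, 25, 26),
                       occlusion_classes = "sitting",
                       accel_rate = 50, frame_rate = 30) {
  if (accel_rate <= 0 || frame_rate <= 0) stop("rates must be positive")
  if (depth_noise < 0 || pixel_noise < 0 || tremor_scale < 0)
    stop("noise levels must be non-negative")
  structure(list(intrinsics = intrinsics, camera_height = camera_height,
                 subject_depth = subject_depth, depth_noise = depth_noise,
                 pixel_noise = pixel_noise, tremor_scale = tremor_scale,
                 occlusion_rate = occlusion_rate,
                 occlusion_duration = occlusion_duration,
                 occlusion_landmarks = occlusion_landmarks,
                 occlusion_classes = occlusion_classes,
                 accel_rate = accel_rate, frame_rate = frame_rate),
            class = "sim_config")
}

#' Accelerometer signal model per activity class
#'
#' Mean chest orientation (g), tremor noise standard deviation (g) and,
#' for walking classes, step frequency (Hz) and oscillation amplitude (g).
#' Static classes have zero oscillation; walking oscillation amplitude
#' strictly increases with the speed band (0.05 / 0.12 / 0.25 g at
#' 1.2 / 1.6 / 1.9 Hz). Standing and sitting differ only by a 7 degree
#' trunk-pitch offset, keeping them genuinely confusable for the wearable
#' branch.
#'
#' @return A data.frame, one row per activity class.
#' @export
accel_class_models <- function() {
  deg <- function(d) d * pi / 180
  pitch <- c(standing = 0, sitting = 7, bending = 50, lying = 87,
             walk_very_low = 3, walk_low = 7, walk_medium = 12)
  data.frame(
    label = activity_classes(),
    mx = 0,
    my = cos(deg(pitch[activity_classes()])),
    mz = sin(deg(pitch[activity_classes()])),
    tremor = c(0.015, 0.015, 0.02, 0.015, 0.03, 0.03, 0.03),
    step_hz = c(0, 0, 0, 0, 1.2, 1.6, 1.9),
    osc_g = c(0, 0, 0, 0, 0.05, 0.12, 0.25),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Generate a synthetic accelerometer stream for one activity
#'
#' Mean orientation per the class model plus Gaussian tremor; walking
#' classes add a sinusoidal oscillation at the class step frequency
#' (phase drawn from the seed) on the trunk axis, with a weaker
#' quadrature component on the anterior axis. Output is clipped to the
#' +/- 2 g full scale.
#'
#' @param activity One of the seven activity labels.
#' @param duration Duration in seconds (> 0).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param t0 Time of the first sample (s).
#' @return An [accel_stream()] at `config$accel_rate` Hz.
#' @export
gen_accel <- function(activity, duration, config = sim_config(), seed = 1,
                      t0 = 0) {
  stopifnot_scalar_num(duration, "duration", 0, strict = TRUE)
  mod <- accel_class_models()
  row <- mod[mod$label == activity, ]
  if (nrow(row) != 1L) stop("unknown activity label: ", activity)
  fs <- config$accel_rate
  n <- round(duration * fs)
  t <- t0 + (seq_len(n) - 1) / fs
  sd <- row$tremor * config$tremor_scale
  with_seed(seed, {
    ax <- row$mx + stats::rnorm(n, 0, sd)
    ay <- row$my + stats::rnorm(n, 0, sd)
    az <- row$mz + stats::rnorm(n, 0, sd)
    if (row$osc_g > 0) {
      phi <- stats::runif(1, 0, 2 * pi)
      ph <- 2 * pi * row$step_hz * (t - t0) + phi
      ay <- ay + row$osc_g * sin(ph)
      az <- az + 0.4 * row$osc_g * sin(ph + 0.7)
    }
    accel_stream(t, pmin(pmax(ax, -2), 2), pmin(pmax(ay, -2), 2),
                 pmin(pmax(az, -2), 2))
  })
}

# ---- skeleton templates -----------------------------------------------------

# gait parameters per walking class: trunk lean (deg), vertical bob
# amplitude (m), per-knee lift amplitude (m), nominal speed (band
# midpoint, km/h)
gait_params <- function() {
  data.frame(label = c("walk_very_low", "walk_low", "walk_medium"),
             lean_deg = c(3, 7, 12),
             bob_m = c(0.015, 0.035, 0.065),
             lift_m = c(0.03, 0.07, 0.12),
             speed_kmh = c(0.75, 2.25, 3.75),
             stringsAsFactors = FALSE)
}

#' Body-frame skeleton template of an activity
#'
#' 33 pose landmarks in a body frame scaled by stature: x lateral (left
#' positive), y vertical up from the floor, z anterior. Walking classes
#' share the standing template with a speed-dependent forward trunk lean;
#' their time-varying gait components (vertical bob, knee lift) are added
#' by [gen_landmarks()].
#'
#' @param activity One of the seven activity labels.
#' @param stature Subject stature in m.
#' @return 33 x 3 matrix (metres), rows in the 0-32 landmark order.
#' @export
skeleton_template <- function(activity, stature = 1.7) {
  s <- stature
  # standing base: per-landmark (height fraction, lateral half-offset
  # fraction, anterior fraction); left landmarks get +x, right -x
  h <- c(0.92, 0.96, 0.96, 0.96, 0.96, 0.96, 0.96, 0.93, 0.93, 0.90, 0.90,
         0.82, 0.82, 0.63, 0.63, 0.45, 0.45, 0.42, 0.42, 0.42, 0.42, 0.42,
         0.42, 0.53, 0.53, 0.28, 0.28, 0.04, 0.04, 0.00, 0.00, 0.02, 0.02)
  lat <- c(0.00, 0.03, 0.04, 0.05, -0.03, -0.04, -0.05, 0.06, -0.06,
           0.02, -0.02, 0.11, -0.11, 0.14, -0.14, 0.15, -0.15,
           0.16, -0.16, 0.17, -0.17, 0.16, -0.16, 0.09, -0.09,
           0.06, -0.06, 0.06, -0.06, 0.05, -0.05, 0.06, -0.06)
  ant <- c(0.05, 0.04, 0.04, 0.04, 0.04, 0.04, 0.04, 0.00, 0.00,
           0.04, 0.04, rep(0.00, 12), 0.00, 0.00, 0.01, 0.01,
           0.00, 0.00, -0.01, -0.01, 0.06, 0.06)
  B <- cbind(x = lat * s, y = h * s, z = ant * s)
  trunk <- 1:23                      # rows for landmarks 0-22
  hip_y <- 0.53 * s
  lean <- function(B, deg) {        # rotate trunk forward about the hip line
    th <- deg * pi / 180
    dy <- B[trunk, 2] - hip_y
    B[trunk, 2] <- hip_y + dy * cos(th)
    B[trunk, 3] <- B[trunk, 3] + dy * sin(th)
    B
  }
  gp <- gait_params()
  if (activity %in% gp$label)
    return(lean(B, gp$lean_deg[gp$label == activity]))
  switch(activity,
    standing = B,
    bending = lean(B, 65),
    sitting = {
      B[trunk, 2] <- B[trunk, 2] - 0.27 * s        # pelvis drops to a chair
      B[24:25, 2] <- 0.26 * s                      # hips on the seat
      B[26:27, 2] <- 0.26 * s; B[26:27, 3] <- 0.24 * s   # knees forward
      B[28:29, 2] <- 0.04 * s; B[28:29, 3] <- 0.26 * s   # ankles below knees
      B[30:31, 2] <- 0.00;     B[30:31, 3] <- 0.24 * s
      B[32:33, 2] <- 0.02 * s; B[32:33, 3] <- 0.32 * s
      B
    },
    lying = {
      # supine on a 0.18 m bed: longitudinal axis maps to lateral x
      out <- cbind(x = B[, 2] - 0.5 * s,
                   y = 0.18 + B[, 3] + 0.02,
                   z = B[, 1] * 0.3)
      out
    },
    stop("unknown activity label: ", activity))
}

#' Generate a synthetic landmark stream for one activity
#'
#' Poses the class template in the world, adds gait motion for walking
#' classes (ping-pong translation across the field of view at the band's
#' nominal speed, vertical bob at twice the step frequency, alternating
#' knee lift), projects through the pinhole camera and corrupts the
#' result with pixel jitter and multiplicative depth noise. Occlusion
#' episodes mark the configured landmarks invisible.
#'
#' @param activity One of the seven activity labels.
#' @param duration Duration in seconds (> 0).
#' @param subject A [subject_profile()] (stature scales the template).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param t0 Time of the first frame (s).
#' @return A [landmark_stream()] at `config$frame_rate` Hz.
#' @export
gen_landmarks <- function(activity, duration, subject, config = sim_config(),
                          seed = 1, t0 = 0) {
  stopifnot_scalar_num(duration, "duration", 0, strict = TRUE)
  if (!activity %in% activity_classes())
    stop("unknown activity label: ", activity)
  s <- subject$height
  B <- skeleton_template(activity, s)
  fr <- config$frame_rate
  n <- round(duration * fr)
  t_rel <- (seq_len(n) - 1) / fr
  K <- config$intrinsics
  gp <- gait_params()
  walking <- activity %in% gp$label
  with_seed(seed, {
    # world-frame landmark coordinates, n x 33 per component
    Xw <- matrix(B[, 1], n, 33, byrow = TRUE)
    Yw <- matrix(B[, 2], n, 33, byrow = TRUE)
    Zb <- matrix(B[, 3], n, 33, byrow = TRUE)  # body anterior component
    d0 <- config$subject_depth + stats::runif(1, -0.3, 0.3)
    if (walking) {
      g <- gp[gp$label == activity, ]
      f <- accel_class_models()
      f <- f$step_hz[f$label == activity]
      v <- g$speed_kmh / 3.6
      xmax <- 0.8 * K$cx / K$fx * d0
      # triangle-wave (ping-pong) walk across the field of view
      x0 <- stats::runif(1, -xmax, xmax)
      dir0 <- sample(c(-1, 1), 1)
      pos <- (x0 + xmax) + dir0 * v * t_rel
      period <- 2 * 2 * xmax
      posm <- pos %% period
      posm <- ifelse(posm < 0, posm + period, posm)
      xpos <- ifelse(posm <= 2 * xmax, posm, 2 * period / 2 - posm) - xmax
      dir <- ifelse(posm <= 2 * xmax, 1, -1) * 1
      phi <- stats::runif(1, 0, 2 * pi)
      ph <- 2 * pi * f * t_rel + phi
      bob <- g$bob_m * sin(2 * ph)
      # anterior axis along the walking direction; lateral axis along depth
      Xc <- xpos + dir * Zb
      Zc <- d0 + dir * Xw
      Yw <- Yw + bob
      liftL <- g$lift_m * pmax(0, sin(ph))
      liftR <- g$lift_m * pmax(0, sin(ph + pi))
      left_leg <- c(26, 28, 30, 32); right_leg <- c(27, 29, 31, 33)
      Yw[, left_leg] <- Yw[, left_leg] + liftL
      Yw[, right_leg] <- Yw[, right_leg] + liftR
      Yc <- config$camera_height - Yw
    } else {
      xpos <- stats::runif(1, -0.3, 0.3)
      Xc <- Xw + xpos
      Zc <- d0 - Zb                        # subject faces the camera
      Yc <- config$camera_height - Yw
    }
    if (all(Zc <= 0.1)) stop("subject behind the camera")
    P_u <- K$fx * Xc / Zc + K$cx
    P_v <- K$fy * Yc / Zc + K$cy
    if (n > 0) {
      hip_u <- (P_u[, 24] + P_u[, 25]) / 2
      if (all(hip_u < 0 | hip_u > 2 * K$cx))
        stop("subject outside the camera field of view for the entire duration")
    }
    u <- P_u + matrix(stats::rnorm(n * 33, 0, config$pixel_noise), n, 33)
    v <- P_v + matrix(stats::rnorm(n * 33, 0, config$pixel_noise), n, 33)
    depth <- Zc * (1 + matrix(stats::rnorm(n * 33, 0, config$depth_noise),
                              n, 33))
    visible <- matrix(TRUE, n, 33)
    if (activity %in% config$occlusion_classes && config$occlusion_rate > 0 &&
        n > 0) {
      occ <- rep(FALSE, n)
      starts <- which(stats::runif(ceiling(duration)) < config$occlusion_rate)
      for (st in starts) {
        i0 <- floor((st - 1) * fr) + 1
        i1 <- min(n, ceiling((st - 1 + config$occlusion_duration) * fr))
        occ[i0:i1] <- TRUE
      }
      visible[occ, config$occlusion_landmarks + 1L] <- FALSE
    }
    landmark_stream(t0 + t_rel, u, v, depth, visible)
  })
}

# ---- protocol execution -----------------------------------------------------

#' Simulate one protocol execution by one subject
#'
#' Concatenates per-segment accelerometer and landmark generator output
#' on a shared clock and attaches per-second ground-truth labels.
#'
#' @param protocol A [protocol()].
#' @param subject A [subject_profile()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return An object of class `multimodal_stream`: list with `accel`
#'   ([accel_stream()]), `frames` ([landmark_stream()]), `labels`
#'   (ground-truth [tick_stream()]), `subject`, `protocol`, `config`,
#'   `seed`.
#' @export
run_protocol <- function(protocol, subject, config = sim_config(), seed = 1) {
  seg <- protocol$segments
  acc <- vector("list", nrow(seg)); lmk <- vector("list", nrow(seg))
  t0 <- 0
  for (k in seq_len(nrow(seg))) {
    acc[[k]] <- gen_accel(seg$activity[k], seg$duration_s[k], config,
                          seed = child_seed(seed, k), t0 = t0)
    lmk[[k]] <- gen_landmarks(seg$activity[k], seg$duration_s[k], subject,
                              config, seed = child_seed(seed, 100 + k),
                              t0 = t0)
    t0 <- t0 + seg$duration_s[k]
  }
  accel <- do.call(rbind, lapply(acc, as.data.frame))
  accel <- accel_stream(accel$t_s, accel$ax_g, accel$ay_g, accel$az_g)
  frames <- landmark_stream(
    unlist(lapply(lmk, `[[`, "t")),
    do.call(rbind, lapply(lmk, `[[`, "u")),
    do.call(rbind, lapply(lmk, `[[`, "v")),
    do.call(rbind, lapply(lmk, `[[`, "depth")),
    do.call(rbind, lapply(lmk, `[[`, "visible")))
  structure(list(accel = accel, frames = frames,
                 labels = protocol_ticks(protocol),
                 subject = subject, protocol = protocol, config = config,
                 seed = seed),
            class = "multimodal_stream")
}

#' @export
print.multimodal_stream <- function(x, ...) {
  cat(sprintf("Multimodal stream: '%s' by subject %s -- %d accel samples, %d frames, %d s\n",
              x$protocol$name, x$subject$id, nrow(x$accel),
              length(x$frames$t), protocol_duration(x$protocol)))
  invisible(x)
}

# ---- training corpus --------------------------------------------------------

#' Generate an aligned labelled training corpus
#'
#' Simulates several short bouts per activity class (each with a fresh
#' subject stature drawn from 1.50-1.90 m and fresh starting position,
#' walking direction and gait phase), runs both feature pipelines and
#' returns exactly `n_per_class` aligned wearable/ambient/fused feature
#' vectors per class. The bout count keeps nuisance factors (stature,
#' position in the walking path, phase) decorrelated from the class
#' label. Occlusion is disabled so every fused vector is complete.
#'
#' @param n_per_class Vectors per class (>= 10).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param n_bouts Bouts per class (default 12).
#' @return A list of class `har_corpus`: `wearable` (n x 18), `ambient`
#'   (n x 10), `fused` (n x 28), `labels`, `seed`.
#' @export
gen_training_corpus <- function(n_per_class = 100, config = sim_config(),
                                seed = 1, n_bouts = 12) {
  if (n_per_class < 10) stop("'n_per_class' must be at least 10")
  config$occlusion_rate <- 0
  classes <- activity_classes()
  # ideal-wear calibration from a synthetic standing bout
  cal <- calibrate_accel(gen_accel("standing", 31, config,
                                   seed = child_seed(seed, 7777)))
  W <- list(); A <- list(); lab <- character(0)
  per_bout <- ceiling(n_per_class / n_bouts)
  dur <- per_bout / 20 + 1.0         # ~20 windows per second plus margin
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    got_w <- NULL; got_a <- NULL
    for (b in seq_len(n_bouts)) {
      sk <- child_seed(seed, ci * 1000 + b)
      stature <- with_seed(child_seed(sk, 1), stats::runif(1, 1.5, 1.9))
      subj <- subject_profile(sprintf("sim_%s_%d", cl, b),
                              weight = 70, height = stature)
      accel <- gen_accel(cl, dur, config, seed = child_seed(sk, 2))
      frames <- gen_landmarks(cl, dur, subj, config, seed = child_seed(sk, 3))
      wf <- wearable_features(accel, cal)
      af <- ambient_features(frames, subj$height, config$intrinsics)
      fidx <- round(wf$t_end * config$frame_rate)
      fidx <- pmin(pmax(fidx, 1L), length(af$t))
      keep <- !is.na(af$features[fidx, 1])
      got_w <- rbind(got_w, wf$features[keep, , drop = FALSE])
      got_a <- rbind(got_a, af$features[fidx[keep], , drop = FALSE])
    }
    take <- round(seq(1, nrow(got_w), length.out = n_per_class))
    W[[ci]] <- got_w[take, , drop = FALSE]
    A[[ci]] <- got_a[take, , drop = FALSE]
    lab <- c(lab, rep(cl, n_per_class))
  }
  W <- do.call(rbind, W); A <- do.call(rbind, A)
  structure(list(wearable = W, ambient = A, fused = fuse_features(W, A),
                 labels = lab, seed = seed),
            class = "har_corpus")
}

#' @export
print.har_corpus <- function(x, ...) {
  cat(sprintf("Training corpus: %d labelled vectors (%d per class), 18+10=28 features\n",
              length(x$labels), length(x$labels) / length(unique(x$labels))))
  invisible(x)
}

#' Window-level fused corpus of a protocol execution
#'
#' Extracts aligned fused feature vectors from a simulated protocol
#' execution, labelling every wearable window with the protocol's
#' ground-truth activity at the window end. Windows whose ambient frame
#' is occluded are dropped.
#'
#' @param stream A [run_protocol()] stream.
#' @param calibration Optional [calibrate_accel()] result (default: a
#'   synthetic standing calibration bout).
#' @return List with `fused`, `wearable`, `ambient` matrices, `labels`,
#'   `t_end`.
#' @export
protocol_corpus <- function(stream, calibration = NULL) {
  cfg <- stream$config
  if (is.null(calibration)) {
    cal_stream <- gen_accel("standing", 31, cfg,
                            seed = child_seed(stream$seed, 99))
    calibration <- calibrate_accel(cal_stream)
  }
  wf <- wearable_features(stream$accel, calibration)
  af <- ambient_features(stream$frames, stream$subject$height, cfg$intrinsics)
  fidx <- round(wf$t_end * cfg$frame_rate)
  fidx <- pmin(pmax(fidx, 1L), length(af$t))
  keep <- !is.na(af$features[fidx, 1])
  truth <- protocol_labels(stream$protocol)
  sec <- pmin(floor(wf$t_end - 1e-9), length(truth) - 1) + 1
  W <- wf$features[keep, , drop = FALSE]
  A <- af$features[fidx[keep], , drop = FALSE]
  list(fused = fuse_features(W, A), wearable = W, ambient = A,
       labels = truth[sec[keep]], t_end = wf$t_end[keep])
}

#' Write a simulated session to disk
#'
#' Writes the accelerometer CSV, landmark JSON-lines (+ intrinsics
#' sidecar), ground-truth labels CSV and a manifest JSON capturing the
#' configuration and seed.
#'
#' @param stream A [run_protocol()] stream.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(stream, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_accel(stream$accel, file.path(dir, "accel.csv"))
  write_landmarks(stream$frames, file.path(dir, "landmarks.jsonl"),
                  K = stream$config$intrinsics,
                  intrinsics_path = file.path(dir, "intrinsics.json"))
  write_ticks(stream$labels, file.path(dir, "labels.csv"))
  cfg <- stream$config
  manifest <- list(protocol = stream$protocol$name,
                   subject = stream$subject[c("id", "weight", "height")],
                   seed = stream$seed,
                   config = cfg[setdiff(names(cfg), "intrinsics")],
                   intrinsics = cfg$intrinsics[c("fx", "fy", "cx", "cy")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
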