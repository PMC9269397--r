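#' Pinhole camera intrinsics
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx = 600, fy = 600, cx = 424, cy = 240) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("Camera intrinsics: fx=%.1f fy=%.1f cx=%.1f cy=%.1f px\n",
              x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

#' Deproject a pixel + depth record to a 3D point
#'
#' Pinhole back-projection into the camera frame (x right, y down,
#' z forward): `x = (u - cx) * depth / fx`, `y = (v - cy) * depth / fy`,
#' `z = depth`. Vectorised over `u`, `v`, `depth`. A non-positive depth is
#' a missing-depth signal: the point is returned as NA (invisible), not an
#' error.
#'
#' @param u,v Pixel coordinates.
#' @param depth Depth in metres.
#' @param K A [camera_intrinsics()].
#' @return A matrix with columns `x`, `y`, `z` (metres); rows with
#'   `depth <= 0` are NA.
#' @export
#' @examples
#' deproject(424, 240, 2, camera_intrinsics())  # (0, 0, 2)
deproject <- function(u, v, depth, K = camera_intrinsics()) {
  bad <- !is.finite(depth) | depth <= 0
  x <- (u - K$cx) * depth / K$fx
  y <- (v - K$cy) * depth / K$fy
  z <- depth
  x[bad] <- NA_real_; y[bad] <- NA_real_; z[bad] <- NA_real_
  cbind(x = x, y = y, z = z)
}

#' Project a 3D camera-frame point to pixel + depth
#'
#' Inverse of [deproject()]; used by the synthetic landmark generator.
#'
#' @param xyz Matrix (or length-3 vector) of camera-frame coordinates (m),
#'   z > 0.
#' @param K A [camera_intrinsics()].
#' @return Matrix with columns `u`, `v`, `depth`.
#' @export
project <- function(xyz, K = camera_intrinsics()) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  cbind(u = K$fx * xyz[, 1] / xyz[, 3] + K$cx,
        v = K$fy * xyz[, 2] / xyz[, 3] + K$cy,
        depth = xyz[, 3])
}

#' Construct a landmark stream
#'
#' Per-frame records of the 33 pose landmarks (indexed 0-32 in the
#' BlazePose convention) as pixel coordinates with per-landmark depth and
#' a visibility flag.
#'
#' @param t Frame times (s), ordered.
#' @param u,v Numeric n x 33 matrices of pixel coordinates.
#' @param depth Numeric n x 33 matrix of depths (m).
#' @param visible Logical n x 33 matrix.
#' @return An object of class `landmark_stream`.
#' @export
landmark_stream <- function(t, u, v, depth, visible) {
  n <- length(t)
  for (m in list(u, v, depth, visible))
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 33L)
      stop("u, v, depth, visible must be n x 33 matrices")
  if (n > 1L && any(diff(t) <= 0)) stop("frames must be ordered by time")
  structure(list(t = as.numeric(t), u = u, v = v, depth = depth,
                 visible = visible), class = "landmark_stream")
}

#' @export
print.landmark_stream <- function(x, ...) {
  cat(sprintf("Landmark stream: %d frames x 33 landmarks, %.1f s\n",
              length(x$t), if (length(x$t)) diff(range(x$t)) else 0))
  invisible(x)
}

#' Extract one frame of a landmark stream as 3D points
#'
#' @param stream A [landmark_stream()].
#' @param i Frame index (1-based).
#' @param K A [camera_intrinsics()].
#' @return 33 x 3 matrix of camera-frame coordinates; invisible or
#'   depth-missing landmarks are NA rows.
#' @export
frame3d <- function(stream, i, K = camera_intrinsics()) {
  p <- deproject(stream$u[i, ], stream$v[i, ], stream$depth[i, ], K)
  p[!stream$visible[i, ], ] <- NA_real_
  p
}

# landmark index pairs (0-based) whose midpoints form the feature set:
# A = mouth corners (9, 10), C = hips (23, 24), D = knees (25, 26)
.pairs_ACD <- list(A = c(9, 10), C = c(23, 24), D = c(25, 26))

#' Names of the 10 ambient features, in declared order
#'
#' Midpoint A (mouth), midpoint C (hips), midpoint D (knees), each as
#' camera-frame x, y, z in metres, followed by the subject height (m).
#'
#' @return Character vector of length 10.
#' @export
ambient_feature_names <- function() {
  c(t(outer(c("A", "C", "D"), c("x", "y", "z"), paste0)), "height")
}

#' Occlusion condition
#'
#' Error signalled by [reduce_landmarks()] when a required landmark pair
#' is invisible; carries the missing 0-based indices in `$indices`.
#'
#' @param indices Missing landmark indices (0-based).
#' @return A condition object of class `occlusion_error`.
#' @export
occlusion_error <- function(indices) {
  structure(class = c("occlusion_error", "error", "condition"),
            list(message = paste("required landmarks occluded:",
                                 paste(indices, collapse = ", ")),
                 call = NULL, indices = indices))
}

#' Reduce a 33-landmark 3D frame to the 10-feature ambient vector
#'
#' Computes the coordinate-wise midpoints of the mouth pair (9, 10), hip
#' pair (23, 24) and knee pair (25, 26) and appends the subject height.
#'
#' @param frame 33 x 3 matrix of camera-frame landmark coordinates
#'   (metres); occluded landmarks as NA rows.
#' @param height Subject height in metres.
#' @return Named numeric vector of length 10 in [ambient_feature_names()]
#'   order.
#' @section Errors: signals an [occlusion_error()] naming the missing
#'   indices when any required landmark is NA.
#' @export
reduce_landmarks <- function(frame, height) {
  need <- unlist(.pairs_ACD)
  miss <- need[!stats::complete.cases(frame[need + 1L, , drop = FALSE])]
  if (length(miss)) stop(occlusion_error(sort(unname(miss))))
  v <- unlist(lapply(.pairs_ACD, function(p)
    colMeans(frame[p + 1L, , drop = FALSE])))
  v <- c(v, height)
  names(v) <- ambient_feature_names()
  v
}

#' Estimate subject stature from a standing frame
#'
#' Vertical extent (max minus min along the gravity-aligned axis) of the
#' visible landmarks. With the default camera convention (y down) the
#' vertical world coordinate is `-y`.
#'
#' @param frame 33 x 3 matrix of camera-frame landmark coordinates.
#' @param up Length-3 unit vector pointing up in the camera frame
#'   (default `c(0, -1, 0)`).
#' @return Estimated stature in metres.
#' @export
estimate_height <- function(frame, up = c(0, -1, 0)) {
  vert <- as.matrix(frame) %*% up
  vert <- vert[is.finite(vert)]
  if (length(vert) < 2L) stop("need at least 2 visible landmarks")
  max(vert) - min(vert)
}

#' Per-frame ambient feature matrix of a whole stream
#'
#' Deprojects every frame and reduces it to the 10-feature vector.
#' Frames whose required landmark pairs are occluded yield NA rows
#' instead of raising, so the fusion stage can fall back to the wearable
#' branch for those seconds.
#'
#' @param stream A [landmark_stream()].
#' @param height Subject height in metres (profile value or
#'   [estimate_height()] output).
#' @param K A [camera_intrinsics()].
#' @return List with `features` (n x 10 matrix, NA rows where occluded)
#'   and `t` (frame times).
#' @export
ambient_features <- function(stream, height, K = camera_intrinsics()) {
  need <- unlist(.pairs_ACD) + 1L
  n <- length(stream$t)
  out <- matrix(NA_real_, n, 10, dimnames = list(NULL, ambient_feature_names()))
  if (n == 0L) return(list(features = out, t = stream$t))
  # vectorised over frames: deproject only the six required landmarks
  for (j in seq_along(.pairs_ACD)) {
    p <- .pairs_ACD[[j]] + 1L
    d1 <- ifelse(stream$visible[, p[1]], stream$depth[, p[1]], NA_real_)
    d2 <- ifelse(stream$visible[, p[2]], stream$depth[, p[2]], NA_real_)
    p1 <- deproject(stream$u[, p[1]], stream$v[, p[1]], d1, K)
    p2 <- deproject(stream$u[, p[2]], stream$v[, p[2]], d2, K)
    out[, (j - 1) * 3 + 1:3] <- (p1 + p2) / 2
  }
  out[, 10] <- height
  out[!stats::complete.cases(out), ] <- NA_real_
  list(features = out, t = stream$t)
}

# ---- landmark stream I/O ----------------------------------------------------

#' Write / read a landmark stream as JSON-lines
#'
#' One frame per line: `{"t_s": ..., "landmarks": [[u,v,depth,visible] x 33]}`.
#' Camera intrinsics go to a sidecar JSON `{fx, fy, cx, cy}`.
#'
#' @param stream A [landmark_stream()].
#' @param path Output path for the JSON-lines file.
#' @param K A [camera_intrinsics()]; written to `intrinsics_path` if given.
#' @param intrinsics_path Optional sidecar path.
#' @export
write_landmarks <- function(stream, path, K = NULL, intrinsics_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(stream$t)) {
    lm <- cbind(stream$u[i, ], stream$v[i, ], stream$depth[i, ],
                as.numeric(stream$visible[i, ]))
    rec <- list(t_s = stream$t[i],
                landmarks = lapply(seq_len(33), function(k) unname(lm[k, ])))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  if (!is.null(K) && !is.null(intrinsics_path))
    jsonlite::write_json(K[c("fx", "fy", "cx", "cy")], intrinsics_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  t <- numeric(n)
  u <- v <- d <- matrix(NA_real_, n, 33)
  vis <- matrix(FALSE, n, 33)
  for (i in seq_len(n)) {
    rec <- jsonlite::fromJSON(lines[i], simplifyMatrix = TRUE)
    t[i] <- rec$t_s
    lm <- rec$landmarks
    u[i, ] <- lm[, 1]; v[i, ] <- lm[, 2]; d[i, ] <- lm[, 3]
    vis[i, ] <- lm[, 4] != 0
  }
  landmark_stream(t, u, v, d, vis)
}

#' @rdname write_landmarks
#' @export
read_intrinsics <- function(path) {
  k <- jsonlite::read_json(path, simplifyVector = TRUE)
  camera_intrinsics(k$fx, k$fy, k$cx, k$cy)
}
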